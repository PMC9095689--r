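# Independent point-to-triangle distance: minimize the quadratic |p - (a +
# u e1 + v e2)|^2 over the simplex by solving the unconstrained problem and,
# if infeasible, clamping along each of the three edges.
oracle_point_tri <- function(p, a, b, c) {
  e1 <- b - a; e2 <- c - a; d <- p - a
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  rhs <- c(sum(e1 * d), sum(e2 * d))
  uv <- tryCatch(solve(G, rhs), error = function(e) c(-1, -1))
  cand <- list()
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    cand <- c(cand, list(a + uv[1] * e1 + uv[2] * e2))
  }
  clamp_edge <- function(p0, p1) {
    t <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
    p0 + min(max(t, 0), 1) * (p1 - p0)
  }
  cand <- c(cand, list(clamp_edge(a, b), clamp_edge(b, c), clamp_edge(c, a)))
  sqrt(min(vapply(cand, function(q) sum((p - q)^2), numeric(1))))
}

oracle_hausdorff <- function(ma, mb) {
  one_way <- function(src, dst) {
    max(apply(src$vertices, 1L, function(p) {
      min(apply(dst$faces, 1L, function(f) {
        oracle_point_tri(p, dst$vertices[f[1], ], dst$vertices[f[2], ],
                         dst$vertices[f[3], ])
      }))
    }))
  }
  max(one_way(ma, mb), one_way(mb, ma))
}

test_that("difference maps report per-vertex distance, direction and Hausdorff", {
  tpl <- base_soleus_template(6)
  same <- mean_difference_map(tpl, tpl)
  expect_equal(same$per_vertex_mm, rep(0, nrow(tpl$vertices)))
  expect_equal(same$hausdorff_mm, 0)

  # push every vertex 0.1 mm outward along its normal: all directions +1
  nrm <- soleusshape:::vertex_normals(tpl)
  out <- surface_mesh(tpl$vertices + 0.1 * nrm, tpl$faces)
  dm <- mean_difference_map(tpl, out)
  expect_equal(dm$per_vertex_mm, rep(0.1, nrow(tpl$vertices)), tolerance = 1e-9)
  expect_true(all(dm$direction == 1L))
  inw <- surface_mesh(tpl$vertices - 0.1 * nrm, tpl$faces)
  expect_true(all(mean_difference_map(tpl, inw)$direction == -1L))

  expect_error(mean_difference_map(tpl, base_soleus_template(8)),
               class = "soleusshape_error_dimension")
})

test_that("surface Hausdorff matches a brute-force oracle on small meshes", {
  tpl <- base_soleus_template(4)          # 50 vertices
  tgt <- apply_mode_deformation(tpl, "aspect", 1.2)
  expect_equal(hausdorff_distance(tpl, tgt), oracle_hausdorff(tpl, tgt),
               tolerance = 1e-10)
  tet <- tetra_mesh()
  tet2 <- surface_mesh(tet$vertices + c(0.3, -0.2, 0.5), tet$faces)
  expect_equal(hausdorff_distance(tet, tet2), oracle_hausdorff(tet, tet2),
               tolerance = 1e-12)
  # symmetry, identity, and the vertex variant upper-bounds the surface one
  expect_equal(hausdorff_distance(tpl, tgt), hausdorff_distance(tgt, tpl))
  expect_equal(hausdorff_distance(tet, tet), 0)
  expect_gte(hausdorff_distance(tpl, tgt, method = "vertex"),
             hausdorff_distance(tpl, tgt) - 1e-12)
})

test_that("difference-map accessors produce tidy output and a plot", {
  tpl <- base_soleus_template(5)
  tgt <- apply_mode_deformation(tpl, "size", 0.5)
  dm <- mean_difference_map(tpl, tgt)
  td <- tidy(dm)
  expect_named(td, c("vertex", "x", "y", "z", "distance_mm", "direction"))
  expect_equal(nrow(td), nrow(tpl$vertices))
  expect_equal(td$distance_mm, dm$per_vertex_mm)
  expect_s3_class(autoplot(dm), "ggplot")
})

test_that("extracted weights reproduce the model's variance spectrum", {
  ch <- linear_mode_cohort(m = 25, n_coords = 45, k_modes = 3,
                           sds = c(3, 2, 1), seed = 19)
  mdl <- fit_pca(ch$vectors, k = 3)
  labs <- rep(c("A", "B"), c(13, 12))
  w <- extract_weights(mdl, ch$vectors, labs)
  expect_named(w, c("specimen_id", "label", "pc1", "pc2", "pc3"))
  # sample covariance of the scores is diagonal with the model variances
  S <- stats::cov(as.matrix(w[, c("pc1", "pc2", "pc3")]))
  expect_equal(S, diag(mdl$variances), tolerance = 1e-8, ignore_attr = TRUE)
  # scores are centred
  expect_equal(colMeans(as.matrix(w[, 3:5])), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(extract_weights(mdl, ch$vectors, labs[1:5]),
               class = "soleusshape_error_dimension")
})

test_that("Shapiro-Wilk agrees with an independent implementation", {
  res <- shapiro_wilk(as.numeric(1:10))
  # frozen values from an independent Royston implementation
  expect_equal(res$W, 0.9701646110856056, tolerance = 1e-6)
  expect_equal(res$p, 0.8923673061902978, tolerance = 1e-5)
  expect_error(shapiro_wilk(c(1, 2)), class = "soleusshape_error_parameter")
  expect_error(shapiro_wilk(rep(1, 10)), class = "soleusshape_error_degenerate")
})

test_that("Levene's mean-centred test matches frozen and package oracles", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8, 10)
  res <- levene(a, b)
  # frozen values from an independent implementation (mean centring)
  expect_equal(res$statistic, 2.4990892531876128, tolerance = 1e-9)
  expect_equal(res$p, 0.15792471098592406, tolerance = 1e-9)
  # cross-check against car::leveneTest with mean centring
  df <- data.frame(y = c(a, b),
                   g = factor(rep(c("a", "b"), c(length(a), length(b)))))
  car_res <- car::leveneTest(y ~ g, data = df, center = mean)
  expect_equal(res$statistic, car_res$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, car_res$`Pr(>F)`[1], tolerance = 1e-10)
  # hand computation: groups (1,2,3,4)/(10,20,30,40); absolute deviations
  # from the group means give SSB = 162, SSW = 101 on (1, 6) df
  h <- levene(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(h$statistic, 972 / 101, tolerance = 1e-12)
  expect_gte(h$statistic, 0)
  # identical spread in both groups: no evidence against equal variances
  expect_equal(levene(c(1, 2), c(5, 6))$p, 1)
  expect_error(levene(1, c(1, 2)), class = "soleusshape_error_parameter")
})

test_that("Holm-Bonferroni reproduces the step-down adjustment by hand", {
  hb <- holm_bonferroni(c(0.01, 0.04, 0.02))
  # sorted: 0.01*3 = 0.03, 0.02*2 = 0.04, max(0.04*1, prev) = 0.04
  expect_equal(hb$adjusted, c(0.03, 0.04, 0.04))
  expect_equal(hb$reject, c(TRUE, TRUE, TRUE))
  hb2 <- holm_bonferroni(c(0.03, 0.04), alpha = 0.05)
  expect_equal(hb2$adjusted, c(0.06, 0.06))
  expect_false(any(hb2$reject))
  expect_error(holm_bonferroni(c(0.5, 1.2)), class = "soleusshape_error_parameter")
  expect_error(holm_bonferroni(0.5, alpha = 1), class = "soleusshape_error_parameter")
})

test_that("Kruskal-Wallis reproduces the exact rank statistic", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # fully separated ranks of n = 6: H = 27/7
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_equal(res$p, 0.049534613435626915, tolerance = 1e-9)
  # interleaved identical groups carry no signal
  res2 <- kruskal_wallis(list(c(1, 3, 5), c(2, 4, 6)))
  expect_gt(res2$p, 0.5)
  expect_error(kruskal_wallis(list(1:3)), class = "soleusshape_error_parameter")
  expect_error(kruskal_wallis(list(1:2, 1:2)), class = "soleusshape_error_parameter")
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  ps <- withr::with_seed(123, vapply(1:1000, function(i) {
    x <- rnorm(20)
    kruskal_wallis(list(x[1:10], x[11:20]))$p
  }, numeric(1)))
  expect_equal(mean(ps), 0.5, tolerance = 0.05)
})

test_that("compare_groups routes PCs to the correct branch and adjusts per family", {
  withr::with_seed(42, {
    n_a <- 12; n_b <- 12
    w <- tibble::tibble(
      specimen_id = sprintf("s%03d", 1:(n_a + n_b)),
      label = rep(c("A", "B"), c(n_a, n_b)),
      pc1 = c(rnorm(n_a, 0, 1), rnorm(n_b, 3, 1)),      # t branch, large effect
      pc2 = c(rnorm(n_a, 0, 1), rnorm(n_b, 0, 1)),      # t branch, null
      pc3 = c(rnorm(n_a, 0, 0.05), rnorm(n_b, 0.5, 3))  # unequal variance -> KW
    )
  })
  res <- compare_groups(w)
  expect_equal(res$pc_index, 1:3)
  expect_equal(res$test_used[1:2], c("t_test", "t_test"))
  expect_equal(res$test_used[3], "kruskal_wallis")
  expect_lt(res$variance_equality_p[3], 0.05)
  expect_true(res$significant[1])
  expect_false(res$significant[2])
  # Holm is applied within the t family only
  sel <- res$test_used == "t_test"
  expect_equal(res$p_adjusted[sel],
               stats::p.adjust(res$p_raw[sel], method = "holm"))
  expect_equal(res$p_adjusted[!sel],
               stats::p.adjust(res$p_raw[!sel], method = "holm"))
})

test_that("compare_groups handles outliers, degenerate PCs and bad input", {
  base <- withr::with_seed(7, c(rnorm(9), rnorm(9)))
  w <- tibble::tibble(
    specimen_id = sprintf("s%03d", 1:18),
    label = rep(c("A", "B"), each = 9),
    pc1 = replace(base, 1, 50),   # s001 is a gross outlier in group A
    pc2 = rep(0, 18)              # degenerate: zero variance in both groups
  )
  res <- compare_groups(w)
  expect_true("s001" %in% res$outliers_excluded[[1]])
  expect_equal(res$test_used[2], "degenerate")
  expect_true(is.na(res$significant[2]))
  expect_match(res$note[2], "zero variance")
  # disabling the outlier rule keeps every specimen
  res_none <- compare_groups(w, outlier_rule = "none")
  expect_length(res_none$outliers_excluded[[1]], 0L)

  expect_error(compare_groups(dplyr::mutate(w, label = "A")),
               class = "soleusshape_error_parameter")
  expect_error(compare_groups(w[c(1:2, 10:18), ]),
               class = "soleusshape_error_parameter")
  expect_error(compare_groups(dplyr::select(w, specimen_id, label)),
               class = "soleusshape_error_parameter")
})
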