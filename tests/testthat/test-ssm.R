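test_that("the mean shape is the coordinate-wise average", {
  v1 <- soleusshape:::new_shape_vector(c(0, 0, 0, 3, 0, 0), 2L)
  v2 <- soleusshape:::new_shape_vector(c(2, 4, 6, 1, 2, 3), 2L)
  mu <- compute_mean(list(v1, v2))
  expect_equal(as.numeric(mu), c(1, 2, 3, 2, 1, 1.5))
  expect_equal(attr(mu, "n_vertices"), 2L)
  expect_error(compute_mean(list()), class = "soleusshape_error_parameter")
})

test_that("two-shape PCA has one mode along the difference with half squared norm", {
  v1 <- soleusshape:::new_shape_vector(c(0, 0, 0, 0, 0, 0), 2L)
  v2 <- soleusshape:::new_shape_vector(c(2, 0, 0, 0, 2, 0), 2L)
  mdl <- fit_pca(list(v1, v2), k = 1)
  expect_equal(as.numeric(mdl$mean), c(1, 0, 0, 0, 1, 0))
  # covariance divisor m - 1 = 1: variance = ||d/2||^2 * 2 / 1 = 4
  expect_equal(mdl$variances, 4)
  expect_equal(abs(as.numeric(mdl$modes)), c(1, 0, 0, 0, 1, 0) / sqrt(2))
  # sign convention: largest-magnitude entry positive
  expect_gt(max(mdl$modes), 0)
  expect_error(fit_pca(list(v1, v2), k = 2), class = "soleusshape_error_parameter")
  expect_error(fit_pca(list(v1), k = 1), class = "soleusshape_error_parameter")
})

test_that("dual (Gram) eigen route matches the direct covariance decomposition", {
  ch <- linear_mode_cohort(m = 8, n_coords = 15, k_modes = 7,
                           sds = c(3, 2.5, 2, 1.5, 1, 0.8, 0.5), seed = 21)
  mdl <- fit_pca(ch$vectors, k = 5)
  X <- sapply(ch$vectors, as.numeric)
  C <- stats::cov(t(X))                     # direct 15 x 15 covariance
  ed <- eigen(C, symmetric = TRUE)
  expect_equal(mdl$all_variances, ed$values[1:7], tolerance = 1e-10)
  for (j in 1:5) {
    # modes agree up to sign
    dot <- abs(sum(mdl$modes[, j] * ed$vectors[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  expect_equal(crossprod(mdl$modes), diag(5), tolerance = 1e-10)
})

test_that("identical training shapes give zero variance and unit reconstruction", {
  v <- soleusshape:::new_shape_vector(rnorm(12), 4L)
  mdl <- fit_pca(list(v, v, v), k = 2)
  expect_equal(mdl$variances, c(0, 0))
  expect_equal(as.numeric(mdl$mean), as.numeric(v))
  expect_equal(as.numeric(reconstruct(mdl, project(mdl, v))), as.numeric(v))
  expect_equal(cumulative_variance(mdl, 2), 1)  # degenerate total treated as full
})

test_that("a rank-3 cohort is recovered exactly: subspace, variances, scores", {
  ch <- linear_mode_cohort(m = 30, n_coords = 60, k_modes = 3,
                           sds = c(3, 2, 1), seed = 5)
  mdl <- fit_pca(ch$vectors, k = 3)
  # residual rank: modes 4..m-1 carry no variance
  expect_lt(sum(mdl$all_variances[4:29]), 1e-12 * sum(mdl$all_variances))
  # principal angles between fitted and true subspaces are all ~0
  sv <- svd(crossprod(mdl$modes, ch$basis))$d
  expect_equal(sv, rep(1, 3), tolerance = 1e-8)
  # every training shape reconstructs exactly from its scores
  for (i in c(1, 15, 30)) {
    rec <- reconstruct(mdl, project(mdl, ch$vectors[[i]]))
    expect_equal(as.numeric(rec), as.numeric(ch$vectors[[i]]), tolerance = 1e-8)
  }
  # model variances equal the sample variances of the (rotated) weights
  expect_equal(sum(mdl$all_variances), sum(apply(ch$weights, 2, var)) *
                 1, tolerance = 1e-10)
})

test_that("projection is the least-squares score and padding reconstructs", {
  ch <- linear_mode_cohort(m = 10, n_coords = 24, k_modes = 2, seed = 9)
  mdl <- fit_pca(ch$vectors, k = 3)
  b <- project(mdl, ch$vectors[[4]])
  expect_length(b, 3L)
  # reconstruct with a truncated weight vector zero-pads the rest
  r1 <- reconstruct(mdl, b[1])
  r2 <- reconstruct(mdl, c(b[1], 0, 0))
  expect_equal(as.numeric(r1), as.numeric(r2))
  expect_error(reconstruct(mdl, rep(0, 4)), class = "soleusshape_error_dimension")
  expect_error(project(mdl, soleusshape:::new_shape_vector(rep(0, 6), 2L)),
               class = "soleusshape_error_dimension")
})

test_that("cumulative variance follows known 9:3:1 spectra", {
  ch <- linear_mode_cohort(m = 200, n_coords = 45, k_modes = 3,
                           sds = c(3, sqrt(3), 1), seed = 31)
  mdl <- fit_pca(ch$vectors, k = 3)
  # data are exactly rank 3, so totals reduce to the three mode variances
  expect_equal(cumulative_variance(mdl, 3), 1, tolerance = 1e-12)
  expect_equal(cumulative_variance(mdl, 1),
               mdl$variances[1] / sum(mdl$variances), tolerance = 1e-12)
  # empirical spectrum near the population 9:3:1 ratios
  expect_equal(mdl$variances / mdl$variances[3], c(9, 3, 1), tolerance = 0.35)
  expect_error(cumulative_variance(mdl, 0), class = "soleusshape_error_parameter")
  expect_error(cumulative_variance(mdl, 4), class = "soleusshape_error_parameter")
})

test_that("closed-form size normalization matches a numerical optimizer", {
  ch <- linear_mode_cohort(m = 4, n_coords = 30, k_modes = 2, seed = 14)
  ref <- compute_mean(ch$vectors)
  out <- size_normalize(ch$vectors, ref)
  for (i in 1:4) {
    x <- as.numeric(ch$vectors[[i]])
    opt <- stats::optimize(function(s) sum((s * x - as.numeric(ref))^2),
                           interval = c(0.1, 10), tol = 1e-10)
    expect_equal(out$scale_factors[i], opt$minimum, tolerance = 1e-6)
    expect_equal(as.numeric(out$normalized[[i]]), x * out$scale_factors[i])
  }
  # exactly scaled copies of one shape recover the reciprocal scales
  base <- as.numeric(ch$vectors[[1]])
  scaled <- lapply(c(0.5, 1, 2), function(s) {
    soleusshape:::new_shape_vector(base * s, attr(ch$vectors[[1]], "n_vertices"))
  })
  out2 <- size_normalize(scaled, ch$vectors[[1]])
  expect_equal(out2$scale_factors, 1 / c(0.5, 1, 2), tolerance = 1e-12)
  expect_error(size_normalize(scaled, soleusshape:::new_shape_vector(rep(0, 6), 2L)),
               class = "soleusshape_error_dimension")
})

test_that("build_model on a pre-corresponded cohort recovers the generator modes", {
  cohort <- mode_mesh_cohort(m = 25, modes = c("size", "margin_side"),
                             sds = c(1, 1), resolution = 8, seed = 17)
  fit <- build_model(cohort$meshes, k = 5, correspond = FALSE)
  expect_s3_class(fit$model, "shape_model")
  expect_equal(fit$model$k, 5L)
  expect_true(all(fit$rms_report$rms_mm == 0))
  # two planted modes dominate: first two PCs explain nearly everything
  expect_gt(cumulative_variance(fit$model, 2), 0.999)
  # weights tibble has tidy structure
  expect_s3_class(fit$weights, "tbl_df")
  expect_named(fit$weights, c("specimen_id", "label", paste0("pc", 1:5)))
  expect_equal(nrow(fit$weights), 25L)
  # mixed topology is rejected when registration is skipped
  bad <- c(cohort$meshes[1:2], list(base_soleus_template(6)))
  expect_error(build_model(bad, correspond = FALSE),
               class = "soleusshape_error_dimension")
  expect_error(build_model(cohort$meshes[1]), class = "soleusshape_error_parameter")
})

test_that("size normalization collapses the variance of a size-dominated cohort", {
  cohort <- mode_mesh_cohort(m = 20, modes = "size", sds = 1.5,
                             resolution = 8, seed = 23)
  raw <- build_model(cohort$meshes, k = 3, correspond = FALSE)
  app <- build_model(cohort$meshes, k = 3, correspond = FALSE, normalize = TRUE)
  expect_true(app$model$normalized)
  expect_false(raw$model$normalized)
  # appearance model removes > 95% of the morphological variance
  expect_lt(sum(app$model$all_variances), 0.05 * sum(raw$model$all_variances))
  expect_false(all(app$scale_factors == 1))
  expect_true(all(raw$scale_factors == 1))
})

test_that("broom-style accessors summarize the spectrum consistently", {
  ch <- linear_mode_cohort(m = 12, n_coords = 30, k_modes = 3, seed = 2)
  mdl <- fit_pca(ch$vectors, k = 3)
  td <- tidy(mdl)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$mode, 1:3)
  expect_equal(td$cum_variance[3], cumulative_variance(mdl, 3))
  expect_true(all(diff(td$variance) <= 0))
  gl <- glance(mdl)
  expect_equal(gl$n_specimens, 12L)
  expect_equal(gl$k, 3L)
  expect_equal(gl$cum_variance_retained, td$cum_variance[3])
  p <- autoplot(mdl)
  expect_s3_class(p, "ggplot")
})
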