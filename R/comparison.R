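#' Cohort comparison
#'
#' Mean-shape difference maps between corresponded cohort means, extraction of
#' per-specimen PC weights from a combined model, and the per-PC two-group
#' statistical battery: Shapiro-Wilk normality and Levene variance-equality
#' gates, pooled two-sample t-test with Holm-Bonferroni correction when the
#' gates pass, Kruskal-Wallis otherwise.
#'
#' @name comparison
NULL

#' Per-vertex difference map between two corresponded meshes
#'
#' `per_vertex_mm` is the Euclidean distance between corresponding vertices
#' (the quantity driving a colour map); `hausdorff_mm` is the symmetric
#' point-to-surface Hausdorff distance (single summary); `direction` is +1
#' where mesh B lies outside mesh A along A's outward normal, -1 inside.
#'
#' @param mesh_a,mesh_b [surface_mesh()]es with identical topology.
#' @return a `difference_map`: `per_vertex_mm`, `hausdorff_mm`, `direction`,
#'   plus `mesh_a` for export/plotting.
#' @export
mean_difference_map <- function(mesh_a, mesh_b) {
  validate_surface_mesh(mesh_a)
  validate_surface_mesh(mesh_b)
  if (nrow(mesh_a$vertices) != nrow(mesh_b$vertices) ||
      !identical(mesh_a$faces, mesh_b$faces)) {
    abort_dimension("difference map requires identical (corresponded) topology")
  }
  dv <- mesh_b$vertices - mesh_a$vertices
  per_vertex <- sqrt(rowSums(dv^2))
  nrm <- vertex_normals(mesh_a)
  direction <- ifelse(rowSums(dv * nrm) >= 0, 1L, -1L)
  structure(list(
    per_vertex_mm = per_vertex,
    hausdorff_mm = hausdorff_distance(mesh_a, mesh_b),
    direction = direction,
    mesh_a = mesh_a
  ), class = "difference_map")
}

#' Symmetric Hausdorff distance between two meshes
#'
#' `method = "surface"` (default) measures each mesh's vertices against the
#' other's triangulated surface; `method = "vertex"` measures against the
#' other's vertex set only (the classical point-set Hausdorff, which
#' upper-bounds the surface variant).
#'
#' @param mesh_a,mesh_b [surface_mesh()]es (any topologies).
#' @param method `"surface"` or `"vertex"`.
#' @return distance in mm.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b, method = c("surface", "vertex")) {
  method <- match.arg(method)
  if (method == "surface") {
    d_ab <- max(closest_on_surface(mesh_a$vertices, mesh_b)$dist)
    d_ba <- max(closest_on_surface(mesh_b$vertices, mesh_a)$dist)
  } else {
    d2 <- outer(rowSums(mesh_a$vertices^2), rowSums(mesh_b$vertices^2), "+") -
      2 * tcrossprod(mesh_a$vertices, mesh_b$vertices)
    d2[d2 < 0] <- 0
    d_ab <- max(sqrt(apply(d2, 1L, min)))
    d_ba <- max(sqrt(apply(d2, 2L, min)))
  }
  max(d_ab, d_ba)
}

#' Tidy a difference map
#' @param x a `difference_map`.
#' @param ... unused.
#' @return tibble: vertex, x, y, z (of mesh A), distance_mm, direction.
#' @export
tidy.difference_map <- function(x, ...) {
  v <- x$mesh_a$vertices
  dist_mm <- x$per_vertex_mm
  dir <- x$direction
  tibble::tibble(vertex = seq_len(nrow(v)), x = v[, 1L], y = v[, 2L],
                 z = v[, 3L], distance_mm = dist_mm, direction = dir)
}

#' Plot a difference map as a flattened colour chart
#'
#' Vertices of mesh A plotted in the medial-lateral / proximal-distal plane,
#' coloured by the per-vertex distance to mesh B.
#'
#' @param object a `difference_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.difference_map <- function(object, ...) {
  td <- tidy.difference_map(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$x, y = .data$z,
                                   colour = .data$distance_mm)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "distance (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medial-lateral (mm)", y = "proximal-distal (mm)",
                  title = sprintf("Mean-shape difference map (Hausdorff %.2f mm)",
                                  object$hausdorff_mm)) +
    ggplot2::theme_minimal()
}

#' Project a cohort onto a model: the "soleus weights"
#'
#' @param model a `shape_model`.
#' @param shape_vectors list of corresponded shape vectors.
#' @param labels per-specimen cohort labels (same length).
#' @param specimen_ids optional ids.
#' @return tibble: specimen_id, label, pc1..pck.
#' @export
extract_weights <- function(model, shape_vectors, labels,
                            specimen_ids = NULL) {
  m <- length(shape_vectors)
  if (length(labels) != m) abort_dimension("labels length does not match shapes")
  if (is.null(specimen_ids)) specimen_ids <- sprintf("s%03d", seq_len(m))
  B <- t(vapply(shape_vectors, function(v) project(model, v), numeric(model$k)))
  colnames(B) <- paste0("pc", seq_len(model$k))
  out <- tibble::as_tibble(as.data.frame(B))
  tibble::add_column(out, specimen_id = specimen_ids, label = labels,
                     .before = 1L)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation, valid for 3 <= n <= 5000.
#'
#' @param values numeric sample.
#' @return list `(W, p)`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    abort_parameter(sprintf("Shapiro-Wilk requires 3 <= n <= 5000, got %d", n))
  }
  if (stats::sd(values) == 0) {
    abort_degenerate("Shapiro-Wilk undefined for a zero-variance sample")
  }
  res <- stats::shapiro.test(values)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Levene's test for variance equality (mean centers)
#'
#' One-way ANOVA F on absolute deviations from the group means.
#'
#' @param group_a,group_b numeric samples, each n >= 2.
#' @return list `(statistic, p)`.
#' @export
levene <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort_parameter("each group needs n >= 2 for Levene's test")
  }
  z <- c(abs(group_a - mean(group_a)), abs(group_b - mean(group_b)))
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  if (stats::sd(z) == 0) return(list(statistic = 0, p = 1))
  fit <- stats::anova(stats::aov(z ~ g))
  list(statistic = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param alpha family-wise level in `(0, 1)`.
#' @return list with `adjusted` (same order as input) and `reject` flags at
#'   `alpha`.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort_parameter("p-values must lie in [0, 1]")
  }
  if (alpha <= 0 || alpha >= 1) abort_parameter("alpha must be in (0, 1)")
  adj <- stats::p.adjust(p_values, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Kruskal-Wallis rank-sum test
#'
#' @param groups list of >= 2 numeric samples, total n >= 5.
#' @return list `(H, p)` with tie-corrected H and chi-square p.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort_parameter("kruskal_wallis needs a list of >= 2 groups")
  }
  if (sum(lengths(groups)) < 5L) abort_parameter("total n must be >= 5")
  res <- stats::kruskal.test(groups)
  list(H = unname(res$statistic), p = res$p.value)
}

# 1.5 x IQR fences per group; returns logical keep mask.
iqr_keep <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  x >= q[1L] - k * (q[2L] - q[1L]) & x <= q[2L] + k * (q[2L] - q[1L])
}

#' Two-group statistical battery over PC weights
#'
#' Per principal component: exclude outliers (beyond 1.5 x IQR from the group
#' quartiles), test each group for normality (Shapiro-Wilk) and the pair for
#' variance equality (Levene). If all three gate p-values exceed 0.05 a pooled
#' two-sample t-test is used; otherwise Kruskal-Wallis. Raw p-values are
#' Holm-Bonferroni adjusted jointly within each branch family (t-branch PCs
#' together; KW-branch PCs together).
#'
#' @param weights tibble from [extract_weights()] with exactly two labels,
#'   each group n >= 3.
#' @param alpha significance level.
#' @param outlier_rule `"iqr"` (1.5 x IQR fences) or `"none"`.
#' @return tibble with one row per PC: pc_index, test_used, statistic, p_raw,
#'   p_adjusted, normality_p_a, normality_p_b, variance_equality_p,
#'   outliers_excluded (list column of specimen ids), significant.
#' @export
compare_groups <- function(weights, alpha = 0.05,
                           outlier_rule = c("iqr", "none")) {
  outlier_rule <- match.arg(outlier_rule)
  labs <- sort(unique(weights$label))
  if (length(labs) != 2L) {
    abort_parameter(sprintf("exactly two labels required, got %d", length(labs)))
  }
  pc_cols <- grep("^pc\\d+$", names(weights), value = TRUE)
  pc_cols <- pc_cols[order(as.integer(sub("^pc", "", pc_cols)))]
  if (length(pc_cols) < 1L) abort_parameter("no pc columns found in weights")
  if (min(table(weights$label)) < 3L) abort_parameter("each group needs n >= 3")

  rows <- vector("list", length(pc_cols))
  for (j in seq_along(pc_cols)) {
    pc <- pc_cols[[j]]
    xa <- weights[[pc]][weights$label == labs[1L]]
    xb <- weights[[pc]][weights$label == labs[2L]]
    ida <- weights$specimen_id[weights$label == labs[1L]]
    idb <- weights$specimen_id[weights$label == labs[2L]]
    excluded <- character(0L)
    if (outlier_rule == "iqr") {
      ka <- iqr_keep(xa); kb <- iqr_keep(xb)
      excluded <- c(ida[!ka], idb[!kb])
      xa <- xa[ka]; xb <- xb[kb]
    }
    row <- list(pc_index = as.integer(sub("^pc", "", pc)),
                test_used = NA_character_, statistic = NA_real_,
                p_raw = NA_real_, p_adjusted = NA_real_,
                normality_p_a = NA_real_, normality_p_b = NA_real_,
                variance_equality_p = NA_real_,
                outliers_excluded = list(excluded),
                significant = NA, note = NA_character_)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      row$test_used <- "degenerate"
      row$note <- "zero variance in both groups"
      rows[[j]] <- row
      next
    }
    sw_a <- tryCatch(shapiro_wilk(xa)$p, soleusshape_error = function(e) 0)
    sw_b <- tryCatch(shapiro_wilk(xb)$p, soleusshape_error = function(e) 0)
    lev <- levene(xa, xb)
    row$normality_p_a <- sw_a
    row$normality_p_b <- sw_b
    row$variance_equality_p <- lev$p
    if (sw_a > 0.05 && sw_b > 0.05 && lev$p > 0.05) {
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      row$test_used <- "t_test"
      row$statistic <- unname(tt$statistic)
      row$p_raw <- tt$p.value
    } else {
      kw <- kruskal_wallis(list(xa, xb))
      row$test_used <- "kruskal_wallis"
      row$statistic <- kw$H
      row$p_raw <- kw$p
    }
    rows[[j]] <- row
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  for (branch in c("t_test", "kruskal_wallis")) {
    sel <- which(out$test_used == branch)
    if (length(sel)) {
      hb <- holm_bonferroni(out$p_raw[sel], alpha)
      out$p_adjusted[sel] <- hb$adjusted
      out$significant[sel] <- hb$reject
    }
  }
  out
}
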