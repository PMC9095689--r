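#' Point-distribution shape models
#'
#' A shape model is the mean shape of a corresponded cohort plus the leading
#' eigenvectors (modes) and eigenvalues (variances) of the sample covariance
#' of the shape vectors: S_i ~ S_bar + P b_i. The "morphological" model keeps
#' size in the data; the "appearance" model is built after least-squares size
#' normalization.
#'
#' @name ssm
NULL

#' Coordinate-wise mean shape
#'
#' @param shape_vectors non-empty list of equal-length shape vectors.
#' @return a `shape_vector`, the arithmetic mean.
#' @export
compute_mean <- function(shape_vectors) {
  if (length(shape_vectors) < 1L) abort_parameter("empty shape-vector list")
  X <- shape_vectors_to_matrix(shape_vectors)
  new_shape_vector(rowMeans(X), nrow(X) %/% 3L)
}

#' Fit a PCA shape model
#'
#' Eigen-decomposition of the sample covariance (divisor m - 1) of deviations
#' from the mean, computed through the m x m Gram matrix (dual route, since
#' 3n >> m). Mode signs follow a fixed convention: the largest-magnitude entry
#' of each mode is positive.
#'
#' @param shape_vectors list of m >= 2 corresponded shape vectors.
#' @param k retained mode count, `k <= m - 1`.
#' @param topology optional reference face matrix stored with the model.
#' @param normalized flag recording whether the inputs were size-normalized
#'   (appearance model) or not (morphological model).
#' @return a `shape_model`: `mean`, `modes` (3n x k orthonormal), `variances`
#'   (k eigenvalues, mm^2, descending), `all_variances` (every nonzero-rank
#'   eigenvalue, for total-variance accounting), `k`, `m`, `topology`,
#'   `normalized`.
#' @export
fit_pca <- function(shape_vectors, k, topology = NULL, normalized = FALSE) {
  m <- length(shape_vectors)
  if (m < 2L) abort_parameter("need at least 2 shapes")
  k <- as.integer(k)
  if (k < 1L || k > m - 1L) {
    abort_parameter(sprintf("k = %d must be in 1..m-1 = %d", k, m - 1L))
  }
  X <- shape_vectors_to_matrix(shape_vectors)
  mu <- rowMeans(X)
  D <- X - mu
  G <- crossprod(D)                      # m x m
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  all_var <- vals[seq_len(m - 1L)] / (m - 1L)
  modes <- matrix(0, nrow(X), k)
  tol <- max(vals) * 1e-12
  for (j in seq_len(k)) {
    if (vals[j] > tol) {
      modes[, j] <- D %*% eg$vectors[, j] / sqrt(vals[j])
    } else {
      # rank-deficient direction: deterministic placeholder basis vector
      modes[j, j] <- 1
    }
  }
  # sign convention: largest-magnitude entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(modes[, j]))
    if (modes[i_max, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(
    mean = new_shape_vector(mu, nrow(X) %/% 3L),
    modes = modes,
    variances = all_var[seq_len(k)],
    all_variances = all_var,
    k = k,
    m = m,
    topology = topology,
    normalized = isTRUE(normalized)
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: %s, %d modes from %d specimens, %d vertices>\n",
              if (x$normalized) "appearance (size-normalized)" else "morphological",
              x$k, x$m, attr(x$mean, "n_vertices")))
  tot <- sum(x$all_variances)
  if (tot > 0) {
    cat(sprintf("  cumulative variance of retained modes: %.1f%%\n",
                100 * sum(x$variances) / tot))
  }
  invisible(x)
}

#' Project a shape onto model modes
#'
#' `b = P' (S - S_bar)`: the specimen's weights (scores) along each principal
#' component.
#'
#' @param model a `shape_model`.
#' @param vec a shape vector of matching length.
#' @return numeric length-k weight vector.
#' @export
project <- function(model, vec) {
  if (length(vec) != length(model$mean)) {
    abort_dimension(sprintf("shape vector length %d does not match model (%d)",
                            length(vec), length(model$mean)))
  }
  as.numeric(crossprod(model$modes, as.numeric(vec) - as.numeric(model$mean)))
}

#' Reconstruct a shape from model weights
#'
#' `S = S_bar + P b`; short weight vectors are zero-padded.
#'
#' @param model a `shape_model`.
#' @param weights numeric vector, length `<= k`.
#' @return a `shape_vector`.
#' @export
reconstruct <- function(model, weights) {
  if (length(weights) > model$k) {
    abort_dimension(sprintf("%d weights supplied but model retains %d modes",
                            length(weights), model$k))
  }
  b <- c(as.numeric(weights), rep(0, model$k - length(weights)))
  new_shape_vector(as.numeric(model$mean) + as.numeric(model$modes %*% b),
                   attr(model$mean, "n_vertices"))
}

#' Cumulative explained variance
#'
#' Fraction of the total training variance (sum over all nonzero-rank
#' eigenvalues, not only the retained k) explained by the first `j` modes.
#'
#' @param model a `shape_model`.
#' @param j mode count, `1 <= j <= k`.
#' @return fraction in `[0, 1]`.
#' @export
cumulative_variance <- function(model, j) {
  j <- as.integer(j)
  if (j < 1L || j > model$k) {
    abort_parameter(sprintf("j = %d must be in 1..k = %d", j, model$k))
  }
  tot <- sum(model$all_variances)
  if (tot == 0) return(1)
  sum(model$variances[seq_len(j)]) / tot
}

#' Least-squares size normalization
#'
#' For each specimen, the scalar s minimizing ||s S - reference||^2 (closed
#' form `s = <S, reference> / <S, S>`) is applied. Inputs are expected to be
#' rigidly aligned already; this removes only uniform scale, producing the
#' data for the appearance model.
#'
#' @param shape_vectors list of equal-length shape vectors.
#' @param reference the reference shape vector.
#' @return list with `normalized` (list of shape vectors) and `scale_factors`.
#' @export
size_normalize <- function(shape_vectors, reference) {
  X <- shape_vectors_to_matrix(shape_vectors)
  ref <- as.numeric(reference)
  if (nrow(X) != length(ref)) abort_dimension("reference length does not match shapes")
  nn <- colSums(X^2)
  if (any(nn == 0)) abort_degenerate("zero-norm shape vector cannot be normalized")
  s <- as.numeric(crossprod(X, ref)) / nn
  nv <- length(ref) %/% 3L
  list(normalized = lapply(seq_along(s), function(i) {
    new_shape_vector(X[, i] * s[i], nv)
  }),
  scale_factors = s)
}

#' Build a shape model from meshes
#'
#' Full pipeline: iterative RBF refitting for correspondence (skipped when
#' `correspond = FALSE` and all meshes already share topology, in which case
#' specimens are only rigidly aligned), optional size normalization against
#' the cohort mean, PCA, and projection of every training shape.
#'
#' @param meshes list of >= 2 [surface_mesh()]es.
#' @param normalize build the appearance (size-normalized) model.
#' @param k retained modes (default 9, capped at m - 1).
#' @param labels optional per-specimen cohort labels.
#' @param specimen_ids optional ids; defaults to `s001, ...`.
#' @param settings [registration_settings()].
#' @param reference registration reference mesh; default the first specimen.
#' @param correspond set FALSE when meshes are already corresponded
#'   vertex-wise (e.g. synthetic cohorts with shared topology).
#' @return list with `model` (a `shape_model`), `weights` (tibble:
#'   specimen_id, label, pc1..pck), `rms_report` (tibble of per-specimen
#'   fitting RMS; zero when registration is skipped), `shape_vectors`
#'   (the aligned, possibly normalized training vectors), `scale_factors`.
#' @export
build_model <- function(meshes, normalize = FALSE, k = 9L, labels = NULL,
                        specimen_ids = NULL,
                        settings = registration_settings(),
                        reference = NULL, correspond = TRUE) {
  m <- length(meshes)
  if (m < 2L) abort_parameter("need at least 2 meshes")
  if (is.null(specimen_ids)) specimen_ids <- sprintf("s%03d", seq_len(m))
  if (is.null(labels)) labels <- rep(NA_character_, m)
  k_use <- min(as.integer(k), m - 1L)
  if (correspond) {
    ref <- if (is.null(reference)) meshes[[1L]] else reference
    reg <- iterative_refit(ref, meshes, settings)
    vecs <- reg$shape_vectors
    rms <- reg$rms_list
    topology <- ref$faces
  } else {
    nv <- vapply(meshes, n_vertices, integer(1L))
    if (length(unique(nv)) != 1L) {
      abort_dimension("correspond = FALSE requires meshes sharing one topology")
    }
    vecs <- lapply(meshes, function(msh) rigid_align(mesh_to_shape_vector(msh))$aligned)
    rms <- rep(0, m)
    topology <- meshes[[1L]]$faces
    reg <- NULL
  }
  scale_factors <- rep(1, m)
  if (normalize) {
    norm <- size_normalize(vecs, compute_mean(vecs))
    vecs <- norm$normalized
    scale_factors <- norm$scale_factors
  }
  model <- fit_pca(vecs, k = k_use, topology = topology, normalized = normalize)
  weights <- extract_weights(model, vecs, labels, specimen_ids = specimen_ids)
  rms_report <- tibble::tibble(specimen_id = specimen_ids, label = labels,
                               rms_mm = rms)
  list(model = model, weights = weights, rms_report = rms_report,
       shape_vectors = vecs, scale_factors = scale_factors,
       registration = reg)
}

# --- broom-style methods -----------------------------------------------------

#' Tidy a shape model's variance spectrum
#'
#' @param x a `shape_model`.
#' @param ... unused.
#' @return tibble with one row per retained mode: `mode`, `variance` (mm^2),
#'   `prop_variance`, `cum_variance` (fractions of total training variance).
#' @export
tidy.shape_model <- function(x, ...) {
  tot <- sum(x$all_variances)
  prop <- if (tot > 0) x$variances / tot else rep(0, x$k)
  tibble::tibble(mode = seq_len(x$k), variance = x$variances,
                 prop_variance = prop, cum_variance = cumsum(prop))
}

#' One-row summary of a shape model
#'
#' @param x a `shape_model`.
#' @param ... unused.
#' @return tibble: `n_specimens`, `n_vertices`, `k`, `normalized`,
#'   `total_variance`, `cum_variance_retained`.
#' @export
glance.shape_model <- function(x, ...) {
  tot <- sum(x$all_variances)
  tibble::tibble(n_specimens = x$m,
                 n_vertices = attr(x$mean, "n_vertices"),
                 k = x$k,
                 normalized = x$normalized,
                 total_variance = tot,
                 cum_variance_retained = if (tot > 0) sum(x$variances) / tot else 1)
}

#' Scree plot of a shape model
#'
#' @param object a `shape_model`.
#' @param ... unused.
#' @return a ggplot: per-mode explained variance with the cumulative curve.
#' @export
autoplot.shape_model <- function(object, ...) {
  td <- tidy.shape_model(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$prop_variance), fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_variance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_variance)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "principal component", y = "explained variance",
                  title = if (object$normalized) "Appearance model" else "Morphological model") +
    ggplot2::theme_minimal()
}
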