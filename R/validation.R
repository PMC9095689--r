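#' Model validation
#'
#' Generality is measured by leave-one-out reconstruction: fit the model
#' without a specimen, reconstruct it, and report the per-vertex RMS error in
#' mm. Registration accuracy is summarized per specimen.
#'
#' @name validation
NULL

# Per-vertex RMS (mm) between two shape vectors: root-mean-square of the
# per-vertex Euclidean distances.
shape_rms <- function(a, b) {
  d <- matrix(as.numeric(a) - as.numeric(b), ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums(d^2)))
}

# Compact NIPALS PLS2: predict responses Y (m x q) from predictors X (m x p)
# with ncomp latent components. Returns a predict closure.
pls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  p <- ncol(Xc)
  ncomp <- min(ncomp, p, nrow(X) - 1L)
  W <- matrix(0, p, ncomp); Pm <- matrix(0, p, ncomp)
  Q <- matrix(0, ncol(Yc), ncomp)
  Xr <- Xc; Yr <- Yc
  for (h in seq_len(ncomp)) {
    w <- crossprod(Xr, Yr[, which.max(colSums(Yr^2)), drop = FALSE])
    if (sqrt(sum(w^2)) < 1e-12) { ncomp <- h - 1L; break }
    w <- w / sqrt(sum(w^2))
    tt <- Xr %*% w
    tt2 <- sum(tt^2)
    pp <- crossprod(Xr, tt) / tt2
    qq <- crossprod(Yr, tt) / tt2
    Xr <- Xr - tt %*% t(pp)
    Yr <- Yr - tt %*% t(qq)
    W[, h] <- w; Pm[, h] <- pp; Q[, h] <- qq
  }
  if (ncomp < 1L) {
    return(function(newX) matrix(my, nrow(as.matrix(newX)), length(my), byrow = TRUE))
  }
  W <- W[, seq_len(ncomp), drop = FALSE]
  Pm <- Pm[, seq_len(ncomp), drop = FALSE]
  Q <- Q[, seq_len(ncomp), drop = FALSE]
  B <- W %*% solve(crossprod(Pm, W)) %*% t(Q)
  function(newX) {
    newX <- as.matrix(newX)
    sweep(sweep(newX, 2L, mx) %*% B, 2L, my, "+")
  }
}

#' Leave-one-out generality
#'
#' For each specimen, a k-mode model is fitted on the remaining m - 1 shapes
#' (in the same normalization state as the input) and the left-out shape is
#' reconstructed. `method = "projection"` reconstructs as
#' `S_bar + P P' (S - S_bar)`; `method = "pls"` predicts the left-out shape
#' from its k fold-model projection scores by partial least-squares
#' regression trained on the fold.
#'
#' @param shape_vectors list of m >= 3 corresponded shape vectors.
#' @param k modes per fold, `k <= m - 2`.
#' @param method `"projection"` (default) or `"pls"`.
#' @return a `loo_report`: tibble `folds` (fold_id, specimen_id, rms_mm),
#'   `mean_rms`, `k_used`, `method`.
#' @export
leave_one_out_rms <- function(shape_vectors, k, method = c("projection", "pls")) {
  method <- match.arg(method)
  m <- length(shape_vectors)
  if (m < 3L) abort_parameter("leave-one-out needs at least 3 specimens")
  k <- as.integer(k)
  if (k > m - 2L) {
    abort_parameter(sprintf("k = %d too large for folds of size %d (max %d)",
                            k, m - 1L, m - 2L))
  }
  rms <- numeric(m)
  for (i in seq_len(m)) {
    fold <- shape_vectors[-i]
    model <- fit_pca(fold, k = k)
    b <- project(model, shape_vectors[[i]])
    if (method == "projection") {
      rec <- reconstruct(model, b)
    } else {
      scores <- t(vapply(fold, function(v) project(model, v), numeric(k)))
      Y <- t(shape_vectors_to_matrix(fold))
      fit <- pls_fit(scores, Y, ncomp = k)
      rec <- new_shape_vector(as.numeric(fit(matrix(b, 1L))),
                              attr(model$mean, "n_vertices"))
    }
    rms[i] <- shape_rms(shape_vectors[[i]], rec)
  }
  structure(list(
    folds = tibble::tibble(fold_id = seq_len(m),
                           specimen_id = sprintf("s%03d", seq_len(m)),
                           rms_mm = rms),
    per_specimen_rms = rms,
    mean_rms = mean(rms),
    k_used = k,
    method = method
  ), class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("<loo_report: %s method, k = %d, mean RMS %.4f mm over %d folds>\n",
              x$method, x$k_used, x$mean_rms, length(x$per_specimen_rms)))
  invisible(x)
}

#' Tidy a leave-one-out report
#' @param x a `loo_report`.
#' @param ... unused.
#' @return the per-fold tibble (fold_id, specimen_id, rms_mm).
#' @export
tidy.loo_report <- function(x, ...) x$folds

#' One-row summary of a leave-one-out report
#' @param x a `loo_report`.
#' @param ... unused.
#' @return tibble: `mean_rms`, `max_rms`, `k_used`, `method`, `n_folds`.
#' @export
glance.loo_report <- function(x, ...) {
  tibble::tibble(mean_rms = x$mean_rms, max_rms = max(x$per_specimen_rms),
                 k_used = x$k_used, method = x$method,
                 n_folds = length(x$per_specimen_rms))
}

#' Summarize registration accuracy
#'
#' @param rms_list per-specimen fitting RMS in mm.
#' @param threshold_mm flag specimens above this RMS (default 1.0 mm, of the
#'   order of the voxel size of typical muscle MRI).
#' @return list with `mean`, `sd`, `max`, `table` (tibble: specimen, rms_mm,
#'   flagged), `n_flagged`.
#' @export
registration_quality <- function(rms_list, threshold_mm = 1.0) {
  if (length(rms_list) < 1L) abort_parameter("empty RMS list")
  tab <- tibble::tibble(specimen = seq_along(rms_list),
                        rms_mm = as.numeric(rms_list),
                        flagged = as.numeric(rms_list) > threshold_mm)
  list(mean = mean(tab$rms_mm),
       sd = if (nrow(tab) > 1L) stats::sd(tab$rms_mm) else 0,
       max = max(tab$rms_mm),
       table = tab,
       n_flagged = sum(tab$flagged))
}
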