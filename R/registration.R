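#' Correspondence and alignment
#'
#' Dense correspondence across specimens is established by non-rigidly warping
#' a reference mesh onto each target with a radial-basis-function (RBF)
#' interpolant driven by iterative closest-point control displacements, then
#' rigidly aligning every fitted mesh to a canonical pose defined by its
#' centre of mass and principal axes of inertia. An outer loop refits the
#' cohort against its evolving mean shape.
#'
#' @name registration
NULL

#' Registration settings
#'
#' @param kernel RBF kernel: `"thin_plate"` (phi(r) = r, the 3-D minimal
#'   bending choice) or `"gaussian"`.
#' @param n_control number of control points selected by farthest-point
#'   sampling on the reference (>= 4 for the affine term).
#' @param regularization non-negative smoothing weight added to the kernel
#'   block diagonal; 0 interpolates control displacements exactly.
#' @param icp_iters outer closest-point iterations inside one fit.
#' @param kernel_scale Gaussian kernel width in mm; default (NULL) is a tenth
#'   of the reference bounding-box diagonal.
#' @param tol_mm convergence threshold on mean RMS improvement for
#'   [iterative_refit()].
#' @param max_iter maximum refit iterations.
#' @return a named list of settings.
#' @export
registration_settings <- function(kernel = c("thin_plate", "gaussian"),
                                  n_control = 200L,
                                  regularization = 0,
                                  icp_iters = 10L,
                                  kernel_scale = NULL,
                                  tol_mm = 0.01,
                                  max_iter = 5L) {
  kernel <- match.arg(kernel)
  if (regularization < 0) abort_parameter("regularization must be non-negative")
  if (icp_iters < 1L) abort_parameter("icp_iters must be >= 1")
  if (max_iter < 1L) abort_parameter("max_iter must be >= 1")
  list(kernel = kernel, n_control = as.integer(n_control),
       regularization = regularization, icp_iters = as.integer(icp_iters),
       kernel_scale = kernel_scale, tol_mm = tol_mm,
       max_iter = as.integer(max_iter))
}

# Farthest-point sampling: deterministic start at the vertex farthest from the
# centroid (ties -> lowest index), then greedy max-min.
farthest_point_sample <- function(vertices, k) {
  n <- nrow(vertices)
  k <- min(k, n)
  cen <- colMeans(vertices)
  d0 <- rowSums(sweep(vertices, 2L, cen)^2)
  sel <- integer(k)
  sel[1L] <- which.max(d0)
  mind <- rowSums(sweep(vertices, 2L, vertices[sel[1L], ])^2)
  if (k > 1L) {
    for (i in 2:k) {
      sel[i] <- which.max(mind)
      di <- rowSums(sweep(vertices, 2L, vertices[sel[i], ])^2)
      mind <- pmin(mind, di)
    }
  }
  sel
}

rbf_kernel_matrix <- function(A, B, kernel, scale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  switch(kernel,
         thin_plate = r,
         gaussian = exp(-d2 / (2 * scale^2)))
}

# Solve for RBF + affine coefficients mapping control points `centers` to
# displacements `disp` (k x 3). Returns a closure evaluating the warp.
rbf_solve <- function(centers, disp, kernel, regularization, scale) {
  k <- nrow(centers)
  K <- rbf_kernel_matrix(centers, centers, kernel, scale)
  if (regularization > 0) K <- K + diag(regularization, k)
  P <- cbind(1, centers)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(disp, matrix(0, 4L, 3L))
  coef <- solve(M, rhs)
  W <- coef[seq_len(k), , drop = FALSE]
  A <- coef[k + 1:4, , drop = FALSE]
  function(V) {
    Phi <- rbf_kernel_matrix(V, centers, kernel, scale)
    V + Phi %*% W + cbind(1, V) %*% A
  }
}

closest_on_surface <- function(query, mesh) {
  .closest_point_mesh(query, mesh$vertices, mesh$faces)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

#' Non-rigid RBF fit of a reference mesh onto a target surface
#'
#' Control points are picked by farthest-point sampling on the reference and
#' their displacements estimated by iterative closest-point (ICP)
#' correspondence to the target surface: an affine ICP stage first captures
#' global pose and scale (so any affine deformation is recovered exactly up
#' to ICP convergence), then the RBF interpolant (kernel plus affine term)
#' of the final control correspondences warps every reference vertex. With
#' zero regularization the warp interpolates the control displacements
#' exactly.
#'
#' @param reference,target [surface_mesh()]es; the fitted output inherits the
#'   reference topology.
#' @param settings a [registration_settings()] list.
#' @return a `registration_result`: `fitted` (shape vector on the reference
#'   topology), `rms_mm` (RMS point-to-surface distance of fitted vertices to
#'   the target), `n_control`, `kernel`, `regularization`, `converged`,
#'   `warning`.
#' @export
rbf_fit <- function(reference, target, settings = registration_settings()) {
  validate_surface_mesh(reference)
  validate_surface_mesh(target)
  if (settings$n_control < 4L) {
    abort_parameter("n_control must be >= 4 (affine term underdetermined)")
  }
  scale <- settings$kernel_scale
  if (is.null(scale)) {
    bb <- apply(reference$vertices, 2L, range)
    scale <- sqrt(sum((bb[2L, ] - bb[1L, ])^2)) / 10
  }
  ctrl_idx <- farthest_point_sample(reference$vertices, settings$n_control)
  C0 <- reference$vertices[ctrl_idx, , drop = FALSE]
  P0 <- cbind(1, C0)
  # stage 1: affine point-to-plane ICP — captures global pose/scale/stretch
  # (point-to-point ICP senses tangential stretch only at the extremities and
  # stalls; minimizing normal-distance converges in a few iterations)
  tfn <- face_normals(target)
  A <- rbind(0, diag(3))           # affine map, rows (b, A')
  converged <- FALSE
  for (it in seq_len(settings$icp_iters)) {
    Xc <- P0 %*% A
    cp <- closest_on_surface(Xc, target)
    N <- tfn[cp$face, , drop = FALSE]
    M <- matrix(0, nrow(C0), 12L)
    for (d in 1:3) M[, (d - 1L) * 4L + 1:4] <- P0 * N[, d]
    A_new <- tryCatch(matrix(qr.solve(M, rowSums(N * cp$point)), 4L, 3L),
                      error = function(e) qr.solve(P0, cp$point))
    step <- max(abs(P0 %*% A_new - Xc))
    A <- A_new
    if (step < 1e-8) { converged <- TRUE; break }
  }
  # stage 2: RBF + affine interpolation of the final correspondences
  cp <- closest_on_surface(P0 %*% A, target)
  disp <- cp$point - C0
  warp <- rbf_solve(C0, disp, settings$kernel, settings$regularization, scale)
  fitted_v <- warp(reference$vertices)
  rms <- sqrt(mean(closest_on_surface(fitted_v, target)$dist^2))
  structure(list(
    fitted = new_shape_vector(as.numeric(t(fitted_v)), nrow(fitted_v)),
    rms_mm = rms,
    n_control = nrow(C0),
    kernel = settings$kernel,
    regularization = settings$regularization,
    control_index = ctrl_idx,
    control_target = C0 + disp,
    converged = converged,
    warning = if (converged) NA_character_ else
      sprintf("ICP did not reach displacement tolerance in %d iterations",
              settings$icp_iters)
  ), class = "registration_result")
}

#' Rigid alignment to the inertia-axes canonical pose
#'
#' Moves the centre of mass (uniform vertex weights) to the origin and rotates
#' the principal axes of the vertex covariance onto the anatomical frame: the
#' largest-variance axis to z, second to x, third to y. Axis signs are
#' disambiguated by requiring a non-negative third-order asymmetry statistic
#' along the first two axes: whichever of the normalized coordinate skewness
#' and the normalized axial/radial-spread covariance `mean(t * r^2)` is larger
#' in magnitude (the latter is robust for elongated shapes whose vertices are
#' spread evenly along the axis but whose girth tapers asymmetrically). The
#' third axis is the cross product of the first two, fixing handedness.
#'
#' @param x a [surface_mesh()] or `shape_vector`.
#' @return list with `aligned` (same type as input) and `transform` (list
#'   `rotation` 3x3, `translation` length-3) such that
#'   `aligned = rotation %*% v + translation` vertex-wise.
#' @export
rigid_align <- function(x) {
  is_mesh <- inherits(x, "surface_mesh")
  V <- if (is_mesh) x$vertices else matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  cm <- colMeans(V)
  Vc <- sweep(V, 2L, cm)
  Cov <- crossprod(Vc) / nrow(Vc)
  ev <- eigen(Cov, symmetric = TRUE)
  lam <- ev$values
  if (lam[1L] <= 0 || (lam[1L] - lam[2L]) / lam[1L] < 1e-9 ||
      (lam[2L] - lam[3L]) / lam[1L] < 1e-9) {
    abort_degenerate("inertia axes are degenerate (near-equal or zero eigenvalues)")
  }
  e1 <- ev$vectors[, 1L]; e2 <- ev$vectors[, 2L]
  tot2 <- rowSums(Vc^2)
  axis_asymmetry <- function(e) {
    t <- as.numeric(Vc %*% e)
    skewness <- mean(t^3) / mean(t^2)^1.5
    taper <- mean(t * (tot2 - t^2)) / (sqrt(mean(t^2)) * mean(tot2 - t^2))
    if (abs(taper) > abs(skewness)) taper else skewness
  }
  if (axis_asymmetry(e1) < 0) e1 <- -e1
  if (axis_asymmetry(e2) < 0) e2 <- -e2
  e3 <- cross3(e1, e2)
  Rm <- rbind(x = e2, y = e3, z = e1)   # rows: new-axis directions
  aligned_V <- unname(Vc %*% t(Rm))
  transform <- list(rotation = unname(Rm), translation = as.numeric(-Rm %*% cm))
  if (is_mesh) {
    out <- surface_mesh(aligned_V, x$faces, frame_note = x$frame_note)
  } else {
    out <- new_shape_vector(as.numeric(t(aligned_V)), nrow(aligned_V))
  }
  list(aligned = out, transform = transform)
}

#' Correspond a cohort against one reference
#'
#' Each target is non-rigidly fitted with [rbf_fit()] and the fitted mesh is
#' rigidly aligned with [rigid_align()]; every output shares the reference
#' topology.
#'
#' @param reference a [surface_mesh()].
#' @param targets list of [surface_mesh()]es (>= 1).
#' @param settings a [registration_settings()] list.
#' @return list with `shape_vectors` (aligned, reference topology), `rms_list`
#'   (per-target fitting RMS in mm), `warnings`.
#' @export
correspond_cohort <- function(reference, targets, settings = registration_settings()) {
  if (length(targets) < 1L) abort_parameter("at least one target mesh is required")
  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    res[[i]] <- tryCatch(rbf_fit(reference, targets[[i]], settings),
                         soleusshape_error = function(e) {
                           rlang::abort(sprintf("target %d: %s", i, conditionMessage(e)),
                                        class = class(e), parent = e)
                         })
  }
  vecs <- lapply(res, function(r) {
    rigid_align(shape_vector_to_mesh(r$fitted, reference$faces))$aligned |>
      mesh_to_shape_vector()
  })
  list(shape_vectors = vecs,
       rms_list = vapply(res, function(r) r$rms_mm, numeric(1L)),
       warnings = vapply(res, function(r) r$warning, character(1L)))
}

#' Iterative refitting against the evolving mean shape
#'
#' Loops correspond -> mean shape -> use mean as next reference, until the
#' mean fitting RMS improves by less than `tol_mm` or `max_iter` is reached.
#'
#' @inheritParams correspond_cohort
#' @return list with `shape_vectors`, `rms_list` (final iteration, per
#'   target), `rms_history` (per-iteration mean RMS), `stopped_by` one of
#'   `"tolerance"`, `"max_iter"`, and the final `reference` mesh.
#' @export
iterative_refit <- function(reference, targets, settings = registration_settings()) {
  ref <- reference
  rms_history <- numeric(0L)
  stopped_by <- "max_iter"
  out <- NULL
  for (it in seq_len(settings$max_iter)) {
    out <- correspond_cohort(ref, targets, settings)
    m_rms <- mean(out$rms_list)
    rms_history <- c(rms_history, m_rms)
    if (it > 1L && (rms_history[it - 1L] - m_rms) < settings$tol_mm) {
      stopped_by <- "tolerance"
      break
    }
    if (it == 1L && m_rms < settings$tol_mm) {
      stopped_by <- "tolerance"
      break
    }
    mean_vec <- compute_mean(out$shape_vectors)
    ref <- shape_vector_to_mesh(mean_vec, ref$faces, frame_note = ref$frame_note)
  }
  list(shape_vectors = out$shape_vectors, rms_list = out$rms_list,
       rms_history = rms_history, stopped_by = stopped_by, reference = ref)
}
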