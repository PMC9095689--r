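# Fixtures are generated in code; no binary data on disk.

tetra_mesh <- function() {
  surface_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  )
}

# Uniform random proper rotation (QR of a Gaussian matrix, det fixed to +1).
rand_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

apply_rigid <- function(mesh, R, t) {
  surface_mesh(sweep(mesh$vertices %*% t(R), 2L, t, "+"), mesh$faces)
}

# Cohort of shape vectors drawn from a known linear mode basis (no meshes,
# for PCA-level tests): returns list(vectors, basis, weights, mean_vec).
linear_mode_cohort <- function(m, n_coords, k_modes, sds = rep(1, k_modes),
                               noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    mu <- stats::rnorm(n_coords, sd = 5)
    B <- qr.Q(qr(matrix(stats::rnorm(n_coords * k_modes), n_coords)))[, seq_len(k_modes), drop = FALSE]
    W <- matrix(stats::rnorm(m * k_modes), m) %*% diag(sds, k_modes)
    X <- mu + B %*% t(W)
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
    nv <- n_coords %/% 3L
    list(vectors = lapply(seq_len(m), function(i) soleusshape:::new_shape_vector(X[, i], nv)),
         basis = B, weights = W,
         mean_vec = mu)
  })
}

# Mesh cohort lying exactly in the span of the generator's displacement modes.
mode_mesh_cohort <- function(m, modes = c("size", "aspect", "margin_side"),
                             sds = rep(1, length(modes)), noise_sd = 0,
                             resolution = 8L, seed = 1L) {
  cfg_sds <- stats::setNames(rep(0, 5L), deformation_modes())
  cfg_sds[modes] <- sds
  cfg <- generator_config(n_subjects = m, mode_sds = cfg_sds,
                          noise_sd = noise_sd, resolution = resolution,
                          seed = seed)
  generate_cohort(cfg)
}

expect_mesh_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$vertices, b$vertices, tolerance = tol)
  expect_identical(a$faces, b$faces)
}
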