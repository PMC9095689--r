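#' Synthetic soleus-like mesh cohorts
#'
#' The generator emulates the study design this package targets: cohorts of
#' elongated, tapered muscle surfaces whose between-subject variation is driven
#' by a small set of known deformation modes (a dominant isotropic size mode
#' plus shape modes), corrupted by per-vertex segmentation-like noise. Because
#' the true per-specimen mode weights are retained, every downstream stage
#' (registration, PCA, validation, group statistics) can be checked against
#' ground truth.
#'
#' @name synthetic
NULL

# Template envelope constants (mm). Chosen to resemble an adolescent soleus:
# 300 long, 80 wide, 40 thick, broad section at 40% of length from the
# proximal end. Not measurements from any imaged cohort.
.tpl <- list(length = 300, half = 150, wx = 40, wy = 20, peak_u = 0.4)

# Width profile along normalized proximal->distal coordinate u in [0,1];
# beta-like bump peaking at u = 0.4, zero at both extremities.
.width_profile <- function(u) {
  w <- u^2 * (1 - u)^3
  w / (.tpl$peak_u^2 * (1 - .tpl$peak_u)^3)
}

# Medial offset of the cross-section centre: bows the muscle toward +x away
# from the broad section (the "curved marginal aspect"); vanishes where the
# width profile peaks so the overall x extent stays 80 mm.
.medial_offset <- function(u) 15 * sin(pi * u) * (1 - .width_profile(u))

#' Deterministic soleus-like template mesh
#'
#' Closed, elongated, tapered surface of revolution-like mesh: length 300 mm
#' (z), maximum width 80 mm (x), maximum thickness 40 mm (y), width profile
#' peaking 40% of the length from the proximal end, with a medial bulge.
#' Vertex centroid at the origin. Deterministic in `resolution`.
#'
#' @param resolution number of cross-section rings (>= 4); the circumference
#'   carries `2 * resolution` vertices, so the mesh has
#'   `2 * resolution^2 + 2` vertices.
#' @param seam_offset integer rotation of the circumferential seam (used by
#'   the generator's topology shuffling); geometry is unchanged, vertex
#'   ordering is not.
#' @return a closed [surface_mesh()].
#' @export
base_soleus_template <- function(resolution = 16L, seam_offset = 0L) {
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 4L) {
    abort_parameter("resolution must be an integer >= 4 rings")
  }
  R <- resolution
  C <- 2L * R
  u <- seq_len(R) / (R + 1)
  j <- seq_len(C) - 1L
  theta <- 2 * pi * ((j + as.integer(seam_offset)) %% C) / C
  w <- .width_profile(u)
  cx <- .medial_offset(u)
  verts <- matrix(0, R * C + 2L, 3L)
  for (i in seq_len(R)) {
    rows <- (i - 1L) * C + seq_len(C)
    verts[rows, 1L] <- cx[i] + .tpl$wx * w[i] * cos(theta)
    verts[rows, 2L] <- .tpl$wy * w[i] * sin(theta)
    verts[rows, 3L] <- .tpl$half - .tpl$length * u[i]
  }
  top <- R * C + 1L    # proximal pole (z = +150)
  bot <- R * C + 2L    # distal pole  (z = -150)
  verts[top, ] <- c(.medial_offset(0), 0, .tpl$half)
  verts[bot, ] <- c(.medial_offset(1), 0, -.tpl$half)
  idx <- function(i, jj) (i - 1L) * C + ((jj - 1L) %% C) + 1L
  faces <- matrix(0L, 2L * (R - 1L) * C + 2L * C, 3L)
  r <- 1L
  for (jj in seq_len(C)) {           # proximal fan
    faces[r, ] <- c(top, idx(1L, jj + 1L), idx(1L, jj)); r <- r + 1L
  }
  for (i in seq_len(R - 1L)) {        # quad strips
    for (jj in seq_len(C)) {
      a <- idx(i, jj); b <- idx(i, jj + 1L)
      cc <- idx(i + 1L, jj + 1L); d <- idx(i + 1L, jj)
      faces[r, ] <- c(a, b, cc); r <- r + 1L
      faces[r, ] <- c(a, cc, d); r <- r + 1L
    }
  }
  for (jj in seq_len(C)) {           # distal fan
    faces[r, ] <- c(bot, idx(R, jj), idx(R, jj + 1L)); r <- r + 1L
  }
  verts <- sweep(verts, 2L, colMeans(verts))
  mesh <- surface_mesh(verts, faces)
  if (mesh_volume(mesh) < 0) {       # enforce outward winding
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Names of the generator's deformation modes
#' @return character vector of the five mode identifiers in composition order.
#' @export
deformation_modes <- function() {
  c("size", "aspect", "margin_side", "proximal_width", "broad_shift")
}

#' Apply one analytic deformation mode to a mesh
#'
#' Smooth vertex-wise deformations mirroring the principal components commonly
#' seen in muscle shape models: overall size; length vs width--thickness
#' aspect (volume-preserving); sideways skew of the curved marginal aspect;
#' width of the proximal extremity; and a superior--inferior shift of the
#' broad section. Amplitude 0 returns the input exactly.
#'
#' * `size`: isotropic scaling by `1 + 0.1 a`.
#' * `aspect`: z scaled by `1 + 0.08 a`, x and y by `(1 + 0.08 a)^(-1/2)`
#'   (exactly volume-preserving for closed meshes).
#' * `margin_side`: x displaced by `6 a sin(pi u)` mm, skewing the width
#'   profile toward +x (a > 0) or -x.
#' * `proximal_width`: x and y multiplied by `1 + 0.1 a ((0.3 - u) / 0.3)^2`
#'   for the proximal 30% of the length.
#' * `broad_shift`: z displaced by a bump field normalized to 15 `a` mm at the
#'   width-profile peak, translating the broad section proximally (a > 0).
#'
#' `u` is the normalized proximal-to-distal coordinate inferred from z.
#'
#' @param mesh a [surface_mesh()].
#' @param mode_id one of [deformation_modes()].
#' @param amplitude dimensionless, in `[-3, 3]`.
#' @return the deformed [surface_mesh()] (same topology).
#' @export
apply_mode_deformation <- function(mesh, mode_id, amplitude) {
  validate_surface_mesh(mesh)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || !is.finite(amplitude) ||
      abs(amplitude) > 3) {
    abort_parameter("amplitude must be a single finite value in [-3, 3]")
  }
  if (!mode_id %in% deformation_modes()) {
    abort_parameter(sprintf("unknown mode_id '%s' (expected one of %s)",
                            mode_id, paste(deformation_modes(), collapse = ", ")))
  }
  if (amplitude == 0) return(mesh)
  v <- mesh$vertices
  zr <- range(v[, 3L])
  u <- (zr[2L] - v[, 3L]) / max(zr[2L] - zr[1L], .Machine$double.eps)
  u <- pmin(pmax(u, 0), 1)
  a <- amplitude
  v <- switch(mode_id,
    size = v * (1 + 0.1 * a),
    aspect = {
      s <- 1 + 0.08 * a
      cbind(v[, 1L] * s^(-0.5), v[, 2L] * s^(-0.5), v[, 3L] * s)
    },
    margin_side = {
      v[, 1L] <- v[, 1L] + 6 * a * sin(pi * u); v
    },
    proximal_width = {
      ramp <- ifelse(u < 0.3, ((0.3 - u) / 0.3)^2, 0)
      mult <- 1 + 0.1 * a * ramp
      cbind(v[, 1L] * mult, v[, 2L] * mult, v[, 3L])
    },
    broad_shift = {
      g <- u * (1 - u) / (.tpl$peak_u * (1 - .tpl$peak_u))
      v[, 3L] <- v[, 3L] + 15 * a * g; v
    })
  surface_mesh(v, mesh$faces, frame_note = mesh$frame_note)
}

# Unit-amplitude displacement fields on the template vertices, one 3n-vector
# per mode. The cohort generator superposes these linearly in the true
# weights, so the noise-free population lies exactly in their span.
mode_displacement_basis <- function(template) {
  v0 <- as.numeric(t(template$vertices))
  vapply(deformation_modes(), function(m) {
    as.numeric(t(apply_mode_deformation(template, m, 1)$vertices)) - v0
  }, numeric(length(v0)))
}

#' Generator configuration
#'
#' @param n_subjects number of specimens (>= 2).
#' @param mode_sds named or positional per-mode SDs of the true weights
#'   (dimensionless); recycled/zero-padded to the five modes of
#'   [deformation_modes()]. Default 1 for every mode.
#' @param noise_sd per-vertex isotropic displacement SD in mm (per
#'   coordinate). Default 0.5 mm, of the order of segmentation/voxel noise.
#' @param resolution template tessellation rings (>= 4).
#' @param group_offset per-mode mean shift of the true weights
#'   (dimensionless), recycled like `mode_sds`. Default 0.
#' @param seed integer RNG seed.
#' @param shuffle_topology if TRUE each specimen is re-tessellated with a
#'   randomly rotated circumferential seam, so vertex indices no longer
#'   correspond across specimens and registration is genuinely exercised.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects,
                             mode_sds = 1,
                             noise_sd = 0.5,
                             resolution = 16L,
                             group_offset = 0,
                             seed = 1L,
                             shuffle_topology = FALSE) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) abort_parameter("n_subjects must be >= 2")
  if (any(mode_sds < 0) || any(!is.finite(mode_sds))) {
    abort_parameter("mode_sds must be finite and non-negative")
  }
  if (length(noise_sd) != 1L || noise_sd < 0 || !is.finite(noise_sd)) {
    abort_parameter("noise_sd must be a single non-negative value")
  }
  if (as.integer(resolution) < 4L) abort_parameter("resolution must be >= 4 rings")
  modes <- deformation_modes()
  expand <- function(x, default) {
    out <- rep(default, length(modes))
    names(out) <- modes
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      unknown <- setdiff(names(x), modes)
      if (length(unknown)) abort_parameter(sprintf("unknown mode name '%s'", unknown[1L]))
      out[names(x)] <- x
    } else {
      out[seq_along(x)] <- x
    }
    out
  }
  structure(list(
    n_subjects = n_subjects,
    mode_sds = expand(mode_sds, if (length(mode_sds) == 1L && is.null(names(mode_sds))) mode_sds else 0),
    noise_sd = noise_sd,
    resolution = as.integer(resolution),
    group_offset = expand(group_offset, if (length(group_offset) == 1L && is.null(names(group_offset))) group_offset else 0),
    seed = as.integer(seed),
    shuffle_topology = isTRUE(shuffle_topology)
  ), class = "generator_config")
}

#' Generate one synthetic cohort
#'
#' Per specimen, true mode weights are drawn independently as
#' `N(group_offset, mode_sds^2)`; the specimen is the template plus the
#' weight-scaled superposition of the five unit-amplitude mode displacement
#' fields, plus i.i.d. isotropic Gaussian vertex noise. Identical seeds give
#' identical output.
#'
#' @param config a [generator_config()].
#' @param label cohort label attached to every specimen.
#' @return a `cohort_sample` list: `meshes`, `true_weights` (tibble, one row
#'   per specimen with the drawn mode weights), `labels`, `template`.
#' @export
generate_cohort <- function(config, label = "A") {
  if (!inherits(config, "generator_config")) {
    abort_parameter("config must be a generator_config")
  }
  template <- base_soleus_template(config$resolution)
  basis <- mode_displacement_basis(template)
  modes <- deformation_modes()
  C <- 2L * config$resolution
  withr::with_seed(config$seed, {
    W <- sapply(modes, function(m) {
      stats::rnorm(config$n_subjects, mean = config$group_offset[[m]],
                   sd = config$mode_sds[[m]])
    })
    W <- matrix(W, nrow = config$n_subjects,
                dimnames = list(NULL, modes))
    seams <- if (config$shuffle_topology) {
      sample.int(C, config$n_subjects, replace = TRUE) - 1L
    } else {
      integer(config$n_subjects)
    }
    meshes <- vector("list", config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      base_i <- if (seams[i] == 0L) template else
        base_soleus_template(config$resolution, seam_offset = seams[i])
      basis_i <- if (seams[i] == 0L) basis else mode_displacement_basis(base_i)
      vec <- as.numeric(t(base_i$vertices)) + as.numeric(basis_i %*% W[i, ])
      if (config$noise_sd > 0) {
        vec <- vec + stats::rnorm(length(vec), sd = config$noise_sd)
      }
      meshes[[i]] <- surface_mesh(matrix(vec, ncol = 3L, byrow = TRUE),
                                  base_i$faces)
    }
  })
  tw <- tibble::as_tibble(as.data.frame(W))
  tw <- tibble::add_column(tw,
    specimen_id = sprintf("%s%03d", label, seq_len(config$n_subjects)),
    label = label, .before = 1L)
  structure(list(meshes = meshes, true_weights = tw,
                 labels = rep(label, config$n_subjects),
                 template = template),
            class = "cohort_sample")
}

#' Generate a two-group synthetic study
#'
#' Concatenates two cohorts labelled `"A"` and `"B"`; any group difference
#' enters only through the configs' `group_offset` (e.g. group A offsets of
#' -0.8 on `size` and +0.8 on `aspect` encode smaller muscles that are also
#' long, thin and narrow).
#'
#' @param config_a,config_b [generator_config()]s sharing `resolution`.
#' @return a `cohort_sample` with `n_a + n_b` specimens and labels A/B.
#' @export
generate_two_group_study <- function(config_a, config_b) {
  if (!inherits(config_a, "generator_config") || !inherits(config_b, "generator_config")) {
    abort_parameter("both configs must be generator_config objects")
  }
  if (config_a$resolution != config_b$resolution) {
    abort_parameter("the two configs must share the template resolution")
  }
  if (config_a$seed == config_b$seed) {
    # independent draws per group; derive a distinct stream for B
    config_b$seed <- config_b$seed + 1000003L
  }
  a <- generate_cohort(config_a, label = "A")
  b <- generate_cohort(config_b, label = "B")
  structure(list(
    meshes = c(a$meshes, b$meshes),
    true_weights = dplyr::bind_rows(a$true_weights, b$true_weights),
    labels = c(a$labels, b$labels),
    template = a$template
  ), class = "cohort_sample")
}

#' Write a cohort to disk as STL files plus a manifest
#'
#' @param cohort a `cohort_sample`.
#' @param dir output directory (created if needed).
#' @param force overwrite a non-empty directory.
#' @return tibble manifest (also written to `manifest.csv`): specimen_id,
#'   label, side, path and the true mode weights.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    abort_io(sprintf("output directory '%s' is not empty (use force = TRUE)", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$true_weights$specimen_id
  paths <- file.path(dir, paste0(ids, ".stl"))
  for (i in seq_along(cohort$meshes)) {
    write_mesh(cohort$meshes[[i]], paths[i], format = "stl")
  }
  manifest <- tibble::add_column(cohort$true_weights,
                                 side = "R",
                                 path = basename(paths),
                                 .after = "label")
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}
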