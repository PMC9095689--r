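#' Study orchestration
#'
#' These functions reproduce the full study workflow on synthetic or
#' user-supplied meshes: generate (or read) a two-group cohort, build
#' per-cohort and combined morphological and appearance models with
#' leave-one-out validation, and compare the groups via difference maps and
#' the per-PC test battery. Each step writes plain-text artifacts (STL/PLY,
#' CSV, JSON) tagged with a hash of the configuration, and reruns under the
#' same seed are byte-identical.
#'
#' @name pipeline
NULL

#' Study configuration
#'
#' @param synthetic list with the two generator blocks: `a` and `b`, each a
#'   [generator_config()]; or NULL when reading meshes from disk.
#' @param mesh_dir directory of STL meshes plus `manifest.csv`
#'   (columns specimen_id, label, side, path) when `synthetic` is NULL; rows
#'   with `side == "L"` are reflected sagittally on load.
#' @param k retained modes per model.
#' @param alpha significance level for group comparison.
#' @param outlier_rule outlier rule for [compare_groups()].
#' @param registration a [registration_settings()] list.
#' @param correspond set FALSE to trust vertex-wise correspondence of the
#'   input meshes (shared topology) and skip non-rigid registration.
#' @param seed study seed (drives the synthetic generators).
#' @return a `study_config` list.
#' @export
study_config <- function(synthetic = NULL, mesh_dir = NULL, k = 9L,
                         alpha = 0.05, outlier_rule = "iqr",
                         registration = registration_settings(),
                         correspond = TRUE, seed = 1L) {
  if (is.null(synthetic) == is.null(mesh_dir)) {
    abort_parameter("exactly one input source: synthetic block or mesh_dir")
  }
  if (k < 1L) abort_parameter("k must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort_parameter("alpha must be in (0, 1)")
  structure(list(synthetic = synthetic, mesh_dir = mesh_dir,
                 k = as.integer(k), alpha = alpha,
                 outlier_rule = outlier_rule, registration = registration,
                 correspond = isTRUE(correspond), seed = as.integer(seed)),
            class = "study_config")
}

#' Default synthetic two-group study configuration
#'
#' The package's reference study: group A emulates a cohort of smaller,
#' longer-thinner muscles (size offset -0.8 SD, aspect offset +0.8 SD,
#' n = 19) versus an unshifted group B (n = 17), unit mode SDs, 0.5 mm vertex
#' noise, ~1500-vertex tessellation, shuffled topology so correspondence must
#' be established by registration.
#'
#' @param seed study seed.
#' @param resolution template rings (27 gives 1460 vertices).
#' @param shuffle_topology re-tessellate each specimen (default TRUE).
#' @param noise_sd per-vertex noise SD in mm.
#' @return a [study_config()].
#' @export
default_study_config <- function(seed = 1L, resolution = 27L,
                                 shuffle_topology = TRUE, noise_sd = 0.5) {
  seed <- as.integer(seed)
  study_config(
    synthetic = list(
      a = generator_config(n_subjects = 19L,
                           group_offset = c(size = -0.8, aspect = 0.8),
                           noise_sd = noise_sd, resolution = resolution,
                           seed = seed, shuffle_topology = shuffle_topology),
      b = generator_config(n_subjects = 17L, noise_sd = noise_sd,
                           resolution = resolution, seed = seed + 500009L,
                           shuffle_topology = shuffle_topology)
    ),
    k = 9L, seed = seed
  )
}

#' Load a study configuration from YAML
#'
#' Top-level keys mirror [study_config()]; generator blocks live under
#' `synthetic: {a: ..., b: ...}` and registration settings under
#' `registration:`.
#'
#' @param path YAML file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    syn <- lapply(y$synthetic, function(blk) {
      for (field in c("mode_sds", "group_offset")) {
        if (!is.null(blk[[field]])) blk[[field]] <- unlist(blk[[field]])
      }
      do.call(generator_config, blk)
    })
  }
  reg <- if (is.null(y$registration)) registration_settings() else
    do.call(registration_settings, y$registration)
  study_config(synthetic = syn, mesh_dir = y$mesh_dir,
               k = y$k %||% 9L, alpha = y$alpha %||% 0.05,
               outlier_rule = y$outlier_rule %||% "iqr",
               registration = reg,
               correspond = y$correspond %||% TRUE,
               seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) rlang::hash(unclass(config))

# --- model persistence (plain-text archive directory) ------------------------

#' Write a shape model to a plain-text archive directory
#'
#' The archive holds mean.csv, modes.csv, variances.csv, topology.csv and
#' meta.json — deterministic text, so identical models produce identical
#' archives.
#'
#' @param model a `shape_model`.
#' @param dir archive directory (created).
#' @param meta optional named list merged into meta.json (e.g. settings,
#'   seed, config hash).
#' @return `dir`, invisibly.
#' @export
write_shape_model <- function(model, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tibble::tibble(mean = as.numeric(model$mean)),
                   file.path(dir, "mean.csv"))
  md <- tibble::as_tibble(as.data.frame(model$modes))
  names(md) <- paste0("mode", seq_len(ncol(md)))
  readr::write_csv(md, file.path(dir, "modes.csv"))
  readr::write_csv(tibble::tibble(all_variance = model$all_variances),
                   file.path(dir, "all_variances.csv"))
  if (!is.null(model$topology)) {
    tp <- as.data.frame(model$topology)
    names(tp) <- c("v1", "v2", "v3")
    readr::write_csv(tibble::as_tibble(tp), file.path(dir, "topology.csv"))
  }
  meta_all <- c(list(k = model$k, m = model$m,
                     n_vertices = attr(model$mean, "n_vertices"),
                     normalized = model$normalized,
                     package_version = as.character(utils::packageVersion("soleusshape"))),
                meta)
  jsonlite::write_json(meta_all, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a shape model archive written by [write_shape_model()]
#' @param dir archive directory.
#' @return a `shape_model`.
#' @export
read_shape_model <- function(dir) {
  if (!file.exists(file.path(dir, "meta.json"))) {
    abort_io(sprintf("no shape-model archive at '%s' (expected meta.json)", dir))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  mu <- readr::read_csv(file.path(dir, "mean.csv"), show_col_types = FALSE)$mean
  modes <- as.matrix(readr::read_csv(file.path(dir, "modes.csv"),
                                     show_col_types = FALSE))
  dimnames(modes) <- NULL
  allv <- readr::read_csv(file.path(dir, "all_variances.csv"),
                          show_col_types = FALSE)$all_variance
  topo <- NULL
  if (file.exists(file.path(dir, "topology.csv"))) {
    topo <- as.matrix(readr::read_csv(file.path(dir, "topology.csv"),
                                      show_col_types = FALSE))
    dimnames(topo) <- NULL
    storage.mode(topo) <- "integer"
  }
  structure(list(
    mean = new_shape_vector(mu, meta$n_vertices),
    modes = modes,
    variances = allv[seq_len(meta$k)],
    all_variances = allv,
    k = as.integer(meta$k), m = as.integer(meta$m),
    topology = topo, normalized = isTRUE(meta$normalized)
  ), class = "shape_model")
}

# --- pipeline steps ----------------------------------------------------------

#' Generate the synthetic study cohort and write it to disk
#'
#' @param config a [study_config()] with a synthetic block.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest tibble.
#' @export
run_generate <- function(config, out_dir, force = FALSE) {
  if (is.null(config$synthetic)) abort_parameter("config has no synthetic block")
  study <- generate_two_group_study(config$synthetic$a, config$synthetic$b)
  manifest <- write_cohort(study, out_dir, force = force)
  snap <- c(config_to_list(config), list(config_hash = config_hash(config)))
  yaml::write_yaml(snap, file.path(out_dir, "config.yaml"))
  manifest
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    out$synthetic <- lapply(out$synthetic, function(g) {
      g <- unclass(g)
      g$mode_sds <- as.list(g$mode_sds)
      g$group_offset <- as.list(g$group_offset)
      g
    })
  }
  out
}

#' Load the study cohort (synthetic or from disk)
#'
#' For disk input, manifest rows with `side == "L"` are reflected against the
#' sagittal plane on load.
#'
#' @param config a [study_config()].
#' @return list with `meshes`, `labels`, `specimen_ids`, and (synthetic only)
#'   `true_weights`.
#' @export
load_study_inputs <- function(config) {
  if (!is.null(config$synthetic)) {
    study <- generate_two_group_study(config$synthetic$a, config$synthetic$b)
    return(list(meshes = study$meshes, labels = study$labels,
                specimen_ids = study$true_weights$specimen_id,
                true_weights = study$true_weights))
  }
  man_path <- file.path(config$mesh_dir, "manifest.csv")
  if (!file.exists(man_path)) {
    abort_io(sprintf("expected manifest at '%s'", man_path))
  }
  man <- readr::read_csv(man_path, show_col_types = FALSE)
  meshes <- lapply(seq_len(nrow(man)), function(i) {
    msh <- read_mesh(file.path(config$mesh_dir, man$path[i]))
    if (!is.null(man$side) && identical(man$side[i], "L")) {
      msh <- reflect_sagittal(msh)
    }
    msh
  })
  list(meshes = meshes, labels = man$label, specimen_ids = man$specimen_id,
       true_weights = NULL)
}

#' Build all study models
#'
#' Builds, for each cohort and for the combined set, both the morphological
#' (non-normalized) and appearance (normalized) models — six models in all —
#' plus leave-one-out reports. Registration (iterative RBF refitting against
#' the common reference, the first specimen of group A) runs once per mesh
#' set; the appearance model reuses its cohort's correspondence.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, model archives, weight CSVs
#'   and LOO/RMS CSVs are written under it.
#' @param inputs optional pre-loaded [load_study_inputs()] result.
#' @return list of builds keyed `A`, `B`, `combined`, each with `morphological`
#'   and `appearance` model builds and `loo` reports, plus `inputs`.
#' @export
run_build <- function(config, out_dir = NULL, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_study_inputs(config)
  labs <- sort(unique(inputs$labels))
  sets <- c(stats::setNames(lapply(labs, function(l) which(inputs$labels == l)), labs),
            list(combined = seq_along(inputs$labels)))
  reference <- inputs$meshes[[1L]]
  builds <- list()
  for (nm in names(sets)) {
    idx <- sets[[nm]]
    morph <- build_model(inputs$meshes[idx], normalize = FALSE, k = config$k,
                         labels = inputs$labels[idx],
                         specimen_ids = inputs$specimen_ids[idx],
                         settings = config$registration,
                         reference = reference,
                         correspond = config$correspond)
    # appearance model reuses the correspondence established for this set
    scale_ref <- compute_mean(morph$shape_vectors)
    norm <- size_normalize(morph$shape_vectors, scale_ref)
    app_model <- fit_pca(norm$normalized, k = min(config$k, length(idx) - 1L),
                         topology = morph$model$topology, normalized = TRUE)
    app_weights <- extract_weights(app_model, norm$normalized,
                                   inputs$labels[idx],
                                   specimen_ids = inputs$specimen_ids[idx])
    appearance <- list(model = app_model, weights = app_weights,
                       rms_report = morph$rms_report,
                       shape_vectors = norm$normalized,
                       scale_factors = norm$scale_factors)
    k_loo <- min(config$k, length(idx) - 2L)
    loo <- list(
      morphological = leave_one_out_rms(morph$shape_vectors, k = k_loo),
      appearance = leave_one_out_rms(norm$normalized, k = k_loo)
    )
    builds[[nm]] <- list(morphological = morph, appearance = appearance,
                         loo = loo)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_hash(config)
    for (nm in names(builds)) {
      for (kind in c("morphological", "appearance")) {
        b <- builds[[nm]][[kind]]
        write_shape_model(b$model, file.path(out_dir, paste0("model_", nm, "_", kind)),
                          meta = list(config_hash = hash, set = nm, kind = kind))
        readr::write_csv(b$weights,
                         file.path(out_dir, sprintf("weights_%s_%s.csv", nm, kind)))
        readr::write_csv(tidy.loo_report(builds[[nm]]$loo[[kind]]),
                         file.path(out_dir, sprintf("loo_%s_%s.csv", nm, kind)))
      }
      readr::write_csv(builds[[nm]]$morphological$rms_report,
                       file.path(out_dir, sprintf("registration_rms_%s.csv", nm)))
    }
    writeLines(c(sprintf("config_hash: %s", hash),
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("soleusshape"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("k: %d", config$k)),
               file.path(out_dir, "run_log.txt"))
  }
  c(builds, list(inputs = inputs))
}

#' Compare the study groups
#'
#' Mean-vs-mean difference maps for the two cohorts (non-normalized and
#' normalized) and the per-PC statistical battery on the combined models'
#' weights. Both difference maps are computed from the combined build's shape
#' vectors, so the two cohort means share one registration frame and — for the
#' appearance map — one size-normalization reference; per-cohort normalization
#' would silently retain the between-group size difference.
#'
#' @param config a [study_config()].
#' @param builds result of [run_build()].
#' @param out_dir optional output directory for PLY difference maps and
#'   CSV/JSON test results.
#' @return list with `difference_maps` (morphological, appearance),
#'   `tests` (tibbles per model kind).
#' @export
run_compare <- function(config, builds, out_dir = NULL) {
  labs <- setdiff(names(builds), c("combined", "inputs"))
  if (length(labs) != 2L) abort_parameter("run_compare needs exactly two cohorts")
  diff_maps <- list()
  for (kind in c("morphological", "appearance")) {
    cb <- builds$combined[[kind]]
    topo <- builds$combined$morphological$model$topology
    all_labs <- cb$weights$label
    mesh_a <- shape_vector_to_mesh(
      compute_mean(cb$shape_vectors[all_labs == labs[1L]]), topo)
    mesh_b <- shape_vector_to_mesh(
      compute_mean(cb$shape_vectors[all_labs == labs[2L]]), topo)
    diff_maps[[kind]] <- mean_difference_map(mesh_a, mesh_b)
  }
  tests <- list(
    morphological = compare_groups(builds$combined$morphological$weights,
                                   alpha = config$alpha,
                                   outlier_rule = config$outlier_rule),
    appearance = compare_groups(builds$combined$appearance$weights,
                                alpha = config$alpha,
                                outlier_rule = config$outlier_rule)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (kind in names(diff_maps)) {
      dm <- diff_maps[[kind]]
      write_mesh(dm$mesh_a, file.path(out_dir, sprintf("diffmap_%s.ply", kind)),
                 format = "ply", scalars = dm$per_vertex_mm)
      ts <- tests[[kind]]
      readr::write_csv(dplyr::select(ts, -"outliers_excluded"),
                       file.path(out_dir, sprintf("tests_%s.csv", kind)))
      jsonlite::write_json(
        list(config_hash = config_hash(config),
             hausdorff_mm = dm$hausdorff_mm,
             mean_per_vertex_mm = mean(dm$per_vertex_mm)),
        file.path(out_dir, sprintf("diffmap_%s.json", kind)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  list(difference_maps = diff_maps, tests = tests)
}

#' Run the whole study end to end
#'
#' @param config a [study_config()].
#' @param out_dir optional root output directory (`models/` and `comparison/`
#'   are created under it).
#' @return list with `builds` and `comparison`.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL) {
  inputs <- load_study_inputs(config)
  builds <- run_build(config,
                      out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "models"),
                      inputs = inputs)
  comparison <- run_compare(config, builds,
                            out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "comparison"))
  list(builds = builds, comparison = comparison)
}
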