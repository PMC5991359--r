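# End-to-end workflow orchestration: generate -> fit -> correspond ->
# densify -> train -> loo -> morpho. Each stage writes its artifacts plus a
# small manifest (config hash, seed, per-specimen RMS where relevant) into a
# self-describing run directory, and later stages load what earlier stages
# wrote, so any stage can be re-run in isolation.

#' Default pipeline configuration
#'
#' @param n_specimens population size
#' @param seed master seed; all stage-level seeds derive from it
#' @return nested configuration list (serializes losslessly to JSON)
#' @export
default_pipeline_config <- function(n_specimens = 40L, seed = 20260101L) {
  list(
    seed = as.integer(seed),
    synthetic = default_synthetic_spec(n_specimens, seed),
    cloud = list(density = 0.25),
    fitting = list(lattice_shape = c(6L, 6L, 6L), regularization_weight = 3e-6,
                   smoothing_weight = 1e-3, coarse_threshold = 0.5,
                   rms_target = 0.3, max_rounds = 10L, variance_keep = 0.98),
    sampling = list(depth = 5, step = 0.25),
    model = list(variance_target = 0.80, density_channel = "bmd"),
    loo = list(max_components = 10L)
  )
}

#' Read / write a pipeline configuration (JSON)
#' @param config configuration list
#' @param path file path
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$synthetic$base_shape_params <- as.list(cfg$synthetic$base_shape_params)
  cfg$synthetic <- validate_synthetic_spec(cfg$synthetic)
  cfg
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

stage_file <- function(stage_dir, stage, what, ext = "rds")
  file.path(stage_dir, stage, paste0(what, ".", ext))

load_stage <- function(stage_dir, stage, what) {
  f <- stage_file(stage_dir, stage, what)
  if (!file.exists(f))
    stop("missing artifact '", what, "' from stage '", stage,
         "'; run that stage first")
  readRDS(f)
}

write_manifest <- function(stage_dir, stage, config, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = config_hash(config),
           seed = config$seed,
           package_version = as.character(utils::packageVersion("mc3ssm"))),
      extra),
    file.path(stage_dir, stage, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
}

#' Run one pipeline stage
#'
#' Stages: `generate` (synthetic population + point clouds), `fit` (coarse
#' host-mesh + fine fit per cloud), `correspond` (model-constrained
#' correspondence loop + alignment), `densify` (voxelize each specimen,
#' sample subchondral density on the fitted mesh), `train` (shape, density
#' and combined models + variance table), `loo` (leave-one-out curves),
#' `morpho` (population morphometry + mode effects), or `run_all`.
#'
#' @param stage stage name
#' @param config configuration from [default_pipeline_config()]
#' @param stage_dir run directory (created if needed)
#' @param verbose print progress?
#' @return invisibly, the stage's main artifact
#' @export
run_stage <- function(stage = c("generate", "fit", "correspond", "densify",
                                "train", "loo", "morpho", "run_all"),
                      config = default_pipeline_config(),
                      stage_dir = "mc3ssm_run", verbose = TRUE) {
  stage <- match.arg(stage)
  if (stage == "run_all") {
    for (s in c("generate", "fit", "correspond", "densify", "train",
                "loo", "morpho"))
      run_stage(s, config, stage_dir, verbose)
    return(invisible(stage_dir))
  }
  dir.create(file.path(stage_dir, stage), recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- switch(stage,
    generate = {
      pop <- sample_population(config$synthetic)
      clouds <- lapply(seq_along(pop$specimens), function(i)
        export_point_cloud(pop$specimens[[i]], density = config$cloud$density,
                           seed = config$seed + i))
      saveRDS(pop, stage_file(stage_dir, stage, "population"))
      saveRDS(clouds, stage_file(stage_dir, stage, "clouds"))
      say("generate: %d specimens, %d-%d cloud points", length(clouds),
          min(vapply(clouds, nrow, 0L)), max(vapply(clouds, nrow, 0L)))
      write_manifest(stage_dir, stage, config,
                     list(n_specimens = length(clouds)))
      pop
    },
    fit = {
      clouds <- load_stage(stage_dir, "generate", "clouds")
      template <- make_base_shape(config$synthetic$base_shape_params)
      fc <- config$fitting
      coarse <- lapply(clouds, function(cl)
        host_mesh_fit(template, cl, lattice_shape = fc$lattice_shape,
                      regularization_weight = fc$regularization_weight))
      fits <- lapply(seq_along(clouds), function(i)
        fine_fit(coarse[[i]], clouds[[i]],
                 smoothing_weight = fc$smoothing_weight))
      saveRDS(list(coarse_rms = vapply(coarse, `[[`, 0, "rms"), fits = fits),
              stage_file(stage_dir, stage, "fits"))
      say("fit: coarse RMS %.3f mm (max %.3f), fine RMS %.3f mm (max %.3f)",
          mean(vapply(coarse, `[[`, 0, "rms")),
          max(vapply(coarse, `[[`, 0, "rms")),
          mean(vapply(fits, `[[`, 0, "rms")),
          max(vapply(fits, `[[`, 0, "rms")))
      write_manifest(stage_dir, stage, config,
                     list(coarse_rms = vapply(coarse, `[[`, 0, "rms"),
                          fine_rms = vapply(fits, `[[`, 0, "rms")))
      fits
    },
    correspond = {
      clouds <- load_stage(stage_dir, "generate", "clouds")
      fits <- load_stage(stage_dir, "fit", "fits")$fits
      template <- make_base_shape(config$synthetic$base_shape_params)
      fc <- config$fitting
      ts <- correspondence_loop(template, clouds, fits,
                                rms_target = fc$rms_target,
                                max_rounds = fc$max_rounds,
                                variance_keep = fc$variance_keep,
                                smoothing_weight = fc$smoothing_weight,
                                verbose = verbose)
      saveRDS(ts, stage_file(stage_dir, stage, "training_set"))
      say("correspond: mean RMS %.3f mm after %d round(s)", ts$mean_rms, ts$rounds)
      write_manifest(stage_dir, stage, config,
                     list(mean_rms = ts$mean_rms, rounds = ts$rounds,
                          rms = ts$rms))
      ts
    },
    densify = {
      pop <- load_stage(stage_dir, "generate", "population")
      ts <- load_stage(stage_dir, "correspond", "training_set")
      dens <- matrix(NA_real_, length(ts$fits), mc3_topology()$n_nodes)
      flags <- dens
      for (i in seq_along(ts$fits)) {
        vol <- voxelize(pop$specimens[[i]], config$synthetic,
                        seed = config$seed + 10000L + i)
        calib <- estimate_calibration(vol)
        fld <- node_density_field(ts$fits[[i]]$mesh, vol, calib,
                                  depth = config$sampling$depth,
                                  step = config$sampling$step)
        dens[i, ] <- fld$rho_ha
        flags[i, ] <- as.numeric(fld$flagged)
        say("densify: specimen %d/%d", i, length(ts$fits))
      }
      saveRDS(list(rho_ha = dens, flagged = flags > 0),
              stage_file(stage_dir, stage, "density"))
      write_manifest(stage_dir, stage, config,
                     list(flagged_nodes = sum(flags > 0)))
      dens
    },
    train = {
      ts <- load_stage(stage_dir, "correspond", "training_set")
      dn <- load_stage(stage_dir, "densify", "density")
      dens <- dn$rho_ha
      dens[is.na(dens)] <- mean(dens, na.rm = TRUE)
      if (identical(config$model$density_channel, "modulus"))
        dens <- rho_ha_to_modulus(pmax(dens, 0))$modulus
      vt <- config$model$variance_target
      models <- list(
        shape = ssm_train(ts$aligned$matrix, "shape", vt),
        density = ssm_train(dens, "density", vt),
        combined = ssm_train(build_combined_matrix(ts$aligned$matrix, dens),
                             "combined", vt))
      saveRDS(models, stage_file(stage_dir, stage, "models"))
      tab <- variance_table(shape = models$shape, density = models$density,
                            combined = models$combined)
      utils::write.csv(tab, stage_file(stage_dir, stage, "variance_table",
                                       "csv"), row.names = FALSE)
      say("train: combined leading fractions %s (retained %d)",
          paste(sprintf("%.3f", utils::head(models$combined$variance_fractions, 3)),
                collapse = " "), models$combined$n_retained)
      write_manifest(stage_dir, stage, config,
                     list(n_retained = vapply(models, `[[`, 0L, "n_retained")))
      models
    },
    loo = {
      ts <- load_stage(stage_dir, "correspond", "training_set")
      dn <- load_stage(stage_dir, "densify", "density")
      dens <- dn$rho_ha
      dens[is.na(dens)] <- mean(dens, na.rm = TRUE)
      if (nrow(dens) < 3) {
        say("loo: skipped (needs at least 3 specimens)")
        curve <- data.frame(k = integer(0), geometric_rms = numeric(0),
                            density_rms = numeric(0))
        utils::write.csv(curve, stage_file(stage_dir, stage, "loo_curve",
                                           "csv"), row.names = FALSE)
        saveRDS(curve, stage_file(stage_dir, stage, "loo_curve"))
        write_manifest(stage_dir, stage, config)
        return(invisible(curve))
      }
      curve <- loo_analysis(ts$aligned$matrix, dens, "combined",
                            max_components = config$loo$max_components)
      utils::write.csv(curve, stage_file(stage_dir, stage, "loo_curve", "csv"),
                       row.names = FALSE)
      saveRDS(curve, stage_file(stage_dir, stage, "loo_curve"))
      say("loo: geometric RMS %.3f mm (k=0) -> %.3f mm (k=%d)",
          curve$geometric_rms[1], curve$geometric_rms[nrow(curve)],
          curve$k[nrow(curve)])
      write_manifest(stage_dir, stage, config)
      curve
    },
    morpho = {
      ts <- load_stage(stage_dir, "correspond", "training_set")
      models <- load_stage(stage_dir, "train", "models")
      tab <- morphometry_table(ts$fits)
      utils::write.csv(tab, stage_file(stage_dir, stage, "morphometry", "csv"),
                       row.names = FALSE)
      eff <- mode_effect_summary(models$combined, n_modes = 3L)
      write_mode_effects(eff,
                         csv_path = stage_file(stage_dir, stage,
                                               "mode_effects", "csv"),
                         json_path = stage_file(stage_dir, stage,
                                                "mode_effects", "json"))
      say("morpho: %d specimens measured, %d mode effects", nrow(tab),
          length(eff))
      write_manifest(stage_dir, stage, config)
      list(morphometry = tab, effects = eff)
    })
  invisible(out)
}
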