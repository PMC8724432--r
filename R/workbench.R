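# Pipeline configuration, validation and orchestration.

pipeline_defaults <- list(
  mode = "self",
  regularization_lambda = 10,
  n_iterations = 6,
  cov_threshold = 0.3,
  apply_cov_selection = FALSE,
  max_distance_mm = 110,
  mesh_h_mm = 2.5,
  generator = "diffusion",
  gain_sigma = 0,
  noise_sigma = 0,
  n_photons = 1e6,
  wavelengths = NA_real_,
  seed = 1L
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML/JSON configuration, checks cross-field constraints,
#' injects defaults (regularization lambda 10, 6 iterations, CoV
#' threshold 0.3, maximum SD distance 110 mm, mesh size 2.5 mm) and
#' echoes them to the log. All problems are collected and reported
#' together.
#'
#' @param config_path path to the configuration file, or a list with
#'   the same fields (useful programmatically)
#' @return a validated `pipeline_config` list
#' @export
load_and_validate <- function(config_path) {
  cfg <- if (is.list(config_path)) config_path else read_config_file(config_path)
  problems <- character(0)
  injected <- setdiff(names(pipeline_defaults), names(cfg))
  cfg <- utils::modifyList(pipeline_defaults, cfg)

  if (!cfg$mode %in% c("self", "reference"))
    problems <- c(problems, "mode must be 'self' or 'reference'")
  has_sim <- !is.null(cfg$scenario) || !is.null(cfg$phantom)
  if (!has_sim)
    problems <- c(problems, "either 'scenario' (preset name) or 'phantom' (YAML path) is required")
  if (!is.null(cfg$scenario) && !is.null(cfg$phantom))
    problems <- c(problems, "give 'scenario' or 'phantom', not both")
  if (!is.null(cfg$scenario) && !cfg$scenario %in% scenario_names)
    problems <- c(problems, sprintf("unknown scenario '%s' (see ?scenario_presets)",
                                    cfg$scenario))
  if (cfg$mode == "reference" && !has_sim && is.null(cfg$reference_measurements))
    problems <- c(problems, "mode 'reference' needs a reference measurement input")
  if (cfg$mode == "self" && !is.null(cfg$reference_measurements))
    problems <- c(problems, "mode 'self' must not be given reference measurements")
  if (!is.null(cfg$phantom) && is.null(cfg$probe))
    problems <- c(problems, "'phantom' configurations also need a 'probe' config path")
  for (f in c("regularization_lambda", "cov_threshold", "max_distance_mm",
              "mesh_h_mm", "gain_sigma", "noise_sigma"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      problems <- c(problems, sprintf("'%s' must be a non-negative number", f))
  if (!is.numeric(cfg$n_iterations) || cfg$n_iterations < 1)
    problems <- c(problems, "'n_iterations' must be >= 1")
  if (!cfg$generator %in% c("diffusion", "mc"))
    problems <- c(problems, "generator must be 'diffusion' or 'mc'")
  if (length(problems))
    dc_stop("dotcal_validation_error",
            paste0("invalid pipeline configuration:\n  - ",
                   paste(problems, collapse = "\n  - ")))
  if (length(injected))
    message("defaults injected: ",
            paste(sprintf("%s=%s", injected,
                          vapply(cfg[injected], function(v) paste(format(v), collapse = ","), "")),
                  collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Normalize and write a pipeline configuration
#'
#' Writing a loaded configuration and re-loading it is idempotent.
#'
#' @param config a `pipeline_config`
#' @param path output YAML/JSON path
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  write_config_file(x, path)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    dc_stop("dotcal_stage_error",
            sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            stage = name)
  })
}

#' Run the full measurement-to-image pipeline
#'
#' Executes simulate (or load) -> exclusions -> optional CoV-based
#' non-boundary selection -> calibrate (self or reference) ->
#' reconstruct -> metrics (-> unmix when several wavelengths with
#' per-wavelength optical properties are configured), writing volumes,
#' reports and a provenance manifest to `out_dir`. Deterministic for a
#' given seed.
#'
#' @param config a `pipeline_config` from [load_and_validate()] (or a
#'   path/list accepted by it)
#' @param out_dir output directory (default `config$out_dir`, or a
#'   tempdir)
#' @return (invisibly) a list with the key artifacts: measurement sets,
#'   classes, reconstruction, metrics, manifest and file paths
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) config <- load_and_validate(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("dotcal_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()

  setup <- stage("setup", {
    if (!is.null(config$scenario)) {
      sc <- scenario_presets(config$scenario)
      list(spec = sc$phantom_spec, probe = sc$probe)
    } else {
      list(spec = read_phantom_yaml(config$phantom),
           probe = read_probe_config(config$probe)$probe)
    }
  })
  phantom <- stage("mesh", build_phantom(setup$spec, h = config$mesh_h_mm))

  pairs <- stage("exclusions", {
    p <- enumerate_pairs(setup$probe)
    p <- apply_exclusions(p, coverage = config$coverage,
                          max_distance = config$max_distance_mm)
    p
  })
  log_counts$after_exclusions <- sum(!pairs$excluded)
  message(sprintf("[exclusions] retained %d of %d pairs",
                  log_counts$after_exclusions, nrow(pairs)))

  sim <- stage("simulate", {
    gm <- gain_model(setup$probe, gain_sigma = config$gain_sigma,
                     noise_sigma = config$noise_sigma, seed = config$seed)
    simulate_dataset(phantom, setup$probe, pairs, gains = gm,
                     generator = config$generator, seed = config$seed,
                     n_photons = config$n_photons)
  })
  task <- sim$task

  selection_report <- NULL
  if (isTRUE(config$apply_cov_selection)) {
    sel <- stage("cov_selection",
                 select_non_boundary(setup$probe, pairs, task,
                                     cov_threshold = config$cov_threshold))
    pairs <- sel$pairs
    selection_report <- sel$report
    keep_mask <- pairs$excluded
    for (nm in c("task", "reference", "predicted"))
      sim[[nm]]$excluded <- keep_mask
    task <- sim$task
    log_counts$after_cov_selection <- sum(!pairs$excluded)
    message(sprintf("[cov_selection] retained %d pairs after %d peel iteration(s)",
                    log_counts$after_cov_selection, nrow(sel$report)))
  }

  calib <- stage("calibrate", {
    classes <- attach_measurements(group_by_distance(pairs), task)
    if (config$mode == "self") {
      est <- build_virtual_reference(task, classes)
      list(classes = classes, estimated = est,
           calibrated = self_calibrate(task, est, sim$predicted),
           report = calibration_report(task, classes, reference = sim$reference))
    } else {
      list(classes = classes, estimated = NULL,
           calibrated = reference_calibrate(task, sim$reference, sim$predicted),
           report = calibration_report(task, classes, reference = sim$reference))
    }
  })
  message(sprintf("[calibrate] mode=%s over %d classes; reference-fidelity error %.4g",
                  config$mode, length(calib$classes),
                  calib$report$overall_error))

  settings <- recon_settings(regularization_lambda = config$regularization_lambda,
                             n_iterations = config$n_iterations)
  image <- stage("reconstruct",
                 reconstruct_absorption(calib$calibrated, phantom$reference,
                                        setup$probe, settings))

  metrics <- stage("metrics", {
    m <- list(calibration_error = calib$report$overall_error,
              mode = config$mode)
    incs <- setup$spec$inclusions
    if (length(incs) == 2) {
      mid_y <- mean(vapply(incs, function(i) i$center[2], numeric(1)))
      pk <- target_peak_ratio(image, split_y = mid_y)
      m$peak1 <- pk$peak1; m$peak2 <- pk$peak2
      m$contrast_ratio <- pk$ratio
      lp <- line_profile_metrics(image, line = list(x = incs[[1]]$center[1],
                                                    z = incs[[1]]$center[3]))
      m$fwhm_mm <- lp$peaks$fwhm
      m$profile <- lp
    }
    m
  })

  arts <- stage("write_outputs", {
    paths <- list(
      measurements = file.path(out_dir, "measurements.csv"),
      exclusions = file.path(out_dir, "exclusion_report.csv"),
      calibration = file.path(out_dir, "calibration_report.json"),
      volume = file.path(out_dir, "mu_a.nii.gz"),
      metrics = file.path(out_dir, "metrics.json"),
      manifest = file.path(out_dir, "manifest.json")
    )
    sets <- list(sim$task, sim$reference, sim$predicted, calib$calibrated)
    if (!is.null(calib$estimated)) sets <- c(sets, list(calib$estimated))
    write_measurements(sets, paths$measurements)
    write_exclusion_report(pairs, paths$exclusions)
    calibration_report(task, calib$classes, reference = sim$reference,
                       path = paths$calibration)
    write_absorption_nifti(image, paths$volume)
    if (!is.null(metrics$profile)) {
      paths$profile <- file.path(out_dir, "profile.csv")
      write_profile_csv(metrics$profile, paths$profile)
    }
    jsonlite::write_json(metrics[setdiff(names(metrics), "profile")],
                         paths$metrics, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths
  })

  manifest <- list(
    config = unclass(config)[order(names(unclass(config)))],
    generator = sim$manifest,
    retained_pairs = log_counts,
    n_classes = length(calib$classes),
    calibration_error = calib$report$overall_error,
    metrics = metrics[setdiff(names(metrics), "profile")],
    outputs = lapply(arts, basename)
  )
  jsonlite::write_json(manifest, arts$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(config = config, probe = setup$probe, phantom = phantom,
                 pairs = pairs, dataset = sim, classes = calib$classes,
                 calibrated = calib$calibrated, image = image,
                 metrics = metrics, selection_report = selection_report,
                 manifest = manifest, paths = arts))
}
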