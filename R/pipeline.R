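#' Validate a pipeline run configuration
#'
#' Checks cross-field constraints, fills defaults and echoes the completed
#' configuration. Configurations are plain named lists; a YAML file path is
#' accepted too.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `seed` (mandatory), `fixtures` (character vector of
#'   [make_fixture_scenario()] presets), `duration_days` (optional override),
#'   `model` (`"rw"`/`"uv"`), `window_len`, `k_set`, `k_max`, `dropout`,
#'   `clock_offset_range` (s), `alpha`, `sound_speed`, `out_dir`.
#' @return The validated config (class `run_config`) with defaults filled,
#'   or an error aggregating every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(fixtures = c("sync_tag", "growing_D"),
                   duration_days = NULL, model = "rw", window_len = 100,
                   k_set = c(1, 2, 4, 8), k_max = 30, dropout = 0.05,
                   clock_offset_range = 0.25, alpha = 0.01,
                   sound_speed = 1500, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]

  errs <- character(0)
  if (is.null(config$seed) || !is.numeric(config$seed))
    errs <- c(errs, "seed is mandatory and must be numeric")
  known <- c("sync_tag", "resting_C", "growing_D")
  if (!all(config$fixtures %in% known))
    errs <- c(errs, paste0("unknown fixture(s): ",
                           paste(setdiff(config$fixtures, known),
                                 collapse = ", ")))
  if (!config$model %in% c("rw", "uv"))
    errs <- c(errs, "model must be 'rw' or 'uv'")
  if (length(config$k_set) < 3)
    errs <- c(errs, "k_set needs at least 3 lags")
  if (config$window_len < 8)
    errs <- c(errs, "window_len must be >= 8")
  if (config$k_max < 8)
    errs <- c(errs, "k_max must be >= 8")
  if (config$dropout < 0 || config$dropout > 1)
    errs <- c(errs, "dropout must be in [0, 1]")
  if (config$sound_speed <= 0)
    errs <- c(errs, "sound_speed must be positive")
  if (!is.null(config$duration_days) && config$duration_days <= 0)
    errs <- c(errs, "duration_days must be positive")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' For each configured fixture: simulate the true path and the detection
#' logs (animal tag plus a fixed sync tag, with per-receiver clock offsets,
#' 1-ms quantization and dropout), synchronize clocks, group arrivals,
#' solve the TDOA positions, fit the state-space movement model with ML
#' noise estimation, and compute localization-error reports, hourly
#' displacement, fractal-dimension windows and (when two seasons are
#' present) the seasonal comparison and gamma GLM. All derived seeds come
#' from `config$seed`, so a rerun with the same config is deterministic.
#'
#' @param config a list or `run_config`; see [validate_config()].
#' @param force overwrite existing outputs in `out_dir`.
#' @return Object of class `run_manifest`: config echo, package version,
#'   per-stage record counts, warnings/tallies and per-fixture results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  config <- validate_config(unclass(config))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    manifest_path <- file.path(out_dir, "manifest.yaml")
    if (file.exists(manifest_path) && !force)
      stop("outputs already exist in ", out_dir,
           "; rerun with force = TRUE to overwrite")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  fixtures <- list()
  tables <- list()
  warnings_tally <- character(0)
  for (i in seq_along(config$fixtures)) {
    name <- config$fixtures[i]
    fseed <- config$seed + 1000L * i
    fx <- make_fixture_scenario(name, seed = fseed,
                                duration_days = config$duration_days)
    geometry <- array_geometry(as.data.frame(unclass(fx$geometry)),
                               attr(fx$geometry, "sync_receiver"),
                               config$sound_speed)
    path <- simulate_true_path(fx$scenario)

    offsets <- with_seed(fseed + 1L, setNames(
      runif(nrow(geometry), -config$clock_offset_range,
            config$clock_offset_range), geometry$receiver_id))
    offsets[attr(geometry, "sync_receiver")] <- 0

    sync_path <- simulate_true_path(movement_scenario(
      "stationary", sigma_true = 0, tau_true = 0,
      step_dt = fx$scenario$step_dt, duration = fx$scenario$duration,
      start = unname(sync_position(geometry)), seed = fseed + 2L))
    # timing jitter sized so the implied per-receiver range error matches
    # the scenario's observation-noise SD
    jitter <- fx$scenario$tau_true / config$sound_speed
    det_animal <- simulate_detections(path, geometry, tag_id = name,
                                      clock_offset = offsets,
                                      dropout = config$dropout,
                                      time_jitter = jitter,
                                      seed = fseed + 3L)
    det_sync <- simulate_detections(sync_path, geometry, tag_id = "sync",
                                    clock_offset = offsets,
                                    dropout = config$dropout,
                                    time_jitter = jitter,
                                    seed = fseed + 4L)
    log <- rbind(as.data.frame(det_animal), as.data.frame(det_sync))
    class(log) <- c("detection_log", "data.frame")

    clock <- synchronize_clocks(log, geometry)
    corrected <- apply_clock_correction(log, clock)
    sets <- group_arrivals(corrected, geometry)
    fixes <- locate_fixes(sets, geometry)

    fx_animal <- fixes[fixes$tag_id == name, ]
    fx_sync <- fixes[fixes$tag_id == "sync", ]
    native <- resample_series(fx_animal, "native")
    fit <- track_ssm(native, model = config$model,
                     dt = fx$scenario$step_dt)

    sync_report <- NULL
    if (nrow(fx_sync) >= 20) {
      sync_native <- resample_series(fx_sync, "native")
      sync_fit <- track_ssm(sync_native, model = "rw",
                            dt = fx$scenario$step_dt)
      truth <- unname(sync_position(geometry))
      sync_report <- list(
        raw = localization_error_report(fx_sync, truth, "raw hyperbolic"),
        smoothed = localization_error_report(
          fitted(sync_fit), truth, "Kalman smoothed"),
        noise = sync_fit$noise)
    }

    hourly_raw <- resample_series(fx_animal, "hourly")
    windows <- extract_windows(hourly_raw, config$window_len,
                               source = name)
    Ds <- vapply(windows, function(w)
      tryCatch(fractal_dimension(w, config$k_set)$D,
               error = function(e) NA_real_), 0)
    degenerate_windows <- sum(is.na(Ds))
    if (degenerate_windows > 0)
      warnings_tally <- c(warnings_tally, paste0(
        name, ": ", degenerate_windows,
        " window(s) with undefined fractal dimension excluded"))
    Ds <- Ds[!is.na(Ds)]

    disp <- displacement_series(fit, "hourly")
    cov <- make_covariates(path, duration = fx$scenario$duration,
                           temp_mean = fx$temp_mean,
                           sun_table = fx$sun_table,
                           boulders = fx$boulders)
    table <- build_displacement_table(disp, cov, boulders = fx$boulders,
                                      individual = name,
                                      season = fx$season)
    glm_fit <- NULL
    if (nrow(table) > 50 && var(table$boulder) > 0) {
      glm_fit <- tryCatch(fit_gamma_glm(table),
                          error = function(e) {
                            warnings_tally <<- c(warnings_tally,
                                                 conditionMessage(e))
                            NULL
                          })
    }
    if (attr(windows, "excluded"))
      warnings_tally <- c(warnings_tally, paste0(
        name, ": no eligible ", config$window_len,
        "-h window; excluded from fractal analysis"))

    counts <- list(
      emissions = nrow(attr(det_animal, "emissions")),
      detections = nrow(det_animal),
      arrival_sets = sum(sets$tag_id == name),
      fixes = nrow(fx_animal),
      hourly_points = sum(!hourly_raw$gap),
      windows = length(windows),
      discarded_ambiguous = sets$tallies$ambiguous,
      discarded_insufficient = sets$tallies$insufficient)

    fixtures[[name]] <- list(
      name = name, counts = counts, noise = fit$noise,
      sync_report = sync_report, D = Ds, glm = glm_fit,
      table_rows = nrow(table))
    tables[[name]] <- table

    if (!is.null(out_dir)) {
      write_detection_log(log, file.path(out_dir,
                                         paste0(name, "_detections.csv")))
      write_fixes(fx_animal, file.path(out_dir, paste0(name, "_fixes.csv")))
      write_trajectory(fit, file.path(out_dir,
                                      paste0(name, "_trajectory.csv")))
      write_displacement_table(table,
                               file.path(out_dir, paste0(name, "_dt1.csv")))
    }
  }

  season_report <- NULL
  seasons <- unique(vapply(tables, function(t) t$season[1], ""))
  if (length(tables) >= 2 && length(seasons) >= 2)
    season_report <- season_comparison_report(tables)

  manifest <- structure(list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("benthtrack")),
    fixtures = fixtures, season_report = season_report,
    warnings = warnings_tally),
    class = "run_manifest")

  if (!is.null(out_dir)) {
    yaml::write_yaml(manifest_summary(manifest),
                     file.path(out_dir, "manifest.yaml"))
  }
  manifest
}

manifest_summary <- function(m) {
  cfg <- m$config[!vapply(m$config, is.null, TRUE)]
  cfg$out_dir <- NULL  # a location, not a run parameter
  list(package_version = m$package_version,
       config = cfg,
       fixtures = lapply(m$fixtures, function(f) {
         list(counts = f$counts,
              sigma = if (!is.null(f$noise)) f$noise$sigma,
              tau = if (!is.null(f$noise)) f$noise$tau,
              D = as.numeric(f$D),
              sync_raw_error = if (!is.null(f$sync_report))
                f$sync_report$raw$mean,
              sync_smoothed_error = if (!is.null(f$sync_report))
                f$sync_report$smoothed$mean)
       }),
       warnings = m$warnings)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run (benthtrack", x$package_version, ")\n")
  for (f in x$fixtures) {
    cat(sprintf("\nFixture %s:\n", f$name))
    cat(sprintf("  emissions %d -> detections %d -> sets %d -> fixes %d\n",
                f$counts$emissions, f$counts$detections,
                f$counts$arrival_sets, f$counts$fixes))
    if (!is.null(f$noise))
      cat(sprintf("  sigma = %.3g m/step, tau = %.3g m\n",
                  f$noise$sigma, f$noise$tau))
    if (length(f$D))
      cat(sprintf("  fractal D (x%d windows): %s\n", length(f$D),
                  paste(sprintf("%.2f", f$D), collapse = ", ")))
    if (!is.null(f$sync_report))
      cat(sprintf("  sync-tag error: raw %.3f m, smoothed %.3f m\n",
                  f$sync_report$raw$mean, f$sync_report$smoothed$mean))
  }
  if (length(x$warnings))
    cat("\nWarnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}
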