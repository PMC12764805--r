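#' Movement scenario for the synthetic-data generator
#'
#' Bundles the ground-truth movement model and noise levels used to simulate
#' an individual. The per-step system-noise SD `sigma_true` plays the role of
#' the state-space model's sigma (movement magnitude per time step) and
#' `tau_true` the positioning-noise SD the observation system adds.
#'
#' @param model_kind one of `"stationary"`, `"random_walk"`,
#'   `"random_walk_drift"`, `"boulder_attracted"`.
#' @param sigma_true system-noise SD, metres per step (per axis).
#' @param tau_true observation-noise SD, metres; recorded for downstream use
#'   by the detection simulator and fixture presets.
#' @param drift mean velocity `c(u, v)` in m/s; used by
#'   `"random_walk_drift"` (mean increment per step is `drift * step_dt`).
#' @param step_dt simulation step, seconds. The default 120 s is the midpoint
#'   of the tag's random 90--150 s emission interval.
#' @param duration total simulated time, seconds.
#' @param start start position `c(x, y)` in metres.
#' @param boulders optional matrix/data frame of boulder-zone centroids
#'   (columns x, y); required for `"boulder_attracted"`.
#' @param attraction bounded pull (metres per step) toward the nearest
#'   boulder centroid for the `"boulder_attracted"` fixture model.
#' @param seed RNG seed; recorded in the scenario.
#' @return An object of class `movement_scenario`.
#' @export
movement_scenario <- function(model_kind = c("random_walk", "stationary",
                                             "random_walk_drift",
                                             "boulder_attracted"),
                              sigma_true = 0.005, tau_true = 0.5,
                              drift = c(0, 0), step_dt = 120,
                              duration = 86400, start = c(40, 40),
                              boulders = NULL, attraction = 0.01,
                              seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(sigma_true >= 0, tau_true >= 0, duration > 0, step_dt > 0,
            length(drift) == 2L, length(start) == 2L,
            is.numeric(seed), length(seed) == 1L)
  if (model_kind == "boulder_attracted" && is.null(boulders))
    stop("boulder_attracted scenarios need boulder centroids")
  if (!is.null(boulders)) {
    boulders <- as.matrix(as.data.frame(boulders)[, 1:2])
    colnames(boulders) <- c("x", "y")
  }
  structure(list(model_kind = model_kind, sigma_true = sigma_true,
                 tau_true = tau_true, drift = as.numeric(drift),
                 step_dt = step_dt, duration = duration,
                 start = as.numeric(start), boulders = boulders,
                 attraction = attraction, seed = as.integer(seed)),
            class = "movement_scenario")
}

#' @export
print.movement_scenario <- function(x, ...) {
  cat(sprintf("Movement scenario: %s\n", x$model_kind))
  cat(sprintf("  sigma = %g m/step, tau = %g m, dt = %g s, duration = %g d\n",
              x$sigma_true, x$tau_true, x$step_dt, x$duration / 86400))
  cat(sprintf("  start (%g, %g), seed %d\n", x$start[1], x$start[2], x$seed))
  invisible(x)
}

#' Simulate a ground-truth movement path
#'
#' Generates true positions at every `step_dt` tick of the scenario.
#' `"stationary"` stays at the start position; `"random_walk"` adds iid
#' Gaussian increments with per-axis SD `sigma_true`; `"random_walk_drift"`
#' adds a deterministic mean increment `drift * step_dt`;
#' `"boulder_attracted"` adds a bounded deterministic pull toward the nearest
#' boulder centroid (a test fixture, not a fitted behavioural model).
#'
#' @param scenario a [movement_scenario()].
#' @return A data frame of class `true_path` with columns `time_s`, `x`, `y`,
#'   one row per step tick (including t = 0).
#' @export
simulate_true_path <- function(scenario) {
  stopifnot(inherits(scenario, "movement_scenario"))
  n <- floor(scenario$duration / scenario$step_dt)
  times <- seq(0, n) * scenario$step_dt
  with_seed(scenario$seed, {
    pos <- matrix(0, n + 1L, 2L)
    pos[1L, ] <- scenario$start
    kind <- scenario$model_kind
    if (kind == "stationary") {
      pos[, 1L] <- scenario$start[1]
      pos[, 2L] <- scenario$start[2]
    } else if (kind %in% c("random_walk", "random_walk_drift")) {
      mu <- if (kind == "random_walk_drift")
        scenario$drift * scenario$step_dt else c(0, 0)
      dx <- rnorm(n, mu[1], scenario$sigma_true)
      dy <- rnorm(n, mu[2], scenario$sigma_true)
      pos[, 1L] <- scenario$start[1] + c(0, cumsum(dx))
      pos[, 2L] <- scenario$start[2] + c(0, cumsum(dy))
    } else if (kind == "boulder_attracted") {
      ctr <- scenario$boulders
      for (i in seq_len(n)) {
        p <- pos[i, ]
        d2 <- (ctr[, 1] - p[1])^2 + (ctr[, 2] - p[2])^2
        nb <- ctr[which.min(d2), ]
        dd <- sqrt(min(d2))
        pull <- if (dd > 1e-12) {
          scenario$attraction * min(dd, 1) * (nb - p) / dd
        } else c(0, 0)
        pos[i + 1L, ] <- p + pull + rnorm(2, 0, scenario$sigma_true)
      }
    } else {
      stop("unknown model_kind: ", kind)
    }
    structure(data.frame(time_s = times, x = pos[, 1L], y = pos[, 2L]),
              scenario = scenario,
              class = c("true_path", "data.frame"))
  })
}

path_position_at <- function(path, t) {
  cbind(approx(path$time_s, path$x, xout = t, rule = 2)$y,
        approx(path$time_s, path$y, xout = t, rule = 2)$y)
}

#' Hourly covariate series
#'
#' Builds the hourly covariate records used by the displacement GLM: water
#' temperature (sinusoidal diel cycle plus optional linear trend), a boulder
#' flag (1 when the true position is strictly within 2 m of the nearest
#' boulder-zone centroid) and a day flag (1 from sunrise up to, but not
#' including, sunset).
#'
#' @param path a `true_path` (used for the boulder flag).
#' @param duration series length, seconds.
#' @param temp_mean,temp_amplitude,temp_trend temperature model: mean (deg C),
#'   diel sinusoid amplitude (deg C) and linear trend (deg C per day).
#' @param sun_table data frame with columns `day` (integer day index from the
#'   series origin), `sunrise_s`, `sunset_s` (seconds of day). Every day in
#'   range must be present.
#' @param boulders boulder-zone centroids (matrix or data frame, columns x, y),
#'   or NULL for no boulder flag (all 0).
#' @param boulder_radius proximity radius, metres (strictly-within rule).
#' @return Data frame of class `covariate_series` with columns `time_s`,
#'   `temp_c`, `boulder`, `day`.
#' @export
make_covariates <- function(path, duration = max(path$time_s),
                            temp_mean = 7.6, temp_amplitude = 0.5,
                            temp_trend = 0, sun_table = default_sun_table(),
                            boulders = NULL, boulder_radius = 2) {
  times <- seq(0, duration, by = 3600)
  days <- floor(times / 86400)
  idx <- match(days, sun_table$day)
  if (anyNA(idx))
    stop("sun_table is missing day(s): ",
         paste(unique(days[is.na(idx)]), collapse = ", "))
  tod <- times %% 86400
  day_flag <- as.integer(tod >= sun_table$sunrise_s[idx] &
                           tod < sun_table$sunset_s[idx])
  temp <- temp_mean + temp_amplitude * sin(2 * pi * tod / 86400) +
    temp_trend * times / 86400
  pos <- path_position_at(path, times)
  boulder <- integer(length(times))
  if (!is.null(boulders)) {
    ctr <- as.matrix(as.data.frame(boulders)[, 1:2])
    boulder <- as.integer(nearest_centroid_dist(pos, ctr) < boulder_radius)
  }
  structure(data.frame(time_s = times, temp_c = temp, boulder = boulder,
                       day = day_flag),
            class = c("covariate_series", "data.frame"))
}

nearest_centroid_dist <- function(pos, centroids) {
  d2 <- sapply(seq_len(nrow(centroids)), function(j)
    (pos[, 1] - centroids[j, 1])^2 + (pos[, 2] - centroids[j, 2])^2)
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1L)
  sqrt(apply(d2, 1L, min))
}

#' @rdname make_covariates
#' @param n_days number of days covered.
#' @param sunrise_s,sunset_s constant sunrise/sunset, seconds of day.
#' @export
default_sun_table <- function(n_days = 45, sunrise_s = 6 * 3600,
                              sunset_s = 17 * 3600) {
  data.frame(day = seq(0, n_days), sunrise_s = sunrise_s,
             sunset_s = sunset_s)
}

#' Default boulder-zone centroids
#'
#' Ten artificial boulder-zone centroids laid out on a grid inside the
#' default 80 m port, mimicking a release experiment where zone 4 is the
#' release point.
#' @param side port side length, metres.
#' @export
boulder_centroids <- function(side = 80) {
  g <- expand.grid(x = c(20, 40, 60), y = c(15, 35, 55))
  out <- rbind(as.matrix(g), c(40, 70)) * side / 80
  colnames(out) <- c("x", "y")
  out
}

#' Preset ground-truthed fixture scenarios
#'
#' Three presets emulating the study conditions of a port release
#' experiment: `"sync_tag"` (a stationary transmitter fixed at the sync
#' receiver, 34 days), `"resting_C"` (autumn resting-stage individual:
#' 34-day track, low movement, 16.4 deg C mean temperature) and
#' `"growing_D"` (late-winter growing-stage individual: 40-day track, higher
#' movement, 7.6 deg C mean temperature).
#'
#' @param name preset name.
#' @param seed RNG seed for the whole bundle.
#' @param duration_days override the preset tracking duration, days. Fixture
#'   presets use the full study durations; tests and examples pass shorter
#'   windows.
#' @return List of class `fixture_scenario` with elements `geometry`,
#'   `scenario`, `boulders`, `sun_table`, `temp_mean`, `name`, `season`.
#' @export
make_fixture_scenario <- function(name = c("sync_tag", "resting_C",
                                           "growing_D"),
                                  seed = 1L, duration_days = NULL) {
  name <- match.arg(name)
  geometry <- port_geometry()
  boulders <- boulder_centroids()
  preset <- switch(name,
    sync_tag = list(kind = "stationary", sigma = 0, days = 34,
                    start = unname(sync_position(geometry)),
                    temp = 16.4, season = "resting"),
    resting_C = list(kind = "random_walk", sigma = 0.001, days = 34,
                     start = unname(boulders[4, ]), temp = 16.4,
                     season = "resting"),
    growing_D = list(kind = "random_walk", sigma = 0.008, days = 40,
                     start = unname(boulders[4, ]), temp = 7.6,
                     season = "growing"))
  days <- duration_days %||% preset$days
  scenario <- movement_scenario(
    model_kind = preset$kind, sigma_true = preset$sigma, tau_true = 0.5,
    step_dt = 120, duration = days * 86400, start = preset$start,
    boulders = boulders, seed = seed)
  structure(list(name = name, geometry = geometry, scenario = scenario,
                 boulders = boulders,
                 sun_table = default_sun_table(n_days = days + 1),
                 temp_mean = preset$temp, season = preset$season),
            class = "fixture_scenario")
}
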