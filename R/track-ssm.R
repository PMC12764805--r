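#' Fit a state-space movement model to a position series
#'
#' The central model-fitting function: given a (possibly gappy) series of
#' planar position fixes, estimates the system-noise SD sigma and
#' observation-noise SD tau by maximum likelihood (unless supplied), runs
#' the Kalman filter, and refines the trajectory with the fixed-interval
#' smoother. sigma summarizes how much the animal moves per time step;
#' tau summarizes the positioning error of the measurement system.
#'
#' @param obs a `position_series` (see [resample_series()]), a data frame
#'   with `x`, `y` and optionally `gap`/`time_s`, or a T x 2 matrix with
#'   NA rows at gaps.
#' @param model `"rw"` (random walk) or `"uv"` (position + velocity).
#' @param dt time step of the series, seconds; taken from the series'
#'   `step` attribute when present.
#' @param sigma,tau noise SDs (metres). If either is `NULL` both are
#'   estimated by [fit_noise()].
#' @param x0,V0 initial state; see [ss_model()].
#' @param ... passed to [fit_noise()].
#' @return Object of class `track_ssm` with components `model` (the
#'   `ss_model` at the fitted parameters), `noise` (a `noise_estimate` or
#'   NULL when sigma/tau were supplied), `estimates` (smoothed
#'   `kalman_estimates`), `time`, `call`.
#' @seealso [displacement_series()], [fractal_dimension()]
#' @examples
#' fx <- make_fixture_scenario("sync_tag", seed = 2, duration_days = 1)
#' path <- simulate_true_path(fx$scenario)
#' obs <- data.frame(x = path$x + rnorm(nrow(path), 0, 0.5),
#'                   y = path$y + rnorm(nrow(path), 0, 0.5))
#' fit <- track_ssm(obs, model = "rw", dt = 120)
#' coef(fit)
#' @export
track_ssm <- function(obs, model = c("rw", "uv"), dt = NULL,
                      sigma = NULL, tau = NULL, x0 = NULL, V0 = NULL, ...) {
  model <- match.arg(model)
  dt <- dt %||% attr(obs, "step") %||% 120
  noise <- NULL
  if (is.null(sigma) || is.null(tau)) {
    noise <- fit_noise(obs, kind = model, dt = dt, x0 = x0, V0 = V0, ...)
    sigma <- noise$sigma
    tau <- noise$tau
  }
  m <- ss_model(model, dt = dt, sigma = sigma, tau = tau, x0 = x0, V0 = V0)
  kf <- kalman_smooth(kalman_filter(m, obs))
  structure(list(model = m, noise = noise, estimates = kf,
                 time = kf$time, call = match.call()),
            class = "track_ssm")
}

#' @export
print.track_ssm <- function(x, ...) {
  kf <- x$estimates
  cat(sprintf("State-space movement model (%s), %d steps (%d observed)\n",
              x$model$kind, nrow(kf$xf), kf$n_used))
  cat(sprintf("  sigma = %.4g m/step, tau = %.4g m%s, logLik = %.2f\n",
              x$model$sigma, x$model$tau,
              if (is.null(x$noise)) " (fixed)" else " (ML)",
              kf$loglik))
  invisible(x)
}

#' @export
summary.track_ssm <- function(object, ...) {
  kf <- object$estimates
  gaps <- sum(!kf$obs_flag)
  innov <- residuals(object)
  out <- list(kind = object$model$kind, dt = object$model$dt,
              sigma = object$model$sigma, tau = object$model$tau,
              fitted_noise = !is.null(object$noise),
              loglik = kf$loglik, n = nrow(kf$xf), n_obs = kf$n_used,
              n_gaps = gaps,
              innov_rms = sqrt(mean(innov^2, na.rm = TRUE)))
  class(out) <- "summary.track_ssm"
  out
}

#' @export
print.summary.track_ssm <- function(x, ...) {
  cat(sprintf("State-space movement model: %s, dt = %g s\n", x$kind, x$dt))
  cat(sprintf("  steps: %d (%d observed, %d gaps)\n", x$n, x$n_obs,
              x$n_gaps))
  cat(sprintf("  sigma = %.4g m/step, tau = %.4g m (%s)\n", x$sigma,
              x$tau, if (x$fitted_noise) "ML" else "fixed"))
  cat(sprintf("  logLik = %.2f, innovation RMS = %.3f m\n", x$loglik,
              x$innov_rms))
  invisible(x)
}

#' @export
coef.track_ssm <- function(object, ...) {
  c(sigma = object$model$sigma, tau = object$model$tau)
}

#' @export
logLik.track_ssm <- function(object, ...) {
  structure(object$estimates$loglik,
            df = if (is.null(object$noise)) 0L else 2L,
            nobs = object$estimates$n_used, class = "logLik")
}

#' Smoothed trajectory of a fitted movement model
#'
#' @param object a `track_ssm`.
#' @param ... unused.
#' @return Data frame `time_s, x, y, Vxx, Vyy, Vxy` plus `u, v` for the
#'   position-velocity model.
#' @export
fitted.track_ssm <- function(object, ...) {
  kf <- object$estimates
  out <- data.frame(time_s = kf$time, x = kf$xs[, 1], y = kf$xs[, 2],
                    Vxx = kf$Vs[1, 1, ], Vyy = kf$Vs[2, 2, ],
                    Vxy = kf$Vs[1, 2, ])
  if (object$model$kind == "uv") {
    out$u <- kf$xs[, 3]
    out$v <- kf$xs[, 4]
  }
  out
}

#' @export
residuals.track_ssm <- function(object,
                                type = c("innovation", "standardized"),
                                ...) {
  type <- match.arg(type)
  kf <- object$estimates
  H <- object$model$H
  innov <- kf$y - kf$xp %*% t(H)
  innov[!kf$obs_flag, ] <- NA
  if (type == "standardized") {
    for (t in which(kf$obs_flag)) {
      S <- H %*% kf$Vp[, , t] %*% t(H) + object$model$R
      innov[t, ] <- backsolve(chol(S), innov[t, ], transpose = TRUE)
    }
  }
  colnames(innov) <- c("x", "y")
  innov
}

#' @export
predict.track_ssm <- function(object, n_ahead = 1, ...) {
  kf <- object$estimates
  m <- object$model
  x <- kf$xf[nrow(kf$xf), ]
  V <- kf$Vf[, , dim(kf$Vf)[3]]
  GQG <- m$G %*% m$Q %*% t(m$G)
  out <- matrix(NA_real_, n_ahead, 2 + 3)
  for (h in seq_len(n_ahead)) {
    x <- as.numeric(m$F %*% x)
    V <- m$F %*% V %*% t(m$F) + GQG
    out[h, ] <- c(x[1], x[2], V[1, 1], V[2, 2], V[1, 2])
  }
  data.frame(time_s = max(kf$time) + seq_len(n_ahead) * m$dt,
             x = out[, 1], y = out[, 2], Vxx = out[, 3], Vyy = out[, 4],
             Vxy = out[, 5])
}

#' Simulate observation series from a fitted movement model
#'
#' Draws new latent paths and noisy observations from the fitted
#' state-space model, starting at the smoothed initial state.
#'
#' @param object a `track_ssm`.
#' @param nsim number of series.
#' @param seed RNG seed.
#' @param ... unused.
#' @return A list of T x 2 observation matrices (invisibly a single matrix
#'   when `nsim = 1`).
#' @export
simulate.track_ssm <- function(object, nsim = 1, seed = NULL, ...) {
  m <- object$model
  kf <- object$estimates
  T_ <- nrow(kf$xf)
  p <- nrow(m$F)
  with_seed(seed, {
    sims <- lapply(seq_len(nsim), function(s) {
      x <- kf$xs[1, ]
      y <- matrix(NA_real_, T_, 2)
      for (t in seq_len(T_)) {
        x <- as.numeric(m$F %*% x) +
          as.numeric(m$G %*% rnorm(p, 0, m$sigma))
        y[t, ] <- as.numeric(m$H %*% x) + rnorm(2, 0, m$tau)
      }
      y
    })
    if (nsim == 1) sims[[1]] else sims
  })
}

#' @export
plot.track_ssm <- function(x, ...) {
  kf <- x$estimates
  obs <- kf$y
  obs[!kf$obs_flag, ] <- NA
  plot(obs[, 1], obs[, 2], pch = 16, cex = 0.4, col = grey(0.6),
       xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  lines(kf$xs[, 1], kf$xs[, 2], col = "red")
  legend("topright", legend = c("fixes", "smoothed"), bty = "n",
         pch = c(16, NA), lty = c(NA, 1), col = c(grey(0.6), "red"))
  invisible(x)
}

#' Per-interval displacement from a smoothed trajectory
#'
#' Computes the Euclidean displacement between consecutive grid positions
#' of the smoothed trajectory (dt1 on the hourly grid). Intervals touching
#' a grid tick with no observed fix nearby are flagged so they can be
#' excluded downstream.
#'
#' @param object a `track_ssm`, or a data frame with `time_s`, `x`, `y`.
#' @param grid `"hourly"`, `"12h"` or `"native"`.
#' @param obs_flag logical vector of per-step observation flags when
#'   `object` is a plain data frame.
#' @return Data frame of class `displacement_series`: `time_s` (interval
#'   end), `x0`, `y0` (position at interval start), `dt1_m`, `flagged`,
#'   plus `speed_m_s` and `heading_rad` from the velocity state for the
#'   position-velocity model.
#' @export
displacement_series <- function(object, grid = c("hourly", "12h", "native"),
                                obs_flag = NULL) {
  grid <- match.arg(grid)
  if (inherits(object, "track_ssm")) {
    tr <- fitted(object)
    obs_flag <- object$estimates$obs_flag
    uv <- object$model$kind == "uv"
  } else {
    tr <- object
    uv <- all(c("u", "v") %in% names(tr))
  }
  if (is.null(obs_flag)) obs_flag <- rep(TRUE, nrow(tr))
  step <- switch(grid, native = NULL, hourly = 3600, `12h` = 43200)
  if (is.null(step)) {
    idx <- seq_len(nrow(tr))
    tick_ok <- obs_flag
  } else {
    rel <- tr$time_s - tr$time_s[1]
    idx <- which(rel %% step == 0)
    # a tick is trustworthy if any observation fell within half a grid step
    half <- step / 2
    obs_times <- tr$time_s[obs_flag]
    tick_ok <- vapply(tr$time_s[idx], function(tt)
      any(abs(obs_times - tt) <= half), TRUE)
  }
  g <- tr[idx, ]
  n <- nrow(g)
  if (n < 2L)
    return(structure(data.frame(time_s = numeric(0), x0 = numeric(0),
                                y0 = numeric(0), dt1_m = numeric(0),
                                flagged = logical(0)),
                     grid = grid, class = c("displacement_series",
                                            "data.frame")))
  d <- sqrt(diff(g$x)^2 + diff(g$y)^2)
  out <- data.frame(time_s = g$time_s[-1], x0 = g$x[-n], y0 = g$y[-n],
                    dt1_m = d,
                    flagged = !(tick_ok[-1] & tick_ok[-n]))
  if (uv) {
    out$speed_m_s <- sqrt(g$u[-1]^2 + g$v[-1]^2)
    out$heading_rad <- atan2(g$v[-1], g$u[-1])
  }
  structure(out, grid = grid,
            class = c("displacement_series", "data.frame"))
}
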