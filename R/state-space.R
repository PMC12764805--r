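#' Build a linear-Gaussian state-space model specification
#'
#' Two movement models are supported. The random-walk (`"rw"`) model has
#' state x_t = (x, y)' with F = G = H = I2: the animal's position diffuses
#' with per-step system noise of SD `sigma` per axis and is observed with
#' noise of SD `tau`. The position--velocity (`"uv"`) model augments the
#' state to (x, y, u, v)' with a first-order (Taylor) step: position
#' advances by velocity times `dt`, so F has `dt` in entries (1,3) and
#' (2,4); only the positions are observed, H = [I2 0]. In both models
#' Q = sigma^2 I and R = tau^2 I.
#'
#' @param kind `"rw"` or `"uv"`.
#' @param dt time step, seconds (must be > 0).
#' @param sigma system-noise SD, metres per step.
#' @param tau observation-noise SD, metres.
#' @param x0 initial state mean; default `NULL` lets the filter initialize
#'   position at the first observed fix (velocities 0).
#' @param V0 initial state covariance; default diffuse diag(100) m^2.
#' @return Object of class `ss_model` with elements `F`, `G`, `H`, `Q`,
#'   `R`, `kind`, `dt`, `sigma`, `tau`, `x0`, `V0`.
#' @export
ss_model <- function(kind = c("rw", "uv"), dt = 120, sigma = 0.005,
                     tau = 0.5, x0 = NULL, V0 = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  stopifnot(sigma >= 0, tau >= 0)
  p <- if (kind == "rw") 2L else 4L
  F <- diag(p)
  if (kind == "uv") { F[1, 3] <- dt; F[2, 4] <- dt }
  H <- if (kind == "rw") diag(2) else cbind(diag(2), matrix(0, 2, 2))
  G <- diag(p)
  if (is.null(V0)) V0 <- diag(100, p)
  if (!isSymmetric(V0) || any(eigen(V0, only.values = TRUE)$values < -1e-10))
    stop("V0 must be symmetric positive semi-definite")
  if (!is.null(x0) && length(x0) != p)
    stop("x0 must have length ", p)
  structure(list(F = F, G = G, H = H, Q = diag(sigma^2, p),
                 R = diag(tau^2, 2), kind = kind, dt = dt,
                 sigma = sigma, tau = tau, x0 = x0, V0 = V0),
            class = "ss_model")
}

#' @export
print.ss_model <- function(x, ...) {
  cat(sprintf("State-space model '%s': dt = %g s, sigma = %g m, tau = %g m\n",
              x$kind, x$dt, x$sigma, x$tau))
  invisible(x)
}

# Coerce a position_series / data.frame / matrix into (y, flags, time).
as_observation_matrix <- function(obs) {
  if (is.matrix(obs)) {
    y <- obs
    time <- seq_len(nrow(y))
  } else {
    y <- cbind(obs$x, obs$y)
    time <- if (!is.null(obs$time_s)) obs$time_s else seq_len(nrow(y))
  }
  flag <- stats::complete.cases(y)
  if (is.data.frame(obs) && !is.null(obs$gap)) flag <- flag & !obs$gap
  y[!flag, ] <- 0  # unused at gap steps
  list(y = y, flag = flag, time = time)
}

default_x0 <- function(model, y, flag) {
  if (!is.null(model$x0)) return(model$x0)
  first <- which(flag)[1]
  if (is.na(first)) stop("series contains no observed steps")
  c(y[first, ], rep(0, nrow(model$F) - 2L))
}

#' Kalman filter
#'
#' Forward predict/update recursion for an [ss_model()]. At gap-flagged
#' steps the filtering step is skipped: the filtered distribution is set
#' equal to the one-step-ahead prediction, so gaps propagate uncertainty
#' without imputing observations. The prediction-error log-likelihood is
#' accumulated over observed steps only.
#'
#' @param model an `ss_model`.
#' @param obs observations: a `position_series`, a data frame with
#'   `x`/`y` (optionally `gap`, `time_s`), or a T x 2 matrix with NA rows
#'   for gaps.
#' @return Object of class `kalman_estimates`: predicted and filtered
#'   state means (`xp`, `xf`; T x p) and covariance arrays (`Vp`, `Vf`;
#'   p x p x T), `loglik`, `n_used`, plus the inputs for the smoother.
#' @export
kalman_filter <- function(model, obs) {
  stopifnot(inherits(model, "ss_model"))
  om <- as_observation_matrix(obs)
  if (!any(om$flag)) stop("all steps are gaps: no observations to filter")
  x0 <- default_x0(model, om$y, om$flag)
  res <- kf_core(om$y, as.integer(om$flag), model$F, model$G, model$H,
                 model$Q, model$R, x0, model$V0)
  structure(list(xp = res$xp, Vp = res$Vp, xf = res$xf, Vf = res$Vf,
                 loglik = res$loglik, n_used = res$n_used,
                 y = om$y, obs_flag = om$flag, time = om$time,
                 model = model),
            class = "kalman_estimates")
}

#' Fixed-interval (RTS) smoother
#'
#' Backward recursion refining every filtered estimate with the full
#' record: the smoothed state at T equals the filtered one, and earlier
#' steps are corrected through the smoother gain
#' A_t = V_(t|t) F' V_(t+1|t)^-1. Singular predicted covariances fall back
#' to a pseudo-inverse (tallied).
#'
#' @param kf a `kalman_estimates` object from [kalman_filter()].
#' @return The same object with smoothed means `xs` (T x p) and
#'   covariances `Vs` (p x p x T) added, plus `pinv_tally`.
#' @export
kalman_smooth <- function(kf) {
  stopifnot(inherits(kf, "kalman_estimates"))
  res <- ks_core(kf$xp, kf$Vp, kf$xf, kf$Vf, kf$model$F)
  if (res$pinv_tally > 0)
    warning("pseudo-inverse used at ", res$pinv_tally, " smoother step(s)")
  kf$xs <- res$xs
  kf$Vs <- res$Vs
  kf$pinv_tally <- res$pinv_tally
  kf
}

#' Negative log-likelihood of (sigma, tau)
#'
#' Prediction-error decomposition: the sum over observed steps of the
#' Gaussian log-density of the filter innovations; gap steps contribute
#' nothing.
#'
#' @param theta `c(sigma, tau)`, both > 0 (or 0 for degenerate checks).
#' @param obs observations as in [kalman_filter()].
#' @param kind,dt,x0,V0 model template, see [ss_model()].
#' @return Scalar negative log-likelihood.
#' @export
ss_nll <- function(theta, obs, kind = "rw", dt = 120, x0 = NULL, V0 = NULL) {
  m <- ss_model(kind, dt, sigma = theta[1], tau = theta[2], x0 = x0, V0 = V0)
  -kalman_filter(m, obs)$loglik
}

#' Maximum-likelihood estimation of system and observation noise
#'
#' Maximizes the state-space likelihood over theta = (sigma, tau) with
#' L-BFGS-B on the log scale (sigma spans orders of magnitude between a
#' fixed sync tag and a moving animal), from several data-moment-seeded
#' starts. For a random walk observed with noise, the variance of one-step
#' position differences is sigma^2 + 2 tau^2 and the lag-1 autocovariance
#' of differences is -tau^2; the starts bracket the moment solution.
#'
#' @param obs observations as in [kalman_filter()].
#' @param kind,dt,x0,V0 model template, see [ss_model()].
#' @param n_starts number of multi-starts (>= 1).
#' @param lower,upper box bounds for sigma and tau, metres.
#' @param control passed to [stats::optim()].
#' @return Object of class `noise_estimate`: `sigma`, `tau`, `loglik`,
#'   `convergence` (0 = success), `iterations`, `starts` (matrix of starts
#'   tried and their objective values).
#' @export
fit_noise <- function(obs, kind = "rw", dt = 120, x0 = NULL, V0 = NULL,
                      n_starts = 3, lower = 1e-8, upper = 1e3,
                      control = list()) {
  om <- as_observation_matrix(obs)
  if (sum(om$flag) < 10L)
    stop("need at least 10 observed steps to estimate noise")

  yy <- om$y[om$flag, , drop = FALSE]
  d <- diff(yy)
  v_diff <- mean(apply(d, 2, var))
  g1 <- mean(vapply(1:2, function(j) {
    n <- nrow(d); if (n < 3) return(0)
    mean((d[-1, j] - mean(d[, j])) * (d[-n, j] - mean(d[, j])))
  }, 0))
  tau0 <- sqrt(max(-g1, v_diff / 4, 1e-6))
  sig0 <- sqrt(max(v_diff - 2 * tau0^2, v_diff / 100, 1e-10))
  starts <- rbind(c(sig0, tau0),
                  c(sig0 / 30, tau0),
                  c(sig0 * 10, tau0 / 2),
                  c(sqrt(v_diff / 3), sqrt(v_diff / 3)))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]

  obj <- function(lpar) {
    nll <- try(ss_nll(exp(lpar), obs, kind, dt, x0, V0), silent = TRUE)
    if (inherits(nll, "try-error") || !is.finite(nll)) 1e12 else nll
  }
  best <- NULL
  tried <- cbind(starts, value = NA_real_)
  for (i in seq_len(nrow(starts))) {
    fit <- try(optim(log(pmin(pmax(starts[i, ], lower * 2), upper / 2)),
                     obj, method = "L-BFGS-B",
                     lower = log(lower), upper = log(upper),
                     control = control),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    tried[i, 3] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("noise optimization failed on all starts")
  est <- exp(best$par)
  structure(list(sigma = est[1], tau = est[2], loglik = -best$value,
                 convergence = best$convergence,
                 iterations = best$counts[["function"]],
                 kind = kind, dt = dt, starts = tried),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "ML noise estimate (%s model): sigma = %.3g m/step, tau = %.3g m\n",
    x$kind, x$sigma, x$tau))
  cat(sprintf("  logLik = %.2f, convergence = %d (%d evaluations)\n",
              x$loglik, x$convergence, x$iterations))
  invisible(x)
}
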