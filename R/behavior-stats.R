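#' Regression-parallelism F test
#'
#' Tests whether two regression lines share a slope (here: whether two
#' log-log coarse-grained-length profiles have the same fractal
#' dimension). S1 is the pooled residual sum of squares under a common
#' slope with separate intercepts; S2 under fully separate fits. Then
#' F = ((S1 - S2) / (phi_A - phi_B)) / (S2 / phi_B) with
#' phi_A - phi_B = 1 and phi_B = n_total - 4, compared against the upper
#' tail of F(1, n_total - 4).
#'
#' @param a,b data frames with columns `x`, `y` (>= 3 points each, x not
#'   all equal within a group).
#' @return Object of class `parallelism_test`: `F`, `p`, `df`, `S1`,
#'   `S2`, `slopes` (per-group OLS slopes), `degenerate` (TRUE when
#'   S2 = 0 and p is reported as 0).
#' @export
parallelism_f_test <- function(a, b) {
  check_group <- function(g, nm) {
    if (nrow(g) < 3) stop("group ", nm, " needs >= 3 points")
    if (var(g$x) == 0) stop("group ", nm, " has constant x")
  }
  check_group(a, "a"); check_group(b, "b")
  n <- nrow(a) + nrow(b)
  cs <- function(g) {
    xb <- mean(g$x); yb <- mean(g$y)
    c(Sxx = sum((g$x - xb)^2), Sxy = sum((g$x - xb) * (g$y - yb)),
      Syy = sum((g$y - yb)^2))
  }
  ma <- cs(a); mb <- cs(b)
  # common slope, separate intercepts
  b_com <- (ma["Sxy"] + mb["Sxy"]) / (ma["Sxx"] + mb["Sxx"])
  S1 <- unname((ma["Syy"] - 2 * b_com * ma["Sxy"] + b_com^2 * ma["Sxx"]) +
                 (mb["Syy"] - 2 * b_com * mb["Sxy"] + b_com^2 * mb["Sxx"]))
  # separate slopes
  b_a <- ma["Sxy"] / ma["Sxx"]
  b_b <- mb["Sxy"] / mb["Sxx"]
  S2 <- unname((ma["Syy"] - ma["Sxy"]^2 / ma["Sxx"]) +
                 (mb["Syy"] - mb["Sxy"]^2 / mb["Sxx"]))
  phi_B <- n - 4L
  degenerate <- S2 <= 0 || !is.finite(S2)
  if (degenerate) {
    Fv <- Inf
    p <- 0
  } else {
    Fv <- ((S1 - S2) / 1) / (S2 / phi_B)
    Fv <- max(Fv, 0)
    p <- pf(Fv, 1, phi_B, lower.tail = FALSE)
  }
  structure(list(F = Fv, p = p, df = c(1L, phi_B), S1 = S1, S2 = S2,
                 slopes = c(a = unname(b_a), b = unname(b_b)),
                 degenerate = degenerate),
            class = "parallelism_test")
}

#' @export
print.parallelism_test <- function(x, ...) {
  cat(sprintf("Parallelism test: F(%d,%d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  slopes: %.4f vs %.4f%s\n", x$slopes[1], x$slopes[2],
              if (x$degenerate) " [degenerate: S2 = 0]" else ""))
  invisible(x)
}

#' Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon test with normal approximation, tie
#' correction and continuity correction (the standard large-sample form),
#' used for displacement comparisons between release periods and between
#' on/off boulder strata.
#'
#' @param a,b numeric samples (non-empty).
#' @return List: `W`, `p`, `all_tied` flag (p = 1 when every value in
#'   both samples is identical).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L)
    return(list(W = length(a) * length(b) / 2, p = 1, all_tied = TRUE))
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, all_tied = FALSE)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) where R2_j is from regressing covariate j on
#' the remaining covariates; values near 1 indicate negligible
#' collinearity. Perfect collinearity is reported as `Inf`.
#'
#' @param covariates data frame of >= 2 numeric covariates (no constant
#'   columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(covariates) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2L)
    stop("VIF is undefined for a single covariate")
  if (any(vapply(covariates, var, 0) == 0))
    stop("constant column among covariates")
  vapply(seq_along(covariates), function(j) {
    fit <- lm(covariates[[j]] ~ ., data = covariates[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect-fit warning
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0) |> setNames(names(covariates))
}

#' Build the hourly displacement table for the GLM
#'
#' Joins hourly displacement (dt1) with the covariate series: water
#' temperature, a boulder flag recomputed from the estimated position at
#' the interval start (strictly within 2 m of the nearest boulder-zone
#' centroid), and the day flag. Rows from intervals adjacent to gaps are
#' dropped and tallied.
#'
#' @param disp a `displacement_series` on the hourly grid (from
#'   [displacement_series()]).
#' @param covariates a `covariate_series` (see [make_covariates()]).
#' @param boulders boulder-zone centroids (matrix/data frame, columns
#'   x, y), or NULL to use the covariate series' flag positions only.
#' @param individual individual ID label.
#' @param season season label (`"resting"` or `"growing"`).
#' @param boulder_radius proximity radius, metres (strict inequality).
#' @return Data frame of class `displacement_table` with columns
#'   `individual, time_s, dt1_m, temp_c, boulder, day, season`;
#'   attribute `tallies` records dropped gap-adjacent rows.
#' @export
build_displacement_table <- function(disp, covariates, boulders = NULL,
                                     individual = "ind1",
                                     season = "growing",
                                     boulder_radius = 2) {
  idx <- match(disp$time_s, covariates$time_s)
  if (anyNA(idx))
    stop("displacement and covariate series are on misaligned time grids")
  boulder <- covariates$boulder[idx]
  if (!is.null(boulders)) {
    ctr <- as.matrix(as.data.frame(boulders)[, 1:2])
    boulder <- as.integer(
      nearest_centroid_dist(cbind(disp$x0, disp$y0), ctr) < boulder_radius)
  }
  keep <- !disp$flagged
  out <- data.frame(individual = individual, time_s = disp$time_s,
                    dt1_m = disp$dt1_m, temp_c = covariates$temp_c[idx],
                    boulder = boulder, day = covariates$day[idx],
                    season = season)[keep, ]
  rownames(out) <- NULL
  structure(out, tallies = list(gap_adjacent_dropped = sum(!keep)),
            class = c("displacement_table", "data.frame"))
}

#' Gamma GLM of hourly displacement (log link)
#'
#' Fits E[dt1] = exp(b0 + b1 * temperature + b2 * boulder + b3 * day) with
#' gamma errors by iteratively reweighted least squares. For the log link
#' the gamma IRLS weights are identically 1, so each iteration is an OLS
#' solve on the working response. The shape parameter alpha (one constant
#' per fit) is estimated as the reciprocal of the Pearson dispersion;
#' coefficient standard errors, t and p values use that dispersion, as in
#' a conventional gamma GLM summary. Zero responses (possible after
#' smoothing a stationary fixture) are replaced by half the smallest
#' positive displacement and tallied.
#'
#' @param table a `displacement_table` (or any data frame with the model
#'   columns).
#' @param formula model formula; default `dt1_m ~ temp_c + boulder + day`.
#' @param max_iter,tol IRLS iteration cap and relative-deviance tolerance.
#' @return Object of class `gamma_glm_fit`: `coefficients` (matrix with
#'   Estimate, SE, t, p), `alpha`, `dispersion`, `deviance`,
#'   `deviance_trace`, `n`, `converged`, `zero_replaced`, `formula`.
#' @export
fit_gamma_glm <- function(table, formula = dt1_m ~ temp_c + boulder + day,
                          max_iter = 100, tol = 1e-12) {
  mf <- stats::model.frame(formula, data = table)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (any(y < 0)) stop("negative displacement in response")
  zero_replaced <- 0L
  if (any(y == 0)) {
    pos <- y[y > 0]
    if (length(pos) == 0L) stop("all responses are zero")
    zero_replaced <- sum(y == 0)
    y[y == 0] <- min(pos) / 2
  }
  if (n <= 10 * p)
    stop("need n > 10 x parameters (", 10 * p, "); got n = ", n)

  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- as.numeric(XtXinv %*% crossprod(X, log(y)))
  dev_fun <- function(mu) 2 * sum(-log(y / mu) + (y - mu) / mu)
  eta <- as.numeric(X %*% beta)
  mu <- exp(eta)
  dev <- dev_fun(mu)
  trace <- dev
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    z <- eta + (y - mu) / mu
    beta <- as.numeric(XtXinv %*% crossprod(X, z))
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
    dev_new <- dev_fun(mu)
    trace <- c(trace, dev_new)
    if (abs(dev_new - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  if (!converged) warning("IRLS did not converge in ", max_iter,
                          " iterations")
  pearson <- sum(((y - mu) / mu)^2)
  dispersion <- pearson / (n - p)
  se <- sqrt(dispersion * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = n - p)
  coefs <- cbind(Estimate = beta, `Std. Error` = se, `t value` = tval,
                 `Pr(>|t|)` = pval)
  rownames(coefs) <- colnames(X)
  structure(list(coefficients = coefs, alpha = 1 / dispersion,
                 dispersion = dispersion, deviance = dev,
                 deviance_trace = trace, n = n, converged = converged,
                 zero_replaced = zero_replaced, formula = formula,
                 fitted = mu),
            class = "gamma_glm_fit")
}

#' @export
print.gamma_glm_fit <- function(x, digits = 5, ...) {
  cat("Gamma GLM (log link), n =", x$n, "\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nShape alpha = %.3f, residual deviance = %.2f%s\n",
              x$alpha, x$deviance,
              if (x$zero_replaced) paste0(" (", x$zero_replaced,
                                          " zero responses replaced)")
              else ""))
  invisible(x)
}

#' @export
coef.gamma_glm_fit <- function(object, ...) {
  setNames(object$coefficients[, 1], rownames(object$coefficients))
}

#' Seasonal and boulder-stratum displacement comparison
#'
#' Summarizes displacement by season (release period) and boulder
#' proximity: per-stratum counts, means +/- SD and medians, a rank-sum
#' test between seasons, and per-individual on/off-boulder rank-sum
#' tests. Empty strata are omitted and tallied.
#'
#' @param tables list of `displacement_table`s (one per individual).
#' @return Object of class `season_comparison`: `by_season` data frame,
#'   `season_test`, `by_individual_boulder` data frame,
#'   `omitted_strata`.
#' @export
season_comparison_report <- function(tables) {
  if (length(tables) < 2L) stop("need displacement tables for >= 2 groups")
  all_t <- do.call(rbind, lapply(tables, as.data.frame))
  omitted <- 0L
  seasons <- unique(all_t$season)
  by_season <- do.call(rbind, lapply(seasons, function(s) {
    d <- all_t$dt1_m[all_t$season == s]
    data.frame(season = s, n = length(d), mean = mean(d), sd = sd(d),
               median = median(d))
  }))
  season_test <- if (length(seasons) == 2L) {
    rank_sum_test(all_t$dt1_m[all_t$season == seasons[1]],
                  all_t$dt1_m[all_t$season == seasons[2]])
  } else NULL
  rows <- list()
  for (id in unique(all_t$individual)) {
    d <- all_t[all_t$individual == id, ]
    on <- d$dt1_m[d$boulder == 1]
    off <- d$dt1_m[d$boulder == 0]
    if (length(on) == 0L || length(off) == 0L) {
      omitted <- omitted + 1L
      next
    }
    ts <- rank_sum_test(on, off)
    rows[[id]] <- data.frame(individual = id, n_on = length(on),
                             n_off = length(off), mean_on = mean(on),
                             mean_off = mean(off), W = ts$W, p = ts$p)
  }
  structure(list(by_season = by_season, season_test = season_test,
                 by_individual_boulder = do.call(rbind, rows),
                 omitted_strata = omitted),
            class = "season_comparison")
}

#' @export
print.season_comparison <- function(x, ...) {
  cat("Displacement by season:\n")
  print(x$by_season, row.names = FALSE)
  if (!is.null(x$season_test))
    cat(sprintf("  rank-sum between seasons: W = %.0f, p = %.3g\n",
                x$season_test$W, x$season_test$p))
  if (!is.null(x$by_individual_boulder)) {
    cat("On/off boulder by individual:\n")
    print(x$by_individual_boulder, row.names = FALSE)
  }
  if (x$omitted_strata)
    cat("  omitted individuals with an empty stratum:", x$omitted_strata,
        "\n")
  invisible(x)
}
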