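#' Coarse-grained trajectory length
#'
#' Higuchi's coarse-grained length of a planar trajectory at lag `k` and
#' phase `m`: the trajectory is subsampled every `k` points starting at
#' point `m`, the Euclidean lengths of the subsampled increments are
#' summed, and the sum is normalized by (N-1) / (floor((N-m)/k) * k) and
#' divided by `k` so that lengths at different lags are comparable.
#'
#' @param xy N x 2 matrix (or data frame with `x`, `y`) of positions at a
#'   regular (hourly) spacing.
#' @param k coarsening lag, integer >= 1.
#' @param m phase, 1 <= m <= k.
#' @return Scalar L_m(k).
#' @export
coarse_grained_length <- function(xy, k, m) {
  xy <- as_xy(xy)
  N <- nrow(xy)
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (k > N - 1) stop("k exceeds N - 1")
  if (m < 1 || m > k) stop("m must satisfy 1 <= m <= k")
  n_inc <- floor((N - m) / k)
  if (n_inc < 1) return(NA_real_)
  idx <- m + (0:n_inc) * k
  d <- diff(xy[idx, , drop = FALSE])
  (sum(sqrt(rowSums(d^2))) * (N - 1) / (n_inc * k)) / k
}

as_xy <- function(xy) {
  if (is.matrix(xy)) xy else as.matrix(xy[, c("x", "y")])
}

#' Mean coarse-grained length
#'
#' Arithmetic mean of [coarse_grained_length()] over all phases
#' m = 1, ..., k.
#'
#' @inheritParams coarse_grained_length
#' @export
mean_length <- function(xy, k) {
  mean(vapply(seq_len(k), function(m) coarse_grained_length(xy, k, m),
              0))
}

#' Higuchi fractal dimension of a trajectory
#'
#' Computes mean coarse-grained lengths over `k_set`, regresses
#' log2 mean length on log2 k by ordinary least squares, and reports
#' D = -slope. D is 1 for a smooth directed path and approaches 2 for a
#' plane-filling (noise-dominated) trajectory. Finite-sample estimates may
#' fall slightly outside [1, 2]; values outside are reported, not clamped,
#' and flagged in `soft_bound_violation`.
#'
#' @param xy positions as in [coarse_grained_length()].
#' @param k_set integer lags used in the regression; at least 3. The
#'   default `c(1, 2, 4, 8)` gives 4 log2-equispaced points per line.
#' @return Object of class `fractal_profile`: `profile` (data frame
#'   `k, mean_length, log2_k, log2_L`), `D`, `slope`, `intercept`,
#'   `slope_se`, `r2`, `rss`, `k_set`, `n_points`,
#'   `soft_bound_violation`.
#' @export
fractal_dimension <- function(xy, k_set = c(1, 2, 4, 8)) {
  xy <- as_xy(xy)
  if (length(k_set) < 3) stop("k_set needs at least 3 lags")
  L <- vapply(k_set, function(k) mean_length(xy, k), 0)
  if (any(!is.finite(L)) || any(L <= 0))
    stop("mean coarse-grained length is zero or undefined: ",
         "fractal dimension not defined (all points identical?)")
  lk <- log2(k_set)
  lL <- log2(L)
  fit <- lm(lL ~ lk)
  sm <- suppressWarnings(summary(fit))  # perfect fit is legitimate here
  structure(list(profile = data.frame(k = k_set, mean_length = L,
                                      log2_k = lk, log2_L = lL),
                 D = -unname(coef(fit)[2]), slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r2 = sm$r.squared, rss = sum(sm$residuals^2),
                 k_set = k_set, n_points = length(k_set),
                 soft_bound_violation =
                   -unname(coef(fit)[2]) < 1 || -unname(coef(fit)[2]) > 2),
            class = "fractal_profile")
}

#' @export
print.fractal_profile <- function(x, ...) {
  cat(sprintf("Higuchi fractal dimension: D = %.3f (se %.3f, R2 = %.3f)\n",
              x$D, x$slope_se, x$r2))
  cat("  k set:", paste(x$k_set, collapse = ", "),
      if (x$soft_bound_violation) " [outside 1 <= D <= 2]" else "", "\n")
  invisible(x)
}

#' Extract eligible trajectory windows from an hourly series
#'
#' Returns maximal-count non-overlapping windows of `window_len`
#' consecutive hours containing no gap run of more than one hour.
#' Single-hour gaps are filled by linear interpolation (tallied); longer
#' gap runs split the series, mirroring the exclusion of records without
#' enough consecutive hourly positions.
#'
#' @param series hourly `position_series` (columns `time_s, x, y, gap`).
#' @param window_len window length in hours (points); must be >= 8 so the
#'   log-log regression has at least 4 lags available.
#' @param source label carried on each window.
#' @return List of class `trajectory_windows`; each element is a matrix of
#'   positions with attributes `start_time` and `source`. Attributes
#'   `excluded` (TRUE when no window is eligible) and `interpolated`
#'   (count of filled single-hour gaps).
#' @export
extract_windows <- function(series, window_len = 100, source = "individual") {
  if (window_len < 8) stop("window_len must be >= 8")
  gap <- series$gap
  r <- rle(gap)
  # interpolate isolated single-hour gaps, break on longer runs
  x <- series$x
  y <- series$y
  interpolated <- 0L
  pos_end <- cumsum(r$lengths)
  pos_start <- pos_end - r$lengths + 1L
  breaks <- logical(nrow(series))
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (r$lengths[j] == 1L && pos_start[j] > 1L &&
        pos_end[j] < nrow(series)) {
      i <- pos_start[j]
      x[i] <- (x[i - 1] + x[i + 1]) / 2
      y[i] <- (y[i - 1] + y[i + 1]) / 2
      interpolated <- interpolated + 1L
    } else {
      breaks[pos_start[j]:pos_end[j]] <- TRUE
    }
  }
  seg_id <- cumsum(c(TRUE, diff(breaks) != 0))
  windows <- list()
  for (s in unique(seg_id[!breaks])) {
    idx <- which(seg_id == s & !breaks)
    n_win <- floor(length(idx) / window_len)
    for (w in seq_len(n_win)) {
      sel <- idx[((w - 1) * window_len + 1):(w * window_len)]
      m <- cbind(x = x[sel], y = y[sel])
      attr(m, "start_time") <- series$time_s[sel[1]]
      attr(m, "source") <- source
      windows[[length(windows) + 1L]] <- m
    }
  }
  structure(windows, excluded = length(windows) == 0L,
            interpolated = interpolated, class = "trajectory_windows")
}

#' Coarsening-scale breakpoint scan
#'
#' Scans for the lag k at which the slope of the (log2 k, log2 mean
#' length) profile changes: for each interior candidate boundary the
#' points are split into two groups, the regression-parallelism F
#' statistic is computed, and the boundary maximizing F is returned with
#' its p-value. With the default `k_max = 30` the two-line fit has
#' F(1, 26) degrees of freedom.
#'
#' @param x a trajectory (matrix / data frame of positions) or a
#'   precomputed profile data frame with columns `k` and `mean_length`.
#' @param k_max largest lag scanned (contiguous k = 1..k_max); >= 8.
#' @param min_side minimum points per side of a candidate boundary.
#' @return Object of class `breakpoint_scan`: `k_star`, `F`, `p`, `df`,
#'   `profile`, and the full candidate table `scan`.
#' @export
breakpoint_scan <- function(x, k_max = 30, min_side = 3) {
  if (k_max < 8) stop("k_max must be >= 8")
  if (is.data.frame(x) && all(c("k", "mean_length") %in% names(x))) {
    prof <- x[x$k <= k_max, ]
  } else {
    xy <- as_xy(x)
    if (k_max > nrow(xy) - 1) stop("window does not support k_max")
    prof <- data.frame(k = seq_len(k_max))
    prof$mean_length <- vapply(prof$k, function(k) mean_length(xy, k), 0)
  }
  prof$log2_k <- log2(prof$k)
  prof$log2_L <- log2(prof$mean_length)
  ks <- prof$k
  cand <- ks[seq_along(ks) >= min_side &
               seq_along(ks) <= length(ks) - min_side]
  if (length(cand) == 0L)
    stop("fewer than ", min_side, " points on one side of every candidate")
  scan <- data.frame(boundary = cand, F = NA_real_, p = NA_real_)
  for (i in seq_along(cand)) {
    lo <- prof[prof$k <= cand[i], c("log2_k", "log2_L")]
    hi <- prof[prof$k > cand[i], c("log2_k", "log2_L")]
    ft <- parallelism_f_test(setNames(lo, c("x", "y")),
                             setNames(hi, c("x", "y")))
    scan$F[i] <- ft$F
    scan$p[i] <- ft$p
  }
  best <- which.max(scan$F)
  structure(list(k_star = scan$boundary[best], F = scan$F[best],
                 p = scan$p[best],
                 df = c(1L, nrow(prof) - 4L),
                 profile = prof, scan = scan),
            class = "breakpoint_scan")
}

#' @export
print.breakpoint_scan <- function(x, ...) {
  cat(sprintf("Coarsening-scale breakpoint: k* = %d, F(%d,%d) = %.2f, p = %.3g\n",
              x$k_star, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
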