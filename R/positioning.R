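#' Estimate per-receiver clock offsets from sync-tag detections
#'
#' Receiver clocks run independently, so arrival times must be aligned
#' before time-difference-of-arrival positioning. A fixed synchronization
#' tag is co-located with one receiver (the clock reference); for every
#' sync emission heard at both the reference and another receiver, the
#' offset of that receiver is the observed arrival difference minus the
#' known propagation delay from the sync position. Offsets between sync
#' emissions are piecewise-linearly interpolated, which also absorbs slow
#' linear clock drift.
#'
#' @param log a `detection_log` containing sync-tag detections.
#' @param geometry an [array_geometry()].
#' @param sync_tag_id tag id of the synchronization transmitter.
#' @param tolerance slack (s) added to the maximum propagation delay when
#'   associating detections of one emission; must exceed the largest
#'   plausible clock offset.
#' @param smooth_window width (s) of the time bins in which per-emission
#'   offset samples are averaged before interpolation; clock error varies
#'   far more slowly than single-detection timing noise, so binning keeps
#'   the correction from absorbing per-emission noise.
#' @return Object of class `clock_model`: per-receiver offset samples, the
#'   binned offset track used for correction, the reference receiver, and
#'   ids of receivers with no usable sync detections (flagged unusable).
#' @export
synchronize_clocks <- function(log, geometry, sync_tag_id = "sync",
                               tolerance = 0.5, smooth_window = 3600) {
  stopifnot(inherits(geometry, "array_geometry"))
  sync <- log[log$tag_id == sync_tag_id, ]
  if (nrow(sync) == 0L)
    stop("no detections of sync tag '", sync_tag_id, "' in the log")
  ref <- attr(geometry, "sync_receiver")
  cc <- attr(geometry, "sound_speed")
  rec <- receiver_xy(geometry)
  sp <- sync_position(geometry)
  prop <- sqrt((rec[, 1] - sp[1])^2 + (rec[, 2] - sp[2])^2) / cc

  window <- array_diameter(geometry) / cc + tolerance
  ord <- order(sync$arrival_time_s)
  arr <- sync$arrival_time_s[ord]
  rid <- sync$receiver_id[ord]
  cl <- cumsum(c(1L, as.integer(diff(arr) > window)))

  ref_rows <- rid == ref
  ref_time <- rep(NA_real_, max(cl))
  ref_time[cl[ref_rows]] <- arr[ref_rows]  # one ref detection per cluster
  ok <- !is.na(ref_time[cl]) & !ref_rows
  samples <- data.frame(receiver_id = rid[ok],
                        time_s = ref_time[cl[ok]],
                        offset_s = arr[ok] - ref_time[cl[ok]] -
                          prop[rid[ok]])
  unusable <- setdiff(rownames(rec), c(ref, unique(samples$receiver_id)))
  if (length(unusable))
    warning("no sync-tag detections at receiver(s): ",
            paste(unusable, collapse = ", "), " - flagged unusable")
  track <- do.call(rbind, lapply(split(samples, samples$receiver_id),
                                 function(s) {
    bin <- floor(s$time_s / smooth_window)
    data.frame(receiver_id = s$receiver_id[1],
               time_s = as.numeric(tapply(s$time_s, bin, mean)),
               offset_s = as.numeric(tapply(s$offset_s, bin, mean)))
  }))
  rownames(track) <- NULL
  structure(list(samples = samples, track = track, reference = ref,
                 unusable = unusable, receivers = rownames(rec),
                 smooth_window = smooth_window),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Clock model (reference", x$reference, "):\n")
  agg <- tapply(x$samples$offset_s, x$samples$receiver_id, mean)
  for (r in names(agg))
    cat(sprintf("  %s: mean offset %+.4f s (%d sync epochs)\n",
                r, agg[r], sum(x$samples$receiver_id == r)))
  if (length(x$unusable))
    cat("  unusable:", paste(x$unusable, collapse = ", "), "\n")
  invisible(x)
}

clock_offset_at <- function(clock, receiver, t) {
  if (receiver == clock$reference) return(rep(0, length(t)))
  s <- clock$track[clock$track$receiver_id == receiver, ]
  if (nrow(s) == 0L) return(rep(NA_real_, length(t)))
  if (nrow(s) == 1L) return(rep(s$offset_s, length(t)))
  approx(s$time_s, s$offset_s, xout = t, rule = 2)$y
}

#' Apply clock corrections to a detection log
#'
#' @param log a `detection_log`.
#' @param clock a `clock_model` from [synchronize_clocks()].
#' @return The log with `arrival_time_s` corrected onto the reference clock;
#'   detections at unusable receivers are dropped (tallied in attribute
#'   `"dropped_unusable"`).
#' @export
apply_clock_correction <- function(log, clock) {
  drop <- log$receiver_id %in% clock$unusable
  out <- log[!drop, ]
  for (r in unique(out$receiver_id)) {
    i <- out$receiver_id == r
    out$arrival_time_s[i] <- out$arrival_time_s[i] -
      clock_offset_at(clock, r, out$arrival_time_s[i])
  }
  attr(out, "dropped_unusable") <- sum(drop)
  class(out) <- c("detection_log", "data.frame")
  out
}

#' Group clock-corrected detections into per-emission arrival sets
#'
#' Detections of the same tag falling within one maximum-propagation window
#' (array diameter / sound speed + tolerance) are attributed to a single
#' emission. Sets heard at fewer receivers than required are discarded:
#' by default a position is attempted only when the signal was detected by
#' all receivers; set `require_all = FALSE` to relax to >= 3 receivers.
#' Ambiguous clusters (the same receiver twice within one window) are
#' discarded and tallied.
#'
#' @param log clock-corrected `detection_log` (single or multiple tags;
#'   sets never mix tags).
#' @param geometry an [array_geometry()].
#' @param require_all require detection at every receiver in the array.
#' @param tolerance association slack, seconds.
#' @return Object of class `arrival_sets`: `tag_id` vector, arrival-time
#'   matrix (rows = sets, columns = receivers) and a `tallies` list
#'   (`ambiguous`, `insufficient`).
#' @export
group_arrivals <- function(log, geometry, require_all = TRUE,
                           tolerance = 0.05) {
  rec_ids <- geometry$receiver_id
  cc <- attr(geometry, "sound_speed")
  window <- array_diameter(geometry) / cc + tolerance
  need <- if (require_all) length(rec_ids) else 3L

  res_t <- list(); res_tag <- character(0)
  ambiguous <- 0L; insufficient <- 0L
  for (tg in unique(log$tag_id)) {
    sub <- log[log$tag_id == tg, ]
    ord <- order(sub$arrival_time_s)
    arr <- sub$arrival_time_s[ord]
    rid <- match(sub$receiver_id[ord], rec_ids)
    cl <- cumsum(c(1L, as.integer(diff(arr) > window)))
    dup_cl <- unique(cl[duplicated(cbind(cl, rid))])
    sizes <- tabulate(cl)
    keep_cl <- setdiff(which(sizes >= need), dup_cl)
    ambiguous <- ambiguous + length(dup_cl)
    insufficient <- insufficient + sum(sizes < need)
    if (length(keep_cl)) {
      m <- matrix(NA_real_, length(keep_cl), length(rec_ids),
                  dimnames = list(NULL, rec_ids))
      sel <- cl %in% keep_cl
      row_idx <- match(cl[sel], keep_cl)
      m[cbind(row_idx, rid[sel])] <- arr[sel]
      res_t[[tg]] <- m
      res_tag <- c(res_tag, rep(tg, length(keep_cl)))
    }
  }
  times <- if (length(res_t)) do.call(rbind, res_t) else
    matrix(NA_real_, 0, length(rec_ids), dimnames = list(NULL, rec_ids))
  structure(list(tag_id = res_tag, times = times,
                 tallies = list(ambiguous = ambiguous,
                                insufficient = insufficient)),
            class = "arrival_sets")
}

#' @export
print.arrival_sets <- function(x, ...) {
  cat("Arrival sets:", nrow(x$times), "emissions,",
      length(unique(x$tag_id)), "tag(s);",
      "discarded:", x$tallies$ambiguous, "ambiguous,",
      x$tallies$insufficient, "insufficient\n")
  invisible(x)
}

# Damped Gauss-Newton on range-difference residuals relative to the
# earliest-arrival receiver (best conditioning). Returns c(x, y, rss, iters)
# or NULL on breakdown.
tdoa_gn <- function(pos_rec, arr, cc, init, max_iter = 100, tol = 1e-12) {
  ref <- which.min(arr)
  oth <- setdiff(seq_along(arr), ref)
  dd_obs <- cc * (arr[oth] - arr[ref])
  p <- init
  resid_at <- function(p) {
    d <- sqrt((pos_rec[, 1] - p[1])^2 + (pos_rec[, 2] - p[2])^2)
    list(r = (d[oth] - d[ref]) - dd_obs, d = d)
  }
  cur <- resid_at(p)
  ssr <- sum(cur$r^2)
  lambda <- 1e-6
  for (it in seq_len(max_iter)) {
    d <- pmax(cur$d, 1e-12)
    ux <- (p[1] - pos_rec[, 1]) / d
    uy <- (p[2] - pos_rec[, 2]) / d
    J <- cbind(ux[oth] - ux[ref], uy[oth] - uy[ref])
    g <- crossprod(J, cur$r)
    A <- crossprod(J)
    step_ok <- FALSE
    for (tries in 1:30) {
      dp <- tryCatch(solve(A + lambda * diag(2), -g), error = function(e) NULL)
      if (is.null(dp)) { lambda <- lambda * 10; next }
      cand <- p + as.numeric(dp)
      new <- resid_at(cand)
      nssr <- sum(new$r^2)
      if (nssr <= ssr + 1e-15) {
        p <- cand; cur <- new; ssr <- nssr
        lambda <- max(lambda / 4, 1e-12)
        step_ok <- TRUE
        if (sqrt(sum(dp^2)) < tol) return(c(p, ssr, it))
        break
      }
      lambda <- lambda * 10
    }
    if (!step_ok) return(c(p, ssr, it))  # stalled at current minimum
  }
  c(p, ssr, max_iter)
}

# Multi-start wrapper: the TDOA least-squares surface can have a spurious
# branch; retry from points spread over the array when the first fit's
# residual is implausibly large for the timing noise.
tdoa_solve <- function(pos_rec, arr, cc, centroid, retry_rms = 1.5) {
  fit <- tdoa_gn(pos_rec, arr, cc, centroid)
  n_pair <- nrow(pos_rec) - 1L
  if (sqrt(fit[3] / n_pair) <= retry_rms) return(fit)
  for (j in seq_len(nrow(pos_rec))) {
    start <- 0.8 * as.numeric(pos_rec[j, ]) + 0.2 * centroid
    cand <- tdoa_gn(pos_rec, arr, cc, start)
    if (cand[3] < fit[3]) fit <- cand
    if (sqrt(fit[3] / n_pair) <= retry_rms) break
  }
  fit
}

#' Solve the hyperbolic (TDOA) positioning problem for one arrival set
#'
#' Nonlinear least squares on range-difference residuals relative to the
#' earliest-arrival receiver, initialized at the array centroid: each
#' receiver pair constrains the transmitter to a hyperbola and the solver
#' returns the planar point best matching all pairs.
#'
#' @param arrivals named numeric vector of clock-corrected arrival times,
#'   names = receiver IDs (NAs allowed; >= 3 finite values required).
#' @param geometry an [array_geometry()].
#' @param init starting point, default array centroid.
#' @param bbox_pad acceptance bounding box = receiver extent padded by this
#'   many metres; solutions outside are rejected.
#' @return One-row data frame: `time_s` (estimated emission time), `x`, `y`,
#'   `residual` (norm of range-difference residuals, m), `n_receivers`,
#'   `ok` (logical), `reason` (`""`, `"too_few_receivers"`,
#'   `"outside_bbox"`, `"no_convergence"`).
#' @export
solve_tdoa <- function(arrivals, geometry, init = NULL, bbox_pad = 20) {
  rec <- receiver_xy(geometry)
  cc <- attr(geometry, "sound_speed")
  use <- !is.na(arrivals)
  n <- sum(use)
  if (n < 3L)
    return(data.frame(time_s = NA_real_, x = NA_real_, y = NA_real_,
                      residual = NA_real_, n_receivers = n, ok = FALSE,
                      reason = "too_few_receivers"))
  pos_rec <- rec[names(arrivals)[use], , drop = FALSE]
  arr <- as.numeric(arrivals[use])
  if (is.null(init)) init <- colMeans(rec)
  fit <- tdoa_solve(pos_rec, arr, cc, init)
  p <- fit[1:2]
  bb <- c(range(rec[, 1]), range(rec[, 2])) + c(-1, 1, -1, 1) * bbox_pad
  outside <- p[1] < bb[1] || p[1] > bb[2] || p[2] < bb[3] || p[2] > bb[4]
  ok <- !outside && all(is.finite(p))
  ref <- which.min(arr)
  d_ref <- sqrt(sum((p - as.numeric(pos_rec[ref, ]))^2))
  data.frame(time_s = arr[ref] - d_ref / cc, x = p[1], y = p[2],
             residual = sqrt(fit[3]), n_receivers = n, ok = ok,
             reason = if (outside) "outside_bbox" else "")
}

#' Locate all arrival sets
#'
#' Applies [solve_tdoa()] to every arrival set and keeps accepted fixes.
#'
#' @param sets an `arrival_sets` object.
#' @param geometry an [array_geometry()].
#' @param ... passed to [solve_tdoa()].
#' @return Data frame of class `position_fixes` with columns
#'   `tag_id, time_s, x, y, residual, n_receivers`, ordered by time;
#'   rejected solves tallied in attribute `"rejected"`.
#' @export
locate_fixes <- function(sets, geometry, bbox_pad = 20) {
  rec <- receiver_xy(geometry)
  cc <- attr(geometry, "sound_speed")
  centroid <- colMeans(rec)
  bb <- c(range(rec[, 1]), range(rec[, 2])) + c(-1, 1, -1, 1) * bbox_pad
  n <- nrow(sets$times)
  res <- matrix(NA_real_, n, 5)  # time, x, y, residual, n_receivers
  ok <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    arr_full <- sets$times[i, ]
    use <- !is.na(arr_full)
    if (sum(use) < 3L) { reason[i] <- "too_few_receivers"; next }
    pos_rec <- rec[use, , drop = FALSE]
    arr <- arr_full[use]
    fit <- tdoa_solve(pos_rec, arr, cc, centroid)
    p <- fit[1:2]
    if (!all(is.finite(p))) { reason[i] <- "no_convergence"; next }
    if (p[1] < bb[1] || p[1] > bb[2] || p[2] < bb[3] || p[2] > bb[4]) {
      reason[i] <- "outside_bbox"; next
    }
    ref <- which.min(arr)
    d_ref <- sqrt(sum((p - as.numeric(pos_rec[ref, ]))^2))
    res[i, ] <- c(arr[ref] - d_ref / cc, p, sqrt(fit[3]), sum(use))
    ok[i] <- TRUE
  }
  fx <- data.frame(tag_id = sets$tag_id[ok], time_s = res[ok, 1],
                   x = res[ok, 2], y = res[ok, 3], residual = res[ok, 4],
                   n_receivers = as.integer(res[ok, 5]))
  fx <- fx[order(fx$time_s), ]
  rownames(fx) <- NULL
  structure(fx, rejected = table(reason[!ok]),
            class = c("position_fixes", "data.frame"))
}

#' Resample position fixes onto a regular time grid
#'
#' Each grid tick is represented by the fix nearest the tick within half a
#' grid step; ticks with no eligible fix are flagged as gaps. When several
#' fixes are equally eligible the earliest is kept (tallied).
#'
#' @param fixes a `position_fixes` data frame (single tag).
#' @param grid `"native"` (120 s, the midpoint of the 90--150 s emission
#'   interval), `"hourly"` or `"12h"`; or supply `step` directly.
#' @param step grid step in seconds (overrides `grid`).
#' @param t0 grid origin, seconds; defaults to 0.
#' @param t_end last tick; defaults to the last fix time rounded down.
#' @return Data frame of class `position_series`: `time_s, x, y, gap`;
#'   attributes `step` and `tallies`.
#' @export
resample_series <- function(fixes, grid = c("hourly", "native", "12h"),
                            step = NULL, t0 = 0, t_end = NULL) {
  if (is.null(step)) {
    grid <- match.arg(grid)
    step <- switch(grid, native = 120, hourly = 3600, `12h` = 43200)
  }
  if (nrow(fixes) == 0L) {
    out <- data.frame(time_s = numeric(0), x = numeric(0), y = numeric(0),
                      gap = logical(0))
    return(structure(out, step = step, tallies = list(duplicates = 0L),
                     class = c("position_series", "data.frame")))
  }
  t_end <- t_end %||% (floor((max(fixes$time_s) - t0) / step) * step + t0)
  ticks <- seq(t0, t_end, by = step)
  tick_idx <- round((fixes$time_s - t0) / step) + 1L
  dist_to_tick <- abs(fixes$time_s - (t0 + (tick_idx - 1L) * step))
  eligible <- dist_to_tick <= step / 2 & tick_idx >= 1L &
    tick_idx <= length(ticks)
  f <- fixes[eligible, ]
  ti <- tick_idx[eligible]
  dt <- dist_to_tick[eligible]
  ord <- order(ti, dt, f$time_s)
  dup <- duplicated(ti[ord])
  sel <- ord[!dup]
  x <- rep(NA_real_, length(ticks)); y <- x
  x[ti[sel]] <- f$x[sel]
  y[ti[sel]] <- f$y[sel]
  out <- data.frame(time_s = ticks, x = x, y = y, gap = is.na(x))
  structure(out, step = step,
            tallies = list(duplicates = sum(dup)),
            class = c("position_series", "data.frame"))
}

#' Localization-error report against a known position
#'
#' Summarizes horizontal (Euclidean) errors of position estimates around a
#' known true position -- e.g. raw hyperbolic fixes of the fixed sync tag
#' versus their Kalman-smoothed counterparts.
#'
#' @param est estimates: anything with `x` and `y` columns, or a 2-column
#'   matrix.
#' @param truth true position `c(x, y)`, or a matrix of per-row truths.
#' @param label optional method label carried into the printout.
#' @return Object of class `error_report`: `mean`, `sd`, `n`, `errors`.
#' @export
localization_error_report <- function(est, truth, label = "estimate") {
  xy <- if (is.matrix(est)) est else cbind(est$x, est$y)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (is.null(dim(truth))) truth <- matrix(truth, nrow(xy), 2, byrow = TRUE)
  err <- sqrt(rowSums((xy - truth)^2))
  structure(list(mean = mean(err), sd = sd(err), n = length(err),
                 errors = err, label = label),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("Localization error (%s): %.3f +/- %.3f m (n = %d)\n",
              x$label, x$mean, x$sd, x$n))
  invisible(x)
}
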