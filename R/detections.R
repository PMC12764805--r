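#' Simulate a detection log for one transmitter
#'
#' Emulates the measurement system: the tag emits at uniform-random intervals
#' in `interval` (90--150 s for the V5-type transmitters emulated here); each
#' receiver records arrival = emission time + range / sound speed + its own
#' clock error, quantized to the receiver's 1-ms temporal resolution, and
#' each detection is dropped independently with probability `dropout`.
#'
#' @param path `true_path` of the transmitter (a stationary path for a fixed
#'   sync tag).
#' @param geometry an [array_geometry()].
#' @param tag_id character tag identifier.
#' @param interval emission-interval bounds, seconds.
#' @param clock_offset named numeric vector of constant per-receiver clock
#'   offsets (s); names are receiver IDs, missing receivers get 0.
#' @param clock_drift per-receiver linear clock drift (s per s), same naming
#'   convention.
#' @param dropout detection-loss probability in `[0, 1]`.
#' @param time_jitter SD of independent Gaussian arrival-time jitter per
#'   detection, seconds (detector/multipath noise on top of quantization);
#'   `time_jitter * sound_speed` is the implied per-receiver range-error SD.
#' @param resolution arrival-time quantization step, seconds (1 ms for the
#'   emulated receivers); `0` disables quantization.
#' @param seed RNG seed.
#' @return Data frame of class `detection_log` with columns `receiver_id`,
#'   `tag_id`, `arrival_time_s`, sorted by arrival time. The true emission
#'   times and positions are attached as attribute `"emissions"` for use as
#'   ground truth in tests and error reports.
#' @export
simulate_detections <- function(path, geometry, tag_id = "tag1",
                                interval = c(90, 150),
                                clock_offset = NULL, clock_drift = NULL,
                                dropout = 0, time_jitter = 0,
                                resolution = 1e-3, seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (dropout < 0 || dropout > 1)
    stop("dropout probability must be in [0, 1]")
  t_end <- max(path$time_s)
  rec <- receiver_xy(geometry)
  ids <- rownames(rec)
  off <- setNames(rep(0, length(ids)), ids)
  drf <- off
  if (!is.null(clock_offset)) off[names(clock_offset)] <- clock_offset
  if (!is.null(clock_drift)) drf[names(clock_drift)] <- clock_drift
  cc <- attr(geometry, "sound_speed")

  with_seed(seed, {
    # emission epochs: cumulative uniform gaps until the path window ends
    n_max <- ceiling(t_end / interval[1]) + 1L
    gaps <- runif(n_max, interval[1], interval[2])
    em <- cumsum(gaps)
    em <- em[em <= t_end]
    pos <- path_position_at(path, em)

    logs <- lapply(ids, function(r) {
      rng <- sqrt((pos[, 1] - rec[r, 1])^2 + (pos[, 2] - rec[r, 2])^2)
      arr <- em + rng / cc + off[r] + drf[r] * em
      if (time_jitter > 0) arr <- arr + rnorm(length(arr), 0, time_jitter)
      if (resolution > 0) arr <- round(arr / resolution) * resolution
      keep <- runif(length(arr)) >= dropout
      data.frame(receiver_id = rep(r, sum(keep)),
                 tag_id = rep(tag_id, sum(keep)),
                 arrival_time_s = arr[keep],
                 emission = which(keep))
    })
    log <- do.call(rbind, logs)
    log <- log[order(log$arrival_time_s, log$receiver_id), ]
    rownames(log) <- NULL
    structure(log,
              emissions = data.frame(emission = seq_along(em), time_s = em,
                                     x = pos[, 1], y = pos[, 2]),
              class = c("detection_log", "data.frame"))
  })
}

#' Read/write detection logs as delimited text
#'
#' The on-disk contract is a comma-separated file with columns
#' `receiver_id, tag_id, arrival_time_s`, arrival times printed with
#' 3 decimal places (1 ms).
#'
#' @param log a `detection_log`.
#' @param file path.
#' @export
write_detection_log <- function(log, file) {
  out <- data.frame(receiver_id = log$receiver_id, tag_id = log$tag_id,
                    arrival_time_s = sprintf("%.3f", log$arrival_time_s))
  write.table(out, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_detection_log
#' @export
read_detection_log <- function(file) {
  log <- read.table(file, header = TRUE, sep = ",",
                    colClasses = c("character", "character", "numeric"))
  structure(log, class = c("detection_log", "data.frame"))
}
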