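#' Receiver array geometry
#'
#' Describes a fixed array of seabed acoustic receivers in a local planar
#' (x--y) coordinate frame, together with the receiver that carries the
#' clock-synchronization tag and the assumed underwater sound speed.
#'
#' @param receivers data frame with columns `receiver_id`, `x`, `y`
#'   (metres in the local planar frame).
#' @param sync_receiver id of the receiver co-located with the fixed
#'   synchronization tag; must be one of `receivers$receiver_id`.
#' @param sound_speed speed of sound in water, m/s. Defaults to 1500 m/s,
#'   a standard nominal value for coastal seawater.
#' @return An object of class `array_geometry`: the receiver table plus
#'   `sync_receiver` and `sound_speed` attributes.
#' @examples
#' geo <- port_geometry()
#' geo
#' @export
array_geometry <- function(receivers, sync_receiver, sound_speed = 1500) {
  stopifnot(is.data.frame(receivers),
            all(c("receiver_id", "x", "y") %in% names(receivers)))
  if (nrow(receivers) < 3L)
    stop("an array needs at least 3 receivers for planar positioning")
  if (anyDuplicated(receivers$receiver_id))
    stop("receiver IDs must be unique")
  if (!all(is.finite(receivers$x)) || !all(is.finite(receivers$y)))
    stop("receiver coordinates must be finite")
  if (!is.numeric(sound_speed) || length(sound_speed) != 1L || sound_speed <= 0)
    stop("sound_speed must be a single positive number")
  sync_receiver <- as.character(sync_receiver)
  if (!sync_receiver %in% as.character(receivers$receiver_id))
    stop("sync_receiver must match one of the receiver IDs")
  out <- receivers[, c("receiver_id", "x", "y")]
  out$receiver_id <- as.character(out$receiver_id)
  structure(out,
            sync_receiver = sync_receiver,
            sound_speed = sound_speed,
            class = c("array_geometry", "data.frame"))
}

#' Default rectangular-port receiver layout
#'
#' A five-receiver layout for a roughly 80 m x 80 m rectangular fishing
#' port: four receivers at the corners and a fifth near the centre at the
#' release point, which also carries the fixed synchronization tag.
#'
#' @param side side length of the square port, metres.
#' @param sound_speed see [array_geometry()].
#' @return An `array_geometry` object.
#' @export
port_geometry <- function(side = 80, sound_speed = 1500) {
  array_geometry(
    data.frame(receiver_id = paste0("St", 1:5),
               x = c(0, side, side, 0, side / 2),
               y = c(0, 0, side, side, side / 2)),
    sync_receiver = "St5",
    sound_speed = sound_speed)
}

#' @export
print.array_geometry <- function(x, ...) {
  cat("Receiver array:", nrow(x), "receivers, sync tag at",
      attr(x, "sync_receiver"),
      sprintf("(c = %g m/s)\n", attr(x, "sound_speed")))
  print(as.data.frame(unclass(x)), row.names = FALSE)
  invisible(x)
}

receiver_xy <- function(geometry) {
  m <- cbind(geometry$x, geometry$y)
  rownames(m) <- geometry$receiver_id
  m
}

sync_position <- function(geometry) {
  i <- match(attr(geometry, "sync_receiver"), geometry$receiver_id)
  c(x = geometry$x[i], y = geometry$y[i])
}

array_diameter <- function(geometry) {
  max(dist(receiver_xy(geometry)))
}
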