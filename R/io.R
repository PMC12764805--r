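#' Delimited-text output contracts
#'
#' Position fixes, smoothed trajectories and displacement tables travel
#' between stages as plain comma-separated text so runs can be inspected
#' and resumed with any tool.
#'
#' @param fixes a `position_fixes` data frame.
#' @param file path.
#' @name benthtrack-io
NULL

#' @rdname benthtrack-io
#' @export
write_fixes <- function(fixes, file) {
  write.table(format(as.data.frame(fixes)[
    , c("time_s", "x", "y", "residual", "n_receivers")],
    digits = 10, trim = TRUE, scientific = FALSE),
    file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname benthtrack-io
#' @export
read_fixes <- function(file) {
  fx <- read.table(file, header = TRUE, sep = ",")
  structure(fx, class = c("position_fixes", "data.frame"))
}

#' @rdname benthtrack-io
#' @param fit a `track_ssm`.
#' @export
write_trajectory <- function(fit, file) {
  tr <- fitted(fit)
  write.table(format(tr, digits = 10, trim = TRUE, scientific = FALSE),
              file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname benthtrack-io
#' @param table a `displacement_table`.
#' @export
write_displacement_table <- function(table, file) {
  out <- as.data.frame(table)[, c("individual", "time_s", "dt1_m",
                                  "temp_c", "boulder", "day")]
  write.table(format(out, digits = 10, trim = TRUE, scientific = FALSE),
              file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname benthtrack-io
#' @export
read_displacement_table <- function(file) {
  t <- read.table(file, header = TRUE, sep = ",")
  structure(t, class = c("displacement_table", "data.frame"))
}
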