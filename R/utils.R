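#' @keywords internal
"_PACKAGE"

## Angles are degrees in all user-facing interfaces and files, radians only
## inside trigonometric kernels. 0 degrees = upward, clockwise positive.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(x) {
  out <- x %% 360
  # %% can return 360 for tiny negative fuzz; pin it
  out[out == 360] <- 0
  out
}

## round-half-up at `digits` decimals; base round() is round-half-even,
## which would turn 35.485 into 35.48 instead of 35.49
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite (got non-finite values)", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a tab-separated table
#'
#' Thin wrapper with the conventions used by every file this package writes:
#' header row, tab delimiter, plain decimal points, no quoting.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x data.frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a configuration sidecar
#'
#' Echoes a config list (including its seed) as pretty JSON next to an
#' output file, so a run can be reproduced from its artifacts alone.
#'
#' @param config a list of parameters.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_json_sidecar <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
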