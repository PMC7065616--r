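#' Force trace
#'
#' Time series of the air-puff force applied to the corneal apex, on the
#' acquisition clock shared with the OCT M-scan.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param force Force in newtons, finite, same length as `time`.
#' @return An object of class `force_trace` with fields `time` and `force`.
#' @export
force_trace <- function(time, force) {
  if (length(time) != length(force))
    cp_stop("corneapuff_invalid_trace", "time and force must have equal length")
  if (!all(is.finite(time)) || !all(is.finite(force)))
    cp_stop("corneapuff_invalid_trace", "time and force must be finite")
  if (length(time) > 1L && any(diff(time) <= 0))
    cp_stop("corneapuff_invalid_trace", "time must be strictly increasing")
  structure(list(time = as.numeric(time), force = as.numeric(force)),
            class = "force_trace")
}

#' Apex displacement trace
#'
#' Inward-positive corneal apex displacement in micrometers. The baseline
#' window marks the pre-stimulus samples whose mean defines zero.
#'
#' @param time Sample times in seconds, strictly increasing.
#' @param x Displacement in micrometers (inward positive).
#' @param baseline_window Integer indices of the pre-stimulus samples, or NULL.
#' @param interpolated Logical per-sample flag for values filled in over
#'   invalid segmentation columns; NULL means none.
#' @return An object of class `displacement_trace`.
#' @export
displacement_trace <- function(time, x, baseline_window = NULL,
                               interpolated = NULL) {
  if (length(time) != length(x))
    cp_stop("corneapuff_invalid_trace", "time and x must have equal length")
  if (!all(is.finite(time)) || !all(is.finite(x)))
    cp_stop("corneapuff_invalid_trace", "time and x must be finite")
  if (length(time) > 1L && any(diff(time) <= 0))
    cp_stop("corneapuff_invalid_trace", "time must be strictly increasing")
  if (is.null(interpolated)) interpolated <- rep(FALSE, length(x))
  structure(list(time = as.numeric(time), x = as.numeric(x),
                 baseline_window = baseline_window,
                 interpolated = interpolated),
            class = "displacement_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> %d samples, %.1f ms, peak %.4g N\n",
              length(x$time), 1e3 * diff(range(x$time)), max(x$force)))
  invisible(x)
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %d samples, %.1f ms, max %.1f um\n",
              length(x$time), 1e3 * diff(range(x$time)), max(x$x)))
  invisible(x)
}

#' @export
as.data.frame.force_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$force)
}

#' @export
as.data.frame.displacement_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$x)
}

#' Read or write a `time_s,value` trace CSV
#'
#' The on-disk exchange format for pressure, force and displacement traces:
#' a two-column CSV with header `time_s,value`.
#'
#' @param path File path.
#' @return `read_trace_csv` returns a data.frame with columns `time_s` and
#'   `value`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    cp_stop("corneapuff_invalid_trace", "trace CSV must have columns time_s,value")
  df[c("time_s", "value")]
}

#' @rdname read_trace_csv
#' @param trace A `force_trace`, `displacement_trace`, or a data.frame with
#'   columns `time_s` and `value`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (is.data.frame(trace)) trace[c("time_s", "value")] else as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
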