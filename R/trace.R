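#' Kinematic trace container
#'
#' A uniformly sampled multichannel time series of limb-state signals. It is a
#' plain data.frame (first column `time_s`) carrying two attributes:
#' `sample_rate` (Hz) and `channel_classes`, a named list mapping each signal
#' class (`hand`, `joint`, `muscle`, and their `d_`-prefixed derivatives) to
#' its column names.
#'
#' @param df data.frame whose first column is `time_s`.
#' @param sample_rate sampling rate in Hz.
#' @param channel_classes named list of character vectors of column names.
#' @return An object of class `kinematic_trace`.
#' @export
kinematic_trace <- function(df, sample_rate, channel_classes) {
  stopifnot(is.data.frame(df), names(df)[1] == "time_s", sample_rate > 0)
  chans <- unlist(channel_classes, use.names = FALSE)
  if (anyDuplicated(chans)) stop("channel names must be unique")
  missing_ch <- setdiff(chans, names(df))
  if (length(missing_ch) > 0) {
    stop("channels not present in data: ", paste(missing_ch, collapse = ", "))
  }
  if (nrow(df) > 0 && anyNA(df[chans])) stop("trace contains missing samples")
  structure(df, sample_rate = sample_rate, channel_classes = channel_classes,
            class = c("kinematic_trace", "data.frame"))
}

#' @export
print.kinematic_trace <- function(x, ...) {
  cc <- attr(x, "channel_classes")
  cat(sprintf("<kinematic_trace> %d samples @ %g Hz\n", nrow(x),
              attr(x, "sample_rate")))
  for (cl in names(cc)) {
    cat(sprintf("  %-9s %s\n", cl, paste(cc[[cl]], collapse = ", ")))
  }
  invisible(x)
}

#' Sample rate of a trace
#' @param trace a [kinematic_trace].
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(trace) attr(trace, "sample_rate")

#' Channel classes of a trace
#' @param trace a [kinematic_trace].
#' @return Named list mapping class names to channel column names.
#' @export
channel_classes <- function(trace) attr(trace, "channel_classes")

#' First temporal derivative of a trace
#'
#' Differentiates every channel with central differences on interior samples
#' and one-sided differences at the two edges, so the output has exactly as
#' many samples as the input (keeping feature matrices of different
#' derivative orders row-aligned). Output channels and classes are prefixed
#' `d_`; units become per second.
#'
#' @param trace a [kinematic_trace] with at least 3 samples.
#' @param order derivative order; only 1 is supported.
#' @return A `kinematic_trace` of the differentiated channels.
#' @export
differentiate <- function(trace, order = 1) {
  stopifnot(inherits(trace, "kinematic_trace"), order == 1)
  if (nrow(trace) < 3) stop("differentiate() needs at least 3 samples")
  dt <- 1 / sample_rate(trace)
  cc <- channel_classes(trace)
  out <- data.frame(time_s = trace$time_s)
  for (ch in unlist(cc, use.names = FALSE)) {
    x <- trace[[ch]]
    n <- length(x)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    out[[paste0("d_", ch)]] <- d
  }
  new_cc <- lapply(cc, function(chs) paste0("d_", chs))
  names(new_cc) <- paste0("d_", names(cc))
  kinematic_trace(out, sample_rate = sample_rate(trace),
                  channel_classes = new_cc)
}
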