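#' Audio signal container
#'
#' A lightweight container for a single-channel sampled waveform. Samples are
#' stored as a numeric vector nominally in \[-1, 1\]; `fs` is the sampling
#' rate in Hz. All analysis functions in the package take and return this
#' type.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz (positive scalar).
#' @return An object of class `audio_signal` with fields `samples` and `fs`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)), fs = 8000)
#' duration(x)
#' @export
audio_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    length(x$samples), x$fs, length(x$samples) / x$fs,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$fs
}

as_audio_signal <- function(x, fs = NULL) {
  if (inherits(x, "audio_signal")) return(x)
  if (is.null(fs)) stop("`fs` is required when `x` is a plain vector", call. = FALSE)
  audio_signal(x, fs)
}
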