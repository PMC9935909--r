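#' Time characteristic waveform (TCW): sliding-window variance
#'
#' The TCW `c(t, delta)` is the variance of the signal over a short window
#' `[t - delta, t + delta]`, written as an integral so it can be evaluated
#' with running sums in O(N):
#' `c[t] = sum(y[tau]^2) * dt - W[t] * ybar[t]^2`, where `ybar[t]` is the
#' window mean, `dt = 1/fs` and `W[t]` is the window measure in seconds
#' (`2 * delta` in the interior; edge windows are truncated, not padded).
#' During an inspiration or expiration burst the local variance is large; in
#' breathing pauses it drops to the background-noise level, which makes the
#' TCW the basic activity envelope of the method.
#'
#' @param signal An [audio_signal()] (or numeric vector with `fs` given).
#' @param delta_s Window half-width in seconds (default 0.1, about one tenth
#'   of an inspiration/expiration phase).
#' @param fs Sampling rate, only needed when `signal` is a plain vector.
#' @return Numeric vector of the same length as the signal; nonnegative.
#' @export
compute_tcw <- function(signal, delta_s = 0.1, fs = NULL) {
  signal <- as_audio_signal(signal, fs)
  y <- signal$samples
  n <- length(y)
  d <- as.integer(round(delta_s * signal$fs))
  if (2L * d + 1L < 2L) stop("`delta_s` window holds fewer than 2 samples", call. = FALSE)
  if (2L * d + 1L > n) stop("`delta_s` window is larger than the signal", call. = FALSE)
  dt <- 1 / signal$fs
  s1 <- windowed_sum(y, d)
  s2 <- windowed_sum(y * y, d)
  cnt <- windowed_count(n, d)
  # dt * (sum y^2 - (sum y)^2 / n_w) = integral variance with truncated window
  tcw <- dt * (s2 - s1 * s1 / cnt)
  pmax(tcw, 0) # guard tiny negative rounding residue
}

#' Characteristic moment waveform (CMW): second moment of the TCW
#'
#' The CMW `I(t, delta, l)` is the second spatial moment of the TCW over a
#' longer window: `I[t] = sum((tau - t)^2 * c[tau]) * dt` for
#' `tau in [t - l, t + l]`, with `(tau - t)` in seconds. Because the
#' quadratic weight suppresses energy near `t` and emphasizes energy about
#' half a breathing cycle away, the CMW is small at burst centres and large
#' at the quiet points between breaths — its extrema drive the cycle
#' segmentation. Computed with running moment sums in O(N); edge windows are
#' truncated.
#'
#' @param tcw Numeric TCW vector from [compute_tcw()].
#' @param l_s Moment window half-width in seconds; sensible values are about
#'   half a breathing cycle (1.5-3 s).
#' @param fs Sampling rate of the TCW grid in Hz.
#' @return Numeric vector of the same length as `tcw`; nonnegative.
#' @export
compute_cmw <- function(tcw, l_s, fs) {
  n <- length(tcw)
  m <- as.integer(round(l_s * fs))
  if (2L * m + 1L < 2L) stop("`l_s` window holds fewer than 2 samples", call. = FALSE)
  if (2L * m + 1L > n) stop("`l_s` window is larger than the signal", call. = FALSE)
  dt <- 1 / fs
  # centre the index to limit cancellation in the running moment sums
  j <- seq_len(n) - (n + 1) / 2
  w0 <- windowed_sum(tcw, m)
  w1 <- windowed_sum(j * tcw, m)
  w2 <- windowed_sum(j * j * tcw, m)
  cmw <- dt^3 * (w2 - 2 * j * w1 + j * j * w0)
  pmax(cmw, 0)
}

#' Moment waveforms of a breathing recording
#'
#' Convenience wrapper computing the TCW and CMW of a signal on a common
#' grid. For recordings longer than `envelope_threshold_s` the waveforms are
#' computed on a decimated RMS-envelope grid (10 ms hop) instead of every
#' sample, which preserves the second-scale structure the segmentation needs
#' at a fraction of the cost.
#'
#' @param signal An [audio_signal()].
#' @param delta_s TCW window half-width in seconds (default 0.1).
#' @param l_s CMW window half-width in seconds (default 2, about half a
#'   breathing cycle).
#' @param envelope_threshold_s Duration above which the decimated envelope
#'   grid is used (default 600 s).
#' @return An object of class `moment_waveforms`: list with `tcw`, `cmw`,
#'   `fs` (grid rate), `hop` (samples of the original signal per grid step),
#'   `delta_s`, `l_s`, and `n_samples` of the source signal.
#' @export
moment_waveforms <- function(signal, delta_s = 0.1, l_s = 2,
                             envelope_threshold_s = 600) {
  signal <- as_audio_signal(signal)
  long <- duration(signal) > envelope_threshold_s
  if (long) {
    hop <- max(1L, as.integer(round(0.01 * signal$fs)))
    n_bins <- length(signal$samples) %/% hop
    e2 <- colMeans(matrix(
      signal$samples[seq_len(n_bins * hop)]^2, nrow = hop
    ))
    grid <- audio_signal(sqrt(e2), signal$fs / hop)
  } else {
    hop <- 1L
    grid <- signal
  }
  tcw <- compute_tcw(grid, delta_s)
  cmw <- compute_cmw(tcw, l_s, grid$fs)
  structure(
    list(
      tcw = tcw, cmw = cmw, fs = grid$fs, hop = hop,
      delta_s = delta_s, l_s = l_s, n_samples = length(signal$samples),
      source_fs = signal$fs
    ),
    class = "moment_waveforms"
  )
}

#' @export
print.moment_waveforms <- function(x, ...) {
  cat(sprintf(
    "<moment_waveforms> %d grid points @ %g Hz (delta = %g s, l = %g s)\n",
    length(x$tcw), x$fs, x$delta_s, x$l_s
  ))
  invisible(x)
}
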