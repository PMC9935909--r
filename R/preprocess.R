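#' Downsample an audio signal by an integer factor
#'
#' Anti-alias low-pass filters the signal (zero-phase Butterworth, cutoff at
#' 0.8 x the new Nyquist frequency) and then keeps every `factor`-th sample.
#' Recordings are typically acquired at 44.1 kHz and reduced to 11.025 kHz
#' (factor 4) before analysis to cut the computation cost; the breathing
#' sound content of interest lies well below the 5512.5 Hz Nyquist of the
#' analysis rate.
#'
#' Output length is `ceiling(length(x) / factor)` (the first sample is always
#' kept).
#'
#' @param signal An [audio_signal()].
#' @param target_fs Target sampling rate in Hz; `signal$fs` must be an
#'   integer multiple of it.
#' @return An [audio_signal()] at `target_fs`.
#' @export
downsample <- function(signal, target_fs = 11025) {
  signal <- as_audio_signal(signal)
  ratio <- signal$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop(
      "signal$fs (", signal$fs, ") is not an integer multiple of target_fs (",
      target_fs, "); resample to a compatible rate first",
      call. = FALSE
    )
  }
  factor <- as.integer(round(ratio))
  if (factor == 1L) return(signal)
  # zero-phase anti-alias low-pass at 0.8 x new Nyquist
  bf <- signal::butter(6, 0.8 / factor, type = "low")
  y <- signal::filtfilt(bf, signal$samples)
  audio_signal(y[seq(1L, length(y), by = factor)], target_fs)
}

#' Equalize amplitude contrast with sliding-window RMS normalization
#'
#' Whole-night breathing recordings show large level swings between faint and
#' loud breathing epochs. This step scales each sample by
#' `target_rms / local RMS`, where the local RMS is measured over a sliding
#' window, so that faint and loud epochs end up at a comparable level.
#' Regions whose local RMS falls below `floor` are treated as silence and
#' left unamplified (gain 1), so background noise in breathing pauses is not
#' blown up. The output is hard-limited to \[-1, 1\].
#'
#' This contrast-diminution step is optional preprocessing: the downstream
#' cycle features are gain-invariant, so it is off by default in
#' [monitor_night()].
#'
#' @param signal An [audio_signal()].
#' @param window_s Sliding RMS window length in seconds (default 2).
#' @param target_rms Target local RMS after equalization (default 0.1).
#' @param floor RMS level below which a region counts as silence
#'   (default 1e-4).
#' @return An [audio_signal()] with equalized amplitude.
#' @export
equalize_amplitude <- function(signal, window_s = 2, target_rms = 0.1,
                               floor = 1e-4) {
  signal <- as_audio_signal(signal)
  if (window_s <= 0) stop("`window_s` must be positive", call. = FALSE)
  h <- max(1L, as.integer(round(window_s * signal$fs / 2)))
  local_rms <- sqrt(moving_average(signal$samples^2, h))
  gain <- ifelse(local_rms < floor, 1, target_rms / local_rms)
  out <- pmin(1, pmax(-1, signal$samples * gain))
  audio_signal(out, signal$fs)
}
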