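#' Cut a cycle into half-overlapping rectangular frames
#'
#' Frames are rectangular (no taper), `win_len` samples long and advance by
#' `hop = win_len / 2` ("the window moves forward by overlapping half of
#' itself"). The number of frames is
#' `floor((length - win_len) / hop) + 1`; a trailing remainder shorter than
#' one hop is dropped. At 11.025 kHz the default 1024-sample window is about
#' 93 ms, and a typical 2.5 s active phase yields about 50 frames.
#'
#' @param cycle_samples Numeric vector of one breathing cycle.
#' @param win_len Window length in samples (default 1024).
#' @param hop Hop in samples (default `win_len / 2`).
#' @return A `win_len` x `n_frames` matrix, one frame per column.
#' @export
frame_signal <- function(cycle_samples, win_len = 1024L, hop = win_len %/% 2L) {
  n <- length(cycle_samples)
  if (n < win_len) {
    stop("cycle (", n, " samples) is shorter than one analysis window (",
         win_len, "); zero-pad the cycle or reduce `win_len`", call. = FALSE)
  }
  n_frames <- (n - win_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  vapply(starts, function(s) cycle_samples[(s + 1L):(s + win_len)],
         numeric(win_len))
}

#' Yule-Walker autoregressive power spectral density of one frame
#'
#' Fits an AR model of the given order by the Yule-Walker method (biased
#' autocovariance; `stats::ar.yw`) and evaluates the one-sided parametric
#' PSD `sigma^2 * dt / |1 + sum(a_k exp(-i 2 pi f k / fs))|^2` on `n_freq`
#' uniform frequencies over `[0, fs/2]`. An all-zero (or constant) frame has
#' no AR model and yields a flat epsilon-level PSD with a warning.
#'
#' @param frame Numeric vector, one analysis frame.
#' @param order AR model order (default 32).
#' @param n_freq Number of PSD grid points (default 513).
#' @param fs Sampling rate in Hz.
#' @param basis Optional precomputed trigonometric basis from
#'   [ar_psd_basis()]; pass it when evaluating many frames on the same grid.
#' @return List of class `psd_frame` with `freqs` (Hz), `psd` (nonnegative),
#'   `a` (AR polynomial coefficients `a_1..a_order` in the denominator
#'   convention `1 + sum a_k z^-k`) and `sigma2` (innovation variance).
#' @export
ar_psd <- function(frame, order = 32L, n_freq = 513L, fs, basis = NULL) {
  n <- length(frame)
  if (n <= order) stop("frame length must exceed the AR order", call. = FALSE)
  if (is.null(basis)) basis <- ar_psd_basis(order, n_freq, fs)
  freqs <- basis$freqs
  if (stats::var(frame) <= .Machine$double.eps) {
    warning("constant frame has no AR model; returning flat epsilon PSD")
    return(structure(
      list(freqs = freqs, psd = rep(1e-20, n_freq),
           a = rep(0, order), sigma2 = 0),
      class = "psd_frame"
    ))
  }
  fit <- stats::ar.yw(frame, aic = FALSE, order.max = order, demean = TRUE)
  a <- -fit$ar                              # 1 + sum a_k z^-k convention
  re <- 1 + basis$cosm %*% a
  im <- basis$sinm %*% a
  denom <- as.numeric(re^2 + im^2)
  psd <- fit$var.pred / fs / denom
  structure(
    list(freqs = freqs, psd = pmax(psd, 0), a = a, sigma2 = fit$var.pred),
    class = "psd_frame"
  )
}

#' Precompute the trigonometric basis for [ar_psd()]
#'
#' @param order AR order.
#' @param n_freq PSD grid size.
#' @param fs Sampling rate in Hz.
#' @return List with `freqs` and the `n_freq` x `order` matrices `cosm`,
#'   `sinm` of `cos/sin(-2 pi f k / fs)`.
#' @export
ar_psd_basis <- function(order, n_freq, fs) {
  freqs <- seq(0, fs / 2, length.out = n_freq)
  k <- seq_len(order)
  phase <- outer(freqs, k, function(f, k) -2 * pi * f * k / fs)
  list(freqs = freqs, cosm = cos(phase), sinm = sin(phase))
}

#' Default Mel-analysis configuration
#'
#' Bundles the knobs of the per-cycle feature extraction: framing, AR order,
#' PSD grid and filter bank geometry.
#'
#' @param win_len Frame length in samples (default 1024).
#' @param hop Frame hop (default `win_len / 2`).
#' @param order AR model order (default 32).
#' @param n_freq PSD grid size (default 513).
#' @param n_filters Number of Mel filters (default 20).
#' @param f_low,f_high Filter-bank band edges in Hz (defaults 0 and fs/2).
#' @param eps Floor applied to band energies before the log (default 1e-12).
#' @return A list of class `mel_config`.
#' @export
mel_config <- function(win_len = 1024L, hop = win_len %/% 2L, order = 32L,
                       n_freq = 513L, n_filters = 20L, f_low = 0,
                       f_high = NULL, eps = 1e-12) {
  structure(
    list(win_len = as.integer(win_len), hop = as.integer(hop),
         order = as.integer(order), n_freq = as.integer(n_freq),
         n_filters = as.integer(n_filters), f_low = f_low, f_high = f_high,
         eps = eps),
    class = "mel_config"
  )
}

#' Log Mel-band energy matrix of one breathing cycle
#'
#' Steps 1-4 of the per-cycle analysis: frame the cycle, estimate each
#' frame's PSD by Yule-Walker AR modelling, weight the PSD by the triangular
#' Mel filter bank, and take base-10 logs of the band energies:
#' `f[i, j] = log10(max(E_i(frame j), eps))`.
#'
#' @param cycle_samples Numeric vector of one segmented cycle.
#' @param fs Sampling rate in Hz.
#' @param config A [mel_config()].
#' @return An `n_filters` x `n_frames` matrix of log10 Mel-band energies
#'   (class `mel_features`, with the filter bank attached as attribute
#'   `filterbank`).
#' @export
mel_features <- function(cycle_samples, fs, config = mel_config()) {
  frames <- frame_signal(cycle_samples, config$win_len, config$hop)
  f_high <- if (is.null(config$f_high)) fs / 2 else config$f_high
  freqs <- seq(0, fs / 2, length.out = config$n_freq)
  bank <- build_filterbank(config$n_filters, config$f_low, f_high, freqs)
  basis <- ar_psd_basis(config$order, config$n_freq, fs)
  vals <- apply(frames, 2, function(fr) {
    p <- ar_psd(fr, order = config$order, n_freq = config$n_freq, fs = fs,
                basis = basis)
    band <- as.numeric(bank$weights %*% p$psd)
    log10(pmax(band, config$eps))
  })
  vals <- matrix(vals, nrow = config$n_filters)
  structure(vals, class = c("mel_features", "matrix"), filterbank = bank)
}

#' Mel-scale label (MsL) sequence of a feature matrix
#'
#' The MsL of a frame is the index of the Mel filter with the largest log
#' band energy in that frame (the column argmax of the feature matrix).
#' Ties break to the lowest filter index, making the result deterministic.
#'
#' @param features A matrix from [mel_features()] (filters x frames).
#' @return Integer vector of labels in `1..n_filters`, one per frame.
#' @export
extract_msl <- function(features) {
  labels <- apply(unclass(features), 2, which.max)
  as.integer(labels)
}

#' Per-cycle MsL occupancy histogram (N_MsL)
#'
#' Counts how many frames of the cycle carry each Mel-scale label; the
#' counts describe where the cycle's spectral energy lives and are the input
#' of the threshold classification rules.
#'
#' @param labels Integer MsL sequence from [extract_msl()].
#' @param n_filters Number of labels (default 20).
#' @return List of class `msl_histogram` with `counts` (length `n_filters`)
#'   and `total` (the frame count).
#' @export
msl_histogram <- function(labels, n_filters = 20L) {
  if (length(labels) == 0L) stop("empty MsL sequence", call. = FALSE)
  if (any(labels < 1L | labels > n_filters)) {
    stop("MsL labels must lie in 1..", n_filters, call. = FALSE)
  }
  structure(
    list(counts = tabulate(labels, nbins = n_filters), total = length(labels)),
    class = "msl_histogram"
  )
}

#' @export
print.msl_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat(sprintf("<msl_histogram> %d frames; nonzero labels: %s\n", x$total,
              paste0(nz, ":", x$counts[nz], collapse = " ")))
  invisible(x)
}
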