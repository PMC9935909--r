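#' Convert frequency in Hz to the Mel scale
#'
#' Uses the base-10 form anchored at 1 kHz:
#' `Mel(f) = 1000 * log10(1 + f/700) / log10(1 + 1000/700)`,
#' so `Mel(1000) = 1000` exactly. The scale is approximately linear below
#' 1 kHz and logarithmic above, mirroring human pitch perception.
#'
#' @param f Frequency in Hz (vectorized, nonnegative).
#' @return Mel-scale frequency.
#' @seealso [mel_to_hz()]
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be nonnegative", call. = FALSE)
  1000 * log10(1 + f / 700) / log10(1 + 1000 / 700)
}

#' Convert Mel-scale frequency back to Hz
#'
#' Exact inverse of [hz_to_mel()].
#'
#' @param m Mel-scale frequency (vectorized, nonnegative).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel frequency must be nonnegative", call. = FALSE)
  700 * (10^(m * log10(1 + 1000 / 700) / 1000) - 1)
}

#' Build a triangular Mel filter bank
#'
#' `n_filters + 2` edge frequencies are spaced uniformly on the Mel scale
#' between `f_low` and `f_high`. Filter `m` rises linearly (in Hz) from edge
#' `m - 1` to peak 1 at edge `m` and falls to zero at edge `m + 1`, so the
#' peak of each triangle is the left edge of the next one. The triangles are
#' sampled on the supplied frequency grid.
#'
#' @param n_filters Number of triangular filters (default 20).
#' @param f_low,f_high Band edges in Hz of the whole bank.
#' @param freqs Frequency grid (Hz, strictly increasing) on which to sample
#'   the filter responses.
#' @return An object of class `mel_filterbank`: list with `n_filters`,
#'   `edges` (length `n_filters + 2`, Hz), `centers` (peak frequencies, Hz),
#'   `weights` (`n_filters` x `length(freqs)` matrix) and `freqs`.
#' @export
build_filterbank <- function(n_filters = 20, f_low = 0, f_high = 5512.5,
                             freqs) {
  if (n_filters < 1L) stop("`n_filters` must be >= 1", call. = FALSE)
  if (!(f_low < f_high)) stop("`f_low` must be below `f_high`", call. = FALSE)
  mel_edges <- seq(hz_to_mel(f_low), hz_to_mel(f_high),
                   length.out = n_filters + 2L)
  edges <- mel_to_hz(mel_edges)
  # grid must resolve the narrowest filter half-width
  min_half <- min(diff(edges))
  if (max(diff(freqs)) > min_half) {
    stop("frequency grid too coarse to resolve the narrowest Mel filter ",
         "(half-width ", signif(min_half, 4), " Hz)", call. = FALSE)
  }
  w <- matrix(0, nrow = n_filters, ncol = length(freqs))
  for (m in seq_len(n_filters)) {
    lo <- edges[m]
    pk <- edges[m + 1L]
    hi <- edges[m + 2L]
    rise <- (freqs - lo) / (pk - lo)
    fall <- (hi - freqs) / (hi - pk)
    w[m, ] <- pmax(0, pmin(rise, fall))
  }
  structure(
    list(
      n_filters = n_filters,
      edges = edges,
      centers = edges[2:(n_filters + 1L)],
      weights = w,
      freqs = freqs
    ),
    class = "mel_filterbank"
  )
}

#' @export
print.mel_filterbank <- function(x, ...) {
  cat(sprintf(
    "<mel_filterbank> %d triangular filters over [%.1f, %.1f] Hz (%d grid points)\n",
    x$n_filters, x$edges[1], x$edges[length(x$edges)], length(x$freqs)
  ))
  invisible(x)
}
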