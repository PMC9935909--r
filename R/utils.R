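# Internal numeric helpers.

# Windowed running sum with truncated edge windows:
# out[t] = sum(x[max(1, t-h) : min(n, t+h)]), O(n) via cumulative sums.
windowed_sum <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  hi <- pmin(n, idx + h)
  lo <- pmax(1L, idx - h)
  cs[hi + 1L] - cs[lo]
}

# Number of samples in the truncated window centred at each position.
windowed_count <- function(n, h) {
  idx <- seq_len(n)
  pmin(n, idx + h) - pmax(1L, idx - h) + 1L
}

# Moving-average smoother with truncated edges.
moving_average <- function(x, h) {
  windowed_sum(x, h) / windowed_count(length(x), h)
}

# Rectified envelope smoothed over `smooth_s` seconds (default 50 ms).
smoothed_envelope <- function(samples, fs, smooth_s = 0.05) {
  h <- max(1L, as.integer(round(smooth_s * fs / 2)))
  moving_average(abs(samples), h)
}

# Root-mean-square of a vector.
rms <- function(x) sqrt(mean(x^2))

# Strict local extrema (interior points) of a numeric vector.
# type = "min" or "max". Plateaus are reduced to their first point.
local_extrema_idx <- function(x, type = c("min", "max")) {
  type <- match.arg(type)
  if (type == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the last non-zero slope through plateaus
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_f <- s
  s_f[!nz] <- NA
  filled <- s_f
  last <- 0
  for (i in seq_len(n - 1L)) {     # short loop only over plateau runs in practice
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  idx <- which(diff(filled) < 0) + 1L
  idx[idx > 1L & idx < n]
}

# Local extrema with a minimum separation (in samples): candidates are ranked
# by prominence (value for maxima, -value for minima) and greedily accepted
# if at least `min_sep` from every already-accepted extremum.
local_extrema_min_sep <- function(x, min_sep, type = c("min", "max")) {
  type <- match.arg(type)
  cand <- local_extrema_idx(x, type)
  if (length(cand) == 0L) return(integer(0))
  ord <- if (type == "max") order(x[cand], decreasing = TRUE) else order(x[cand])
  cand <- cand[ord]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0L || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}
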