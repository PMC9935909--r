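# Shared fixtures and independent oracles for the test suite.

FS <- 11025

# ---- independent brute-force oracles (direct definition, double loop) -------

tcw_bruteforce <- function(y, delta_s, fs) {
  d <- round(delta_s * fs)
  dt <- 1 / fs
  n <- length(y)
  vapply(seq_len(n), function(t) {
    w <- y[max(1, t - d):min(n, t + d)]
    dt * (sum(w^2) - sum(w)^2 / length(w))
  }, numeric(1))
}

cmw_bruteforce <- function(tcw, l_s, fs) {
  m <- round(l_s * fs)
  dt <- 1 / fs
  n <- length(tcw)
  vapply(seq_len(n), function(t) {
    j <- max(1, t - m):min(n, t + m)
    sum(((j - t) * dt)^2 * tcw[j]) * dt
  }, numeric(1))
}

# ---- spectral helpers --------------------------------------------------------

# FFT power fraction of x inside [lo, hi] Hz
power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  half <- p[seq_len(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * fs / n
  sum(half[f >= lo & f <= hi]) / sum(half)
}

# dominant FFT frequency of x
dominant_freq <- function(x, fs) {
  n <- length(x)
  half <- Mod(stats::fft(x))[2:(n %/% 2)]
  f <- (2:(n %/% 2) - 1) * fs / n
  f[which.max(half)]
}

# ---- audio fixtures ----------------------------------------------------------

# breath-like burst with the two-lobe inspiration/expiration envelope
two_lobe_burst <- function(duration_s = 2.5, level = 0.1, fs = FS) {
  b <- gen_breath_burst(duration_s, level = level, fs = fs)
  tt <- seq_along(b) / length(b)
  b * (0.3 + 0.7 * sin(2 * pi * tt)^2)
}

# recording with bursts at given onset times over background noise
burst_train <- function(onsets_s, duration_s = 2.5, total_s = NULL,
                        level = 0.1, noise_sd = 0.01, fs = FS, seed = 1) {
  set.seed(seed)
  if (is.null(total_s)) total_s <- max(onsets_s) + duration_s + 2
  x <- numeric(round(total_s * fs))
  for (t0 in onsets_s) {
    b <- two_lobe_burst(duration_s, level, fs)
    i0 <- round(t0 * fs)
    x[(i0 + 1):(i0 + length(b))] <- x[(i0 + 1):(i0 + length(b))] + b
  }
  audio_signal(x + rnorm(length(x), sd = noise_sd), fs)
}

# write a 16-bit PCM WAV directly (independent of write_wav) for read tests
write_pcm16_raw <- function(samples_q, fs, path, channels = 1L) {
  n <- length(samples_q)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(channels), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2 * channels), con, size = 4, endian = "little")
  writeBin(as.integer(2 * channels), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(as.integer(samples_q), con, size = 2, endian = "little")
  path
}

# small truth table used by label I/O tests
example_labels <- function() {
  data.frame(
    start_s = c(1, 5.2, 9.5),
    end_s = c(3.4, 7.6, 12),
    state = c("normal", "abnormal", "normal"),
    snore = c(0L, 1L, 0L),
    event = c("none", "hypopnea", "none"),
    stringsAsFactors = FALSE
  )
}
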