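# Synthetic labelled breathing audio.
#
# The generator emulates the acoustic structure the monitoring method
# assumes: quasi-periodic inspiration/expiration noise bursts whose energy
# is dominated by the 500-1500 Hz breathing band, an added low-frequency
# (< 500 Hz) harmonic component for snoring, an added low-plus-high
# frequency obstruction component for abnormal breathing, and silent
# breathing stops of 6-10 s (hypopnea) or > 10 s (apnea).

# Gaussian noise with an arbitrary spectral amplitude shape, via FFT masking.
shaped_noise <- function(n, fs, amp_fn) {
  if (n <= 0L) return(numeric(0))
  n2 <- stats::nextn(n)               # pad to a fast FFT length
  w <- stats::rnorm(n2)
  f <- (seq_len(n2) - 1L) * fs / n2
  f_fold <- pmin(f, fs - f)
  mask <- amp_fn(f_fold)
  x <- Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n2
  x[seq_len(n)]
}

# Raised-cosine (Tukey) taper: flat with half-cosine ramps of `ramp` samples.
tukey_env <- function(n, ramp) {
  env <- rep(1, n)
  r <- min(ramp, n %/% 2L)
  if (r > 0L) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- up
    env[n + 1L - seq_len(r)] <- up
  }
  env
}

scale_rms <- function(x, level) {
  r <- rms(x)
  if (r == 0) return(x * 0)
  x * (level / r)
}

#' Generate one band-limited breathing noise burst
#'
#' Band-pass filtered Gaussian noise with a raised-cosine amplitude
#' envelope. Within the band the spectral density is tilted downward with
#' frequency (`~ f^-0.8`), as real breath noise is, so the dominant density
#' sits near the lower band edge. At least 80% of the spectral power lies
#' inside `band`.
#'
#' @param duration_s Burst duration in seconds (0 gives an empty vector).
#' @param band Length-2 numeric, `(lo_hz, hi_hz)` with `0 < lo < hi <= fs/2`.
#' @param level Target RMS of the burst.
#' @param fs Sampling rate in Hz (default 11025).
#' @return Numeric sample vector.
#' @export
gen_breath_burst <- function(duration_s, band = c(500, 1500), level = 0.1,
                             fs = 11025) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] <= fs / 2)) {
    stop("invalid band: need 0 < lo < hi <= fs/2", call. = FALSE)
  }
  n <- as.integer(round(duration_s * fs))
  if (n <= 0L) return(numeric(0))
  lo <- band[1]; hi <- band[2]
  ramp <- 0.1 * (hi - lo)
  amp <- function(f) {
    a <- rep(0, length(f))
    core <- f >= lo & f <= hi
    a[core] <- (pmax(f[core], lo) / lo)^-0.8
    up <- f >= lo - ramp & f < lo
    a[up] <- 0.5 * (1 - cos(pi * (f[up] - (lo - ramp)) / ramp))
    dn <- f > hi & f <= hi + ramp
    a[dn] <- (hi / lo)^-0.8 * 0.5 * (1 + cos(pi * (f[dn] - hi) / ramp))
    a
  }
  x <- shaped_noise(n, fs, amp)
  env <- tukey_env(n, as.integer(round(0.05 * fs)))
  scale_rms(x * env, level)
}

#' Generate a snore component
#'
#' A harmonic pulse train at the snore fundamental `f0` (harmonics up to
#' 480 Hz, shaped by a formant-like envelope peaking near 170 Hz) plus weak
#' sub-500 Hz noise. At least 70% of the power lies below 500 Hz.
#'
#' @param duration_s Duration in seconds.
#' @param f0_hz Snore fundamental in Hz, typically 50-120 (must be < 250).
#' @param level Target RMS.
#' @param fs Sampling rate in Hz.
#' @return Numeric sample vector.
#' @export
gen_snore_component <- function(duration_s, f0_hz = 90, level = 0.1,
                                fs = 11025) {
  if (f0_hz >= 250) stop("snore fundamental must be below 250 Hz", call. = FALSE)
  n <- as.integer(round(duration_s * fs))
  if (n <= 0L) return(numeric(0))
  t <- (seq_len(n) - 1L) / fs
  ks <- seq_len(max(1L, floor(480 / f0_hz)))
  amps <- exp(-((ks * f0_hz - 170)^2) / (2 * 80^2))
  phases <- stats::runif(length(ks), 0, 2 * pi)
  harm <- rowSums(vapply(seq_along(ks), function(i) {
    amps[i] * cos(2 * pi * ks[i] * f0_hz * t + phases[i])
  }, numeric(n)))
  noise <- shaped_noise(n, fs, function(f) {
    as.numeric(f >= 30 & f <= 480) * 0.5 * (1 - cos(pi * pmin(f / 60, 1)))
  })
  x <- scale_rms(harm, 1) + scale_rms(noise, 0.25)
  scale_rms(x, level)
}

#' Generate an abnormal-breathing component
#'
#' Obstructed breathing adds energy both below 500 Hz and in the upper
#' spectrum: the component is the sum of flat sub-500 Hz noise and a
#' high-frequency obstruction-noise band whose power density peaks near
#' 3.4 kHz and extends past 3500 Hz. At least 60% of the power lies outside
#' the 500-3500 Hz mid band.
#'
#' @param duration_s Duration in seconds.
#' @param level Target RMS.
#' @param fs Sampling rate in Hz (must exceed 7000 so the high band exists).
#' @return Numeric sample vector.
#' @export
gen_abnormal_component <- function(duration_s, level = 0.1, fs = 11025) {
  if (fs / 2 <= 3500) stop("fs/2 must exceed 3500 Hz", call. = FALSE)
  n <- as.integer(round(duration_s * fs))
  if (n <= 0L) return(numeric(0))
  high <- shaped_noise(n, fs, function(f) exp(-((f - 3395)^2) / (2 * 424^2)))
  low <- shaped_noise(n, fs, function(f) {
    as.numeric(f >= 80 & f <= 480) * 0.5 * (1 - cos(pi * pmin((f - 60) / 60, 1)))
  })
  # sub-500 power at 0.8 x the high-band power
  x <- scale_rms(high, 1) + scale_rms(low, sqrt(0.8))
  scale_rms(x, level)
}

#' Configuration of the synthetic night generator
#'
#' Defaults mirror the timing the method assumes: a mean breathing cycle of
#' 4 s whose inspiration/expiration phase lasts about 2.5 s, a breathing
#' band 20 dB above the room noise, and event probabilities giving a
#' handful of apnea/hypopnea stops per night.
#'
#' @param fs Sampling rate in Hz (default 11025).
#' @param n_cycles Number of breathing cycles (default 100).
#' @param cycle_s Mean cycle length in seconds (default 4).
#' @param active_s Mean inspiration/expiration phase length (default 2.5).
#' @param jitter Coefficient of variation of the cycle timings (default 0.1).
#' @param snr_db Breathing-band SNR over the background noise in dB
#'   (default 20).
#' @param p_snore Per-cycle probability of a snore component (default 0.2).
#' @param p_abnormal Per-cycle probability of the abnormal component
#'   (default 0.3).
#' @param p_apnea,p_hypopnea Per-gap probabilities of an apnea (> 10 s) or
#'   hypopnea (6-10 s) breathing stop (defaults 0.05 each).
#' @param seed RNG seed for reproducible nights (default `NULL`: use the
#'   current RNG state).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 11025, n_cycles = 100L, cycle_s = 4,
                             active_s = 2.5, jitter = 0.1, snr_db = 20,
                             p_snore = 0.2, p_abnormal = 0.3,
                             p_apnea = 0.05, p_hypopnea = 0.05,
                             seed = NULL) {
  probs <- c(p_snore, p_abnormal, p_apnea, p_hypopnea)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (fs <= 0 || n_cycles < 1L) stop("need fs > 0 and n_cycles >= 1", call. = FALSE)
  if (active_s >= cycle_s) stop("`active_s` must be below `cycle_s`", call. = FALSE)
  structure(
    list(fs = fs, n_cycles = as.integer(n_cycles), cycle_s = cycle_s,
         active_s = active_s, jitter = jitter, snr_db = snr_db,
         p_snore = p_snore, p_abnormal = p_abnormal,
         p_apnea = p_apnea, p_hypopnea = p_hypopnea, seed = seed),
    class = "synthetic_config"
  )
}

#' Generate a labelled synthetic night of breathing audio
#'
#' Assembles `n_cycles` breathing cycles, each an active phase (a breathing
#' noise burst with a two-lobe inspiration/expiration envelope) followed by
#' an inter-cycle gap. Snoring cycles carry the harmonic snore component on
#' the inspiration lobe; abnormal cycles carry the obstruction component on
#' the expiration lobe (and a snore component with probability 0.8, since
#' abnormal breathing usually co-occurs with snoring). Gaps are replaced by
#' hypopnea (uniform 6-10 s) or apnea (uniform 10-25 s) breathing stops with
#' the configured probabilities, and the cycle preceding such a stop is
#' made abnormal. White background noise sits `snr_db` below the
#' breathing-band RMS. The same seed reproduces the identical waveform and
#' truth table.
#'
#' @param config A [synthetic_config()].
#' @return List of class `labeled_recording` with `audio` (an
#'   [audio_signal()]) and `truth` (a label `data.frame` in the
#'   [read_labels()] schema).
#' @export
gen_night <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  n_cyc <- config$n_cycles
  breath_level <- 0.1
  snore_level <- 0.15
  abnormal_level <- 0.18

  # --- timing and per-cycle flags -------------------------------------------
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  active <- clamp(config$active_s * (1 + config$jitter * stats::rnorm(n_cyc)),
                  0.6 * config$active_s, 1.4 * config$active_s)
  base_gap <- config$cycle_s - config$active_s
  gaps <- clamp(base_gap * (1 + config$jitter * stats::rnorm(n_cyc)), 0.5, 3)
  event <- rep("none", n_cyc)
  u <- stats::runif(n_cyc)
  for (i in seq_len(n_cyc - 1L)) {  # the final gap is the recording tail
    if (u[i] < config$p_apnea) {
      gaps[i] <- stats::runif(1, 10, 25)
      event[i] <- "apnea"
    } else if (u[i] < config$p_apnea + config$p_hypopnea) {
      gaps[i] <- stats::runif(1, 6, 10)
      event[i] <- "hypopnea"
    }
  }
  abnormal <- stats::runif(n_cyc) < config$p_abnormal | event != "none"
  snore <- stats::runif(n_cyc) < config$p_snore |
    (abnormal & stats::runif(n_cyc) < 0.8)
  f0 <- stats::runif(n_cyc, 50, 120)

  # --- audio assembly -------------------------------------------------------
  lead_s <- 1
  pieces <- vector("list", 2L * n_cyc + 1L)
  pieces[[1L]] <- numeric(as.integer(round(lead_s * fs)))
  t_cursor <- lead_s
  start_s <- end_s <- numeric(n_cyc)
  ramp <- as.integer(round(0.05 * fs))
  for (i in seq_len(n_cyc)) {
    n_a <- as.integer(round(active[i] * fs))
    tt <- seq_len(n_a) / n_a
    # two-lobe inspiration/expiration envelope with a shallow mid-cycle dip
    env <- tukey_env(n_a, ramp) * (0.3 + 0.7 * sin(2 * pi * tt)^2)
    # smooth crossfade between the inspiration and expiration halves
    half <- n_a %/% 2L
    xfade <- min(as.integer(round(0.05 * fs)), half %/% 2L)
    w_insp <- rep(1, n_a)
    if (xfade > 1L) {
      idx <- (half - xfade + 1L):(half + xfade)
      w_insp[idx] <- 0.5 * (1 + cos(pi * seq_along(idx) / length(idx)))
    }
    w_insp[(half + xfade + 1L):n_a] <- 0
    w_exp <- 1 - w_insp
    x <- gen_breath_burst(active[i], level = breath_level, fs = fs)[seq_len(n_a)] / breath_level
    x <- x * env * breath_level
    if (snore[i]) {
      s <- gen_snore_component(active[i], f0_hz = f0[i], level = 1, fs = fs)[seq_len(n_a)]
      x <- x + s * env * w_insp * snore_level
    }
    if (abnormal[i]) {
      a <- gen_abnormal_component(active[i], level = 1, fs = fs)[seq_len(n_a)]
      x <- x + a * env * w_exp * abnormal_level
    }
    pieces[[2L * i]] <- x
    start_s[i] <- t_cursor
    end_s[i] <- t_cursor + n_a / fs
    n_g <- as.integer(round(gaps[i] * fs))
    pieces[[2L * i + 1L]] <- numeric(n_g)
    t_cursor <- end_s[i] + n_g / fs
  }
  samples <- unlist(pieces, use.names = FALSE)
  noise_sd <- breath_level * 10^(-config$snr_db / 20)
  samples <- samples + stats::rnorm(length(samples), sd = noise_sd)
  peak <- max(abs(samples))
  if (peak > 0.99) samples <- samples * (0.99 / peak)

  truth <- data.frame(
    start_s = start_s,
    end_s = end_s,
    state = ifelse(abnormal, "abnormal", "normal"),
    snore = as.integer(snore),
    event = event,
    stringsAsFactors = FALSE
  )
  structure(
    list(audio = audio_signal(samples, fs), truth = truth, config = config),
    class = "labeled_recording"
  )
}

#' @rdname gen_night
#' @export
simulate_night <- gen_night

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf(
    "<labeled_recording> %.1f s @ %g Hz; %d cycles (%d abnormal, %d snore, %d apnea, %d hypopnea)\n",
    duration(x$audio), x$audio$fs, nrow(x$truth),
    sum(x$truth$state == "abnormal"), sum(x$truth$snore),
    sum(x$truth$event == "apnea"), sum(x$truth$event == "hypopnea")
  ))
  invisible(x)
}
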