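#' Full monitoring configuration
#'
#' Bundles every tunable of the pipeline: preprocessing, moment-waveform
#' segmentation, Mel feature extraction and the threshold rules.
#'
#' @param equalize Apply [equalize_amplitude()] before analysis? (default
#'   `FALSE`; the Mel-label features are gain-invariant, so equalization
#'   only matters for recordings with extreme level drift).
#' @param delta_s,l_s Moment-waveform windows in seconds (defaults 0.1, 2).
#' @param min_cycle_s Shortest plausible cycle in seconds (default 1.5).
#' @param active_frac TCW active-phase fraction (default 0.05).
#' @param alpha Weak-cycle merge threshold fraction (default 0.2).
#' @param mel A [mel_config()].
#' @param sets An [msl_sets()].
#' @param thresholds A [threshold_config()].
#' @param edge_correction Pause-edge bias compensation, see
#'   [pause_durations()].
#' @return List of class `monitor_config`.
#' @export
monitor_config <- function(equalize = FALSE, delta_s = 0.1, l_s = 2,
                           min_cycle_s = 1.5, active_frac = 0.01, alpha = 0.2,
                           mel = mel_config(), sets = msl_sets(),
                           thresholds = threshold_config(),
                           edge_correction = -0.12) {
  structure(
    list(equalize = equalize, delta_s = delta_s, l_s = l_s,
         min_cycle_s = min_cycle_s, active_frac = active_frac, alpha = alpha,
         mel = mel, sets = sets, thresholds = thresholds,
         edge_correction = edge_correction),
    class = "monitor_config"
  )
}

#' Monitor a night of breathing audio
#'
#' Runs the full pipeline: (optional) amplitude equalization, moment-waveform
#' cycle segmentation, per-cycle Mel-label feature extraction, threshold
#' classification of every cycle as normal/abnormal with a snore flag,
#' apnea/hypopnea calling on the breathing stops, and the night-level report
#' with the sleep-quality ratio `R_sleep`. If a ground-truth label table is
#' supplied, detected cycles are matched to truth cycles by interval overlap
#' and state/snore accuracies are added to the result.
#'
#' @param signal An [audio_signal()] (11.025 kHz analysis rate; use
#'   [downsample()] first for 44.1 kHz recordings), or a plain numeric
#'   vector with `fs` given.
#' @param config A [monitor_config()].
#' @param truth Optional truth `data.frame` in the [read_labels()] schema.
#' @param fs Sampling rate when `signal` is a plain vector.
#' @return An object of class `sleep_monitor`: list with `cycles` (per-cycle
#'   data.frame: `start_s`, `end_s`, `fl`, `fm`, `fh`, `state`, `snore`,
#'   `event`), `report` (a `monitoring_report`), `segmentation`, `config`,
#'   and — when truth was given — `accuracy` and the matched `truth`.
#' @examples
#' \donttest{
#' night <- gen_night(synthetic_config(n_cycles = 12, seed = 1))
#' fit <- monitor_night(night$audio, truth = night$truth)
#' fit
#' summary(fit)
#' }
#' @export
monitor_night <- function(signal, config = monitor_config(), truth = NULL,
                          fs = NULL) {
  signal <- as_audio_signal(signal, fs)
  if (config$equalize) signal <- equalize_amplitude(signal)

  seg <- segment_cycles(
    signal, delta_s = config$delta_s, l_s = config$l_s,
    min_cycle_s = config$min_cycle_s, active_frac = config$active_frac,
    alpha = config$alpha
  )

  n <- nrow(seg$cycles)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    cyc <- signal$samples[(seg$cycles$start_idx[i] + 1L):seg$cycles$end_idx[i]]
    feats <- mel_features(cyc, signal$fs, config$mel)
    hist <- msl_histogram(extract_msl(feats), config$mel$n_filters)
    labels[[i]] <- classify_cycle(symbolize(hist, config$sets, config$thresholds))
  }

  report <- summarize_night(labels, seg, config$edge_correction)

  cycles <- data.frame(
    start_s = seg$cycles$start_idx / seg$fs,
    end_s = seg$cycles$end_idx / seg$fs,
    fl = vapply(labels, function(l) l$fl_sym, integer(1)),
    fm = vapply(labels, function(l) l$fm_sym, integer(1)),
    fh = vapply(labels, function(l) l$fh_sym, integer(1)),
    state = vapply(labels, function(l) l$state, character(1)),
    snore = as.integer(vapply(labels, function(l) l$snore, logical(1))),
    stringsAsFactors = FALSE
  )
  cycles$event <- "none"
  if (n > 1L && nrow(report$events) > 0L) {
    # attach each interior pause's event to the preceding cycle
    prev <- findInterval(report$events$start_s, cycles$end_s - 1e-9)
    ok <- prev >= 1L & prev <= n
    cycles$event[prev[ok]] <- report$events$event[ok]
  }

  out <- structure(
    list(cycles = cycles, report = report, segmentation = seg,
         config = config, fs = signal$fs,
         n_samples = length(signal$samples)),
    class = "sleep_monitor"
  )
  if (!is.null(truth)) {
    truth <- validate_labels(truth)
    out$truth <- truth
    out$accuracy <- evaluate_against_truth(out, truth)
  }
  out
}

#' Match detected cycles to truth cycles and score them
#'
#' Each truth cycle is matched to the detected cycle with the largest time
#' overlap; truth cycles with no overlapping detection count as errors for
#' both accuracies. Returns the same accuracy pair as
#' [score_against_truth()], plus the cycle-count recovery and per-event
#' recall.
#'
#' @param fit A `sleep_monitor`.
#' @param truth Truth `data.frame` in the [read_labels()] schema.
#' @return List with `accuracy_state`, `accuracy_snore`, `n_truth`,
#'   `n_detected`, `matched` (truth rows with a match), and `events`
#'   (data.frame of truth events with the detected class).
#' @export
evaluate_against_truth <- function(fit, truth) {
  stopifnot(inherits(fit, "sleep_monitor"))
  truth <- validate_labels(truth)
  det <- fit$cycles
  n_t <- nrow(truth)
  match_idx <- rep(NA_integer_, n_t)
  for (i in seq_len(n_t)) {
    ov <- pmin(det$end_s, truth$end_s[i]) - pmax(det$start_s, truth$start_s[i])
    if (length(ov) > 0L && max(ov) > 0) match_idx[i] <- which.max(ov)
  }
  ok <- !is.na(match_idx)
  state_ok <- ok & det$state[match_idx] == truth$state
  snore_ok <- ok & det$snore[match_idx] == truth$snore

  ev_rows <- which(truth$event != "none")
  events <- data.frame(
    truth_event = truth$event[ev_rows],
    detected_event = ifelse(is.na(match_idx[ev_rows]), "unmatched",
                            det$event[match_idx[ev_rows]]),
    stringsAsFactors = FALSE
  )
  list(
    accuracy_state = mean(state_ok),
    accuracy_snore = mean(snore_ok),
    n_truth = n_t,
    n_detected = nrow(det),
    matched = sum(ok),
    events = events
  )
}

#' @export
print.sleep_monitor <- function(x, ...) {
  cat(sprintf("<sleep_monitor> %.1f min of audio @ %g Hz\n",
              x$n_samples / x$fs / 60, x$fs))
  cat(sprintf("  %d cycles: %d normal, %d abnormal, %d with snore\n",
              nrow(x$cycles), sum(x$cycles$state == "normal"),
              sum(x$cycles$state == "abnormal"), sum(x$cycles$snore)))
  cat(sprintf("  events: %d apnea, %d hypopnea | R_sleep = %.1f %%\n",
              x$report$apnea_count, x$report$hypopnea_count,
              100 * x$report$R_sleep))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  vs truth: state accuracy %.3f, snore accuracy %.3f\n",
                x$accuracy$accuracy_state, x$accuracy$accuracy_snore))
  }
  invisible(x)
}

#' @export
summary.sleep_monitor <- function(object, ...) {
  print(object$report)
  invisible(object$report)
}

#' @export
as.data.frame.sleep_monitor <- function(x, ...) x$cycles

#' Plot a monitored night
#'
#' Draws the smoothed signal envelope with the detected cycles shaded by
#' state (normal grey, abnormal red, snore hatched blue baseline) and the
#' called apnea/hypopnea stops marked.
#'
#' @param x A `sleep_monitor`.
#' @param signal Optional [audio_signal()] to draw the envelope from (the
#'   fit does not keep the audio).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sleep_monitor <- function(x, signal = NULL, ...) {
  cyc <- x$cycles
  if (!is.null(signal)) {
    signal <- as_audio_signal(signal)
    hop <- max(1L, as.integer(round(signal$fs / 50)))
    env <- smoothed_envelope(signal$samples, signal$fs)
    idx <- seq(1L, length(env), by = hop)
    graphics::plot(idx / signal$fs, env[idx], type = "l", col = "grey40",
                   xlab = "time (s)", ylab = "envelope", ...)
  } else {
    graphics::plot(NA, xlim = c(0, x$n_samples / x$fs), ylim = c(0, 1),
                   xlab = "time (s)", ylab = "", yaxt = "n", ...)
  }
  usr <- graphics::par("usr")
  for (i in seq_len(nrow(cyc))) {
    col <- if (cyc$state[i] == "abnormal") grDevices::adjustcolor("red", 0.25)
           else grDevices::adjustcolor("grey", 0.3)
    graphics::rect(cyc$start_s[i], usr[3], cyc$end_s[i], usr[4],
                   col = col, border = NA)
    if (cyc$snore[i] == 1L) {
      graphics::segments(cyc$start_s[i], usr[3], cyc$end_s[i], usr[3],
                         col = "blue", lwd = 3)
    }
  }
  ev <- x$report$events
  ev <- ev[ev$event != "none", , drop = FALSE]
  if (nrow(ev) > 0L) {
    graphics::abline(v = (ev$start_s + ev$end_s) / 2,
                     col = ifelse(ev$event == "apnea", "darkred", "orange"),
                     lty = 2)
  }
  invisible(x)
}

#' Export a monitoring report as JSON
#'
#' @param fit A `sleep_monitor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(fit, path) {
  stopifnot(inherits(fit, "sleep_monitor"))
  rep <- fit$report
  payload <- list(
    T_monitoring_h = rep$T_monitoring, T_normal_h = rep$T_normal,
    T_abnormal_h = rep$T_abnormal, T_snore_h = rep$T_snore,
    R_sleep = rep$R_sleep, cycle_count = rep$cycle_count,
    apnea_count = rep$apnea_count, hypopnea_count = rep$hypopnea_count
  )
  if (!is.null(fit$accuracy)) {
    payload$accuracy_state <- fit$accuracy$accuracy_state
    payload$accuracy_snore <- fit$accuracy$accuracy_snore
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
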