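#' MsL label sets for snore / normal / abnormal components
#'
#' The low-frequency set `FL` flags the snore component, the mid set `FM`
#' the normal breathing component, and the high set `FH` the abnormal
#' component. The defaults are the common partition found to work across
#' individuals: label 2 for snore, labels 4-7 for normal breathing and
#' labels 15-17 for abnormal breathing.
#'
#' @param FL,FM,FH Integer label sets; must be pairwise disjoint and within
#'   `1..n_labels`.
#' @param n_labels Number of Mel labels (default 20).
#' @return List of class `msl_sets`.
#' @export
msl_sets <- function(FL = 2L, FM = 4:7, FH = 15:17, n_labels = 20L) {
  FL <- as.integer(FL); FM <- as.integer(FM); FH <- as.integer(FH)
  all_labels <- c(FL, FM, FH)
  if (any(all_labels < 1L | all_labels > n_labels)) {
    stop("label sets must lie in 1..", n_labels, call. = FALSE)
  }
  if (anyDuplicated(all_labels)) {
    stop("FL, FM and FH must be pairwise disjoint", call. = FALSE)
  }
  structure(list(FL = FL, FM = FM, FH = FH, n_labels = n_labels),
            class = "msl_sets")
}

#' Threshold configuration for the symbolization rules
#'
#' Thresholds are fractions of a reference active-phase frame count: with
#' the default `ref_frames = 50` (an inspiration/expiration phase of about
#' 2.5 s), the FM and FH thresholds are 40% (about 20 frames) and the FL
#' threshold is 20% (about 10 frames).
#'
#' @param frac_FM,frac_FH,frac_FL Threshold fractions in (0, 1].
#' @param ref_frames Reference frame count (default 50).
#' @return List of class `threshold_config` with the fractions, `ref_frames`
#'   and the resolved per-set thresholds `theta_FM`, `theta_FH`, `theta_FL`.
#' @export
threshold_config <- function(frac_FM = 0.4, frac_FH = 0.4, frac_FL = 0.2,
                             ref_frames = 50L) {
  fr <- c(frac_FM, frac_FH, frac_FL)
  if (any(fr <= 0 | fr > 1)) stop("fractions must lie in (0, 1]", call. = FALSE)
  if (ref_frames < 1L) stop("`ref_frames` must be >= 1", call. = FALSE)
  structure(
    list(frac_FM = frac_FM, frac_FH = frac_FH, frac_FL = frac_FL,
         ref_frames = ref_frames,
         theta_FM = frac_FM * ref_frames,
         theta_FH = frac_FH * ref_frames,
         theta_FL = frac_FL * ref_frames),
    class = "threshold_config"
  )
}

#' Symbolize one cycle's MsL histogram against the set thresholds
#'
#' A set's symbol is 1 if and only if any single label of the set occurs
#' strictly more often than the set's threshold ("larger than the red
#' threshold line"); a count exactly equal to the threshold does not fire.
#'
#' @param hist An [msl_histogram()] for one cycle.
#' @param sets An [msl_sets()].
#' @param thr A [threshold_config()].
#' @return Named integer vector `c(fl, fm, fh)`, each 0 or 1.
#' @export
symbolize <- function(hist, sets = msl_sets(), thr = threshold_config()) {
  stopifnot(inherits(hist, "msl_histogram"))
  fires <- function(labels, theta) as.integer(any(hist$counts[labels] > theta))
  c(fl = fires(sets$FL, thr$theta_FL),
    fm = fires(sets$FM, thr$theta_FM),
    fh = fires(sets$FH, thr$theta_FH))
}

#' Classify one cycle from its FL/FM/FH symbols
#'
#' The breathing state is abnormal exactly when the high-frequency set
#' fires (`fh = 1`); otherwise it is normal, including the quiet all-zero
#' case. The cycle is breathing-with-snore exactly when the low-frequency
#' set fires (`fl = 1`); abnormal cycles frequently carry the snore
#' component as well. The mid symbol `fm` is retained for reporting (a
#' heavy-breathing indicator) but does not enter the state rule.
#'
#' @param symbols Named vector from [symbolize()].
#' @return List of class `cycle_label` with `fl_sym`, `fm_sym`, `fh_sym`,
#'   `state` ("normal"/"abnormal") and `snore` (logical).
#' @export
classify_cycle <- function(symbols) {
  structure(
    list(
      fl_sym = as.integer(symbols[["fl"]]),
      fm_sym = as.integer(symbols[["fm"]]),
      fh_sym = as.integer(symbols[["fh"]]),
      state = if (symbols[["fh"]] == 1L) "abnormal" else "normal",
      snore = symbols[["fl"]] == 1L
    ),
    class = "cycle_label"
  )
}

#' Classify a breathing stop by its duration
#'
#' Apnea is a breathing stop of more than 10 s; a typical hypopnea is a
#' breathing stop of 6 to 10 s (closed interval, so gaps of exactly 6 s or
#' 10 s count as hypopnea); anything shorter is an ordinary inter-breath
#' pause.
#'
#' @param gap_s Breathing-stop duration in seconds (vectorized,
#'   nonnegative).
#' @return Character vector in `{"none", "hypopnea", "apnea"}`.
#' @export
classify_pause <- function(gap_s) {
  if (any(gap_s < 0)) stop("gap duration must be nonnegative", call. = FALSE)
  ifelse(gap_s > 10, "apnea", ifelse(gap_s >= 6, "hypopnea", "none"))
}

#' Night-level sleep quality ratio R_Sleep
#'
#' `R_Sleep = T_Normal / T_Monitoring`: the fraction of the monitored time
#' spent in the normal breathing state.
#'
#' @param T_normal Total normal-breathing duration (same unit as
#'   `T_monitoring`).
#' @param T_monitoring Total monitoring duration (> 0).
#' @return The ratio as a fraction in \[0, 1\].
#' @export
compute_rsleep <- function(T_normal, T_monitoring) {
  if (any(T_monitoring <= 0)) stop("monitoring time must be positive", call. = FALSE)
  if (any(T_normal < 0) || any(T_normal > T_monitoring)) {
    stop("need 0 <= T_normal <= T_monitoring", call. = FALSE)
  }
  T_normal / T_monitoring
}

#' Summarise per-cycle labels into a night-level monitoring report
#'
#' Each pause is attributed to the state of the preceding cycle, so the
#' per-state durations add up to the monitored time minus any leading
#' silence. Breathing-stop events are called by [classify_pause()] on the
#' interior pause durations.
#'
#' @param labels List of `cycle_label`s, aligned 1:1 with `seg$cycles`.
#' @param seg A `segmentation`.
#' @param edge_correction Passed to [pause_durations()].
#' @return List of class `monitoring_report` with fields `T_monitoring`,
#'   `T_normal`, `T_abnormal`, `T_snore` (hours), `R_sleep` (fraction),
#'   `cycle_count`, `apnea_count`, `hypopnea_count`, and `events` (the
#'   interior pause table with the called event class).
#' @export
summarize_night <- function(labels, seg, edge_correction = -0.12) {
  stopifnot(inherits(seg, "segmentation"))
  n <- nrow(seg$cycles)
  if (length(labels) != n) {
    stop("labels (", length(labels), ") and cycles (", n, ") are misaligned",
         call. = FALSE)
  }
  T_monitoring <- seg$n_samples / seg$fs
  state <- vapply(labels, function(l) l$state, character(1))
  snore <- vapply(labels, function(l) l$snore, logical(1))

  if (n > 0L) {
    # span of cycle k = cycle plus the pause up to the next cycle (or the end)
    next_start <- c(seg$cycles$start_idx[-1L], seg$n_samples)
    span_s <- (next_start - seg$cycles$start_idx) / seg$fs
    cycle_s <- (seg$cycles$end_idx - seg$cycles$start_idx) / seg$fs
    T_normal <- sum(span_s[state == "normal"]) / 3600
    T_abnormal <- sum(span_s[state == "abnormal"]) / 3600
    T_snore <- sum(cycle_s[snore]) / 3600
  } else {
    T_normal <- T_abnormal <- T_snore <- 0
  }

  events <- pause_durations(seg, edge_correction)
  events$event <- if (nrow(events) > 0L) classify_pause(events$gap_s) else character(0)

  structure(
    list(
      T_monitoring = T_monitoring / 3600,
      T_normal = T_normal,
      T_abnormal = T_abnormal,
      T_snore = T_snore,
      R_sleep = if (T_monitoring > 0) T_normal / (T_monitoring / 3600) else NA_real_,
      cycle_count = n,
      apnea_count = sum(events$event == "apnea"),
      hypopnea_count = sum(events$event == "hypopnea"),
      events = events
    ),
    class = "monitoring_report"
  )
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat("Night-level breathing monitoring report\n")
  cat(sprintf("  monitored        %6.2f h\n", x$T_monitoring))
  cat(sprintf("  normal breathing %6.2f h\n", x$T_normal))
  cat(sprintf("  abnormal         %6.2f h\n", x$T_abnormal))
  cat(sprintf("  snoring          %6.2f h\n", x$T_snore))
  cat(sprintf("  R_sleep          %6.1f %%\n", 100 * x$R_sleep))
  cat(sprintf("  cycles %d | apnea events %d | hypopnea events %d\n",
              x$cycle_count, x$apnea_count, x$hypopnea_count))
  invisible(x)
}

#' Score predicted cycle labels against aligned ground truth
#'
#' @param predicted,truth Equal-length lists of `cycle_label`s (or data
#'   frames with `state` and `snore` columns), aligned cycle by cycle.
#' @return Named numeric vector `c(accuracy_state, accuracy_snore)`.
#' @export
score_against_truth <- function(predicted, truth) {
  p <- labels_to_frame(predicted)
  t <- labels_to_frame(truth)
  if (nrow(p) != nrow(t)) {
    stop("predicted (", nrow(p), ") and truth (", nrow(t),
         ") have different lengths", call. = FALSE)
  }
  c(accuracy_state = mean(p$state == t$state),
    accuracy_snore = mean(p$snore == t$snore))
}

labels_to_frame <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("state", "snore") %in% names(x)))
    return(data.frame(state = as.character(x$state),
                      snore = as.logical(as.integer(x$snore))))
  }
  data.frame(
    state = vapply(x, function(l) l$state, character(1)),
    snore = vapply(x, function(l) l$snore, logical(1))
  )
}
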