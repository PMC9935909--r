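#' Segment a night of breathing audio into cycles and pauses
#'
#' Implements extrema-based cycle segmentation on the moment waveforms:
#' \enumerate{
#'   \item find the local minimum sequence `C_min` of the CMW (burst centres)
#'     with a minimum separation of `min_cycle_s`;
#'   \item within a window of half-width `l_s` centred on each `C_min` point,
#'     locate the TCW local maximum, giving the burst-peak sequence `T_max`;
#'   \item take CMW local maxima as candidate cycle boundaries and shift each
#'     to the quietest point (TCW valley) between the adjacent `T_max`
#'     points.
#' }
#' Consecutive adjusted boundaries delimit per-breath segments. Within each
#' segment the active phase (the cycle proper) is the contiguous region
#' around the TCW peak where the TCW stays above `active_frac` of the
#' segment peak; everything between consecutive active phases is a pause.
#'
#' @param mw A [moment_waveforms()] object.
#' @param min_cycle_s Shortest plausible breathing cycle in seconds (default
#'   1.5); used as the minimum separation for extrema detection and as the
#'   minimum cycle duration.
#' @param active_frac Peak-relative floor of the active-phase threshold
#'   (default 0.01). The effective threshold of a segment is
#'   `max(3 x background TCW, active_frac x segment peak)`, where the
#'   background level is the 10th percentile of the TCW over the recording;
#'   this keeps the active phase intact when one lobe of a cycle is much
#'   louder than the other, while still rejecting the noise floor.
#' @return An object of class `segmentation`: list with
#'   `cycles` (data.frame `start_idx`, `end_idx`, half-open sample
#'   intervals), `pauses` (data.frame `start_idx`, `end_idx`), `fs` (sample
#'   rate of the indices), `extrema` (list with `c_min`, `t_max`,
#'   `boundaries`, in grid indices) and the segmentation parameters.
#' @export
find_cycle_boundaries <- function(mw, min_cycle_s = 1.5, active_frac = 0.01) {
  stopifnot(inherits(mw, "moment_waveforms"))
  # extrema and active-phase detection run on a 10 ms grid: breathing
  # structure lives at the second scale, and this keeps the search O(n/100)
  ahop <- max(1L, as.integer(round(0.01 * mw$fs)))
  fs_g <- mw$fs / ahop
  tcw <- mw$tcw[seq(1L, length(mw$tcw), by = ahop)]
  cmw <- mw$cmw[seq(1L, length(mw$cmw), by = ahop)]
  n <- length(tcw)
  sep <- max(2L, as.integer(round(min_cycle_s * fs_g)))
  lw <- max(1L, as.integer(round(mw$l_s * fs_g)))

  c_min <- local_extrema_min_sep(cmw, sep, "min")
  t_max <- integer(0)
  for (c0 in c_min) {
    win <- max(1L, c0 - lw):min(n, c0 + lw)
    t_max <- c(t_max, win[which.max(tcw[win])])
  }
  t_max <- sort(unique(t_max))
  # peaks closer than one minimum cycle belong to the same burst (e.g. the
  # inspiration and expiration lobes): keep only the stronger of each pair,
  # so no boundary can be placed in a mid-cycle dip between them
  if (length(t_max) > 1L) {
    ord <- t_max[order(tcw[t_max], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (length(kept) == 0L || all(abs(kept - p) >= sep)) kept <- c(kept, p)
    }
    t_max <- sort(kept)
  }

  cand <- local_extrema_min_sep(cmw, sep, "max")
  boundaries <- integer(0)
  if (length(t_max) >= 1L && length(cand) >= 1L) {
    fence <- c(1L, t_max, n)
    for (b in cand) {
      k <- findInterval(b, fence, rightmost.closed = TRUE)
      lo <- fence[k]
      hi <- fence[min(k + 1L, length(fence))]
      if (hi - lo < 2L) next
      win <- lo:hi
      boundaries <- c(boundaries, win[which.min(tcw[win])])
    }
  }
  boundaries <- sort(unique(boundaries))

  few <- length(boundaries) < 2L
  if (few) {
    warning("fewer than 2 cycle boundaries found; returning a single-cycle result")
  }
  seg_edges <- unique(c(1L, boundaries, n + 1L))

  cycles <- list()
  n_full <- length(mw$tcw)
  min_len <- as.integer(round(min_cycle_s * mw$fs))
  bg <- stats::quantile(tcw, 0.1, names = FALSE)   # background (pause) TCW level
  for (k in seq_len(length(seg_edges) - 1L)) {
    lo <- seg_edges[k]
    hi <- seg_edges[k + 1L] - 1L
    if (hi - lo + 1L < 3L) next
    win <- lo:hi
    pk <- win[which.max(tcw[win])]
    if (tcw[pk] <= 0 || tcw[pk] <= 5 * bg) next    # noise-only segment
    thr <- max(3 * bg, active_frac * tcw[pk])
    above <- tcw[win] >= thr
    # contiguous run containing the peak
    pk_rel <- pk - lo + 1L
    a0 <- pk_rel
    while (a0 > 1L && above[a0 - 1L]) a0 <- a0 - 1L
    a1 <- pk_rel
    while (a1 < length(above) && above[a1 + 1L]) a1 <- a1 + 1L
    # segment bounds and coarse active edges on the full waveform grid
    lo_f <- (lo - 1L) * ahop + 1L
    hi_f <- min(n_full, hi * ahop)
    start <- (lo + a0 - 2L) * ahop + 1L
    end <- min(n_full, (lo + a1 - 1L) * ahop)
    # refine each edge at full resolution against a fraction of the local
    # lobe peak: a level crossing relative to the nearest lobe is invariant
    # to how loud that lobe is, so edge positions (and hence measured pause
    # durations) carry the same small bias for faint and loud breaths alike
    mid <- (start + end) %/% 2L
    half_win <- as.integer(round(0.5 * mw$fs))
    pk_s <- max(mw$tcw[start:min(end, start + half_win)])
    pk_e <- max(mw$tcw[max(start, end - half_win):end])
    floor_edge <- if (bg > 0) 3 * bg else 0
    thr_s <- max(0.05 * pk_s, floor_edge)
    thr_e <- max(0.05 * pk_e, floor_edge)
    ws <- max(lo_f, start - 4L * ahop):mid
    cross <- which(mw$tcw[ws] >= thr_s)
    if (length(cross) > 0L) start <- ws[cross[1L]]
    we <- mid:min(hi_f, end + 4L * ahop)
    cross <- which(mw$tcw[we] >= thr_e)
    if (length(cross) > 0L) end <- we[cross[length(cross)]]
    # enforce the minimum cycle duration by symmetric expansion within the segment
    short <- min_len - (end - start + 1L)
    if (short > 0L) {
      start <- max(lo_f, start - short %/% 2L - short %% 2L)
      end <- min(hi_f, end + short %/% 2L)
      short <- min_len - (end - start + 1L)
      if (short > 0L) {
        start <- max(lo_f, start - short)
        end <- min(hi_f, end + (min_len - (end - start + 1L)))
      }
    }
    if (end - start + 1L < min_len) next
    cycles[[length(cycles) + 1L]] <- c(start, end)
  }

  cycles_df <- grid_cycles_to_samples(cycles, hop = mw$hop,
                                      n_samples = mw$n_samples)
  structure(
    list(
      cycles = cycles_df,
      pauses = pauses_from_cycles(cycles_df, mw$n_samples),
      fs = mw$source_fs,
      n_samples = mw$n_samples,
      extrema = list(c_min = c_min, t_max = t_max, boundaries = boundaries),
      min_cycle_s = min_cycle_s,
      active_frac = active_frac,
      delta_s = mw$delta_s,
      l_s = mw$l_s
    ),
    class = "segmentation"
  )
}

# Convert grid-index [start, end] (closed) cycle pairs to half-open sample
# intervals on the source grid.
grid_cycles_to_samples <- function(cycles, hop, n_samples) {
  if (length(cycles) == 0L) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  m <- do.call(rbind, cycles)
  start <- (m[, 1] - 1L) * hop
  end <- m[, 2] * hop
  data.frame(start_idx = as.integer(start), end_idx = as.integer(pmin(end, n_samples)))
}

pauses_from_cycles <- function(cycles_df, n_samples) {
  edges_lo <- c(0L, cycles_df$end_idx)
  edges_hi <- c(cycles_df$start_idx, n_samples)
  keep <- edges_hi > edges_lo
  data.frame(start_idx = edges_lo[keep], end_idx = edges_hi[keep])
}

#' Merge spuriously segmented weak "cycles" into the surrounding pause
#'
#' Long breathing stops are noise-only, yet the extrema search can still cut
#' faint "cycles" out of them. A segmented cycle whose peak envelope
#' amplitude (rectified signal smoothed over 50 ms) is below
#' `alpha` x the mean of the per-cycle peak envelope amplitudes is not a real
#' breath: it is removed and its span rejoins the adjacent pause.
#'
#' @param result A `segmentation` from [find_cycle_boundaries()].
#' @param signal The [audio_signal()] the segmentation came from.
#' @param alpha Amplitude-threshold fraction (default 0.2); `alpha = 0`
#'   disables merging.
#' @return A `segmentation` with weak cycles removed and pauses recomputed.
#' @export
merge_weak_pauses <- function(result, signal, alpha = 0.2) {
  stopifnot(inherits(result, "segmentation"))
  signal <- as_audio_signal(signal)
  if (alpha <= 0 || nrow(result$cycles) == 0L) return(result)
  env <- smoothed_envelope(signal$samples, signal$fs)
  peaks <- vapply(seq_len(nrow(result$cycles)), function(i) {
    max(env[(result$cycles$start_idx[i] + 1L):result$cycles$end_idx[i]])
  }, numeric(1))
  # reference level: mean of the clearly-active peaks (>= half the largest),
  # so noise-only "cycles" cannot drag the reference down with them
  ref <- mean(peaks[peaks >= 0.5 * max(peaks)])
  keep <- peaks >= alpha * ref
  result$cycles <- result$cycles[keep, , drop = FALSE]
  rownames(result$cycles) <- NULL
  result$pauses <- pauses_from_cycles(result$cycles, result$n_samples)
  result
}

#' Segment a breathing recording (one-call wrapper)
#'
#' Runs [moment_waveforms()], [find_cycle_boundaries()] and
#' [merge_weak_pauses()] with one set of parameters.
#'
#' @param signal An [audio_signal()].
#' @param delta_s,l_s Moment-waveform windows, see [moment_waveforms()].
#' @param min_cycle_s,active_frac See [find_cycle_boundaries()].
#' @param alpha See [merge_weak_pauses()].
#' @return A `segmentation` object.
#' @export
segment_cycles <- function(signal, delta_s = 0.1, l_s = 2, min_cycle_s = 1.5,
                           active_frac = 0.01, alpha = 0.2) {
  signal <- as_audio_signal(signal)
  mw <- moment_waveforms(signal, delta_s = delta_s, l_s = l_s)
  seg <- find_cycle_boundaries(mw, min_cycle_s = min_cycle_s,
                               active_frac = active_frac)
  merge_weak_pauses(seg, signal, alpha = alpha)
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation> %d cycles, %d pauses over %.1f s @ %g Hz\n",
    nrow(x$cycles), nrow(x$pauses), x$n_samples / x$fs, x$fs
  ))
  invisible(x)
}

#' Durations of the segmented pauses in seconds
#'
#' Only pauses lying between two cycles count as breathing stops; leading and
#' trailing silence of the recording is not a breathing stop. The TCW is a
#' `2 * delta_s` moving window, so its threshold crossings land a fixed small
#' offset outside the true burst edges; the raw gap is compensated by
#' `2 * edge_correction * delta_s` to remove that systematic bias.
#'
#' @param seg A `segmentation`.
#' @param edge_correction Fraction of `delta_s` by which each threshold
#'   crossing overshoots into the pause (default -0.12, calibrated on clean
#'   synthetic bursts; the negative sign means the detected active phase
#'   slightly overcovers the burst, so time is added back to the gap).
#' @return Data frame with `start_s`, `end_s`, `gap_s` for the interior
#'   pauses, in recording order.
#' @export
pause_durations <- function(seg, edge_correction = -0.12) {
  stopifnot(inherits(seg, "segmentation"))
  p <- seg$pauses
  if (nrow(seg$cycles) > 0L) {
    interior <- p$start_idx >= min(seg$cycles$end_idx) &
      p$end_idx <= max(seg$cycles$start_idx)
    p <- p[interior, , drop = FALSE]
  }
  corr <- 2 * edge_correction * seg$delta_s
  data.frame(
    start_s = p$start_idx / seg$fs,
    end_s = p$end_idx / seg$fs,
    gap_s = pmax(0, (p$end_idx - p$start_idx) / seg$fs - corr)
  )
}
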