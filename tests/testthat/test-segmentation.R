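test_that("periodic breathing at 4 s period over 60 s yields 15 +/- 1 cycles", {
  x <- burst_train(seq(1, 57, by = 4), duration_s = 2.5, total_s = 61, seed = 7)
  seg <- segment_cycles(x)
  expect_gte(nrow(seg$cycles), 14)
  expect_lte(nrow(seg$cycles), 16)
})

test_that("pure silence yields at most one cycle and does not crash", {
  x <- audio_signal(numeric(20 * FS), FS)
  seg <- suppressWarnings(segment_cycles(x))
  expect_lte(nrow(seg$cycles), 1)
})

test_that("two bursts separated by 12 s give 2 cycles and a 12 s pause", {
  x <- burst_train(c(2, 2 + 2.5 + 12), total_s = 21, seed = 3)
  seg <- segment_cycles(x)
  expect_equal(nrow(seg$cycles), 2)
  pd <- pause_durations(seg)
  expect_equal(nrow(pd), 1)
  expect_equal(pd$gap_s, 12, tolerance = 0.5 / 12)
})

test_that("pause duration measurement is unbiased on fresh fixtures", {
  errs <- vapply(1:8, function(s) {
    set.seed(300 + s)
    g <- runif(1, 5, 13)
    x <- burst_train(c(2, 2 + 2.5 + g), total_s = 10 + g, seed = 300 + s)
    pd <- pause_durations(segment_cycles(x))
    pd$gap_s[1] - g
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  expect_lt(max(abs(errs)), 0.1)
})

test_that("cycles are sorted, non-overlapping and at least min_cycle_s long", {
  for (s in 1:3) {
    x <- burst_train(cumsum(runif(8, 3.5, 5)), total_s = 45, seed = 40 + s)
    seg <- segment_cycles(x)
    cyc <- seg$cycles
    expect_true(all(diff(cyc$start_idx) > 0))
    expect_true(all(cyc$end_idx > cyc$start_idx))
    if (nrow(cyc) > 1) {
      expect_true(all(cyc$start_idx[-1] >= cyc$end_idx[-nrow(cyc)]))
    }
    expect_true(all((cyc$end_idx - cyc$start_idx) / seg$fs >= 1.5 - 1e-6))
    # every pause lies between cycles or at the recording edges
    expect_true(all(seg$pauses$end_idx > seg$pauses$start_idx))
  }
})

test_that("shifting the signal shifts all boundaries accordingly", {
  x <- burst_train(c(3, 7, 11), total_s = 17, seed = 9)
  shift_s <- 0.5
  k <- round(shift_s * FS)
  y <- audio_signal(c(numeric(k), x$samples[1:(length(x$samples) - k)]), FS)
  seg_x <- segment_cycles(x)
  seg_y <- segment_cycles(y)
  expect_equal(nrow(seg_y$cycles), nrow(seg_x$cycles))
  # interior boundaries move by the shift, to within the 10 ms analysis hop
  expect_equal(seg_y$cycles$start_idx, seg_x$cycles$start_idx + k,
               tolerance = 0.02 * FS)
})

test_that("merge_weak_pauses removes a faint noise blip between real breaths", {
  set.seed(5)
  fs <- FS
  blip <- 0.005 * two_lobe_burst(1.6, level = 1, fs = fs)  # 5 % of breath level
  x <- numeric(20 * fs)
  for (t0 in c(2, 15)) {
    b <- two_lobe_burst(2.5, 0.1, fs)
    x[(round(t0 * fs) + 1):(round(t0 * fs) + length(b))] <- b
  }
  x[(9 * fs + 1):(9 * fs + length(blip))] <- blip
  sig <- audio_signal(x + rnorm(length(x), sd = 1e-3), fs)

  mw <- moment_waveforms(sig)
  seg <- find_cycle_boundaries(mw)
  merged <- merge_weak_pauses(seg, sig, alpha = 0.2)
  expect_lt(nrow(merged$cycles), nrow(seg$cycles))
  expect_equal(nrow(merged$cycles), 2)
  # the blip's span rejoined the pause: one long pause between the breaths
  pd <- pause_durations(merged)
  expect_equal(nrow(pd), 1)
  expect_gt(pd$gap_s, 10)
})

test_that("merge_weak_pauses is a no-op for uniform cycles and alpha = 0", {
  x <- burst_train(c(2, 6, 10), total_s = 15, seed = 12)
  mw <- moment_waveforms(x)
  seg <- find_cycle_boundaries(mw)
  expect_identical(merge_weak_pauses(seg, x, alpha = 0), seg)
  merged <- merge_weak_pauses(seg, x, alpha = 0.2)
  expect_equal(merged$cycles, seg$cycles)
})

test_that("recovered cycle count is within 5 % of truth on generator output", {
  night <- gen_night(synthetic_config(n_cycles = 40, seed = 21))
  seg <- segment_cycles(night$audio)
  expect_gte(nrow(seg$cycles), 38)
  expect_lte(nrow(seg$cycles), 42)
})
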