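test_that("set and threshold constructors enforce their invariants", {
  s <- msl_sets()
  expect_equal(s$FL, 2L)
  expect_equal(s$FM, 4:7)
  expect_equal(s$FH, 15:17)
  expect_error(msl_sets(FL = 4L), "disjoint")
  expect_error(msl_sets(FL = 0L), "1..20")

  thr <- threshold_config()
  expect_equal(thr$theta_FM, 20)
  expect_equal(thr$theta_FH, 20)
  expect_equal(thr$theta_FL, 10)
  expect_error(threshold_config(frac_FM = 0), "\\(0, 1\\]")
})

test_that("symbolize fires on any set label strictly above its threshold", {
  mk <- function(counts) structure(list(counts = counts, total = sum(counts)),
                                   class = "msl_histogram")
  counts <- rep(0L, 20)
  counts[16] <- 25L
  expect_equal(symbolize(mk(counts)), c(fl = 0L, fm = 0L, fh = 1L))

  counts <- rep(0L, 20)
  counts[2] <- 10L                      # exactly at theta_FL = 10
  expect_equal(symbolize(mk(counts))[["fl"]], 0L)
  counts[2] <- 11L
  expect_equal(symbolize(mk(counts))[["fl"]], 1L)

  expect_equal(symbolize(mk(rep(0L, 20))), c(fl = 0L, fm = 0L, fh = 0L))
})

test_that("classify_cycle follows the FH/FL rules", {
  ab_sn <- classify_cycle(c(fl = 1L, fm = 0L, fh = 1L))
  expect_equal(ab_sn$state, "abnormal")
  expect_true(ab_sn$snore)

  norm <- classify_cycle(c(fl = 0L, fm = 1L, fh = 0L))
  expect_equal(norm$state, "normal")
  expect_false(norm$snore)

  quiet <- classify_cycle(c(fl = 0L, fm = 0L, fh = 0L))
  expect_equal(quiet$state, "normal")
  expect_false(quiet$snore)
})

test_that("classify_pause uses > 10 s for apnea and [6, 10] s for hypopnea", {
  expect_equal(classify_pause(12), "apnea")
  expect_equal(classify_pause(8), "hypopnea")
  expect_equal(classify_pause(3), "none")
  # boundary convention: 6.0 and 10.0 are hypopnea; just above 10 is apnea
  expect_equal(classify_pause(c(6, 10, 10.0001, 5.9999)),
               c("hypopnea", "hypopnea", "apnea", "none"))
  expect_error(classify_pause(-1), "nonnegative")
})

test_that("compute_rsleep reproduces the worked-example ratios", {
  expect_equal(round(100 * compute_rsleep(6, 7.7), 1), 77.9)
  expect_equal(round(100 * compute_rsleep(2.3, 6.8), 1), 33.8)
  expect_equal(100 * compute_rsleep(2.8, 5), 56)
  expect_equal(compute_rsleep(0, 5), 0)
  expect_error(compute_rsleep(1, 0), "positive")
  expect_error(compute_rsleep(6, 5), "T_normal")
})

test_that("summarize_night aggregates durations, events and R_sleep", {
  # deterministic fixture: 10 cycles of 4 s (2.5 s active + 1.5 s gap)
  fs <- 1000
  starts <- seq(1, by = 4, length.out = 10)
  cycles <- data.frame(start_idx = as.integer(starts * fs),
                       end_idx = as.integer((starts + 2.5) * fs))
  seg <- structure(
    list(cycles = cycles,
         pauses = melbreath:::pauses_from_cycles(cycles, 42 * fs),
         fs = fs, n_samples = 42 * fs, delta_s = 0.1, l_s = 2),
    class = "segmentation"
  )
  sym <- function(fh, fl = 0L) classify_cycle(c(fl = fl, fm = 0L, fh = fh))
  labels <- c(lapply(1:6, function(i) sym(0L)),    # 6 normal
              lapply(1:4, function(i) sym(1L, 1L)))  # 4 abnormal with snore

  rep <- summarize_night(labels, seg, edge_correction = 0)
  expect_equal(rep$cycle_count, 10)
  expect_equal(rep$T_monitoring, 42 / 3600)
  # per-state spans: cycle + following pause = 4 s each; last cycle spans to end
  expect_equal(rep$T_normal * 3600, 6 * 4)
  expect_equal(rep$T_abnormal * 3600, 4 * 4 + (42 - (37 + 4)))
  expect_equal(rep$T_snore * 3600, 4 * 2.5)
  expect_equal(rep$R_sleep, (6 * 4) / 42)
  expect_lte(rep$T_normal + rep$T_abnormal, rep$T_monitoring + 1e-12)
  expect_equal(rep$apnea_count, 0)
  expect_equal(rep$hypopnea_count, 0)

  expect_error(summarize_night(labels[1:3], seg), "misaligned")
})

test_that("all-abnormal nights give R_sleep = 0", {
  fs <- 1000
  cycles <- data.frame(start_idx = c(1000L, 5000L), end_idx = c(3500L, 7500L))
  seg <- structure(
    list(cycles = cycles,
         pauses = melbreath:::pauses_from_cycles(cycles, 10000L),
         fs = fs, n_samples = 10000L, delta_s = 0.1, l_s = 2),
    class = "segmentation"
  )
  labels <- lapply(1:2, function(i) classify_cycle(c(fl = 0L, fm = 0L, fh = 1L)))
  rep <- summarize_night(labels, seg)
  expect_equal(rep$R_sleep, 0)
})

test_that("score_against_truth counts matching states and snore flags", {
  mk <- function(states, snores) {
    data.frame(state = states, snore = as.integer(snores))
  }
  a <- mk(rep(c("normal", "abnormal"), 5), rep(c(0, 1), 5))
  expect_equal(score_against_truth(a, a),
               c(accuracy_state = 1, accuracy_snore = 1))

  flipped <- mk(rev(a$state), a$snore)
  expect_equal(score_against_truth(flipped, a)[["accuracy_state"]], 0)

  b <- a
  b$state[1:3] <- ifelse(a$state[1:3] == "normal", "abnormal", "normal")
  expect_equal(score_against_truth(b, a)[["accuracy_state"]], 0.7)

  expect_error(score_against_truth(a, a[1:5, ]), "different lengths")
})
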