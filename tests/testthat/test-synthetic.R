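test_that("gen_breath_burst is band-limited with a raised-cosine envelope", {
  set.seed(1)
  x <- gen_breath_burst(1, band = c(500, 1500), level = 0.1, fs = FS)
  expect_equal(length(x), FS)
  expect_gte(power_fraction(x, FS, 500, 1500), 0.8)
  expect_length(gen_breath_burst(0, level = 0.1, fs = FS), 0)
  # linearity: doubling the level doubles the RMS
  set.seed(2)
  a <- gen_breath_burst(1, level = 0.1, fs = FS)
  set.seed(2)
  b <- gen_breath_burst(1, level = 0.2, fs = FS)
  expect_equal(sqrt(mean(b^2)) / sqrt(mean(a^2)), 2, tolerance = 0.05)
  expect_error(gen_breath_burst(1, band = c(1500, 500), fs = FS), "invalid band")
})

test_that("gen_snore_component concentrates power below 500 Hz at f0 harmonics", {
  set.seed(3)
  x <- gen_snore_component(2, f0_hz = 90, level = 0.1, fs = FS)
  expect_gte(power_fraction(x, FS, 0, 500), 0.7)

  set.seed(4)
  y <- gen_snore_component(4, f0_hz = 60, level = 0.1, fs = FS)
  n <- length(y)
  spec <- Mod(stats::fft(y))[seq_len(n %/% 2)]
  f <- (seq_len(n %/% 2) - 1) * FS / n
  # the three strongest spectral peaks sit on multiples of 60 Hz (within 2 Hz)
  ord <- order(spec, decreasing = TRUE)
  top <- f[ord[1:3]]
  expect_true(all(abs(top / 60 - round(top / 60)) * 60 < 2))

  expect_true(all(gen_snore_component(1, 90, level = 0, fs = FS) == 0))
  expect_error(gen_snore_component(1, f0_hz = 300, fs = FS), "below 250")
})

test_that("gen_abnormal_component has most power outside the 500-3500 mid band", {
  set.seed(5)
  x <- gen_abnormal_component(2, level = 0.1, fs = FS)
  out <- 1 - power_fraction(x, FS, 500, 3500)
  expect_gte(out, 0.6)
  # spectral energy extends above 3500 Hz
  expect_gt(power_fraction(x, FS, 3500, FS / 2), 0.1)
  # at equal RMS the mid-band fraction is far below a breathing burst's
  set.seed(6)
  b <- gen_breath_burst(2, level = 0.1, fs = FS)
  expect_lt(power_fraction(x, FS, 500, 3500), power_fraction(b, FS, 500, 3500))
  expect_length(gen_abnormal_component(0, fs = FS), 0)
})

test_that("gen_night is deterministic for a fixed seed", {
  cfg <- synthetic_config(n_cycles = 10, seed = 77)
  a <- gen_night(cfg)
  b <- gen_night(cfg)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_identical(a$truth, b$truth)
})

test_that("without event probabilities no truth gap exceeds 6 s", {
  cfg <- synthetic_config(n_cycles = 30, p_apnea = 0, p_hypopnea = 0, seed = 5)
  night <- gen_night(cfg)
  tr <- night$truth
  gaps <- tr$start_s[-1] - tr$end_s[-nrow(tr)]
  expect_true(all(gaps < 6))
  expect_true(all(tr$event == "none"))
})

test_that("snore-cycle fraction matches the configured probability", {
  fracs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_cycles = 100, p_snore = 0.2, p_abnormal = 0,
                            p_apnea = 0, p_hypopnea = 0, seed = 500 + s)
    mean(gen_night(cfg)$truth$snore)
  }, numeric(1))
  expect_gte(mean(fracs), 0.12)
  expect_lte(mean(fracs), 0.28)
})

test_that("generated audio stays within [-1, 1] and truth is consistent", {
  night <- gen_night(synthetic_config(n_cycles = 20, seed = 8))
  x <- night$audio
  expect_true(all(abs(x$samples) <= 1))
  tr <- night$truth
  expect_true(all(tr$end_s > tr$start_s))
  expect_true(all(tr$start_s[-1] >= tr$end_s[-nrow(tr)]))
  expect_lte(max(tr$end_s), duration(x))
  # active phases are at least 3x louder (RMS) than the adjacent gaps
  for (i in seq_len(nrow(tr) - 1)) {
    act <- x$samples[round(tr$start_s[i] * FS + 1):round(tr$end_s[i] * FS)]
    gap <- x$samples[round(tr$end_s[i] * FS + 1):round(tr$start_s[i + 1] * FS)]
    expect_gt(sqrt(mean(act^2)) / sqrt(mean(gap^2)), 3)
  }
  # truth table round-trips through the label schema
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(tr, path)
  expect_equal(read_labels(path), tr, tolerance = 1e-9)
})
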