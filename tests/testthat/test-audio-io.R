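test_that("audio_signal validates its fields", {
  x <- audio_signal(c(0, 0.5, -0.5), fs = 100)
  expect_s3_class(x, "audio_signal")
  expect_equal(duration(x), 0.03)
  expect_error(audio_signal(numeric(0), 100), "at least one")
  expect_error(audio_signal(c(0, NA), 100), "finite")
  expect_error(audio_signal(0, -1), "positive")
})

test_that("read_wav reads PCM files and scales by the 16-bit full scale", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_pcm16_raw(rep(0L, 44100), 44100, path)
  x <- read_wav(path)
  expect_equal(length(x$samples), 44100)
  expect_equal(x$fs, 44100)
  expect_true(all(x$samples == 0))

  # full-scale square wave: -32768 -> -1.0, +32767 -> +0.999969...
  write_pcm16_raw(rep(c(-32768L, 32767L), 50), 8000, path)
  sq <- read_wav(path)
  expect_equal(min(sq$samples), -1)
  expect_equal(max(sq$samples), 32767 / 32768, tolerance = 1e-12)
})

test_that("read_wav keeps the first channel of a stereo file", {
  path <- withr::local_tempfile(fileext = ".wav")
  left <- as.integer(round(1000 * sin(2 * pi * 5 * (0:99) / 100)))
  right <- rep(0L, 100)
  inter <- as.vector(rbind(left, right))
  write_pcm16_raw(inter, 8000, path, channels = 2L)
  x <- read_wav(path)
  expect_equal(length(x$samples), 100)
  expect_equal(x$samples, left / 32768, tolerance = 1e-12)
})

test_that("read_wav rejects missing and malformed files", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeLines("this is not audio and long enough to carry a header", bad)
  expect_error(read_wav(bad), "RIFF")
})

test_that("write_wav / read_wav round trip preserves 16-bit quantization", {
  path <- withr::local_tempfile(fileext = ".wav")
  set.seed(11)
  x <- audio_signal(runif(5000, -1, 1), fs = 11025)
  write_wav(x, path)
  y <- read_wav(path)
  expect_equal(y$fs, x$fs)
  expect_equal(y$samples, x$samples, tolerance = 1 / 32768)
  # a second round trip is exact (already quantized)
  write_wav(y, path)
  expect_identical(read_wav(path)$samples, y$samples)
})

test_that("downsample keeps length bookkeeping and tone content", {
  t <- (0:44099) / 44100
  x <- audio_signal(sin(2 * pi * 100 * t), fs = 44100)
  y <- downsample(x, 11025)
  expect_equal(y$fs, 11025)
  expect_equal(length(y$samples), 11025)
  expect_equal(dominant_freq(y$samples, y$fs), 100, tolerance = 2)
  # amplitude preserved within 1 % well below the cutoff
  expect_equal(max(abs(y$samples)), 1, tolerance = 0.01)
})

test_that("downsample anti-aliases above the new Nyquist", {
  t <- (0:(4 * 44100 - 1)) / 44100
  keep <- audio_signal(sin(2 * pi * 5000 * t), fs = 44100)
  kill <- audio_signal(sin(2 * pi * 6000 * t), fs = 44100)
  yk <- downsample(keep, 11025)
  ya <- downsample(kill, 11025)
  # the 5 kHz tone survives as the dominant component
  expect_equal(dominant_freq(yk$samples, 11025), 5000, tolerance = 10)
  # the 6 kHz tone (which would fold to 5025 Hz) is attenuated > 20 dB
  expect_lt(20 * log10(sqrt(mean(ya$samples^2)) / sqrt(0.5)), -20)
})

test_that("downsample requires an integer rate ratio and is idempotent", {
  x <- audio_signal(rnorm(44100), fs = 44100)
  expect_error(downsample(x, 16000), "integer multiple")
  y <- downsample(x, 11025)
  expect_identical(downsample(y, 11025), y)
})

test_that("equalize_amplitude normalizes level but leaves silence alone", {
  set.seed(4)
  fs <- 2000
  # uniform unit-RMS noise -> output RMS within 5 % of target everywhere
  x <- audio_signal(rnorm(10 * fs), fs)
  y <- equalize_amplitude(x, window_s = 2, target_rms = 0.1)
  mid <- y$samples[fs:(9 * fs)]
  expect_equal(sqrt(mean(mid^2)), 0.1, tolerance = 0.05)

  # faint and loud bursts end up at comparable level
  two <- audio_signal(c(0.05 * rnorm(4 * fs), 0.5 * rnorm(4 * fs)), fs)
  z <- equalize_amplitude(two, window_s = 1, target_rms = 0.1)
  r1 <- sqrt(mean(z$samples[fs:(3 * fs)]^2))
  r2 <- sqrt(mean(z$samples[(5 * fs):(7 * fs)]^2))
  expect_gt(r1 / r2, 0.8)
  expect_lt(r1 / r2, 1.25)

  # silence stays silent and output never exceeds full scale
  s <- audio_signal(numeric(fs), fs)
  expect_identical(equalize_amplitude(s)$samples, s$samples)
  expect_lte(max(abs(z$samples)), 1)
})

test_that("label CSV round trip is lossless and validation names bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- example_labels()
  write_labels(rec, path)
  expect_equal(read_labels(path), rec)

  bad <- rec
  bad$end_s[2] <- bad$start_s[2]
  expect_error(write_labels(bad, path), "row 2.*end_s")

  bad <- rec
  bad$state[3] <- "weird"
  expect_error(write_labels(bad, path), "row 3.*weird")

  bad <- rec
  bad$start_s[2] <- 2  # overlaps row 1 (ends at 3.4)
  expect_error(write_labels(bad, path), "overlap")
})
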