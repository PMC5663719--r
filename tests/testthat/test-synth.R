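test_that("harmonic stacks carry their programmed fundamental", {
  cfg <- synth_config()
  x <- synth_syllable(600, 100, cfg)
  tr <- yin_f0(x, cfg$sample_rate)
  v <- tr$f0_hz[tr$aperiodicity < 0.2]
  expect_gt(length(v), 50)
  expect_lt(abs(median(v) - 600), 0.5)
})

test_that("zero rolloff gives a pure sine", {
  cfg <- synth_config(harmonic_rolloff = 0)
  x <- synth_syllable(600, 100, cfg)
  w <- 0.5 * (1 - cos(2 * pi * seq_along(x) / length(x)))
  spec <- Mod(stats::fft(x * w))^2
  half <- spec[seq_len(length(x) / 2)]
  freqs <- (seq_along(half) - 1) * cfg$sample_rate / length(x)
  peak <- freqs[which.max(half)]
  expect_lt(abs(peak - 600), 15)
  # energy outside the fundamental's neighbourhood is negligible: no
  # harmonics above the fundamental survive a zero rolloff
  expect_lt(sum(half[abs(freqs - 600) > 100]) / sum(half), 1e-3)
})

test_that("partials above Nyquist are truncated with a warning", {
  cfg <- synth_config(sample_rate = 16000, n_harmonics = 10)
  expect_warning(x <- synth_syllable(3000, 50, cfg), "Nyquist")
  expect_true(all(is.finite(x)))
})

test_that("calls have an aperiodic onset followed by voiced frames", {
  cfg <- synth_config()
  x <- synth_call(600, 90, cfg)
  tr <- yin_f0(x, cfg$sample_rate)
  onset <- tr[tr$time_ms < cfg$onset_noise_ms - 5, ]
  body <- tr[tr$time_ms > cfg$onset_noise_ms + 10, ]
  expect_gt(mean(onset$aperiodicity >= 0.2), 0.8)
  expect_gt(mean(body$aperiodicity < 0.2), 0.8)
  expect_lt(abs(median_pitch(tr) - 600), 1)
})

test_that("a source-state truth yields source-ordered, source-pitched bouts", {
  t1 <- fixture_tasks$task1
  truth <- truth_at_state(t1, 3, "source")
  cfg <- synth_config(seed = 11, renditions_per_day = 10)
  st <- generate_rendition_stream(t1, truth, 3, cfg)
  # every bout is ABC repeated
  for (b in unique(st$bout_id)) {
    labs <- st$label[st$bout_id %in% b]
    expect_equal(labs, rep(c("A", "B", "C"), 2))
  }
  med <- median(semitone_offset(st$true_f0_hz[st$label == "C"], 600))
  expect_lt(abs(med - 0), 3 * 0.25 / sqrt(20))
})

test_that("a truth at the target intermediate reproduces pitch-first song", {
  # pitch already at target, grammar still at source: the learner sings the
  # source order with the shifted syllable (an intermediate never tutored)
  t1 <- fixture_tasks$task1
  truth <- truth_at_state(t1, 2, "source")
  truth$pitch[, "C"] <- 2
  cfg <- synth_config(seed = 2, renditions_per_day = 10)
  st <- generate_rendition_stream(t1, truth, 2, cfg)
  expect_equal(unique(st$label[st$position_in_bout %in% c(3, 6)]), "C")
  med <- median(semitone_offset(st$true_f0_hz[st$label == "C"], 600))
  expect_lt(abs(med - 2), 0.2)
})

test_that("streams are deterministic under a fixed seed", {
  t5 <- fixture_tasks$task5
  truth <- truth_at_state(t5, 2, "source", call_pitch = -3.5)
  cfg <- synth_config(seed = 42, renditions_per_day = 8)
  a <- generate_rendition_stream(t5, truth, 2, cfg)
  b <- generate_rendition_stream(t5, truth, 2, cfg)
  expect_identical(a, b)
})

test_that("datasets write byte-identical annotation CSVs under one seed", {
  t1 <- fixture_tasks$task1
  truth <- truth_at_state(t1, 2, "source")
  cfg <- synth_config(seed = 7, renditions_per_day = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a <- generate_dataset(t1, truth, 2, cfg, dir = d1)
  b <- generate_dataset(t1, truth, 2, cfg, dir = d2)
  expect_identical(readLines(a$csv), readLines(b$csv))
  expect_gte(nrow(a$annotations), 2 * 6)
})

test_that("an empty truth yields an empty dataset without error", {
  t1 <- fixture_tasks$task1
  truth <- truth_at_state(t1, 1, "source")
  d <- generate_dataset(t1, truth, 0, synth_config(seed = 1),
                        dir = withr::local_tempdir())
  expect_equal(nrow(d$annotations), 0)
  expect_true(file.exists(d$csv))
})

test_that("WAV files round-trip through the PCM16 reader", {
  x <- sin(2 * pi * 440 * (0:3199) / 32000) * 0.5
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 32000, p)
  back <- read_wav(p)
  expect_equal(back$sr, 32000)
  expect_equal(back$wave, x, tolerance = 1e-4)
})

test_that("audio datasets are consistent with their annotations", {
  t1 <- fixture_tasks$task1
  truth <- truth_at_state(t1, 1, "source")
  cfg <- synth_config(seed = 3, renditions_per_day = 4)
  ds <- generate_dataset(t1, truth, 1, cfg, audio = TRUE,
                         dir = withr::local_tempdir())
  m <- measure_dataset(ds, cfg$sample_rate)
  harm <- m[m$label == "C", ]
  err <- abs(12 * log2(harm$median_pitch_hz / harm$true_f0_hz))
  expect_lt(max(err), 0.05)
})
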