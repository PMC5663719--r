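test_that("pitch-correction fraction interpolates linearly and unclamped", {
  expect_equal(fraction_pitch_corrected(0, 0, 2), 0)
  expect_equal(fraction_pitch_corrected(2, 0, 2), 1)
  expect_equal(fraction_pitch_corrected(1, 0, 2), 0.5)
  expect_equal(fraction_pitch_corrected(3, 0, 2), 1.5)
  expect_equal(fraction_pitch_corrected(-1, 0, 2), -0.5)
  expect_equal(fraction_pitch_corrected(3, 0, 2, clamp = TRUE), 1)
  expect_error(fraction_pitch_corrected(1, 1, 1), "differ")
})

test_that("syntax fractions follow the converging/diverging mean rule", {
  # source-order stream ABC-repeats: C preceded by B, followed by A
  src <- motif_stream(c("A", "B", "C"), n_bouts = 6)
  sf <- syntax_fractions(src, "C", conv_target = "A", div_target = "B")
  expect_equal(sf$converging, 0)
  expect_equal(sf$diverging, 0)
  expect_equal(sf$overall, 0)
  # target-order stream ACB-repeats: C preceded by A, followed by B
  tgt <- motif_stream(c("A", "C", "B"), n_bouts = 6)
  sf2 <- syntax_fractions(tgt, "C", "A", "B")
  expect_equal(sf2$converging, 1)
  expect_equal(sf2$diverging, 1)
  expect_equal(sf2$overall, 1)
  # converging acquired, diverging not: overall is forced to 1/2
  mix <- motif_stream(c("A", "C", "Z"), n_bouts = 6)
  sf3 <- syntax_fractions(mix, "C", "A", "B")
  expect_equal(sf3$converging, 1)
  expect_equal(sf3$diverging, 0)
  expect_equal(sf3$overall, 0.5)
  expect_error(syntax_fractions(src, "Q", "A", "B"), "not present")
})

test_that("bout-edge focal renditions are excluded from the fractions", {
  # single-syllable bouts: no context at all -> absent values, not zeros
  st <- make_stream(list("C", "C", "C"))
  sf <- syntax_fractions(st, "C", "A", "B")
  expect_true(is.na(sf$converging))
  expect_equal(sf$n_conv, 0)
})

test_that("syntax shift scale hits its endpoints and zero", {
  variants <- c("B" = 0, "B-2" = -2, "B+2" = 2)
  correct <- c("A>B-2", "B-2>C", "C>B+2", "B+2>A")
  incorrect <- c("A>B+2", "B+2>C", "C>B-2", "B-2>A")
  # all correct target transitions (B shifted down, in B-2's context)
  down <- motif_stream(c("A", "B", "C"), n_bouts = 5,
                       labels_pitch = c("B" = -2))
  s1 <- syntax_shift_scale(down, "B", variants, correct, incorrect)
  expect_equal(s1$shift_scale, 1)
  # all incorrect: B shifted up but still sung between A and C
  up <- motif_stream(c("A", "B", "C"), n_bouts = 5,
                     labels_pitch = c("B" = 2))
  s2 <- syntax_shift_scale(up, "B", variants, correct, incorrect)
  expect_equal(s2$shift_scale, -1)
  # source transitions (unshifted B): neither set -> 0
  none <- motif_stream(c("A", "B", "C"), n_bouts = 5,
                       labels_pitch = c("B" = 0))
  s3 <- syntax_shift_scale(none, "B", variants, correct, incorrect)
  expect_equal(s3$shift_scale, 0)
  expect_error(
    syntax_shift_scale(none, "B", variants, correct, correct[1]),
    "disjoint")
})

test_that("shift scale equals the correct fraction when incorrect set is empty", {
  variants <- c("C" = 0, "C+2" = 2)
  correct <- c("A>C+2", "C+2>B")
  st <- motif_stream(c("A", "C", "B"), n_bouts = 5,
                     labels_pitch = c("C" = 2))
  s <- syntax_shift_scale(st, "C", variants, correct, character(0))
  sf <- syntax_fractions(st, "C", "A", "B")
  expect_equal(s$shift_scale, sf$overall)
})

test_that("sliding windows match the closed-form count", {
  # N = 40, bin 30, overlap 25 -> 3 windows at 1, 6, 11
  expect_equal(binned_starts(40), c(1, 6, 11))
  expect_equal(length(binned_series(rnorm(40))), 3)
  expect_equal(length(binned_series(rnorm(29))), 0)
  expect_equal(binned_series(rep(7, 60)), rep(7, 7))
  for (n in 0:200) {
    expected <- if (n < 30) 0 else floor((n - 30) / 5) + 1
    expect_length(binned_starts(n), expected)
  }
  expect_error(binned_starts(10, bin = 5, overlap = 5), "bin > overlap")
  expect_error(binned_starts(10, bin = 5, overlap = -1), "bin > overlap")
})

test_that("pitch-vs-syntax summary is absent when pitch never reaches 45%", {
  st <- motif_stream(c("A", "C", "B"), n_bouts = 20,
                     labels_pitch = c("C" = 0.1))
  cur <- pitch_vs_syntax_curve(st, "C", 0, 2, "A", "B")
  expect_true(all(cur$bins$pitch < 0.45))
  expect_true(is.na(cur$summary))
})

test_that("endpoint summaries recover programmed endpoint states", {
  # fully matched: target order, target pitch
  done <- multiday_stream(0:4, replicate(5, c("A", "C", "B"),
                                         simplify = FALSE),
                          replicate(5, c("C" = 2), simplify = FALSE))
  es <- endpoint_summary(done, "C", 0, 2, "A", "B")
  expect_equal(es$pitch_correction, 1)
  expect_equal(es$syntax_correction, 1)
  expect_equal(es$days, 2:4)
  # frozen at source
  frozen <- multiday_stream(0:4, replicate(5, c("A", "B", "C"),
                                           simplify = FALSE),
                            replicate(5, c("C" = 0), simplify = FALSE))
  es2 <- endpoint_summary(frozen, "C", 0, 2, "A", "B")
  expect_equal(es2$pitch_correction, 0)
  expect_equal(es2$syntax_correction, 0)
})

test_that("endpoint recovery tolerates rendition noise at realistic n", {
  # programmed endpoint: pitch fraction 0.8, target-order bouts at p = 0.3,
  # with 60 renditions/day and 0.25 st jitter; bouts are padded so the
  # focal syllable is never bout-final
  set.seed(31)
  days <- 0:2
  coins <- logical(0)
  st <- do.call(rbind, lapply(days, function(d) {
    bouts <- replicate(30, {
      tgt <- runif(1) < 0.3
      coins <<- c(coins, tgt)
      c(rep(if (tgt) c("A", "C", "B") else c("A", "B", "C"), 2), "A")
    }, simplify = FALSE)
    s <- make_stream(bouts, day = d)
    jit <- rnorm(sum(s$label == "C"), 0, 0.25)
    s$true_f0_hz[s$label == "C"] <- apply_shift(600, 1.6 + jit)
    s
  }))
  es <- endpoint_summary(st, "C", 0, 2, "A", "B")
  expect_lt(abs(es$pitch_correction - 0.8), 0.05)
  expect_lt(abs(es$syntax_correction - mean(coins)), 0.05)
  expect_lt(abs(mean(coins) - 0.3), 0.06)  # the draw itself is on target
})

test_that("cohort percentages round half away from zero", {
  expect_equal(cohort_percentages(rep(c(TRUE, FALSE), c(20, 6)))$percent, 77)
  p <- cohort_percentages(4, n = 26)
  expect_equal(p$percent, 15)
  expect_equal(p$count, 4)
  expect_equal(cohort_percentages(0, n = 12)$percent, 0)
  expect_equal(cohort_percentages(1, n = 8)$percent, 13) # 12.5 rounds up
})

test_that("the recruitment null model is (1/2)^n", {
  expect_equal(null_call_probability(7), 0.0078125)
  expect_equal(round(null_call_probability(7), 3), 0.008)
  expect_equal(null_call_probability(1), 0.5)
  expect_equal(null_call_probability(0), 1)
})

test_that("vacancy histograms are direction-normalized and mirror on flip", {
  r <- data.frame(day = 0, bout_id = 1, position_in_bout = 1,
                  label = c(rep("B", 10), rep("call1", 10)),
                  onset_ms = 1:20, offset_ms = 2:21,
                  true_f0_hz = apply_shift(600, c(rep(2.1, 10),
                                                  rep(-2.1, 10))),
                  is_call = rep(c(FALSE, TRUE), each = 10))
  h <- vacancy_histogram(r, list(focal = "B", call = "call1"),
                         source = 0, direction = 1)
  focal_mass <- h[h$group == "focal", ]
  expect_equal(focal_mass$bin_mid[which.max(focal_mass$count)], 2.25)
  call_mass <- h[h$group == "call", ]
  expect_equal(call_mass$bin_mid[which.max(call_mass$count)], -2.25)
  h2 <- vacancy_histogram(r, list(focal = "B"), source = 0, direction = -1)
  f2 <- h2[h2$group == "focal", ]
  expect_equal(f2$bin_mid[which.max(f2$count)], -2.25)
  # no calls in the repertoire: empty histogram for that group
  h3 <- vacancy_histogram(r[r$label == "B", ], list(call = "call1"),
                          source = 0, direction = 1)
  expect_equal(nrow(h3), 0)
})
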