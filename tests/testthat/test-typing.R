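test_that("spectrogram segments are deterministic and pitch-separable", {
  cfg <- synth_config()
  sr <- cfg$sample_rate
  w600 <- synth_syllable(600, 100, cfg)
  w900 <- synth_syllable(900, 100, cfg)
  s1 <- spectrogram_segment(w600, sr, 0, 100)
  s2 <- spectrogram_segment(w600, sr, 0, 100)
  expect_identical(s1, s2)
  # energy of a pure-ish tone concentrates around its fundamental's row
  peak_row <- which.max(rowSums(10^s1))
  f_row <- (peak_row - 1) * sr / 256
  expect_lt(abs(f_row - 600), sr / 256)
  # between-type distance exceeds within-type distance under jitter
  jit <- function(f) synth_syllable(apply_shift(f, rnorm(1, 0, 0.25)),
                                    100, cfg)
  set.seed(8)
  d_within <- sqrt(sum((spectrogram_segment(jit(600), sr, 0, 100) -
                          spectrogram_segment(jit(600), sr, 0, 100))^2))
  d_between <- sqrt(sum((spectrogram_segment(jit(600), sr, 0, 100) -
                           spectrogram_segment(jit(900), sr, 0, 100))^2))
  expect_gt(d_between, d_within)
})

test_that("knn classification recovers types and breaks ties predictably", {
  cfg <- synth_config()
  sr <- cfg$sample_rate
  seg <- function(f) spectrogram_segment(synth_syllable(f, 100, cfg),
                                         sr, 0, 100)
  tpl <- structure(list(list(label = "low", segments = list(seg(600))),
                        list(label = "high", segments = list(seg(900)))),
                   class = "type_templates")
  # a segment equal to a template is assigned that template's label
  expect_equal(knn_classify(seg(600), tpl, k = 1), "low")
  expect_equal(knn_classify(seg(900), tpl, k = 1), "high")
  # duplicate template sets at identical distance: deterministic label order
  tpl_dup <- structure(list(list(label = "b", segments = list(seg(600))),
                            list(label = "a", segments = list(seg(600)))),
                       class = "type_templates")
  expect_equal(knn_classify(seg(600), tpl_dup, k = 1), "a")
  expect_error(knn_classify(seg(600), structure(list(),
                                                class = "type_templates")),
               "no templates")
  expect_error(knn_classify(seg(600), tpl, k = 2))
})

test_that("end-to-end typing on a two-type dataset is near-perfect", {
  # two harmonic types a semitone apart in a deterministic grammar
  ref <- 600
  src <- song_model("s", list(syllable_spec("L", "harmonic", 0),
                              syllable_spec("H", "harmonic", 6)), ref)
  tgt <- song_model("t", list(syllable_spec("L", "harmonic", 0),
                              syllable_spec("H+2", "harmonic", 8)), ref)
  task <- imitation_task("x", src, tgt,
                         data.frame(source_label = "H",
                                    target_label = "H+2", shift = 2))
  truth <- truth_at_state(task, 2, "source")
  cfg <- synth_config(seed = 21, renditions_per_day = 12)
  ds <- generate_dataset(task, truth, 2, cfg, audio = TRUE,
                         dir = withr::local_tempdir())
  tpl <- build_templates(ds, sr = cfg$sample_rate, seed = 2)
  cl <- classify_renditions(ds, tpl, sr = cfg$sample_rate)
  expect_gte(mean(cl$label_knn == cl$label), 0.99)
})

test_that("context refinement resolves lumped pitch variants", {
  # task-4-like stream: B between A and C, B+1 between C and A(wrap);
  # both lumped under "B?"
  st <- motif_stream(c("A", "B", "C", "B+1"), n_bouts = 6)
  lumped <- st
  lumped$label[lumped$label %in% c("B", "B+1")] <- "B"  # one cluster
  ctx <- list("B" = list(pred = "A"), "B+1" = list(pred = "C"))
  ref <- refine_by_context(lumped, c("B", "B+1"), ctx)
  # recovered everywhere the predecessor is defined (bout-initial B has no
  # predecessor and no pitch fallback here)
  defined <- !is.na(songmatch:::rendition_context(lumped)$pred) &
    lumped$label == "B"
  expect_equal(ref$label_refined[defined], st$label[defined])
  # idempotence on already-separated labels
  ref2 <- refine_by_context(st, c("B", "B+1"), ctx)
  expect_equal(ref2$label_refined, st$label)
})

test_that("bout-initial renditions resolve via a following-context rule", {
  st <- motif_stream(c("B", "C"), n_bouts = 3)
  ctx <- list("B" = list(succ = "C"), "Bx" = list(succ = "Z"))
  ref <- refine_by_context(st, c("B", "Bx"), ctx)
  first <- which(st$label == "B" & st$position_in_bout == 1)
  expect_equal(unique(ref$label_refined[first]), "B")
})

test_that("percent clustered counts labelled renditions", {
  r <- data.frame(label = c(rep("A", 19), NA))
  expect_equal(percent_clustered(r), 95)
  expect_equal(percent_clustered(data.frame(label = "A")), 100)
  expect_warning(v <- percent_clustered(data.frame(label = character(0))),
                 "undefined")
  expect_true(is.na(v))
})

test_that("template stores survive a save/load round trip", {
  cfg <- synth_config()
  seg <- spectrogram_segment(synth_syllable(600, 100, cfg),
                             cfg$sample_rate, 0, 100)
  tpl <- structure(list(list(label = "x", segments = list(seg))),
                   class = "type_templates")
  dir <- withr::local_tempdir()
  save_templates(tpl, dir)
  back <- load_templates(dir)
  expect_equal(back[[1]]$label, "x")
  expect_equal(back[[1]]$segments[[1]], seg, ignore_attr = TRUE,
               tolerance = 1e-6)
})
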