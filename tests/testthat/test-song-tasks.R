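test_that("semitone arithmetic is exact and self-inverse", {
  expect_equal(semitone_offset(880, 440), 12)
  expect_equal(semitone_offset(440, 440), 0)
  # derived via the closed form of apply_shift: 440 * 2^(2/12) = 493.8833
  expect_equal(semitone_offset(440 * 2^(2 / 12), 440), 2)
  expect_equal(apply_shift(440, 12), 880)
  expect_equal(apply_shift(600, 0), 600)
  expect_equal(apply_shift(440, 2), 493.8833, tolerance = 1e-6)
  for (s in seq(-12, 12, by = 1.5)) {
    expect_equal(semitone_offset(apply_shift(600, s), 600), s,
                 tolerance = 1e-9)
  }
  expect_error(semitone_offset(-1, 440), "positive")
  expect_error(apply_shift(0, 2), "positive")
})

test_that("target bigrams include the motif wrap", {
  m <- song_model("acb", list(syllable_spec("A", "nonharmonic"),
                              syllable_spec("C", "harmonic", 0),
                              syllable_spec("B", "nonharmonic")))
  expect_setequal(target_bigrams(m), c("A>C", "C>B", "B>A"))
  expect_setequal(target_bigrams(c("A", "B")), c("A>B", "B>A"))
  expect_equal(target_bigrams(c("A", "A")), "A>A")
})

test_that("the task library encodes the declared pitch geometries", {
  tl <- fixture_tasks
  expect_named(tl, c("task1", "task2", "task3", "task4.1", "task4.2",
                     "task5"))
  # task 3: two equidistant targets, two semitones down and up
  pm3 <- tl$task3$pitch_mismatches
  expect_setequal(pm3$shift, c(-2, 2))
  expect_equal(sort(motif_pitches(tl$task3$target)[c("B-2", "B+2")]),
               c("B-2" = -2, "B+2" = 2))
  # task 4.1: close targets (1 st) in the wrong context, far (2 st) in the
  # correct one
  p <- assignment_problem(tl$task4.1)
  expect_equal(p$cost, matrix(c(2, 1, 1, 2), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # task 4.2 is the reverse orientation with the same cost structure
  p2 <- assignment_problem(tl$task4.2)
  expect_equal(sort(as.numeric(p2$cost)), c(1, 1, 2, 2))
  # tasks 3 and 5 offer exactly two targets to one source syllable
  for (tk in list(tl$task3, tl$task5)) {
    expect_equal(sum(tk$pitch_mismatches$source_label == "B"), 2)
  }
  # every declared shift is consistent with the model pitches
  for (tk in tl) {
    sp <- motif_pitches(tk$source)
    tp <- motif_pitches(tk$target)
    pm <- tk$pitch_mismatches
    for (i in seq_len(nrow(pm))) {
      expect_equal(unname(tp[pm$target_label[i]] - sp[pm$source_label[i]]),
                   pm$shift[i])
    }
  }
})

test_that("task 1 with zero shift degenerates to a pure permutation", {
  t1 <- task_library(shift1 = 0)$task1
  expect_equal(nrow(t1$pitch_mismatches), 0)
  sp <- motif_pitches(t1$source)
  tp <- motif_pitches(t1$target)
  expect_equal(unname(sp["C"]), unname(tp["C+0"]))
  expect_setequal(sub("\\+0$", "", motif_labels(t1$target)),
                  motif_labels(t1$source))
})

test_that("non-shifted syllables share base pitch between source and target", {
  for (tk in fixture_tasks) {
    sp <- motif_pitches(tk$source)
    tp <- motif_pitches(tk$target)
    shared <- setdiff(intersect(names(sp), names(tp)),
                      tk$pitch_mismatches$source_label)
    expect_equal(sp[shared], tp[shared])
  }
})

test_that("tasks survive a YAML round trip", {
  for (nm in c("task1", "task4.1", "task5")) {
    tk <- fixture_tasks[[nm]]
    path <- withr::local_tempfile(fileext = ".yaml")
    task_to_yaml(tk, path)
    back <- task_from_yaml(path)
    expect_equal(back$task_id, tk$task_id)
    expect_equal(motif_labels(back$source), motif_labels(tk$source))
    expect_equal(motif_pitches(back$target), motif_pitches(tk$target))
    expect_equal(back$pitch_mismatches, tk$pitch_mismatches)
  }
})

test_that("model and task validation rejects malformed input", {
  expect_error(syllable_spec("X", "harmonic", NA), "base_pitch")
  expect_error(syllable_spec("X", "nonharmonic", duration = -1), "duration")
  expect_error(song_model("m", list(syllable_spec("A", "nonharmonic"))),
               ">= 2")
  t1 <- fixture_tasks$task1
  expect_error(imitation_task("x", t1$source, t1$target,
                              data.frame(source_label = "C",
                                         target_label = "C+2",
                                         shift = 0)),
               "nonzero")
  expect_error(imitation_task("x", t1$source, t1$target,
                              data.frame(source_label = "Z",
                                         target_label = "C+2",
                                         shift = 2)),
               "missing from the source")
})
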