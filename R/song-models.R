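#' Syllable specification
#'
#' A syllable in a song model. Harmonic syllables carry a fundamental
#' frequency expressed in semitones relative to the model's reference
#' frequency; non-harmonic syllables and calls are identified by label only.
#' Pitch-variant labels use ASCII superscript notation, e.g. `"B+2"` for the
#' variant of `B` shifted up by two semitones.
#'
#' @param label Single syllable label, e.g. `"A"` or `"B+2"`.
#' @param kind One of `"harmonic"`, `"nonharmonic"`, `"call"`.
#' @param base_pitch Pitch in semitones relative to the model reference
#'   frequency. Required (finite) for harmonic syllables and calls, `NA` for
#'   non-harmonic syllables.
#' @param duration Duration in milliseconds (> 0).
#' @return An object of class `syllable_spec`.
#' @export
syllable_spec <- function(label, kind = c("harmonic", "nonharmonic", "call"),
                          base_pitch = NA_real_, duration = 100) {
  kind <- match.arg(kind)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a positive scalar (ms)", call. = FALSE)
  }
  if (kind %in% c("harmonic", "call")) {
    if (!is.numeric(base_pitch) || !is.finite(base_pitch)) {
      stop("harmonic syllables and calls need a finite base_pitch (semitones)",
           call. = FALSE)
    }
  } else {
    base_pitch <- NA_real_
  }
  structure(list(label = label, kind = kind,
                 base_pitch = as.numeric(base_pitch),
                 duration = as.numeric(duration)),
            class = "syllable_spec")
}

#' Song model
#'
#' An ordered motif of [syllable_spec()] objects plus the acoustic reference
#' frame. Playbacks in serial-tutoring experiments present the motif a fixed
#' number of times in a row (two, by default), so bigram statistics treat the
#' motif as cyclic: the wrap transition from the last back to the first
#' syllable is part of the model's syntax.
#'
#' @param name Model name.
#' @param motif List of [syllable_spec()] (length >= 2).
#' @param reference_freq Reference frequency in Hz mapping `base_pitch = 0`.
#' @param motifs_per_playback Motif renditions per playback (default 2).
#' @return An object of class `song_model`.
#' @export
song_model <- function(name, motif, reference_freq = 600,
                       motifs_per_playback = 2) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(motif) || length(motif) < 2L ||
      !all(vapply(motif, inherits, logical(1), "syllable_spec"))) {
    stop("motif must be a list of >= 2 syllable_spec objects", call. = FALSE)
  }
  if (!is.numeric(reference_freq) || reference_freq <= 0) {
    stop("reference_freq must be positive (Hz)", call. = FALSE)
  }
  # repeated labels are allowed (a type can occur twice in a motif) but must
  # then refer to the identical spec
  labs <- vapply(motif, `[[`, character(1), "label")
  for (l in unique(labs[duplicated(labs)])) {
    specs <- motif[labs == l]
    if (!all(vapply(specs, identical, logical(1), specs[[1]]))) {
      stop("label '", l, "' reused with conflicting specifications",
           call. = FALSE)
    }
  }
  structure(list(name = name, motif = motif,
                 reference_freq = as.numeric(reference_freq),
                 motifs_per_playback = as.integer(motifs_per_playback)),
            class = "song_model")
}

#' @export
print.song_model <- function(x, ...) {
  labs <- motif_labels(x)
  st <- vapply(x$motif, `[[`, numeric(1), "base_pitch")
  pit <- ifelse(is.na(st), "", sprintf(" (%+.3g st)", st))
  cat("<song_model> ", x$name, ": ",
      paste0(labs, pit, collapse = " "),
      "  [ref ", x$reference_freq, " Hz]\n", sep = "")
  invisible(x)
}

#' Motif labels of a song model
#'
#' @param model A [song_model()].
#' @return Character vector of syllable labels in motif order.
#' @export
motif_labels <- function(model) {
  stopifnot(inherits(model, "song_model"))
  vapply(model$motif, `[[`, character(1), "label")
}

#' Motif pitches of a song model
#'
#' @param model A [song_model()].
#' @return Named numeric vector of base pitches in semitones (NA for
#'   non-harmonic syllables), one per motif position.
#' @export
motif_pitches <- function(model) {
  p <- vapply(model$motif, `[[`, numeric(1), "base_pitch")
  names(p) <- motif_labels(model)
  p
}

#' Syllable transitions (bigrams) of a song model
#'
#' Returns the set of ordered label pairs performed when the motif is
#' repeated: all within-motif adjacent pairs plus the wrap pair from the last
#' syllable back to the first.
#'
#' @param model A [song_model()], or a character vector of motif labels.
#' @return Character vector of bigrams in `"X>Y"` notation (duplicates
#'   removed).
#' @examples
#' m <- song_model("acb", list(
#'   syllable_spec("A", "nonharmonic"),
#'   syllable_spec("C", "harmonic", 0),
#'   syllable_spec("B", "nonharmonic")))
#' target_bigrams(m) # AC, CB, BA
#' @export
target_bigrams <- function(model) {
  labs <- if (inherits(model, "song_model")) motif_labels(model) else model
  stopifnot(is.character(labs), length(labs) >= 2L)
  unique(bigram_id(labs, c(labs[-1], labs[1])))
}

# canonical bigram notation used everywhere bigram sets are compared
bigram_id <- function(from, to) paste0(from, ">", to)

#' Imitation task
#'
#' A source/target song-model pair with declared pitch and syntax mismatches.
#' The task is what a serial-tutoring experiment presents to the learner: the
#' source is tutored first; once mastered, tutoring switches to the target.
#'
#' @param task_id Task identifier, e.g. `"1"` or `"4.1"`.
#' @param source,target [song_model()] objects sharing a reference frequency.
#' @param pitch_mismatches Data frame with columns `source_label`,
#'   `target_label`, `shift` (semitones, nonzero); one row per
#'   source-syllable/target-syllable pitch pairing.
#' @param syntax_mismatch Free-text description of the order change.
#' @return An object of class `imitation_task`.
#' @export
imitation_task <- function(task_id, source, target, pitch_mismatches,
                           syntax_mismatch = "") {
  stopifnot(inherits(source, "song_model"), inherits(target, "song_model"))
  pm <- as.data.frame(pitch_mismatches)
  need <- c("source_label", "target_label", "shift")
  if (!all(need %in% names(pm))) {
    stop("pitch_mismatches needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pm) && any(pm$shift == 0)) {
    stop("pitch mismatch shifts must be nonzero", call. = FALSE)
  }
  if (!all(pm$source_label %in% motif_labels(source))) {
    stop("pitch_mismatches reference labels missing from the source motif",
         call. = FALSE)
  }
  if (!all(pm$target_label %in% motif_labels(target))) {
    stop("pitch_mismatches reference labels missing from the target motif",
         call. = FALSE)
  }
  structure(list(task_id = as.character(task_id), source = source,
                 target = target, pitch_mismatches = pm,
                 syntax_mismatch = syntax_mismatch),
            class = "imitation_task")
}

#' @export
print.imitation_task <- function(x, ...) {
  cat("<imitation_task ", x$task_id, ">  ",
      paste(motif_labels(x$source), collapse = " "), "  ->  ",
      paste(motif_labels(x$target), collapse = " "), "\n", sep = "")
  if (nrow(x$pitch_mismatches)) {
    with(x$pitch_mismatches,
         cat("  pitch: ", paste(sprintf("%s->%s (%+g st)", source_label,
                                        target_label, shift),
                                collapse = ", "), "\n", sep = ""))
  }
  if (nzchar(x$syntax_mismatch)) cat("  syntax:", x$syntax_mismatch, "\n")
  invisible(x)
}

# variant label in ASCII notation: base "B" + shift +2 -> "B+2"
variant_label <- function(base, shift) {
  sprintf("%s%+d", base, as.integer(round(shift)))
}

#' The serial-tutoring task library
#'
#' Builds the five imitation tasks used throughout the package (task 4 in
#' both orientations). Shift sizes the experimental design varied across
#' birds are exposed as arguments; defaults are two semitones.
#'
#' * task 1: `A B C -> A C+ B` -- one pitch mismatch plus a permuted order.
#' * task 2: `A B C -> A+ C+ B` -- pitch mismatches in two syllables; no
#'   single alignment accommodates both.
#' * task 3: `A B C -> A B- C B+` -- one syllable offered two equidistant
#'   targets (2 st down in the same sequential context, 2 st up in a new
#'   context).
#' * task 4.1: `A B C B+1 -> A B+2 C B-1` -- spectrally close (1 st) targets
#'   in the wrong context vs. farther (2 st) targets in the correct context.
#' * task 4.2: the same models with source and target interchanged.
#' * task 5: `A B -> A B+ A B-` -- two equidistant targets, no sequential
#'   bias.
#'
#' @param shift1 Pitch shift of the task-1 mismatch in semitones (the design
#'   used 1 or 2).
#' @param shift2 Length-2 numeric, shifts of the A and C mismatches in task 2
#'   (per-bird variants; default +2, +2).
#' @param reference_freq Reference frequency (Hz) shared by all models;
#'   `base_pitch = 0` maps to this frequency (the source syllable's
#'   fundamental).
#' @return Named list of [imitation_task()] objects
#'   (`task1`, `task2`, `task3`, `task4.1`, `task4.2`, `task5`).
#' @export
task_library <- function(shift1 = 2, shift2 = c(2, 2), reference_freq = 600) {
  stopifnot(length(shift1) == 1L, length(shift2) == 2L)
  nh <- function(l, dur = 80) syllable_spec(l, "nonharmonic", duration = dur)
  h <- function(l, st, dur = 100) syllable_spec(l, "harmonic", st, dur)
  sm <- function(name, ...) song_model(name, list(...), reference_freq)
  mm <- function(s, t, shift) data.frame(source_label = s, target_label = t,
                                         shift = shift)

  tasks <- list()

  # task 1: ABC -> A C+ B (C harmonic at 0 st)
  c1 <- variant_label("C", shift1)
  tasks$task1 <- imitation_task(
    "1",
    sm("t1-source", nh("A"), nh("B"), h("C", 0)),
    sm("t1-target", nh("A"), h(c1, shift1), nh("B")),
    if (shift1 != 0) mm("C", c1, shift1) else
      data.frame(source_label = character(), target_label = character(),
                 shift = numeric()),
    "permutation: BC swapped")

  # task 2: ABC -> A+ C+ B (A at -3 st, C at +3 st; both shifted)
  a2 <- variant_label("A", shift2[1]); c2 <- variant_label("C", shift2[2])
  tasks$task2 <- imitation_task(
    "2",
    sm("t2-source", h("A", -3), nh("B"), h("C", 3)),
    sm("t2-target", h(a2, -3 + shift2[1]), h(c2, 3 + shift2[2]), nh("B")),
    rbind(mm("A", a2, shift2[1]), mm("C", c2, shift2[2])),
    "permutation: BC swapped")

  # task 3: ABC -> A B- C B+ (B at 0 st; targets at -2 and +2)
  tasks$task3 <- imitation_task(
    "3",
    sm("t3-source", nh("A"), h("B", 0), nh("C")),
    sm("t3-target", nh("A"), h("B-2", -2), nh("C"), h("B+2", 2)),
    rbind(mm("B", "B-2", -2), mm("B", "B+2", 2)),
    "insertion: second B variant appended after C")

  # task 4.1: A B C B+1 -> A B+2 C B-1
  src4 <- sm("t4-source", nh("A"), h("B", 0), nh("C"), h("B+1", 1))
  tgt4 <- sm("t4-target", nh("A"), h("B+2", 2), nh("C"), h("B-1", -1))
  pm41 <- rbind(mm("B", "B+2", 2), mm("B", "B-1", -1),
                mm("B+1", "B+2", 1), mm("B+1", "B-1", -2))
  tasks$task4.1 <- imitation_task("4.1", src4, tgt4, pm41,
                                  "close targets in swapped contexts")

  # task 4.2: source and target interchanged
  pm42 <- rbind(mm("B+2", "B", -2), mm("B+2", "B+1", -1),
                mm("B-1", "B", 1), mm("B-1", "B+1", 2))
  tasks$task4.2 <- imitation_task("4.2", tgt4, src4, pm42,
                                  "close targets in swapped contexts")

  # task 5: AB -> A B+ A B- (B at 0 st)
  tasks$task5 <- imitation_task(
    "5",
    sm("t5-source", nh("A"), h("B", 0)),
    sm("t5-target", nh("A"), h("B+2", 2), nh("A"), h("B-2", -2)),
    rbind(mm("B", "B+2", 2), mm("B", "B-2", -2)),
    "insertion: motif doubled with two B variants")

  tasks
}

#' Serialize an imitation task to YAML
#'
#' @param task An [imitation_task()].
#' @param path File path; if `NULL` the YAML string is returned.
#' @return `path` (invisibly) or the YAML string.
#' @export
task_to_yaml <- function(task, path = NULL) {
  stopifnot(inherits(task, "imitation_task"))
  ser_model <- function(m) {
    list(name = m$name, reference_freq = m$reference_freq,
         motifs_per_playback = m$motifs_per_playback,
         motif = lapply(m$motif, function(s) {
           out <- list(label = s$label, kind = s$kind, duration = s$duration)
           if (!is.na(s$base_pitch)) out$base_pitch <- s$base_pitch
           out
         }))
  }
  obj <- list(task_id = task$task_id,
              source = ser_model(task$source),
              target = ser_model(task$target),
              pitch_mismatches = unname(split(task$pitch_mismatches,
                                              seq_len(nrow(task$pitch_mismatches)))) |>
                lapply(function(r) list(source_label = r$source_label,
                                        target_label = r$target_label,
                                        shift = r$shift)),
              syntax_mismatch = task$syntax_mismatch)
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read an imitation task from YAML
#'
#' @param path File path or a YAML string produced by [task_to_yaml()].
#' @return An [imitation_task()].
#' @export
task_from_yaml <- function(path) {
  obj <- if (file.exists(path)) yaml::read_yaml(path) else
    yaml::yaml.load(path)
  de_model <- function(m) {
    motif <- lapply(m$motif, function(s) {
      syllable_spec(s$label, s$kind,
                    base_pitch = if (is.null(s$base_pitch)) NA_real_ else
                      s$base_pitch,
                    duration = s$duration)
    })
    song_model(m$name, motif, m$reference_freq, m$motifs_per_playback)
  }
  pm <- do.call(rbind, lapply(obj$pitch_mismatches, as.data.frame))
  if (is.null(pm)) {
    pm <- data.frame(source_label = character(), target_label = character(),
                     shift = numeric())
  }
  imitation_task(obj$task_id, de_model(obj$source), de_model(obj$target),
                 pm, obj$syntax_mismatch %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
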