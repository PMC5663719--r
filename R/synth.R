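#' Synthesis configuration
#'
#' Parameters of the synthetic serial-tutoring dataset generator. Defaults
#' emulate developmental zebra finch song recordings: harmonic-stack song
#' syllables in the 300-4000 Hz fundamental band, short within-bout stops,
#' much longer silences between bouts, and calls performed outside song
#' bouts with a noisy onset.
#'
#' @param sample_rate Sample rate in Hz (>= 16000).
#' @param n_harmonics Number of partials in harmonic stacks.
#' @param harmonic_rolloff Amplitude ratio between successive partials.
#' @param onset_noise_ms Aperiodic onset of calls, ms.
#' @param gap_within_bout Range (ms) of uniform within-bout stop durations;
#'   must stay below the bout-segmentation threshold (see [group_bouts()]).
#' @param gap_between_bouts Range (ms) of uniform between-bout silences.
#' @param renditions_per_day Motif renditions emitted per day. 60 keeps
#'   simulations fast while holding daily binomial error on transition
#'   frequencies near +/-6%.
#' @param pitch_jitter_sd Per-rendition pitch jitter, semitones (Gaussian in
#'   semitone space, i.e. multiplicative in Hz).
#' @param call_rate Probability that each repertoire call is performed in a
#'   given between-bout interval.
#' @param seed Integer seed; fixed seed gives byte-identical annotations.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 32000, n_harmonics = 8,
                         harmonic_rolloff = 0.75, onset_noise_ms = 20,
                         gap_within_bout = c(40, 80),
                         gap_between_bouts = c(500, 1500),
                         renditions_per_day = 60, pitch_jitter_sd = 0.25,
                         call_rate = 0.4, seed = NULL) {
  stopifnot(sample_rate >= 16000, renditions_per_day >= 1,
            pitch_jitter_sd >= 0, length(gap_within_bout) == 2L,
            length(gap_between_bouts) == 2L)
  structure(list(sample_rate = sample_rate, n_harmonics = n_harmonics,
                 harmonic_rolloff = harmonic_rolloff,
                 onset_noise_ms = onset_noise_ms,
                 gap_within_bout = gap_within_bout,
                 gap_between_bouts = gap_between_bouts,
                 renditions_per_day = renditions_per_day,
                 pitch_jitter_sd = pitch_jitter_sd, call_rate = call_rate,
                 seed = seed),
            class = "synth_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

raised_cosine_ramps <- function(x, sr, ramp_ms = 5) {
  n <- length(x)
  nr <- min(round(ramp_ms * sr / 1000), floor(n / 2))
  if (nr < 1) return(x)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  x
}

rms_normalize <- function(x, target = 0.1) {
  r <- sqrt(mean(x^2))
  if (r > 0) x * target / r else x
}

#' Synthesize a harmonic-stack syllable
#'
#' Partials at integer multiples of `f0` with geometric amplitude rolloff,
#' 5 ms raised-cosine on/off ramps, RMS-normalized. Partials above the
#' Nyquist frequency are dropped with a warning.
#'
#' @param f0 Fundamental frequency in Hz (300-4000, the plausible band for
#'   zebra finch harmonic syllables).
#' @param duration Duration in ms (>= 20).
#' @param config A [synth_config()].
#' @return Numeric waveform.
#' @export
synth_syllable <- function(f0, duration, config = synth_config()) {
  stopifnot(f0 >= 300, f0 <= 4000, duration >= 20)
  sr <- config$sample_rate
  n <- round(duration * sr / 1000)
  t <- (seq_len(n) - 1) / sr
  x <- numeric(n)
  kmax <- config$n_harmonics
  if (kmax * f0 >= sr / 2) {
    kmax <- max(1L, floor((sr / 2 - 1) / f0))
    warning("partials above Nyquist dropped (keeping ", kmax, ")",
            call. = FALSE)
  }
  roll <- config$harmonic_rolloff
  for (k in seq_len(kmax)) {
    amp <- if (k == 1) 1 else roll^(k - 1)
    if (amp == 0) next
    x <- x + amp * sin(2 * pi * k * f0 * t + 0.7 * k)
  }
  rms_normalize(raised_cosine_ramps(x, sr))
}

# deterministic band-limited noise token for a non-harmonic syllable type.
# Each label maps to a fixed frequency band and a fixed noise realization, so
# renditions of a type are acoustically identical up to duration: the package
# does not model the phonology of non-harmonic syllables beyond a template.
nonharmonic_band <- function(label) {
  bands <- list(c(1600, 2600), c(4200, 6200), c(2700, 4000), c(6400, 8200))
  letter <- substr(label, 1, 1)
  idx <- (utf8ToInt(letter) - utf8ToInt("A")) %% length(bands) + 1
  bands[[idx]]
}

synth_nonharmonic <- function(label, duration, config = synth_config()) {
  sr <- config$sample_rate
  n <- round(duration * sr / 1000)
  band <- nonharmonic_band(label)
  # fixed realization per label: random phases from a label-derived seed
  seed <- sum(utf8ToInt(label)) * 7919L
  x <- with_seed(seed, {
    nf <- 2^ceiling(log2(n))
    freqs <- (0:(nf / 2)) * sr / nf
    amp <- as.numeric(freqs >= band[1] & freqs <= band[2])
    phase <- runif(length(amp), 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full <- c(spec, Conj(rev(spec[2:(length(spec) - 1)])))
    Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  })
  rms_normalize(raised_cosine_ramps(x, sr))
}

#' Synthesize a call
#'
#' Calls are modelled after zebra finch distance calls: an initial aperiodic
#' (noisy) onset followed by a harmonic stack.
#'
#' @param f0 Fundamental of the harmonic part, Hz.
#' @param duration Total duration, ms.
#' @param config A [synth_config()]; `onset_noise_ms` sets the noisy onset.
#' @return Numeric waveform.
#' @export
synth_call <- function(f0, duration, config = synth_config()) {
  sr <- config$sample_rate
  n_on <- round(config$onset_noise_ms * sr / 1000)
  body <- synth_syllable(f0, duration - config$onset_noise_ms, config)
  onset <- with_seed(sum(utf8ToInt("call")) + round(f0), {
    stats::rnorm(n_on)
  })
  onset <- rms_normalize(raised_cosine_ramps(onset, sr, 2))
  rms_normalize(c(onset, body))
}

#' Ground-truth developmental trajectory
#'
#' The programmed state of a simulated learner: per-day true pitch of each
#' syllable type, per-day syllable-transition probabilities, the call pool,
#' and the source-to-target assignment the learner is following. Used by the
#' rendition-stream generator and as the reference in recovery tests.
#'
#' @param days Integer vector of day indices (day 0 = switch to the target).
#' @param pitch Numeric matrix `length(days) x n_types`: true pitch per day
#'   in semitones; columns named by type label; `NA` columns for
#'   non-harmonic types.
#' @param transitions List, one element per day, each a row-stochastic
#'   matrix over type labels (rows: from, columns: to).
#' @param calls Optional numeric matrix `length(days) x n_calls` of call
#'   pitches (semitones), columns named by call id.
#' @param target_choice Optional named character vector: the target label
#'   chosen for each source syllable.
#' @return An object of class `ground_truth`.
#' @export
ground_truth_trajectory <- function(days, pitch, transitions, calls = NULL,
                                    target_choice = NULL) {
  stopifnot(is.matrix(pitch), nrow(pitch) == length(days),
            length(transitions) == length(days))
  for (d in seq_along(transitions)) {
    tm <- transitions[[d]]
    stopifnot(is.matrix(tm), nrow(tm) == ncol(tm))
    rs <- rowSums(tm)
    if (any(abs(rs - 1) > 1e-8)) {
      stop("transition probabilities out of each label must sum to 1 (day ",
           days[d], ")", call. = FALSE)
    }
  }
  if (any(is.infinite(pitch))) stop("pitch trajectories must be finite")
  if (!is.null(calls)) stopifnot(is.matrix(calls),
                                 nrow(calls) == length(days))
  structure(list(days = days, pitch = pitch, transitions = transitions,
                 calls = calls, target_choice = target_choice),
            class = "ground_truth")
}

#' Constant ground truth at the source (or target) state of a task
#'
#' Convenience constructor: a trajectory frozen at the source song (pitch at
#' source values, deterministic source syntax), or at the target state under
#' a given source-to-target assignment.
#'
#' @param task An [imitation_task()].
#' @param n_days Number of days.
#' @param state `"source"` or `"target"`.
#' @param call_pitch Optional call pitch (semitones) to place one call
#'   (`"call1"`) in the repertoire.
#' @return A [ground_truth_trajectory()].
#' @export
truth_at_state <- function(task, n_days, state = c("source", "target"),
                           call_pitch = NULL) {
  state <- match.arg(state)
  labs <- motif_labels(task$source)
  ulabs <- unique(labs)
  pit <- motif_pitches(task$source)[ulabs]
  if (state == "target") {
    # move each mismatched syllable to its first declared target
    pm <- task$pitch_mismatches
    for (l in unique(pm$source_label)) {
      pit[l] <- pit[l] + pm$shift[pm$source_label == l][1]
    }
  }
  days <- seq_len(n_days) - 1L
  pitch <- matrix(rep(pit, each = n_days), nrow = n_days,
                  dimnames = list(NULL, ulabs))
  tm <- cycle_matrix(labs, ulabs)
  if (state == "target") {
    # source syllables rearranged in target order (one-to-one tasks only)
    ord <- motif_labels(task$target)
    inv <- stats::setNames(task$pitch_mismatches$source_label,
                           task$pitch_mismatches$target_label)
    motor_ord <- ifelse(ord %in% names(inv), inv[ord], ord)
    tm <- cycle_matrix(unname(motor_ord), ulabs)
  }
  calls <- NULL
  if (!is.null(call_pitch)) {
    calls <- matrix(call_pitch, nrow = n_days, ncol = 1,
                    dimnames = list(NULL, "call1"))
  }
  ground_truth_trajectory(days, pitch, rep(list(tm), n_days), calls)
}

# deterministic cyclic grammar over a motif label sequence
cycle_matrix <- function(motif_labs, all_labs = unique(motif_labs)) {
  tm <- matrix(0, length(all_labs), length(all_labs),
               dimnames = list(all_labs, all_labs))
  nxt <- c(motif_labs[-1], motif_labs[1])
  for (i in seq_along(motif_labs)) tm[motif_labs[i], nxt[i]] <- tm[motif_labs[i], nxt[i]] + 1
  # rows never visited: stay uniform over the motif start (unreachable)
  zero <- rowSums(tm) == 0
  tm[zero, motif_labs[1]] <- 1
  tm / rowSums(tm)
}

#' Generate an annotated rendition stream
#'
#' Samples the performed song of a learner over days: bouts of syllables
#' drawn from the day's transition probabilities, with per-rendition pitch
#' equal to the day's true pitch plus Gaussian jitter in semitone space, and
#' repertoire calls emitted between bouts. This is the annotation-only fast
#' path of the generator; [generate_dataset()] adds audio.
#'
#' @param task An [imitation_task()].
#' @param truth A [ground_truth_trajectory()] covering `n_days`.
#' @param n_days Number of days to emit.
#' @param config A [synth_config()]; `config$seed` makes the stream
#'   reproducible.
#' @return Data frame with columns `day`, `bout_id`, `position_in_bout`,
#'   `label`, `onset_ms`, `offset_ms`, `true_f0_hz`, `is_call`.
#' @export
generate_rendition_stream <- function(task, truth, n_days,
                                      config = synth_config()) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_days > length(truth$days)) {
    stop("truth covers ", length(truth$days), " days; ", n_days,
         " requested", call. = FALSE)
  }
  labs <- colnames(truth$pitch)
  tlabs <- rownames(truth$transitions[[1]])
  if (!all(tlabs %in% c(labs, colnames(truth$calls)))) {
    stop("transition labels not covered by pitch/call labels", call. = FALSE)
  }
  src_labels <- unique(motif_labels(task$source))
  if (!all(src_labels %in% labs)) {
    stop("truth labels do not cover the task's source motif", call. = FALSE)
  }
  ref <- task$source$reference_freq
  durs <- syllable_durations(task)
  with_seed(config$seed, {
    acc <- list(day = integer(0), bout_id = integer(0),
                position_in_bout = integer(0), label = character(0),
                dur = numeric(0), is_call = logical(0), st = numeric(0))
    push <- function(day, bout, pos, lab, dur, call, st) {
      acc$day[length(acc$day) + 1L] <<- day
      acc$bout_id[length(acc$bout_id) + 1L] <<- bout
      acc$position_in_bout[length(acc$position_in_bout) + 1L] <<- pos
      acc$label[length(acc$label) + 1L] <<- lab
      acc$dur[length(acc$dur) + 1L] <<- dur
      acc$is_call[length(acc$is_call) + 1L] <<- call
      acc$st[length(acc$st) + 1L] <<- st
    }
    bout_counter <- 0L
    start_lab <- motif_labels(task$source)[1]
    motif_len <- length(motif_labels(task$source))
    syl_per_bout <- task$source$motifs_per_playback * motif_len
    n_bouts <- max(1L, round(config$renditions_per_day /
                               task$source$motifs_per_playback))
    for (di in seq_len(n_days)) {
      day <- truth$days[di]
      tm <- truth$transitions[[di]]
      cols <- colnames(tm)
      for (b in seq_len(n_bouts)) {
        bout_counter <- bout_counter + 1L
        lab <- start_lab
        for (pos in seq_len(syl_per_bout)) {
          st <- truth_pitch_st(lab, di, truth)
          push(day, bout_counter, pos, lab, durs[[lab]] %||% 80, FALSE, st)
          lab <- cols[sample.int(length(cols), 1L, prob = tm[lab, ])]
        }
        # calls live outside bouts, in the silent intervals
        for (cid in colnames(truth$calls)) {
          if (stats::runif(1) < config$call_rate) {
            push(day, NA_integer_, NA_integer_, cid, 70, TRUE,
                 truth$calls[di, cid])
          }
        }
      }
    }
    n <- length(acc$day)
    jitter <- stats::rnorm(n, 0, config$pitch_jitter_sd)
    f0 <- ifelse(is.na(acc$st), NA_real_,
                 apply_shift(ref, ifelse(is.na(acc$st), 0, acc$st) + jitter))
    # timing: within-bout stops, longer silences between bouts and around
    # calls
    gap_within <- stats::runif(n, config$gap_within_bout[1],
                               config$gap_within_bout[2])
    gap_between <- stats::runif(n, config$gap_between_bouts[1],
                                config$gap_between_bouts[2])
    bout_chg <- c(TRUE, acc$bout_id[-1] != acc$bout_id[-n] |
                    is.na(acc$bout_id[-1]) != is.na(acc$bout_id[-n]) |
                    acc$day[-1] != acc$day[-n])
    bout_chg[is.na(bout_chg)] <- TRUE
    gap <- ifelse(bout_chg | acc$is_call, gap_between, gap_within)
    onset <- numeric(n)
    clock <- 0
    prev_day <- acc$day[1]
    for (i in seq_len(n)) {
      if (acc$day[i] != prev_day) { clock <- 0; prev_day <- acc$day[i] }
      else clock <- clock + gap[i]
      onset[i] <- clock
      clock <- clock + acc$dur[i]
    }
    res <- data.frame(day = acc$day, bout_id = acc$bout_id,
                      position_in_bout = acc$position_in_bout,
                      label = acc$label, onset_ms = onset,
                      offset_ms = onset + acc$dur, true_f0_hz = f0,
                      is_call = acc$is_call)
    rownames(res) <- NULL
    res
  })
}

# programmed pitch of a label on a given day (NA for non-harmonic types)
truth_pitch_st <- function(lab, day_idx, truth) {
  if (lab %in% colnames(truth$calls)) return(truth$calls[day_idx, lab])
  truth$pitch[day_idx, lab]
}

# duration lookup: motif syllable specs, 70 ms for calls
syllable_durations <- function(task) {
  specs <- c(task$source$motif, task$target$motif)
  durs <- lapply(specs, `[[`, "duration")
  names(durs) <- vapply(specs, `[[`, character(1), "label")
  durs[!duplicated(names(durs))]
}

#' Generate a dataset directory (annotations and optional audio)
#'
#' Writes `annotations.csv` and, when `audio = TRUE`, one WAV file per day
#' whose content is consistent with the annotation (segment boundaries and
#' true fundamental frequencies).
#'
#' @param task,truth,n_days,config As in [generate_rendition_stream()].
#' @param audio Write per-day WAV files?
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `annotations` (data frame), `csv` path and
#'   `wav` paths (possibly empty).
#' @export
generate_dataset <- function(task, truth, n_days, config = synth_config(),
                             audio = FALSE, dir = tempfile("songdata")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (n_days == 0) {
    ann <- data.frame(day = integer(), bout_id = integer(),
                      position_in_bout = integer(), label = character(),
                      onset_ms = numeric(), offset_ms = numeric(),
                      true_f0_hz = numeric(), is_call = logical())
  } else {
    ann <- generate_rendition_stream(task, truth, n_days, config)
  }
  csv <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, csv, row.names = FALSE)
  wavs <- character(0)
  if (audio && nrow(ann)) {
    sr <- config$sample_rate
    kinds <- syllable_kinds(task)
    for (d in unique(ann$day)) {
      day_ann <- ann[ann$day == d, ]
      total <- ceiling((max(day_ann$offset_ms) + 100) * sr / 1000)
      wave <- numeric(total)
      for (i in seq_len(nrow(day_ann))) {
        r <- day_ann[i, ]
        dur <- r$offset_ms - r$onset_ms
        snd <- if (r$is_call) {
          synth_call(r$true_f0_hz, dur, config)
        } else if (!is.na(r$true_f0_hz)) {
          synth_syllable(r$true_f0_hz, dur, config)
        } else {
          synth_nonharmonic(r$label, dur, config)
        }
        i0 <- round(r$onset_ms * sr / 1000) + 1
        idx <- i0:(i0 + length(snd) - 1)
        wave[idx] <- wave[idx] + snd
      }
      p <- file.path(dir, sprintf("day_%03d.wav", d))
      write_wav(wave, sr, p)
      wavs <- c(wavs, p)
    }
  }
  invisible(list(annotations = ann, csv = csv, wav = wavs, dir = dir))
}

# kind lookup by label over both models
syllable_kinds <- function(task) {
  specs <- c(task$source$motif, task$target$motif)
  k <- vapply(specs, `[[`, character(1), "kind")
  names(k) <- vapply(specs, `[[`, character(1), "label")
  k[!duplicated(names(k))]
}
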