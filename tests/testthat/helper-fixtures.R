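# shared fixtures: built once per test run, in code

fixture_tasks <- task_library()

# a small annotated stream with hand-controlled bout structure:
# rows are (day, bout, position, label); pitches optional
make_stream <- function(bouts, day = 0L, labels_pitch = NULL,
                        ref_freq = 600) {
  rows <- list()
  clock <- 0
  bid <- 0L
  for (bout in bouts) {
    bid <- bid + 1L
    for (pos in seq_along(bout)) {
      lab <- bout[[pos]]
      st <- if (!is.null(labels_pitch) && lab %in% names(labels_pitch)) {
        labels_pitch[[lab]]
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        day = day, bout_id = bid, position_in_bout = pos, label = lab,
        onset_ms = clock, offset_ms = clock + 80,
        true_f0_hz = if (is.na(st)) NA_real_ else apply_shift(ref_freq, st),
        is_call = FALSE)
      clock <- clock + 130
    }
    clock <- clock + 500
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# repeated-motif bouts: n_bouts bouts of n_motifs motif repetitions
motif_stream <- function(motif, n_bouts = 5, n_motifs = 2, day = 0L,
                         labels_pitch = NULL) {
  make_stream(replicate(n_bouts, rep(motif, n_motifs), simplify = FALSE),
              day = day, labels_pitch = labels_pitch)
}

# multi-day stream builder: one motif order + pitch per day
multiday_stream <- function(days, motif_by_day, pitch_by_day,
                            n_bouts = 5, n_motifs = 2) {
  do.call(rbind, lapply(seq_along(days), function(i) {
    motif_stream(motif_by_day[[i]], n_bouts, n_motifs, day = days[i],
                 labels_pitch = pitch_by_day[[i]])
  }))
}
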