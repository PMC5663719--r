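#' Wiener entropy of a power spectrum
#'
#' Log ratio of the geometric to the arithmetic mean of spectral power:
#' 0 for a flat (noise-like) spectrum, strongly negative for tonal sounds.
#' Line spectra drive the geometric mean to zero; the value is clamped at
#' `floor`.
#'
#' @param power_spectrum Nonnegative numeric vector of power values.
#' @param floor Clamp for the log ratio (default -12).
#' @return Scalar `<= 0` (or `NA` with a warning for an all-zero spectrum).
#' @export
wiener_entropy <- function(power_spectrum, floor = -12) {
  stopifnot(is.numeric(power_spectrum), all(power_spectrum >= 0))
  if (all(power_spectrum == 0)) {
    warning("all-zero spectrum: Wiener entropy undefined", call. = FALSE)
    return(NA_real_)
  }
  if (any(power_spectrum == 0)) return(floor)
  val <- mean(log(power_spectrum)) - log(mean(power_spectrum))
  max(val, floor)
}

# short-time log power (dB) on a ms grid; window ~5 ms for segmentation
frame_power_db <- function(x, sr, hop_ms = 1, win_ms = 5) {
  W <- max(2L, round(win_ms * sr / 1000))
  hop <- max(1L, round(hop_ms * sr / 1000))
  N <- length(x)
  if (N < W) return(data.frame(time_ms = numeric(), power_db = numeric()))
  starts <- seq(1L, N - W + 1L, by = hop)
  cs <- c(0, cumsum(x^2))
  p <- (cs[starts + W] - cs[starts]) / W
  data.frame(time_ms = (starts - 1) / sr * 1000,
             power_db = 10 * log10(pmax(p, 1e-12)))
}

#' Segment syllables by amplitude threshold
#'
#' Maximal runs of frames whose short-time power exceeds `threshold_db`
#' below the recording's peak power; gaps shorter than `min_gap` are merged,
#' runs shorter than `min_dur` discarded.
#'
#' @param x Numeric waveform.
#' @param sr Sample rate, Hz.
#' @param threshold_db Threshold relative to peak frame power, dB (positive
#'   number of dB below peak; default 35).
#' @param min_dur Minimum segment duration, ms.
#' @param min_gap Gaps shorter than this (ms) are merged.
#' @return Data frame with `onset_ms`, `offset_ms` (zero rows for silence).
#' @export
segment_syllables <- function(x, sr, threshold_db = 35, min_dur = 20,
                              min_gap = 5) {
  stopifnot(threshold_db > 0, min_dur > 0, min_gap >= 0)
  fp <- frame_power_db(x, sr)
  empty <- data.frame(onset_ms = numeric(), offset_ms = numeric())
  if (!nrow(fp)) return(empty)
  if (max(fp$power_db) < -80) return(empty)   # digital silence
  above <- fp$power_db > max(fp$power_db) - threshold_db
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(onset_ms = fp$time_ms[starts[r$values]],
                    offset_ms = fp$time_ms[ends[r$values]] + 1)
  # merge gaps shorter than min_gap
  if (nrow(seg) > 1) {
    keep <- list(seg[1, ])
    for (i in 2:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg$onset_ms[i] - last$offset_ms < min_gap) {
        keep[[length(keep)]]$offset_ms <- seg$offset_ms[i]
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }
  seg <- seg[seg$offset_ms - seg$onset_ms >= min_dur, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Group renditions into song bouts
#'
#' Consecutive renditions whose stop duration (previous offset to next
#' onset) is below `stop_threshold` share a bout. The threshold follows the
#' typical stop duration in crystallized song (150-200 ms; default 175).
#' Grouping is done within each day. Renditions flagged as calls are left
#' outside bouts (`NA` bout id) unless `include_calls = TRUE`.
#'
#' @param renditions Data frame with `onset_ms`, `offset_ms` and optionally
#'   `day` and `is_call`; must be time-sorted within day.
#' @param stop_threshold Maximum within-bout stop, ms (150-200 sensible).
#' @param include_calls Treat calls like song syllables when grouping?
#' @return The input with a `bout_id` column (integer, `NA` for excluded
#'   calls).
#' @export
group_bouts <- function(renditions, stop_threshold = 175,
                        include_calls = FALSE) {
  r <- as.data.frame(renditions)
  if (!nrow(r)) {
    r$bout_id <- integer(0)
    return(r)
  }
  if (is.null(r$day)) r$day <- 0L
  if (is.null(r$is_call)) r$is_call <- FALSE
  ord <- order(r$day, r$onset_ms)
  if (!identical(ord, seq_len(nrow(r)))) {
    stop("renditions must be sorted by day and onset", call. = FALSE)
  }
  r$bout_id <- NA_integer_
  counter <- 0L
  for (d in unique(r$day)) {
    sel <- which(r$day == d & (include_calls | !r$is_call))
    if (!length(sel)) next
    gaps <- r$onset_ms[sel[-1]] - r$offset_ms[sel[-length(sel)]]
    new_bout <- c(TRUE, gaps >= stop_threshold)
    r$bout_id[sel] <- counter + cumsum(new_bout)
    counter <- counter + sum(new_bout)
  }
  r
}

#' Median pitch of one rendition
#'
#' Median f0 over voiced frames, after discarding the leading contiguous
#' aperiodic run (the noisy onset characteristic of distance calls). Absent
#' (`NA`) if fewer than half the remaining frames are voiced.
#'
#' @param track Data frame from [yin_f0()] for a single rendition.
#' @param threshold Aperiodicity threshold separating voiced frames.
#' @return Median f0 in Hz, or `NA`.
#' @export
median_pitch <- function(track, threshold = 0.2) {
  if (!nrow(track)) return(NA_real_)
  voiced <- track$aperiodicity < threshold
  # drop the leading contiguous aperiodic run
  if (!voiced[1]) {
    first <- which(voiced)[1]
    if (is.na(first)) return(NA_real_)
    track <- track[first:nrow(track), , drop = FALSE]
    voiced <- voiced[first:length(voiced)]
  }
  if (mean(voiced) < 0.5) return(NA_real_)
  stats::median(track$f0_hz[voiced], na.rm = TRUE)
}

#' Measure renditions of a recording
#'
#' Runs the pitch tracker and spectral measures on each annotated (or
#' segmented) rendition of a day's waveform and appends measured columns.
#'
#' @param wave Numeric waveform of one recording.
#' @param sr Sample rate, Hz.
#' @param segments Data frame with `onset_ms`, `offset_ms` (other columns
#'   passed through), e.g. annotation rows or [segment_syllables()] output.
#' @param fmin,fmax,threshold Passed to [yin_f0()] / [median_pitch()].
#' @return `segments` with added `median_pitch_hz`, `median_entropy`,
#'   `frac_voiced`.
#' @export
measure_renditions <- function(wave, sr, segments, fmin = 300, fmax = 4000,
                               threshold = 0.2) {
  seg <- as.data.frame(segments)
  seg$median_pitch_hz <- NA_real_
  seg$median_entropy <- NA_real_
  seg$frac_voiced <- NA_real_
  pad <- ceiling(sr / fmin) + round(0.025 * sr)
  for (i in seq_len(nrow(seg))) {
    i0 <- max(1L, round(seg$onset_ms[i] * sr / 1000) + 1L)
    i1 <- min(length(wave), round(seg$offset_ms[i] * sr / 1000) + pad)
    snip <- wave[i0:i1]
    tr <- yin_f0(snip, sr, fmin, fmax, threshold = threshold)
    # keep frames starting inside the rendition
    tr <- tr[tr$time_ms <= seg$offset_ms[i] - seg$onset_ms[i], , drop = FALSE]
    if (nrow(tr)) {
      seg$median_pitch_hz[i] <- median_pitch(tr, threshold)
      seg$frac_voiced[i] <- mean(tr$aperiodicity < threshold)
    }
    spec <- Mod(stats::fft(snip * hanning_window(length(snip))))^2
    half <- spec[seq_len(floor(length(spec) / 2))]
    seg$median_entropy[i] <- wiener_entropy(half)
  }
  seg
}

hanning_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
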