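#' Per-day median pitch of a syllable type, in semitones
#'
#' Day-level pitch values are medians over that day's renditions, measured
#' pitch (`median_pitch_hz`) when present, programmed pitch (`true_f0_hz`)
#' otherwise.
#'
#' @param renditions Annotation data frame.
#' @param label Type label (matched against `label_refined` when present,
#'   else `label`).
#' @param ref_freq Reference frequency, Hz.
#' @return Data frame with `day`, `pitch_st`, `n`.
#' @export
day_pitch_medians <- function(renditions, label, ref_freq = 600) {
  r <- as.data.frame(renditions)
  labs <- r$label_refined %||% r$label
  hz <- if (!is.null(r$median_pitch_hz)) r$median_pitch_hz else r$true_f0_hz
  sel <- labs %in% label & !is.na(hz)
  if (!any(sel)) return(data.frame(day = integer(), pitch_st = numeric(),
                                   n = integer()))
  st <- semitone_offset(hz[sel], ref_freq)
  agg <- stats::aggregate(st, list(day = r$day[sel]), stats::median)
  nn <- stats::aggregate(st, list(day = r$day[sel]), length)
  data.frame(day = agg$day, pitch_st = agg$x, n = nn$x)
}

#' Fraction of pitch error corrected
#'
#' Linear position of a pitch between the source (0) and target (1)
#' values. Unclamped: overshoot beyond the target exceeds 1 and movement
#' away from the target is negative.
#'
#' @param pitch Pitch values in semitones (e.g. per-day medians).
#' @param source,target Source and target pitch in semitones (must differ).
#' @param clamp Clamp the fraction into `[0, 1]`?
#' @return Numeric vector of fractions.
#' @export
fraction_pitch_corrected <- function(pitch, source, target, clamp = FALSE) {
  if (!is.finite(source) || !is.finite(target) || source == target) {
    stop("source and target pitch must differ", call. = FALSE)
  }
  f <- (pitch - source) / (target - source)
  if (clamp) f <- pmin(pmax(f, 0), 1)
  f
}

#' Converging and diverging syntax-correction fractions
#'
#' For each rendition of the focal syllable, the preceding (converging) and
#' following (diverging) syllables within its bout are compared with the
#' target context. The daily converging (diverging) fraction is the share
#' of focal renditions whose predecessor (successor) matches the target;
#' the overall fraction is their arithmetic mean. Bout-edge renditions are
#' excluded from the respective fraction; within a bout, motif repetitions
#' make the wrap transition an ordinary adjacency.
#'
#' @param renditions Annotation data frame with `label`, `bout_id`,
#'   `onset_ms` (and `day`).
#' @param focal_label Focal syllable label(s) (a lineage; pitch variants of
#'   one motor syllable may share the lineage).
#' @param conv_target Label expected before the focal syllable in the
#'   target song.
#' @param div_target Label expected after it.
#' @param label_col Column holding labels.
#' @return Data frame `day`, `converging`, `diverging`, `overall`,
#'   `n_conv`, `n_div`. Days with no focal renditions are absent.
#' @export
syntax_fractions <- function(renditions, focal_label, conv_target,
                             div_target, label_col = "label") {
  r <- as.data.frame(renditions)
  if (!any(r[[label_col]] %in% focal_label)) {
    stop("focal label not present", call. = FALSE)
  }
  ctx <- rendition_context(r, label_col)
  foc <- which(r[[label_col]] %in% focal_label)
  out <- lapply(sort(unique(r$day[foc])), function(d) {
    i <- foc[r$day[foc] == d]
    cv <- ctx$pred[i]; dv <- ctx$succ[i]   # NA at bout edges -> excluded
    conv <- if (any(!is.na(cv))) mean(cv[!is.na(cv)] %in% conv_target)
            else NA_real_
    divv <- if (any(!is.na(dv))) mean(dv[!is.na(dv)] %in% div_target)
            else NA_real_
    data.frame(day = d, converging = conv, diverging = divv,
               overall = mean(c(conv, divv)),
               n_conv = sum(!is.na(cv)), n_div = sum(!is.na(dv)))
  })
  do.call(rbind, out)
}

#' Syntax shift scale in [-1, 1]
#'
#' Signed syntax score: +1 when the focal syllable is always performed in
#' correct target transitions, -1 when always in the declared incorrect
#' (away-from-target) transitions, 0 when transitions are neither (e.g. the
#' unchanged source syntax). The focal rendition's own identity is resolved
#' by pitch (nearest declared variant), so a pitch-shifted syllable sung in
#' its old context scores negative.
#'
#' @param renditions Annotation data frame.
#' @param focal_label Focal lineage label(s).
#' @param variants Named numeric: pitch (semitones) of each variant label
#'   the focal syllable can express, e.g. `c(B = 0, "B-2" = -2, "B+2" = 2)`.
#' @param correct_bigrams,incorrect_bigrams Character vectors of bigrams in
#'   `"X>Y"` notation (see [target_bigrams()]); must be disjoint.
#' @param ref_freq Reference frequency, Hz.
#' @param label_col Column holding labels.
#' @return Data frame `day`, `shift_scale`, `n`.
#' @export
syntax_shift_scale <- function(renditions, focal_label, variants,
                               correct_bigrams, incorrect_bigrams,
                               ref_freq = 600, label_col = "label") {
  if (length(intersect(correct_bigrams, incorrect_bigrams))) {
    stop("correct and incorrect bigram sets must be disjoint", call. = FALSE)
  }
  r <- as.data.frame(renditions)
  ctx <- rendition_context(r, label_col)
  hz <- if (!is.null(r$median_pitch_hz)) r$median_pitch_hz else r$true_f0_hz
  foc <- which(r[[label_col]] %in% focal_label)
  if (!length(foc)) stop("focal label not present", call. = FALSE)
  score1 <- function(bg) {
    if (is.na(bg)) return(NA_real_)
    if (bg %in% correct_bigrams) return(1)
    if (bg %in% incorrect_bigrams) return(-1)
    0
  }
  sc <- vapply(foc, function(i) {
    v <- if (!is.na(hz[i])) {
      st <- semitone_offset(hz[i], ref_freq)
      names(variants)[which.min(abs(st - variants))]
    } else r[[label_col]][i]
    conv <- if (is.na(ctx$pred[i])) NA_real_ else
      score1(bigram_id(ctx$pred[i], v))
    divv <- if (is.na(ctx$succ[i])) NA_real_ else
      score1(bigram_id(v, ctx$succ[i]))
    mean(c(conv, divv), na.rm = TRUE)
  }, numeric(1))
  agg <- stats::aggregate(sc, list(day = r$day[foc]), mean, na.rm = TRUE)
  nn <- stats::aggregate(sc, list(day = r$day[foc]), length)
  data.frame(day = agg$day, shift_scale = agg$x, n = nn$x)
}

#' Sliding-window medians of an ordered series
#'
#' Windows of `bin` consecutive samples advancing by `bin - overlap`
#' samples. For `N >= bin` samples there are
#' `floor((N - bin) / (bin - overlap)) + 1` windows, otherwise none.
#'
#' @param x Ordered numeric vector (e.g. consecutive rendition values).
#' @param bin Window size in samples (default 30).
#' @param overlap Overlap between consecutive windows (default 25;
#'   `bin > overlap >= 0`).
#' @param fun Summary function per window (default [stats::median()]).
#' @return Numeric vector of window summaries (length possibly 0).
#' @export
binned_series <- function(x, bin = 30, overlap = 25, fun = stats::median) {
  starts <- binned_starts(length(x), bin, overlap)
  vapply(starts, function(s) fun(x[s:(s + bin - 1)]), numeric(1))
}

#' @rdname binned_series
#' @param n Series length.
#' @return For `binned_starts`: integer vector of window start indices.
#' @export
binned_starts <- function(n, bin = 30, overlap = 25) {
  if (bin <= overlap || overlap < 0) {
    stop("need bin > overlap >= 0", call. = FALSE)
  }
  step <- bin - overlap
  if (n < bin) return(integer(0))
  seq(1L, n - bin + 1L, by = step)
}

#' Paired pitch-versus-syntax correction curve
#'
#' Bins the focal syllable's consecutive renditions (bin size 30, overlap
#' 25 by default) and pairs, per bin, the fraction of pitch correction
#' (median over the bin) with the fraction of syntax correction (mean of
#' converging and diverging fractions over the bin). The summary is the
#' mean syntax correction over bins whose pitch correction lies in the
#' `window` (45-55% by default) -- i.e. how much syntax had changed by the
#' time pitch was half corrected.
#'
#' @param renditions Annotation data frame.
#' @param focal_label Focal lineage label(s).
#' @param source,target Source/target pitch of the focal syllable,
#'   semitones.
#' @param conv_target,div_target Target context labels.
#' @param ref_freq Reference frequency, Hz.
#' @param bin,overlap Binning parameters.
#' @param window Pitch-correction window for the summary.
#' @param label_col Column holding labels.
#' @return List with `bins` (data frame `pitch`, `syntax`) and `summary`
#'   (scalar, `NA` if no bin falls in the window).
#' @export
pitch_vs_syntax_curve <- function(renditions, focal_label, source, target,
                                  conv_target, div_target, ref_freq = 600,
                                  bin = 30, overlap = 25,
                                  window = c(0.45, 0.55),
                                  label_col = "label") {
  r <- as.data.frame(renditions)
  ctx <- rendition_context(r, label_col)
  hz <- if (!is.null(r$median_pitch_hz)) r$median_pitch_hz else r$true_f0_hz
  foc <- which(r[[label_col]] %in% focal_label)
  ord <- foc[order(r$day[foc], r$onset_ms[foc])]
  pitch_fr <- fraction_pitch_corrected(semitone_offset(hz[ord], ref_freq),
                                       source, target)
  conv <- ifelse(is.na(ctx$pred[ord]), NA,
                 as.numeric(ctx$pred[ord] %in% conv_target))
  divv <- ifelse(is.na(ctx$succ[ord]), NA,
                 as.numeric(ctx$succ[ord] %in% div_target))
  starts <- binned_starts(length(ord), bin, overlap)
  bins <- do.call(rbind, lapply(starts, function(s) {
    i <- s:(s + bin - 1)
    data.frame(pitch = stats::median(pitch_fr[i], na.rm = TRUE),
               syntax = mean(c(mean(conv[i], na.rm = TRUE),
                               mean(divv[i], na.rm = TRUE)), na.rm = TRUE))
  }))
  if (is.null(bins)) bins <- data.frame(pitch = numeric(),
                                        syntax = numeric())
  sel <- bins$pitch >= window[1] & bins$pitch <= window[2]
  list(bins = bins,
       summary = if (any(sel, na.rm = TRUE))
         mean(bins$syntax[which(sel)]) else NA_real_)
}

#' Endpoint summary of a learning trajectory
#'
#' Pitch and syntax correction over the renditions of the final days
#' (default 3) pooled together.
#'
#' @param renditions Annotation data frame.
#' @param focal_label Focal lineage label(s).
#' @param source,target Source/target pitch, semitones.
#' @param conv_target,div_target Target context labels.
#' @param last_n_days Days pooled at the end (default 3).
#' @param ref_freq Reference frequency, Hz.
#' @param label_col Column holding labels.
#' @return List with `pitch_correction`, `syntax_correction`,
#'   `converging`, `diverging`, `days`.
#' @export
endpoint_summary <- function(renditions, focal_label, source, target,
                             conv_target, div_target, last_n_days = 3,
                             ref_freq = 600, label_col = "label") {
  r <- as.data.frame(renditions)
  stopifnot(nrow(r) > 0)
  days <- sort(unique(r$day))
  keep <- days[days > max(days) - last_n_days]
  rr <- r[r$day %in% keep, ]
  # pool the endpoint days as one; bout identities must stay distinct
  rr$bout_id <- ifelse(is.na(rr$bout_id), NA,
                       paste(rr$day, rr$bout_id))
  rr$day <- 0L
  pm <- day_pitch_medians(rr, focal_label, ref_freq)
  sf <- syntax_fractions(rr, focal_label, conv_target, div_target,
                         label_col)
  list(pitch_correction = fraction_pitch_corrected(pm$pitch_st, source,
                                                   target),
       syntax_correction = sf$overall[1],
       converging = sf$converging[1], diverging = sf$diverging[1],
       days = keep)
}

#' Cohort percentage with retained counts
#'
#' Integer percentages as reported for bird cohorts, rounded half away
#' from zero.
#'
#' @param flags Logical vector, one entry per bird (or a count, with `n`).
#' @param n Cohort size when `flags` is a count.
#' @return List with `percent` (integer), `count`, `n`.
#' @export
cohort_percentages <- function(flags, n = NULL) {
  if (is.logical(flags)) {
    count <- sum(flags); n <- length(flags)
  } else {
    stopifnot(!is.null(n))
    count <- flags
  }
  stopifnot(n >= 1)
  pct <- 100 * count / n
  list(percent = sign(pct) * floor(abs(pct) + 0.5), count = count, n = n)
}

#' Null probability that every recruited call avoids the occupied target
#'
#' Under purely greedy (non-competitive) matching with randomly distributed
#' call origins, each bird's recruited call would land on the vacant rather
#' than the occupied target with probability 1/2; across independent birds
#' the probability that all do is `0.5^n`.
#'
#' @param n_birds Number of birds (>= 0).
#' @return Probability `0.5^n_birds`.
#' @examples
#' null_call_probability(7) # 0.0078125, i.e. p = 0.008
#' @export
null_call_probability <- function(n_birds) {
  stopifnot(n_birds >= 0)
  0.5^n_birds
}

#' Pitch-distance histograms around the source syllable
#'
#' Distribution of endpoint pitch distances from the source syllable's
#' pitch, normalized by the direction in which the focal syllable shifted
#' (positive = same direction as the focal shift), within a +/-6 semitone
#' window. Computed separately for the focal syllable's descendants, the
#' recruited call, and all other harmonic vocalizations, to show which
#' precursor converged on which target.
#'
#' @param renditions Endpoint annotation data frame (harmonic renditions;
#'   rows without pitch are dropped).
#' @param groups Named list of label vectors: `focal`, `call`, `other`.
#' @param source Source pitch, semitones.
#' @param direction Sign of the focal syllable's shift (+1 or -1).
#' @param ref_freq Reference frequency, Hz.
#' @param window Half-width of the histogram window, semitones.
#' @param binwidth Histogram bin width, semitones.
#' @return Data frame `group`, `bin_mid`, `count`, `prop`.
#' @export
vacancy_histogram <- function(renditions, groups, source, direction,
                              ref_freq = 600, window = 6, binwidth = 0.5) {
  stopifnot(direction %in% c(-1, 1))
  r <- as.data.frame(renditions)
  hz <- if (!is.null(r$median_pitch_hz)) r$median_pitch_hz else r$true_f0_hz
  breaks <- seq(-window, window, by = binwidth)
  mids <- breaks[-length(breaks)] + binwidth / 2
  out <- lapply(names(groups), function(g) {
    sel <- r$label %in% groups[[g]] & !is.na(hz)
    d <- direction * (semitone_offset(hz[sel], ref_freq) - source)
    d <- d[abs(d) <= window]
    if (!length(d)) {
      return(data.frame(group = character(), bin_mid = numeric(),
                        count = integer(), prop = numeric()))
    }
    cnt <- table(cut(d, breaks, include.lowest = TRUE))
    data.frame(group = g, bin_mid = mids, count = as.integer(cnt),
               prop = as.integer(cnt) / sum(cnt))
  })
  do.call(rbind, out)
}
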