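#' Fixed-shape log-power spectrogram segment
#'
#' A 70 ms log-power spectrogram centered (by default) on the rendition
#' midpoint, used as the feature for nearest-neighbour syllable typing.
#' Renditions shorter than the segment are zero-padded, so all segments
#' share one shape.
#'
#' @param wave Waveform of the whole recording.
#' @param sr Sample rate, Hz.
#' @param onset_ms,offset_ms Rendition boundaries.
#' @param center_ms Segment center (default the rendition midpoint).
#' @param seg_ms Segment length, ms (default 70).
#' @param nfft FFT size (default 256); hop is `nfft / 2`.
#' @return Matrix of log10 power, frequencies in rows, frames in columns.
#' @export
spectrogram_segment <- function(wave, sr, onset_ms, offset_ms,
                                center_ms = NULL, seg_ms = 70, nfft = 256) {
  if (is.null(center_ms)) center_ms <- (onset_ms + offset_ms) / 2
  half <- round(seg_ms / 2 * sr / 1000)
  c0 <- round(center_ms * sr / 1000)
  idx <- (c0 - half + 1):(c0 + half)
  snip <- numeric(length(idx))
  ok <- idx >= 1 & idx <= length(wave)
  snip[ok] <- wave[idx[ok]]
  hop <- nfft / 2
  starts <- seq(1L, length(snip) - nfft + 1L, by = hop)
  win <- hanning_window(nfft)
  mat <- vapply(starts, function(s) {
    sp <- Mod(stats::fft(snip[s:(s + nfft - 1)] * win))^2
    sp[seq_len(nfft / 2)]
  }, numeric(nfft / 2))
  log10(mat + 1e-10)
}

#' Build syllable-type templates from an annotated dataset
#'
#' Samples labelled renditions from a generated (ground-truth) dataset and
#' stores their spectrogram segments as type templates. Experimental data
#' would instead use user-curated templates ([load_templates()]).
#'
#' @param dataset A [generate_dataset()] result with audio, or a list with
#'   `annotations` and `dir`.
#' @param n_per_label Template segments per type.
#' @param sr Sample rate of the audio.
#' @param seed Seed for the rendition sample.
#' @return An object of class `type_templates`: list of `label`, `segments`.
#' @export
build_templates <- function(dataset, n_per_label = 5, sr = 32000,
                            seed = 1L) {
  ann <- dataset$annotations
  waves <- day_waves(dataset)
  tpl <- list()
  with_seed(seed, {
    for (lab in unique(ann$label)) {
      rows <- ann[ann$label == lab, ]
      take <- rows[sample(nrow(rows), min(n_per_label, nrow(rows))), ]
      segs <- lapply(seq_len(nrow(take)), function(i) {
        r <- take[i, ]
        spectrogram_segment(waves[[as.character(r$day)]], sr, r$onset_ms,
                            r$offset_ms)
      })
      tpl[[length(tpl) + 1L]] <- list(label = lab, segments = segs)
    }
  })
  structure(tpl, class = "type_templates")
}

day_waves <- function(dataset) {
  waves <- lapply(dataset$wav, function(p) read_wav(p)$wave)
  names(waves) <- sub("^day_0*(\\d+)\\.wav$", "\\1", basename(dataset$wav))
  waves
}

#' Classify a spectrogram segment by k-nearest templates
#'
#' Majority label among the `k` template segments nearest in Euclidean
#' distance (on the flattened log-power matrices); ties are broken by the
#' smallest mean distance, then by label order.
#'
#' @param segment Matrix from [spectrogram_segment()].
#' @param templates A `type_templates` object.
#' @param k Number of neighbours (odd, >= 1).
#' @return The winning label (character).
#' @export
knn_classify <- function(segment, templates, k = 5) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (!length(templates)) stop("no templates supplied", call. = FALSE)
  v <- as.numeric(segment)
  labs <- character(0); dists <- numeric(0)
  for (tp in templates) {
    for (s in tp$segments) {
      labs <- c(labs, tp$label)
      dists <- c(dists, sqrt(sum((v - as.numeric(s))^2)))
    }
  }
  ord <- order(dists, labs)   # equal distances resolved by label order
  kk <- min(k, length(dists))
  top <- labs[ord[seq_len(kk)]]
  topd <- dists[ord[seq_len(kk)]]
  counts <- table(top)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1) {
    meand <- vapply(winners, function(l) mean(topd[top == l]), numeric(1))
    winners <- winners[meand == min(meand)]
    winners <- sort(winners)
  }
  winners[1]
}

#' Classify all renditions of a dataset
#'
#' @param dataset Dataset with audio (see [build_templates()]).
#' @param templates A `type_templates` object.
#' @param k Neighbours for [knn_classify()].
#' @param sr Sample rate.
#' @return The annotation data frame with a `label_knn` column.
#' @export
classify_renditions <- function(dataset, templates, k = 5, sr = 32000) {
  ann <- dataset$annotations
  waves <- day_waves(dataset)
  ann$label_knn <- vapply(seq_len(nrow(ann)), function(i) {
    r <- ann[i, ]
    seg <- spectrogram_segment(waves[[as.character(r$day)]], sr, r$onset_ms,
                               r$offset_ms)
    knn_classify(seg, templates, k)
  }, character(1))
  ann
}

#' Refine a lumped cluster pair by sequential context
#'
#' Spectrally close syllable types (e.g. a type and its one-semitone pitch
#' variant) can be lumped into a single cluster. When the two types live in
#' different sequential contexts, the lump can be resolved by the observed
#' preceding or following syllable: renditions whose predecessor (or
#' successor) matches a type's expected context are reassigned to that type.
#' Renditions matching neither context fall back to the nearest type pitch,
#' when pitch information is available.
#'
#' @param renditions Data frame with `label` (and `bout_id`, `onset_ms`;
#'   `median_pitch_hz` enables the pitch fallback).
#' @param pair Character of length 2: the two lumped labels.
#' @param context Named list: for each label of `pair`, a list with
#'   optional `pred` and/or `succ` expected context labels.
#' @param label_col Column holding the (lumped) labels.
#' @param ref_freq Reference frequency for the pitch fallback.
#' @param type_pitch Optional named semitone pitches of the two types for
#'   the fallback.
#' @return `renditions` with a `label_refined` column.
#' @export
refine_by_context <- function(renditions, pair, context,
                              label_col = "label", ref_freq = 600,
                              type_pitch = NULL) {
  stopifnot(length(pair) == 2)
  if (is.null(context) || !all(pair %in% names(context))) {
    stop("a context rule for both labels is required", call. = FALSE)
  }
  r <- as.data.frame(renditions)
  labs <- r[[label_col]]
  r$label_refined <- labs
  in_pair <- which(labs %in% pair)
  if (!length(in_pair)) {
    stop("neither label of the pair occurs", call. = FALSE)
  }
  ctx <- rendition_context(r, label_col)
  for (i in in_pair) {
    hit <- NA_character_
    for (lab in pair) {
      rule <- context[[lab]]
      ok_pred <- !is.null(rule$pred) && !is.na(ctx$pred[i]) &&
        ctx$pred[i] %in% rule$pred
      ok_succ <- !is.null(rule$succ) && !is.na(ctx$succ[i]) &&
        ctx$succ[i] %in% rule$succ
      if (ok_pred || ok_succ) { hit <- lab; break }
    }
    if (is.na(hit) && !is.null(type_pitch) &&
        !is.null(r$median_pitch_hz) && !is.na(r$median_pitch_hz[i])) {
      st <- semitone_offset(r$median_pitch_hz[i], ref_freq)
      hit <- names(type_pitch)[which.min(abs(st - type_pitch))]
    }
    if (!is.na(hit)) r$label_refined[i] <- hit
  }
  r
}

# preceding and following labels within each bout (NA at bout edges);
# bouts are identified per day, so bout ids may restart across days
rendition_context <- function(r, label_col = "label") {
  n <- nrow(r)
  pred <- rep(NA_character_, n)
  succ <- rep(NA_character_, n)
  if (is.null(r$bout_id)) r$bout_id <- 1L
  day <- if (is.null(r$day)) rep(0L, n) else r$day
  ord <- order(day, r$onset_ms)
  labs <- r[[label_col]]
  key <- paste(day, r$bout_id)
  key[is.na(r$bout_id)] <- NA
  for (b in unique(key[!is.na(key)])) {
    sel <- ord[key[ord] %in% b]
    if (length(sel) < 2) next
    pred[sel[-1]] <- labs[sel[-length(sel)]]
    succ[sel[-length(sel)]] <- labs[sel[-1]]
  }
  data.frame(pred = pred, succ = succ)
}

#' Percentage of renditions assigned to a type
#'
#' @param renditions Data frame with a `label` column (`NA` = unassigned).
#' @param label_col Column to assess.
#' @return Percentage in `[0, 100]`, `NA` (with a warning) for an empty set.
#' @export
percent_clustered <- function(renditions, label_col = "label") {
  labs <- as.data.frame(renditions)[[label_col]]
  if (!length(labs)) {
    warning("no renditions: percent clustered undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * mean(!is.na(labs))
}

#' Save or load a template store
#'
#' Templates are stored as one CSV matrix per segment plus a JSON manifest,
#' so user-curated template sets can be assembled by hand.
#'
#' @param templates A `type_templates` object.
#' @param dir Directory.
#' @return `dir` (save) or a `type_templates` object (load).
#' @export
save_templates <- function(templates, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (ti in seq_along(templates)) {
    tp <- templates[[ti]]
    files <- character(0)
    for (si in seq_along(tp$segments)) {
      f <- sprintf("tpl_%02d_%02d.csv", ti, si)
      utils::write.table(tp$segments[[si]], file.path(dir, f), sep = ",",
                         row.names = FALSE, col.names = FALSE)
      files <- c(files, f)
    }
    manifest[[length(manifest) + 1L]] <- list(label = tp$label,
                                              files = files)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_templates
#' @export
load_templates <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tpl <- lapply(manifest, function(m) {
    segs <- lapply(m$files, function(f) {
      as.matrix(utils::read.table(file.path(dir, f), sep = ","))
    })
    list(label = m$label, segments = segs)
  })
  structure(tpl, class = "type_templates")
}
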