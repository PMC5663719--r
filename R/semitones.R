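#' Pitch offset in semitones between two frequencies
#'
#' The semitone scale is logarithmic: one octave (a doubling of frequency)
#' spans 12 semitones. Pitch mismatches between source and target syllables
#' are expressed on this scale throughout the package.
#'
#' @param f Frequency in Hz. Vectorized.
#' @param f_ref Reference frequency in Hz.
#' @return Offset of `f` from `f_ref` in semitones, `12 * log2(f / f_ref)`.
#' @seealso [apply_shift()] for the inverse operation.
#' @examples
#' semitone_offset(880, 440) # one octave up = 12
#' apply_shift(440, 2)       # two semitones above concert A
#' @export
semitone_offset <- function(f, f_ref) {
  stopifnot(is.numeric(f), is.numeric(f_ref))
  if (any(f <= 0) || any(f_ref <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  12 * log2(f / f_ref)
}

#' Shift a frequency by a number of semitones
#'
#' @param f Frequency in Hz. Vectorized.
#' @param s Shift in semitones (positive = up).
#' @return `f * 2^(s / 12)`, in Hz.
#' @export
apply_shift <- function(f, s) {
  stopifnot(is.numeric(f), is.numeric(s))
  if (any(f <= 0)) stop("frequencies must be positive", call. = FALSE)
  f * 2^(s / 12)
}
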