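#' Fundamental frequency track (cumulative-mean-normalized difference)
#'
#' Estimates f0 once per hop (default every millisecond) from the
#' autocorrelation-family difference function
#' \deqn{d_t(\tau) = \sum_{j=t}^{t+W-1} (x_j - x_{j+\tau})^2,}
#' normalized by its cumulative mean,
#' \deqn{d'_t(\tau) = d_t(\tau)\,\tau / \sum_{k \le \tau} d_t(k),}
#' choosing the first dip of \eqn{d'} below the aperiodicity threshold
#' (falling back to the global minimum) and refining the lag by parabolic
#' interpolation of \eqn{d}. The value of \eqn{d'} at the chosen lag is
#' returned as the frame's aperiodicity; frames whose aperiodicity exceeds
#' the threshold are unvoiced and carry `NA` f0.
#'
#' The implementation is vectorized over lags (one cumulative sum per lag),
#' so cost scales as `O(N * sr / fmin)` rather than per-frame.
#'
#' @param x Numeric waveform.
#' @param sr Sample rate, Hz.
#' @param fmin,fmax Search band for f0, Hz (`fmin < fmax < sr/2`).
#' @param hop_ms Hop between frames, ms (default 1).
#' @param win_ms Analysis window, ms (default 25).
#' @param threshold Aperiodicity threshold (default 0.2): dips of the
#'   normalized difference below it count as periodic.
#' @return Data frame with `time_ms` (frame start), `f0_hz` (`NA` when
#'   unvoiced) and `aperiodicity` in `[0, ~1]`. Zero rows if the signal is
#'   shorter than one analysis window plus the largest lag.
#' @export
yin_f0 <- function(x, sr, fmin = 300, fmax = 4000, hop_ms = 1, win_ms = 25,
                   threshold = 0.2) {
  stopifnot(fmin < fmax, fmax < sr / 2, hop_ms > 0, win_ms > 0)
  W <- round(win_ms * sr / 1000)
  hop <- max(1L, round(hop_ms * sr / 1000))
  tau_min <- max(2L, floor(sr / fmax))
  tau_max <- ceiling(sr / fmin)
  N <- length(x)
  empty <- data.frame(time_ms = numeric(), f0_hz = numeric(),
                      aperiodicity = numeric())
  if (N < W + tau_max + 1L) return(empty)
  starts <- seq(1L, N - W - tau_max, by = hop)
  nf <- length(starts)
  D <- matrix(0, nf, tau_max)
  for (tau in seq_len(tau_max)) {
    e <- (x[1:(N - tau)] - x[(1 + tau):N])^2
    cs <- c(0, cumsum(e))
    D[, tau] <- cs[starts + W] - cs[starts]
  }
  cum <- t(apply(D, 1, cumsum))
  Dp <- D * rep(seq_len(tau_max), each = nf) /
    pmax(cum, .Machine$double.xmin)
  f0 <- rep(NA_real_, nf)
  ap <- rep(NA_real_, nf)
  idx <- tau_min:tau_max
  for (i in seq_len(nf)) {
    dp <- Dp[i, ]
    below <- idx[dp[idx] < threshold]
    if (length(below)) {
      t0 <- below[1]
      while (t0 < tau_max && dp[t0 + 1] < dp[t0]) t0 <- t0 + 1L
    } else {
      t0 <- idx[which.min(dp[idx])]
    }
    ap[i] <- dp[t0]
    delta <- 0
    if (t0 > 1L && t0 < tau_max) {
      a <- D[i, t0 - 1L]; b <- D[i, t0]; cc <- D[i, t0 + 1L]
      den <- a - 2 * b + cc
      if (den > 0) delta <- 0.5 * (a - cc) / den
      if (abs(delta) > 1) delta <- 0
    }
    f0[i] <- sr / (t0 + delta)
  }
  f0[ap >= threshold] <- NA_real_
  data.frame(time_ms = (starts - 1) / sr * 1000, f0_hz = f0,
             aperiodicity = ap)
}
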