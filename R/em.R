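#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Plain expectation-maximization on pitch samples (semitones): E-step
#' responsibilities, M-step weight/mean/variance updates, until the
#' log-likelihood improvement falls below `tol` or `max_iter` is reached.
#' Variances are clamped at `var_floor` (component collapse is reported
#' via the `collapsed` flag and a warning).
#'
#' @param x Numeric samples (length >= K).
#' @param K Number of components (default: length of `init_means`).
#' @param init_means Initial component means; in the target-matching
#'   analogy these are the learner's own syllable and call pitches.
#' @param init_vars Initial variances (recycled; default 1).
#' @param init_weights Initial weights (default uniform).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum iterations (default 500).
#' @param var_floor Variance floor in semitones^2 (default 1e-4).
#' @return An object of class `gmm_state`: `weights`, `means`, `variances`,
#'   `responsibilities` (n x K, rows sum to 1), `log_likelihood`,
#'   `ll_trace`, `iterations`, `converged`, `collapsed`.
#' @export
em_fit <- function(x, K = length(init_means), init_means,
                   init_vars = 1, init_weights = NULL, tol = 1e-8,
                   max_iter = 500, var_floor = 1e-4) {
  stopifnot(length(x) >= K, var_floor > 0, K >= 1)
  if (missing(init_means)) init_means <- stats::quantile(x, (1:K) / (K + 1))
  mu <- as.numeric(init_means)
  stopifnot(length(mu) == K)
  v <- rep_len(as.numeric(init_vars), K)
  w <- if (is.null(init_weights)) rep(1 / K, K) else init_weights / sum(init_weights)
  n <- length(x)
  ll_trace <- numeric(0)
  collapsed <- rep(FALSE, K)
  r <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], sqrt(v[k])),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rs <- rowSums(dens)
    rs[rs <= 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    r <- dens / rs
    nk <- colSums(r)
    w <- nk / n
    for (k in seq_len(K)) {
      if (nk[k] < 1e-12) { collapsed[k] <- TRUE; next }
      mu[k] <- sum(r[, k] * x) / nk[k]
      vk <- sum(r[, k] * (x - mu[k])^2) / nk[k]
      if (vk < var_floor) collapsed[k] <- TRUE
      v[k] <- max(vk, var_floor)
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol) break
  }
  if (any(collapsed)) {
    warning("component variance clamped at the floor", call. = FALSE)
  }
  structure(list(weights = w, means = mu, variances = v,
                 responsibilities = r, log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, iterations = length(ll_trace),
                 converged = length(ll_trace) < max_iter,
                 collapsed = collapsed),
            class = "gmm_state")
}

#' @export
print.gmm_state <- function(x, ...) {
  cat("<gmm_state> K =", length(x$means), " logLik =",
      format(x$log_likelihood), if (x$converged) "(converged)" else
        "(max_iter)", "\n")
  print(data.frame(weight = x$weights, mean = x$means,
                   variance = x$variances))
  invisible(x)
}

#' Map mixture components to target syllables
#'
#' Each component -- initialized at one of the learner's own syllable or
#' call pitches -- is mapped to the target pitch nearest its converged
#' mean. A non-injective outcome (two components tracking one target) is
#' flagged.
#'
#' @param state A [em_fit()] result.
#' @param target_pitches Numeric target pitches (semitones).
#' @param target_labels Optional target labels (default indices).
#' @param motor_labels Optional labels of the motor precursors seeding the
#'   components (default component indices).
#' @return List with `mapping` (named character), `injective` flag, and
#'   `means`.
#' @export
assign_by_responsibility <- function(state, target_pitches,
                                     target_labels = NULL,
                                     motor_labels = NULL) {
  stopifnot(inherits(state, "gmm_state"))
  if (is.null(target_labels)) {
    target_labels <- as.character(seq_along(target_pitches))
  }
  if (is.null(motor_labels)) {
    motor_labels <- as.character(seq_along(state$means))
  }
  idx <- vapply(state$means, function(m) which.min(abs(m - target_pitches)),
                integer(1))
  list(mapping = stats::setNames(target_labels[idx], motor_labels),
       injective = !anyDuplicated(idx), means = state$means)
}

# fixed-bandwidth mode seeking on weighted samples: EM mean updates for a
# single Gaussian of fixed variance against the residual data; if the
# kernel sees no residual mass the component jumps to the residual centroid
mode_seek <- function(x, w, mu, bandwidth, max_iter = 200) {
  for (i in seq_len(max_iter)) {
    k <- w * stats::dnorm(x, mu, bandwidth)
    if (sum(k) < 1e-12 * max(sum(w), 1e-12)) {
      if (sum(w) <= 0) break
      mu <- sum(w * x) / sum(w)
      next
    }
    mu_new <- sum(k * x) / sum(k)
    if (abs(mu_new - mu) < 1e-10) return(mu_new)
    mu <- mu_new
  }
  mu
}

#' Greedy-competitive target matching as staged Gaussian-mixture EM
#'
#' Expresses the winner-take-all competitive matcher in mixture-model
#' terms. Components enter in the order the learner's precursors do: motif
#' syllables first, calls afterwards (calls are recruited late in
#' development). Each entering component runs fixed-variance EM (mode
#' seeking with a kernel at the pitch-jitter scale) on the renditions not
#' yet claimed, so it climbs onto the nearest remaining mode of the target
#' pitch distribution; renditions within the occupancy radius `epsilon` of
#' a converged component are then claimed (the occupied chair is removed
#' from the game). A final plain [em_fit()] polish refines all components
#' jointly, and [assign_by_responsibility()] reads off the mapping.
#'
#' @param x Target-song pitch renditions, semitones.
#' @param motor_pitches Named pitches of the motif syllables (semitones).
#' @param call_pitches Named pitches of the call pool.
#' @param target_pitches Named pitches of the target syllables the mapping
#'   is read against.
#' @param bandwidth Mode-seeking kernel bandwidth, semitones (default 0.5).
#' @param epsilon Occupancy radius, semitones (default 1.5).
#' @param polish Run the final joint EM refinement?
#' @return List with `mapping` (motor/call label -> target label),
#'   `injective`, `phase_means` (after mode seeking), `state` (final
#'   `gmm_state`, `NULL` when `polish = FALSE`).
#' @export
em_match_targets <- function(x, motor_pitches, call_pitches = NULL,
                             target_pitches, bandwidth = 0.5,
                             epsilon = 1.5, polish = TRUE) {
  init <- c(motor_pitches, call_pitches)
  stopifnot(length(init) >= 1, length(x) >= length(init))
  w <- rep(1, length(x))
  mus <- numeric(length(init))
  for (i in seq_along(init)) {
    mu <- mode_seek(x, w, init[[i]], bandwidth)
    mus[i] <- mu
    w[abs(x - mu) < epsilon] <- 0
  }
  state <- NULL
  means <- mus
  if (polish) {
    state <- em_fit(x, init_means = mus, init_vars = bandwidth^2)
    means <- state$means
  }
  fake <- if (is.null(state)) {
    structure(list(means = means), class = "gmm_state")
  } else state
  res <- assign_by_responsibility(fake, unname(target_pitches),
                                  names(target_pitches) %||%
                                    as.character(seq_along(target_pitches)),
                                  names(init) %||%
                                    as.character(seq_along(init)))
  list(mapping = res$mapping, injective = res$injective,
       phase_means = mus, state = state)
}
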