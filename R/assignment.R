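#' Syllable-to-target assignment problem
#'
#' Collects the harmonic (pitch-bearing) motor syllables of a task's source
#' song -- optionally padded with repertoire calls -- and the harmonic target
#' syllables, together with the spectral cost matrix of absolute semitone
#' distances. Non-harmonic syllables are matched by label identity outside
#' the assignment (the tasks' mismatches are pitch-only).
#'
#' @param task An [imitation_task()].
#' @param call_pitches Optional named numeric vector of call pitches
#'   (semitones) padding the motor side.
#' @return An object of class `assignment_problem` with `motor_labels`,
#'   `motor_pitches`, `motor_positions` (motif index, `NA` for calls),
#'   `target_labels`, `target_pitches`, `target_positions`, `cost`.
#' @export
assignment_problem <- function(task, call_pitches = NULL) {
  stopifnot(inherits(task, "imitation_task"))
  sp <- motif_pitches(task$source)
  tp <- motif_pitches(task$target)
  ms <- which(!is.na(sp) & !duplicated(names(sp)))
  ts <- which(!is.na(tp) & !duplicated(names(tp)))
  motor_labels <- names(sp)[ms]
  motor_pitches <- unname(sp[ms])
  motor_positions <- ms
  if (!is.null(call_pitches)) {
    motor_labels <- c(motor_labels, names(call_pitches))
    motor_pitches <- c(motor_pitches, unname(call_pitches))
    motor_positions <- c(motor_positions, rep(NA_integer_,
                                              length(call_pitches)))
  }
  structure(list(motor_labels = motor_labels,
                 motor_pitches = motor_pitches,
                 motor_positions = motor_positions,
                 target_labels = names(tp)[ts],
                 target_pitches = unname(tp[ts]),
                 target_positions = ts,
                 cost = spectral_costs(motor_pitches, unname(tp[ts]))),
            class = "assignment_problem")
}

#' Spectral cost matrix
#'
#' @param motor_pitches,target_pitches Pitches in semitones.
#' @return Matrix of absolute semitone distances, motor syllables in rows.
#' @export
spectral_costs <- function(motor_pitches, target_pitches) {
  stopifnot(all(is.finite(motor_pitches)), all(is.finite(target_pitches)))
  abs(outer(motor_pitches, target_pitches, `-`))
}

new_assignment_result <- function(mapping, cost, method,
                                  sequence_cost = NA_real_, lambda = NA_real_,
                                  log = NULL) {
  structure(list(mapping = mapping, spectral_cost = cost,
                 sequence_cost = sequence_cost,
                 total_cost = if (is.na(lambda)) cost else
                   cost + lambda * sequence_cost,
                 lambda = lambda, method = method, log = log),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result ", x$method, ">\n", sep = "")
  m <- x$mapping
  cat("  ", paste(names(m), "->", ifelse(is.na(m), "(unmatched)", m),
                  collapse = ", "), "\n", sep = "")
  cat("  spectral cost ", format(x$spectral_cost), "\n", sep = "")
  if (!is.na(x$sequence_cost)) {
    cat("  sequence cost ", x$sequence_cost, " (lambda ", x$lambda,
        ", total ", format(x$total_cost), ")\n", sep = "")
  }
  invisible(x)
}

#' Optimal linear assignment
#'
#' Minimum-cost one-to-one matching of motor syllables (rows) to target
#' syllables (columns). When there are more motor syllables than targets,
#' the surplus stays unmatched (equivalently, dummy targets of zero cost);
#' every target is matched whenever `nrow >= ncol`. Among cost ties the
#' lexicographically smallest mapping is returned.
#'
#' @param cost Numeric cost matrix (rows: motor, columns: targets), or an
#'   [assignment_problem()].
#' @return An `assignment_result`; `mapping` is an integer vector of target
#'   column indices per row (`NA` = unmatched), named by motor labels when
#'   available.
#' @export
solve_lap <- function(cost) {
  prob <- NULL
  if (inherits(cost, "assignment_problem")) {
    prob <- cost; cost <- prob$cost
  }
  if (!length(cost)) {
    return(new_assignment_result(integer(0), 0, "lap"))
  }
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr >= nc) {
    # solve with targets as agents so that every target is matched
    sol <- clue::solve_LSAP(t(cost))
    mapping <- rep(NA_integer_, nr)
    mapping[as.integer(sol)] <- seq_len(nc)
  } else {
    sol <- clue::solve_LSAP(cost)
    mapping <- as.integer(sol)
  }
  mapping <- canonicalize_ties(cost, mapping)
  total <- mapping_cost(cost, mapping)
  if (!is.null(prob)) names(mapping) <- prob$motor_labels
  new_assignment_result(mapping, total, "lap")
}

mapping_cost <- function(cost, mapping) {
  i <- which(!is.na(mapping))
  sum(cost[cbind(i, mapping[i])])
}

# deterministic tie-break: pairwise swaps toward the lexicographically
# smallest mapping among equal-cost optima
canonicalize_ties <- function(cost, mapping, tol = 1e-9) {
  n <- length(mapping)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mi <- mapping[i]; mj <- mapping[j]
        old <- sum(cost[cbind(c(i, j), c(mi, mj))], na.rm = TRUE)
        new <- sum(cost[cbind(c(i, j), c(mj, mi))], na.rm = TRUE)
        swap_less <- (is.na(mi) && !is.na(mj)) ||
          (!is.na(mi) && !is.na(mj) && mj < mi)
        if (abs(new - old) < tol && swap_less) {
          mapping[c(i, j)] <- c(mj, mi)
          changed <- TRUE
        }
      }
    }
    if (!changed) return(mapping)
  }
}

#' Brute-force linear assignment (testing oracle)
#'
#' Exhaustive minimum over all injective motor-to-target mappings that
#' match every target. Refuses more than 8 targets.
#'
#' @param cost Numeric cost matrix (rows: motor, columns: targets;
#'   `nrow >= ncol`).
#' @return An `assignment_result` (lexicographically smallest optimum).
#' @export
solve_lap_bruteforce <- function(cost) {
  if (!length(cost)) return(new_assignment_result(integer(0), 0,
                                                  "bruteforce"))
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr >= nc)
  if (nc > 8) stop("brute force limited to 8 targets", call. = FALSE)
  best <- NULL; best_cost <- Inf
  rec <- function(t_idx, used, acc, partial) {
    if (partial > best_cost + 1e-12) return()
    if (t_idx > nc) {
      mapping <- rep(NA_integer_, nr)
      mapping[acc] <- seq_len(nc)
      if (partial < best_cost - 1e-12 ||
          (partial < best_cost + 1e-12 && !is.null(best) &&
           lex_less(mapping, best))) {
        best <<- mapping; best_cost <<- min(best_cost, partial)
      }
      return()
    }
    for (r in seq_len(nr)) {
      if (used[r]) next
      used[r] <- TRUE
      rec(t_idx + 1, used, c(acc, r), partial + cost[r, t_idx])
      used[r] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nr), integer(0), 0)
  new_assignment_result(best, mapping_cost(cost, best), "bruteforce")
}

lex_less <- function(a, b) {
  av <- ifelse(is.na(a), Inf, a); bv <- ifelse(is.na(b), Inf, b)
  d <- which(av != bv)
  length(d) > 0 && av[d[1]] < bv[d[1]]
}

#' Sequence cost of an assignment
#'
#' Number of target-song transitions (bigrams, including the motif wrap)
#' the learner must newly acquire if its motor syllables are relabelled by
#' their assigned targets while keeping the source order. This counts
#' syntax work as the acquisition of individual transitions, matching how
#' syntax learning proceeds (one transition at a time), rather than as an
#' edit distance.
#'
#' @param mapping Named character vector, source label -> target label.
#'   Source syllables absent from the mapping keep their own label.
#' @param source_motif,target_motif Character vectors of motif labels, or
#'   [song_model()] objects.
#' @return Integer count of unacquired target bigrams.
#' @export
sequence_cost <- function(mapping, source_motif, target_motif) {
  src <- if (inherits(source_motif, "song_model"))
    motif_labels(source_motif) else source_motif
  tgt <- if (inherits(target_motif, "song_model"))
    motif_labels(target_motif) else target_motif
  if (length(tgt) < 2) return(0L)
  relab <- ifelse(src %in% names(mapping), unname(mapping[src]), src)
  performed <- target_bigrams(relab)
  needed <- target_bigrams(tgt)
  sum(!(needed %in% performed))
}

#' Combined spectral-plus-sequence (quadratic) assignment cost
#'
#' Total cost `spectral + lambda * sequence` of a full source-to-target
#' mapping: the spectral term sums semitone distances over matched harmonic
#' pairs, the sequence term counts unacquired target transitions
#' ([sequence_cost()]). With `lambda = 0` this is the linear-assignment
#' objective; interaction between assigned positions enters only through
#' the sequence term, which is what makes the joint problem quadratic.
#'
#' @param task An [imitation_task()].
#' @param mapping Named character vector, source label -> target label
#'   (harmonic syllables; non-harmonic syllables map by identity).
#' @param lambda Sequence-cost weight (>= 0).
#' @param call_pitches Optional named call pitches (semitones) for mappings
#'   that recruit calls.
#' @return List with `spectral`, `sequence`, `total`.
#' @export
qap_total <- function(task, mapping, lambda = 1, call_pitches = NULL) {
  stopifnot(lambda >= 0)
  sp <- c(motif_pitches(task$source), call_pitches)
  sp <- sp[!duplicated(names(sp))]
  tp <- motif_pitches(task$target)
  tp <- tp[!duplicated(names(tp))]
  spectral <- 0
  for (m in names(mapping)) {
    t <- mapping[[m]]
    if (!is.na(sp[m]) && t %in% names(tp) && !is.na(tp[t])) {
      spectral <- spectral + abs(unname(sp[m]) - unname(tp[t]))
    }
  }
  full <- full_mapping(task, mapping)
  seqc <- sequence_cost(full, task$source, task$target)
  list(spectral = spectral, sequence = seqc,
       total = spectral + lambda * seqc)
}

# complete a harmonic mapping with identity matches for non-harmonic labels
full_mapping <- function(task, mapping) {
  src <- unique(motif_labels(task$source))
  tgt <- unique(motif_labels(task$target))
  extra <- setdiff(intersect(src, tgt), names(mapping))
  c(mapping, stats::setNames(extra, extra))
}

#' Exhaustive minimizer of the combined cost
#'
#' Enumerates all injective assignments of the harmonic motor syllables
#' (plus calls) to the harmonic targets (at most 8) and returns the mapping
#' minimizing [qap_total()].
#'
#' @inheritParams qap_total
#' @return List with `mapping` (named character), `spectral`, `sequence`,
#'   `total`.
#' @export
qap_minimize <- function(task, lambda = 1, call_pitches = NULL) {
  prob <- assignment_problem(task, call_pitches)
  nt <- length(prob$target_labels)
  if (nt > 8) stop("exhaustive search limited to 8 targets", call. = FALSE)
  nm <- length(prob$motor_labels)
  stopifnot(nm >= nt)
  best <- NULL; best_total <- Inf
  rec <- function(t_idx, used, acc) {
    if (t_idx > nt) {
      mapping <- stats::setNames(prob$target_labels,
                                 prob$motor_labels[acc])
      mapping <- mapping[order(match(names(mapping), prob$motor_labels))]
      res <- qap_total(task, mapping, lambda, call_pitches)
      if (res$total < best_total - 1e-12) {
        best <<- c(res, list(mapping = mapping))
        best_total <<- res$total
      }
      return()
    }
    for (m in seq_len(nm)) {
      if (used[m]) next
      used[m] <- TRUE
      rec(t_idx + 1, used, c(acc, m))
      used[m] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nm), integer(0))
  best
}

#' Greedy-competitive ("musical chairs") target assignment
#'
#' Iterative winner-take-all dynamics over an [assignment_problem()]:
#'
#' 1. every unassigned motif syllable selects its spectrally nearest
#'    unoccupied target (exact ties, within `1e-9` semitones, are broken
#'    uniformly at random under `tie_seed`);
#' 2. when several syllables select one target, the nearest wins and the
#'    losers reselect among the remaining targets;
#' 3. a won target is occupied and excluded from further selection;
#' 4. targets left vacant after all motif syllables are placed recruit the
#'    nearest available call.
#'
#' The result is injective and covers every target whenever enough motor
#' precursors exist; otherwise the result is flagged partial. The
#' `occupancy_radius` is carried in the event log for use by the
#' developmental simulator (a target counts as matched once its occupant's
#' pitch is within this radius); it does not change the static mapping.
#' With `compete = "convergence"` the competitive exclusion is applied
#' only once a winner has converged; for the static solution the resulting
#' mapping is identical and only the logged event order differs.
#'
#' @param problem An [assignment_problem()] (or an [imitation_task()], in
#'   which case `call_pitches` pads the motor side).
#' @param tie_seed Seed for random tie-breaks.
#' @param occupancy_radius Occupancy radius in semitones (default 0.5).
#' @param compete `"selection"` (default) or `"convergence"`.
#' @param call_pitches Used when `problem` is a task.
#' @return An `assignment_result` with an event `log` data frame
#'   (`step`, `event`, `motor`, `target`, `distance`) and a `partial` flag
#'   in `log` attributes when targets stay vacant.
#' @export
musical_chairs <- function(problem, tie_seed = NULL, occupancy_radius = 0.5,
                           compete = c("selection", "convergence"),
                           call_pitches = NULL) {
  compete <- match.arg(compete)
  if (inherits(problem, "imitation_task")) {
    problem <- assignment_problem(problem, call_pitches)
  }
  stopifnot(inherits(problem, "assignment_problem"))
  cost <- problem$cost
  nm <- length(problem$motor_labels)
  nt <- length(problem$target_labels)
  is_call <- is.na(problem$motor_positions)
  mapping <- rep(NA_integer_, nm)
  occupied <- rep(FALSE, nt)
  log <- list()
  step <- 0L
  with_seed(tie_seed, {
    # phase 1: motif syllables compete
    free_motor <- which(!is_call)
    while (length(free_motor) && any(!occupied)) {
      step <- step + 1L
      picks <- vapply(free_motor, function(m) {
        cands <- which(!occupied)
        d <- cost[m, cands]
        tied <- cands[d < min(d) + 1e-9]
        if (length(tied) > 1) sample(tied, 1) else tied
      }, integer(1))
      for (t in unique(picks)) {
        contenders <- free_motor[picks == t]
        d <- cost[contenders, t]
        tied <- contenders[d < min(d) + 1e-9]
        winner <- if (length(tied) > 1) sample(tied, 1) else tied
        for (m in contenders) {
          log[[length(log) + 1L]] <- data.frame(
            step = step,
            event = if (m == winner) "select" else "displaced",
            motor = problem$motor_labels[m],
            target = problem$target_labels[t], distance = cost[m, t])
        }
        mapping[winner] <- t
        occupied[t] <- TRUE
      }
      free_motor <- which(!is_call & is.na(mapping))
    }
    # phase 2: vacant targets recruit the nearest available call
    for (t in order(problem$target_positions)) {
      if (occupied[t]) next
      calls <- which(is_call & is.na(mapping))
      step <- step + 1L
      if (!length(calls)) {
        log[[length(log) + 1L]] <- data.frame(
          step = step, event = "vacant", motor = NA_character_,
          target = problem$target_labels[t], distance = NA_real_)
        next
      }
      d <- cost[calls, t]
      tied <- calls[d < min(d) + 1e-9]
      winner <- if (length(tied) > 1) sample(tied, 1) else tied
      mapping[winner] <- t
      occupied[t] <- TRUE
      log[[length(log) + 1L]] <- data.frame(
        step = step, event = "recruit",
        motor = problem$motor_labels[winner],
        target = problem$target_labels[t],
        distance = cost[winner, t])
    }
  })
  log <- do.call(rbind, log)
  partial <- any(!occupied)
  if (partial) {
    warning("targets left vacant: no available call", call. = FALSE)
  }
  names(mapping) <- problem$motor_labels
  res <- new_assignment_result(mapping, mapping_cost(cost, mapping),
                               paste0("musical_chairs/", compete),
                               log = log)
  res$partial <- partial
  res$occupancy_radius <- occupancy_radius
  res
}

#' Predicted source-to-target mapping under a learning strategy
#'
#' * `"global"`: motor syllables are matched to the target syllables at the
#'   same motif position (temporal correspondence); targets beyond the
#'   source length stay vacant and recruit calls.
#' * `"greedy"`: the winner-take-all competitive mapping of
#'   [musical_chairs()].
#' * `"chunk"`: the source motif is split into consecutive bigrams (plus a
#'   final unigram when odd) and each chunk is matched to the target chunk
#'   minimizing the summed spectral cost, ties broken by target position.
#'
#' @param task An [imitation_task()].
#' @param strategy `"global"`, `"greedy"` or `"chunk"`.
#' @param call_pitches Named call pitches (semitones) available for
#'   recruitment.
#' @param tie_seed Tie-break seed for the greedy strategy.
#' @param mismatch_penalty Spectral cost charged when a chunk pairs
#'   syllables of different kinds or labels without pitch (default 12
#'   semitones, i.e. an octave: effectively forbidding such pairings).
#' @return Named character vector: source label (or call id) -> target
#'   label. Unmatched motor syllables are absent.
#' @export
strategy_predict <- function(task, strategy = c("global", "greedy", "chunk"),
                             call_pitches = NULL, tie_seed = NULL,
                             mismatch_penalty = 12) {
  strategy <- match.arg(strategy)
  src <- motif_labels(task$source)
  tgt <- motif_labels(task$target)
  sp <- c(motif_pitches(task$source), call_pitches)
  tp <- motif_pitches(task$target)
  if (strategy == "global") {
    n <- min(length(src), length(tgt))
    mapping <- stats::setNames(tgt[seq_len(n)], src[seq_len(n)])
    mapping <- mapping[!duplicated(names(mapping))]
    vacant <- setdiff(tgt, unname(mapping))
    vacant <- vacant[!is.na(tp[vacant])]
    mapping <- c(mapping, recruit_calls(vacant, tp, call_pitches))
    return(mapping)
  }
  if (strategy == "greedy") {
    res <- musical_chairs(task, tie_seed = tie_seed,
                          call_pitches = call_pitches)
    prob <- assignment_problem(task, call_pitches)
    m <- res$mapping[!is.na(res$mapping)]
    mapping <- stats::setNames(prob$target_labels[m], names(m))
    return(c(mapping, identity_part(task, mapping)))
  }
  # chunk: consecutive source bigrams vs all adjacent target bigrams
  chunks <- split(seq_along(src), ceiling(seq_along(src) / 2))
  tpairs <- cbind(seq_along(tgt), c(seq_along(tgt)[-1], 1L))
  used <- rep(FALSE, length(tgt))
  syl_cost <- function(s, t) {
    if (!is.na(sp[s]) && !is.na(tp[t])) return(abs(sp[s] - tp[t]))
    if (is.na(sp[s]) && is.na(tp[t]) && s == t) return(0)
    mismatch_penalty
  }
  mapping <- character(0)
  for (ch in chunks) {
    s_lab <- src[ch]
    if (length(ch) == 2) {
      costs <- apply(tpairs, 1, function(pr) {
        if (any(used[pr])) return(Inf)
        syl_cost(s_lab[1], tgt[pr[1]]) + syl_cost(s_lab[2], tgt[pr[2]])
      })
      best <- which.min(costs)   # ties: first (earliest target position)
      pr <- tpairs[best, ]
      mapping[s_lab] <- tgt[pr]
      used[pr] <- TRUE
    } else {
      costs <- vapply(seq_along(tgt), function(t) {
        if (used[t]) return(Inf)
        syl_cost(s_lab, tgt[t])
      }, numeric(1))
      t <- which.min(costs)
      mapping[s_lab] <- tgt[t]
      used[t] <- TRUE
    }
  }
  vacant <- tgt[!used & !is.na(tp[tgt])]
  c(mapping, recruit_calls(vacant, tp, call_pitches))
}

recruit_calls <- function(vacant, tp, call_pitches) {
  out <- character(0)
  for (v in vacant) {
    avail <- setdiff(names(call_pitches), names(out))
    if (!length(avail)) break
    d <- abs(call_pitches[avail] - tp[v])
    out[avail[which.min(d)]] <- v
  }
  out
}

identity_part <- function(task, mapping) {
  src <- unique(motif_labels(task$source))
  tgt <- unique(motif_labels(task$target))
  extra <- setdiff(intersect(src, tgt), names(mapping))
  stats::setNames(extra, extra)
}
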