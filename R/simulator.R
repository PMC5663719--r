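#' Simulation parameters for developmental trajectories
#'
#' Dynamics of a simulated learner after the switch to target tutoring.
#' Pitch approaches the assigned target exponentially; missing target
#' transitions are acquired sequentially (one at a time), each entering the
#' grammar at a usage that ramps up and saturates below 1 (newly acquired
#' transitions are performed in combination with the existing source
#' transitions); vacant-target calls are recruited after a lag.
#'
#' @param pitch_rate Exponential approach rate constant, per day (default
#'   0.2: half the remaining pitch error is corrected every ~3.5 days).
#' @param pitch_noise_sd Day-level pitch wobble, semitones (on top of the
#'   per-rendition jitter of [synth_config()]).
#' @param occupancy_radius Semitones within which a target counts as
#'   matched (default 0.5).
#' @param p_transition_acquire Per-day probability of acquiring the next
#'   missing target transition (default 0.05).
#' @param transition_ramp_days Time constant of the usage ramp of an
#'   acquired transition, days.
#' @param usage_max Saturating usage probability of an acquired transition
#'   (default 0.9: source transitions persist at endpoint).
#' @param recruitment_lag Days before a recruited call starts shifting
#'   toward its target.
#' @param n_days Days simulated (day 0 = switch).
#' @param renditions_per_day Motif renditions per day (passed to the
#'   stream generator).
#' @param call_pitch Named numeric: repertoire call pitches in semitones
#'   (default one call at -3.5).
#' @param seed Seed for the whole simulation.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(pitch_rate = 0.2, pitch_noise_sd = 0.05,
                       occupancy_radius = 0.5,
                       p_transition_acquire = 0.05,
                       transition_ramp_days = 5, usage_max = 0.9,
                       recruitment_lag = 5, n_days = 40,
                       renditions_per_day = 60,
                       call_pitch = c(call1 = -3.5), seed = NULL) {
  stopifnot(pitch_rate >= 0, pitch_noise_sd >= 0, occupancy_radius > 0,
            p_transition_acquire >= 0, p_transition_acquire <= 1,
            usage_max >= 0, usage_max <= 1, n_days >= 1)
  structure(list(pitch_rate = pitch_rate, pitch_noise_sd = pitch_noise_sd,
                 occupancy_radius = occupancy_radius,
                 p_transition_acquire = p_transition_acquire,
                 transition_ramp_days = transition_ramp_days,
                 usage_max = usage_max, recruitment_lag = recruitment_lag,
                 n_days = n_days, renditions_per_day = renditions_per_day,
                 call_pitch = call_pitch, seed = seed),
            class = "sim_params")
}

#' Simulate a developmental learning trajectory
#'
#' Day 0 starts from a mastered source song. The syllable-to-target
#' assignment is fixed on day 0 by [strategy_predict()]; pitches then move
#' toward their assigned targets by exponential approach, recruited calls
#' join after `recruitment_lag` days, and missing target transitions are
#' acquired sequentially and mixed into the grammar with a ramping usage.
#' Renditions are emitted through [generate_rendition_stream()], so the
#' trajectory carries both the observable stream and its ground truth.
#'
#' @param task An [imitation_task()].
#' @param strategy `"global"`, `"greedy"` or `"chunk"`.
#' @param params A [sim_params()].
#' @param config A [synth_config()]; its `renditions_per_day` and `seed`
#'   are overridden by `params`.
#' @return An object of class `learning_trajectory`: list with
#'   `renditions`, `truth`, `assignment`, `events`, `task`, `strategy`,
#'   `params`.
#' @export
simulate_learning <- function(task, strategy = "greedy",
                              params = sim_params(),
                              config = synth_config()) {
  stopifnot(inherits(task, "imitation_task"), inherits(params, "sim_params"))
  config$renditions_per_day <- params$renditions_per_day
  config$seed <- NULL
  with_seed(params$seed, {
    chairs_log <- NULL
    mapping <- if (strategy == "greedy") {
      res <- musical_chairs(task, call_pitches = params$call_pitch)
      chairs_log <- res$log
      prob <- assignment_problem(task, params$call_pitch)
      m <- res$mapping[!is.na(res$mapping)]
      mp <- stats::setNames(prob$target_labels[m], names(m))
      c(mp, identity_part(task, mp))
    } else {
      strategy_predict(task, strategy, call_pitches = params$call_pitch)
    }
    truth <- build_truth(task, mapping, params)
    stream <- generate_rendition_stream(task, truth, params$n_days, config)
    structure(list(renditions = stream, truth = truth,
                   assignment = mapping,
                   events = list(chairs = chairs_log,
                                 acquired = attr(truth, "acquired"),
                                 recruited = attr(truth, "recruited")),
                   task = task, strategy = strategy, params = params),
              class = "learning_trajectory")
  })
}

#' @export
print.learning_trajectory <- function(x, ...) {
  cat("<learning_trajectory> task", x$task$task_id, "strategy", x$strategy,
      "\n  ", nrow(x$renditions), "renditions over",
      length(unique(x$renditions$day)), "days\n")
  m <- x$assignment
  cat("  assignment:", paste(names(m), "->", m, collapse = ", "), "\n")
  invisible(x)
}

# ground truth of a simulated learner under a fixed assignment
build_truth <- function(task, mapping, params) {
  n_days <- params$n_days
  days <- seq_len(n_days) - 1L
  src_labs <- unique(motif_labels(task$source))
  sp <- motif_pitches(task$source)[src_labs]
  tp <- motif_pitches(task$target)
  tp <- tp[!duplicated(names(tp))]
  calls <- params$call_pitch
  call_ids <- names(calls)

  # pitch trajectories: exponential approach toward the assigned target
  pitch <- matrix(rep(sp, each = n_days), nrow = n_days,
                  dimnames = list(NULL, src_labs))
  for (l in src_labs) {
    t <- mapping[l]
    if (is.na(sp[l]) || is.na(t) || is.null(t) || !(t %in% names(tp)) ||
        is.na(tp[t])) next
    pitch[, l] <- tp[t] + (sp[l] - tp[t]) * exp(-params$pitch_rate * days)
  }
  if (params$pitch_noise_sd > 0) {
    harm <- colnames(pitch)[!is.na(pitch[1, ])]
    pitch[, harm] <- pitch[, harm] +
      stats::rnorm(n_days * length(harm), 0, params$pitch_noise_sd)
  }

  # recruited calls: flat until the lag, then exponential toward target
  call_mat <- NULL
  recruited <- character(0)
  if (length(calls)) {
    call_mat <- matrix(rep(unname(calls), each = n_days), nrow = n_days,
                       dimnames = list(NULL, call_ids))
    for (cid in call_ids) {
      t <- mapping[cid]
      if (is.na(t) || is.null(t) || !(t %in% names(tp)) || is.na(tp[t])) next
      recruited <- c(recruited, cid)
      dd <- pmax(days - params$recruitment_lag, 0)
      on <- days >= params$recruitment_lag
      call_mat[on, cid] <- tp[t] +
        (calls[cid] - tp[t]) * exp(-params$pitch_rate * dd[on])
    }
  }

  # grammar: the target motif relabelled into motor lineages tells which
  # transitions must be acquired
  inv <- stats::setNames(names(mapping), unname(mapping))
  tgt_labs <- motif_labels(task$target)
  motor_order <- ifelse(tgt_labs %in% names(inv), inv[tgt_labs], tgt_labs)
  all_labs <- unique(c(src_labs, call_ids))
  src_tm <- cycle_matrix(motif_labels(task$source), all_labs)
  needed <- needed_transitions(motif_labels(task$source),
                               unname(motor_order))
  # sequential acquisition, one transition at a time
  acq_day <- rep(NA_integer_, nrow(needed))
  nxt <- 1L
  for (d in days) {
    if (nxt > nrow(needed)) break
    # transitions involving an unrecruited call wait for the lag
    involves_call <- needed$from[nxt] %in% call_ids |
      needed$to[nxt] %in% call_ids
    if (involves_call && d < params$recruitment_lag) next
    if (stats::runif(1) < params$p_transition_acquire) {
      acq_day[nxt] <- d
      nxt <- nxt + 1L
    }
  }
  transitions <- lapply(seq_len(n_days), function(di) {
    d <- days[di]
    tm <- src_tm
    for (i in seq_len(nrow(needed))) {
      if (is.na(acq_day[i]) || d < acq_day[i]) next
      u <- params$usage_max *
        (1 - exp(-(d - acq_day[i] + 1) / params$transition_ramp_days))
      from <- needed$from[i]; to <- needed$to[i]
      row <- src_tm[from, ]
      tm[from, ] <- row * (1 - u)
      tm[from, to] <- tm[from, to] + u
    }
    tm / rowSums(tm)
  })
  truth <- ground_truth_trajectory(days, pitch, transitions, call_mat,
                                   target_choice = mapping)
  attr(truth, "acquired") <- cbind(needed, day = acq_day)
  attr(truth, "recruited") <- recruited
  truth
}

# target transitions (in motor-lineage labels) absent from the source song
needed_transitions <- function(src_motif, motor_order_target) {
  src_bg <- target_bigrams(src_motif)
  tgt_bg <- unique(data.frame(from = motor_order_target,
                              to = c(motor_order_target[-1],
                                     motor_order_target[1])))
  miss <- !(bigram_id(tgt_bg$from, tgt_bg$to) %in% src_bg)
  tgt_bg[miss, , drop = FALSE]
}

#' Simulate a cohort of learners
#'
#' Independent simulations with per-bird seeds, summarized the way cohort
#' endpoint panels are: per-bird endpoint pitch/syntax corrections for each
#' pitch-mismatched syllable, plus cohort means and standard errors.
#'
#' @param task An [imitation_task()].
#' @param strategy Strategy name.
#' @param n_birds Number of birds.
#' @param params A [sim_params()] (per-bird seeds derived from
#'   `params$seed`).
#' @param config A [synth_config()].
#' @param keep_trajectories Keep the full per-bird trajectories? (memory)
#' @return List with `endpoint` (data frame: bird, syllable,
#'   chosen_target, pitch_correction, syntax_correction), `summary`
#'   (cohort mean and sem per column) and optionally `trajectories`.
#' @export
batch_simulate <- function(task, strategy = "greedy", n_birds = 10,
                           params = sim_params(), config = synth_config(),
                           keep_trajectories = FALSE) {
  stopifnot(n_birds >= 1)
  base_seed <- params$seed %||% 1L
  rows <- list()
  trajs <- if (keep_trajectories) vector("list", n_birds) else NULL
  for (b in seq_len(n_birds)) {
    p <- params
    p$seed <- (base_seed + 7919L * b) %% .Machine$integer.max
    traj <- simulate_learning(task, strategy, p, config)
    if (keep_trajectories) trajs[[b]] <- traj
    rows[[b]] <- trajectory_endpoint(traj, bird = b)
  }
  endpoint <- do.call(rbind, rows)
  num <- c("pitch_correction", "syntax_correction")
  summary <- data.frame(
    metric = num,
    mean = vapply(num, function(cn) mean(endpoint[[cn]], na.rm = TRUE),
                  numeric(1)),
    sem = vapply(num, function(cn) {
      v <- endpoint[[cn]][!is.na(endpoint[[cn]])]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)))
  out <- list(endpoint = endpoint, summary = summary)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Cohort target-choice experiment
#'
#' Which target does each bird's focal syllable select under the
#' greedy-competitive rule? Baseline pitch varies across experimental
#' birds, so each simulated bird perturbs its motor pitches by Gaussian
#' noise before competing; exact ties are broken by the per-bird seed.
#'
#' @param task An [imitation_task()].
#' @param n_birds Number of birds.
#' @param pitch_sd Per-bird baseline pitch deviation, semitones (default
#'   0.25, the rendition jitter scale).
#' @param call_pitches Call pool (semitones).
#' @param seed Cohort seed.
#' @return Data frame: `bird`, one column per harmonic motor syllable with
#'   the label of its chosen target, and `distance` columns with the
#'   unperturbed semitone distance to that choice.
#' @export
cohort_target_choice <- function(task, n_birds = 100, pitch_sd = 0.25,
                                 call_pitches = NULL, seed = 1L) {
  prob0 <- assignment_problem(task, call_pitches)
  motif_idx <- which(!is.na(prob0$motor_positions))
  with_seed(seed, {
    rows <- lapply(seq_len(n_birds), function(b) {
      prob <- prob0
      prob$motor_pitches[motif_idx] <- prob$motor_pitches[motif_idx] +
        stats::rnorm(length(motif_idx), 0, pitch_sd)
      prob$cost <- spectral_costs(prob$motor_pitches, prob$target_pitches)
      res <- musical_chairs(prob, tie_seed = sample.int(2^30, 1))
      m <- res$mapping[motif_idx]
      choice <- prob0$target_labels[m]
      d0 <- prob0$cost[cbind(motif_idx, m)]
      out <- data.frame(bird = b)
      for (i in seq_along(motif_idx)) {
        lab <- prob0$motor_labels[motif_idx[i]]
        out[[lab]] <- choice[i]
        out[[paste0("dist_", lab)]] <- d0[i]
      }
      out
    })
    do.call(rbind, rows)
  })
}

#' Endpoint metrics of one simulated trajectory
#'
#' @param traj A [simulate_learning()] result.
#' @param bird Bird index carried into the output.
#' @param last_n_days Days pooled at the end.
#' @return Data frame: one row per pitch-mismatched source syllable with
#'   the chosen target, endpoint pitch correction (toward the chosen
#'   target) and endpoint syntax correction.
#' @export
trajectory_endpoint <- function(traj, bird = 1L, last_n_days = 3) {
  task <- traj$task
  ref <- task$source$reference_freq
  sp <- motif_pitches(task$source)
  tp <- motif_pitches(task$target)
  tp <- tp[!duplicated(names(tp))]
  focal <- unique(task$pitch_mismatches$source_label)
  rows <- lapply(focal, function(l) {
    t <- traj$assignment[l]
    if (is.na(t) || !(t %in% names(tp)) || is.na(tp[t])) {
      return(data.frame(bird = bird, syllable = l,
                        chosen_target = NA_character_,
                        pitch_correction = NA_real_,
                        syntax_correction = NA_real_))
    }
    ctx <- target_context(task, traj$assignment, t)
    es <- endpoint_summary(traj$renditions, l, sp[l], tp[t],
                           ctx["conv"], ctx["div"],
                           last_n_days = last_n_days, ref_freq = ref)
    data.frame(bird = bird, syllable = l, chosen_target = unname(t),
               pitch_correction = es$pitch_correction,
               syntax_correction = es$syntax_correction)
  })
  do.call(rbind, rows)
}

# converging/diverging context of a target syllable, translated into the
# motor-lineage labels observed in the stream
target_context <- function(task, mapping, target_label) {
  tgt <- motif_labels(task$target)
  inv <- stats::setNames(names(mapping), unname(mapping))
  pos <- which(tgt == target_label)[1]
  n <- length(tgt)
  pred <- tgt[(pos - 2) %% n + 1]
  succ <- tgt[pos %% n + 1]
  to_motor <- function(l) if (l %in% names(inv)) unname(inv[l]) else l
  c(conv = to_motor(pred), div = to_motor(succ))
}
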