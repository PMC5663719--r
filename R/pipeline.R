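#' Run configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' so typos fail loudly.
#'
#' @param task Task name in [task_library()] (e.g. `"task5"`), or an
#'   [imitation_task()].
#' @param strategy Learning strategy for the simulation stage.
#' @param audio Synthesize audio and run the acoustic pipeline
#'   (segmentation bypassed in favour of the generated annotations)? When
#'   `FALSE`, metrics are computed from ground-truth labels and programmed
#'   pitch.
#' @param n_days,renditions_per_day Simulation length.
#' @param seed Master seed for every stochastic stage.
#' @param sim Named list overriding [sim_params()] fields.
#' @param synth Named list overriding [synth_config()] fields.
#' @param out_dir Output directory (default a tempdir).
#' @return An object of class `run_config`.
#' @export
run_config <- function(task = "task1", strategy = "greedy", audio = FALSE,
                       n_days = 40, renditions_per_day = 60, seed = 1L,
                       sim = list(), synth = list(),
                       out_dir = tempfile("songmatch_run")) {
  cfg <- as.list(environment())
  known_sim <- names(formals(sim_params))
  known_synth <- names(formals(synth_config))
  if (length(setdiff(names(sim), known_sim))) {
    stop("unknown sim parameter(s): ",
         paste(setdiff(names(sim), known_sim), collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(names(synth), known_synth))) {
    stop("unknown synth parameter(s): ",
         paste(setdiff(names(synth), known_synth), collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()]. Unknown keys are
#'   rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, obj)
}

#' Run the full analysis pipeline
#'
#' Orchestrates one reproducible run: simulate a learner
#' ([simulate_learning()]), optionally synthesize audio and re-measure it
#' (pitch tracking and nearest-neighbour typing), compute the trajectory
#' metrics for every pitch-mismatched syllable, and compare the simulated
#' assignment against the optimal linear assignment and the EM matcher.
#' Writes `metrics.csv`, `summary.json`, `config_used.yaml` and
#' `run_log.txt` into the output directory.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @return Invisibly, the report: list with `trajectory`, `metrics`,
#'   `assignment` (simulated/optimal/EM mappings and costs), `files`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  cat("songmatch ", as.character(utils::packageVersion("songmatch")),
      " seed ", config$seed, "\n", sep = "", file = logf)

  task <- if (inherits(config$task, "imitation_task")) config$task else
    task_library()[[config$task]]
  if (is.null(task)) stop("unknown task: ", config$task, call. = FALSE)

  stage <- function(name, expr) {
    logline("stage ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim_args <- utils::modifyList(
    list(n_days = config$n_days,
         renditions_per_day = config$renditions_per_day,
         seed = config$seed),
    config$sim)
  params <- do.call(sim_params, sim_args)
  synth_args <- utils::modifyList(list(seed = config$seed), config$synth)
  scfg <- do.call(synth_config, synth_args)

  traj <- stage("simulate", simulate_learning(task, config$strategy,
                                              params, scfg))
  renditions <- traj$renditions

  if (config$audio) {
    renditions <- stage("acoustics", {
      ds <- generate_dataset(task, traj$truth, config$n_days, scfg,
                             audio = TRUE,
                             dir = file.path(config$out_dir, "audio"))
      measured <- measure_dataset(ds, scfg$sample_rate)
      tpl <- build_templates(ds, sr = scfg$sample_rate,
                             seed = config$seed)
      classified <- classify_renditions(ds, tpl, sr = scfg$sample_rate)
      measured$label_knn <- classified$label_knn
      measured
    })
  }

  metrics <- stage("metrics", pipeline_metrics(task, traj, renditions))
  assign_cmp <- stage("assignment", assignment_report(task, traj, params))

  files <- list(metrics = file.path(config$out_dir, "metrics.csv"),
                summary = file.path(config$out_dir, "summary.json"),
                config = file.path(config$out_dir, "config_used.yaml"),
                log = logf)
  utils::write.csv(metrics, files$metrics, row.names = FALSE)
  cfg_ser <- config
  cfg_ser$task <- if (inherits(config$task, "imitation_task"))
    config$task$task_id else config$task
  yaml::write_yaml(unclass(cfg_ser), files$config)
  summary <- list(task = task$task_id, strategy = config$strategy,
                  seed = config$seed,
                  assignment = as.list(traj$assignment),
                  optimal_lap = as.list(assign_cmp$optimal_mapping),
                  em_mapping = as.list(assign_cmp$em_mapping),
                  greedy_matches_lap = assign_cmp$greedy_matches_lap,
                  em_matches_greedy = assign_cmp$em_matches_greedy,
                  spectral_cost = assign_cmp$spectral_cost,
                  recruited = traj$events$recruited,
                  endpoint = lapply(split(
                    trajectory_endpoint(traj),
                    seq_len(nrow(trajectory_endpoint(traj)))), as.list),
                  elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")))
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logline("done")
  invisible(list(trajectory = traj, metrics = metrics,
                 assignment = assign_cmp, files = files, config = config))
}

# per-day tidy metrics for every pitch-mismatched syllable
pipeline_metrics <- function(task, traj, renditions) {
  ref <- task$source$reference_freq
  sp <- motif_pitches(task$source)
  tp <- motif_pitches(task$target)
  tp <- tp[!duplicated(names(tp))]
  label_col <- if (!is.null(renditions$label_refined)) "label_refined" else
    "label"
  out <- list()
  for (l in unique(task$pitch_mismatches$source_label)) {
    t <- traj$assignment[l]
    if (is.na(t) || !(t %in% names(tp)) || is.na(tp[t])) next
    pm <- day_pitch_medians(renditions, l, ref)
    pc <- fraction_pitch_corrected(pm$pitch_st, sp[l], tp[t])
    ctx <- target_context(task, traj$assignment, t)
    sf <- syntax_fractions(renditions, l, ctx["conv"], ctx["div"],
                           label_col = label_col)
    out[[length(out) + 1L]] <- data.frame(
      day = pm$day, syllable = l, metric = "pitch_correction", value = pc)
    out[[length(out) + 1L]] <- data.frame(
      day = sf$day, syllable = l, metric = "syntax_correction",
      value = sf$overall)
  }
  # calls tracked toward their recruited target
  for (cid in traj$events$recruited) {
    t <- traj$assignment[cid]
    pm <- day_pitch_medians(renditions, cid, ref)
    if (!nrow(pm)) next
    pc <- fraction_pitch_corrected(pm$pitch_st,
                                   traj$params$call_pitch[cid], tp[t])
    out[[length(out) + 1L]] <- data.frame(
      day = pm$day, syllable = cid, metric = "call_pitch_correction",
      value = pc)
  }
  do.call(rbind, out)
}

# simulated vs optimal vs EM assignment
assignment_report <- function(task, traj, params) {
  prob <- assignment_problem(task, params$call_pitch)
  lap <- solve_lap(prob)
  opt <- stats::setNames(prob$target_labels[lap$mapping[!is.na(lap$mapping)]],
                         prob$motor_labels[!is.na(lap$mapping)])
  # EM matcher on the endpoint target-pitch renditions implied by the task
  tgt <- prob$target_pitches
  x <- with_seed(1L, unlist(lapply(tgt, function(m)
    stats::rnorm(60, m, 0.3))))
  motor <- stats::setNames(prob$motor_pitches[is.na(prob$motor_positions) == FALSE],
                           prob$motor_labels[!is.na(prob$motor_positions)])
  # calls only compete for targets the motif syllables cannot cover
  n_vacant <- max(0L, length(tgt) - length(motor))
  calls <- if (n_vacant > 0) params$call_pitch[seq_len(
    min(n_vacant, length(params$call_pitch)))] else NULL
  em <- em_match_targets(x, motor, calls,
                         stats::setNames(prob$target_pitches,
                                         prob$target_labels))
  harm <- names(opt)
  sim_map <- traj$assignment[harm]
  list(optimal_mapping = opt, em_mapping = em$mapping,
       greedy_matches_lap = identical(unname(sim_map[harm]),
                                      unname(opt[harm])),
       em_matches_greedy = identical(unname(em$mapping[harm]),
                                     unname(traj$assignment[harm])),
       spectral_cost = lap$spectral_cost)
}

#' Acoustic measurement of a generated dataset
#'
#' Runs [measure_renditions()] on every day of a dataset with audio, using
#' the annotations as segment boundaries (annotation-guided path; see
#' [segment_syllables()] for the blind path).
#'
#' @param dataset A [generate_dataset()] result with audio.
#' @param sr Sample rate, Hz.
#' @return The annotation data frame plus measured columns.
#' @export
measure_dataset <- function(dataset, sr) {
  ann <- dataset$annotations
  waves <- day_waves(dataset)
  out <- lapply(unique(ann$day), function(d) {
    measure_renditions(waves[[as.character(d)]], sr,
                       ann[ann$day == d, ])
  })
  do.call(rbind, out)
}

#' Quickstart demo: competitive matching with call recruitment
#'
#' Runs the two-equidistant-targets task (one syllable offered targets two
#' semitones up and down) with the greedy-competitive strategy and prints
#' where each precursor converged: the focal syllable claims one target,
#' a call is recruited to the vacant one.
#'
#' @param seed Seed.
#' @param out_dir Output directory.
#' @return The [run_pipeline()] report, invisibly.
#' @export
demo_task5 <- function(seed = 1L, out_dir = tempfile("songmatch_demo")) {
  report <- run_pipeline(run_config(task = "task5", strategy = "greedy",
                                    n_days = 30, renditions_per_day = 40,
                                    seed = seed, out_dir = out_dir))
  traj <- report$trajectory
  cat("assignment:", paste(names(traj$assignment), "->", traj$assignment,
                           collapse = ", "), "\n")
  cat("recruited calls:", paste(traj$events$recruited, collapse = ", "),
      "\n")
  ep <- trajectory_endpoint(traj)
  print(ep)
  hist <- vacancy_histogram(
    traj$renditions[traj$renditions$day >= max(traj$renditions$day) - 2, ],
    groups = list(focal = "B", call = traj$events$recruited),
    source = 0,
    direction = if (traj$assignment["B"] == "B+2") 1 else -1,
    ref_freq = traj$task$source$reference_freq)
  invisible(c(report, list(vacancy = hist)))
}
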