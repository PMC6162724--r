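# Scripted, seeded characterisation studies: weighting sweeps, intervention
# timing sweeps, trajectory reports and cohort-level closed-loop summaries.

as_problem_list <- function(instances) {
  if (inherits(instances, "search_problem")) return(list(instances))
  if (is.data.frame(instances)) {
    return(lapply(seq_len(nrow(instances)), function(i) {
      puzzle_problem(instances$start[i], instances$goal[i])
    }))
  }
  if (is.list(instances)) {
    return(lapply(instances, function(x) {
      if (inherits(x, "search_problem")) x else resolve_instance(x)
    }))
  }
  stop("instances must be search problems or a puzzle instance data frame")
}

new_sweep_result <- function(axis, axis_type, nodes, explored, cost_ratio,
                             reference_nodes, optimal_cost) {
  # Reduction is measured on distinct states explored (the quantity the
  # speed-accuracy characterisation plots): re-expansions caused by the
  # engine's re-opening policy are bookkeeping, not new exploration.
  reduction <- 1 - explored / reference_nodes
  structure(list(axis = axis, axis_type = axis_type,
                 nodes_expanded = nodes, nodes_explored = explored,
                 reduction = reduction,
                 cost_ratio = cost_ratio, reference_nodes = reference_nodes,
                 optimal_cost = optimal_cost,
                 median_nodes = apply(nodes, 2, median),
                 median_reduction = apply(reduction, 2, median)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> axis:", x$axis_type, "=",
      paste(x$axis, collapse = ", "), "over", nrow(x$nodes_expanded),
      "instances\n  median nodes expanded:",
      paste(round(x$median_nodes), collapse = ", "),
      "\n  median reduction:",
      paste(sprintf("%.3f", x$median_reduction), collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the weighting coefficient over a fixture set
#'
#' Runs fixed-weight weighted A* from the onset for every instance and every
#' weight in `omega_grid`, against an admissible reference run per instance.
#' Node counts are heavy-tailed across instances, so medians summarise the
#' sweep.
#'
#' @param instances Search problems (list) or a puzzle instance data frame.
#' @param omega_grid Weights within `[0.5, 0.7]`.
#' @param node_budget Per-run expansion budget.
#' @return A `sweep_result`: per-instance matrices of `nodes_expanded`
#'   (expansion events), `nodes_explored` (distinct states), `reduction`
#'   (`1 - nodes_explored / reference`) and `cost_ratio`
#'   (`achieved / optimal`), plus per-weight medians.
#' @export
sweep_weighting <- function(instances, omega_grid = c(0.5, 0.55, 0.575, 0.6),
                            node_budget = 5e6) {
  if (any(omega_grid < 0.5 | omega_grid > 0.7)) {
    stop("omega_grid must lie within [0.5, 0.7]")
  }
  problems <- as_problem_list(instances)
  refs <- lapply(problems, astar, node_budget = node_budget,
                 keep_trace = FALSE)
  ref_nodes <- vapply(refs, `[[`, numeric(1), "nodes_expanded")
  opt_cost <- vapply(refs, `[[`, numeric(1), "solution_cost")
  n <- length(problems)
  k <- length(omega_grid)
  nodes <- matrix(NA_real_, n, k, dimnames = list(NULL, omega_grid))
  expl <- matrix(NA_real_, n, k, dimnames = list(NULL, omega_grid))
  cost <- matrix(NA_real_, n, k, dimnames = list(NULL, omega_grid))
  for (j in seq_len(k)) {
    sched <- weight_schedule(omega_grid[j])
    for (i in seq_len(n)) {
      wa <- weighted_astar(problems[[i]], sched,
                           reference_exploration = ref_nodes[i],
                           optimal_cost = opt_cost[i],
                           node_budget = node_budget, keep_trace = FALSE)
      nodes[i, j] <- wa$trace$nodes_expanded
      expl[i, j] <- wa$trace$nodes_explored
      cost[i, j] <- wa$trace$solution_cost
    }
  }
  new_sweep_result(omega_grid, "omega", nodes, expl,
                   cost / opt_cost, ref_nodes, opt_cost)
}

#' Sweep the intervention trigger fraction at a fixed weight
#'
#' Runs dynamically triggered weighted A* (weight `omega_fixed` installed
#' once the given fraction of the admissible reference exploration has been
#' expanded) for every instance and every fraction.  Fraction 0 is the
#' fixed-weight run from the onset; fraction 1 never fires within the run.
#'
#' @inheritParams sweep_weighting
#' @param omega_fixed The weight installed at the trigger (default 0.57, a
#'   coefficient known to reduce the search space).
#' @param fraction_grid Trigger fractions in `[0, 1]`.
#' @return A `sweep_result` over the fraction axis.
#' @export
sweep_intervention_timing <- function(instances, omega_fixed = 0.57,
                                      fraction_grid = c(0, 0.1, 0.25, 0.5),
                                      node_budget = 5e6) {
  stopifnot(all(fraction_grid >= 0 & fraction_grid <= 1))
  problems <- as_problem_list(instances)
  refs <- lapply(problems, astar, node_budget = node_budget,
                 keep_trace = FALSE)
  ref_nodes <- vapply(refs, `[[`, numeric(1), "nodes_expanded")
  opt_cost <- vapply(refs, `[[`, numeric(1), "solution_cost")
  n <- length(problems)
  k <- length(fraction_grid)
  nodes <- matrix(NA_real_, n, k, dimnames = list(NULL, fraction_grid))
  expl <- matrix(NA_real_, n, k, dimnames = list(NULL, fraction_grid))
  cost <- matrix(NA_real_, n, k, dimnames = list(NULL, fraction_grid))
  for (j in seq_len(k)) {
    sched <- weight_schedule(
      0.5, data.frame(fraction = fraction_grid[j], weight = omega_fixed),
      monotone = TRUE)
    for (i in seq_len(n)) {
      wa <- weighted_astar(problems[[i]], sched,
                           reference_exploration = ref_nodes[i],
                           optimal_cost = opt_cost[i],
                           node_budget = node_budget, keep_trace = FALSE)
      nodes[i, j] <- wa$trace$nodes_expanded
      expl[i, j] <- wa$trace$nodes_explored
      cost[i, j] <- wa$trace$solution_cost
    }
  }
  new_sweep_result(fraction_grid, "trigger_fraction", nodes, expl,
                   cost / opt_cost, ref_nodes, opt_cost)
}

#' Heuristic-trajectory report for a search trace
#'
#' Exports the expanded-node heuristic series together with its oscillation
#' (backtracking) count and the linear trend of `h` against expansion index
#' — oscillations indicate backtracking; a clean negative slope indicates
#' monotone progression towards the goal.
#'
#' @param trace A `search_trace`.
#' @return A `trajectory_report`: `series` (data frame `expansion`, `h`),
#'   `oscillations`, `slope`.
#' @export
trajectory_report <- function(trace) {
  h <- if (inherits(trace, "search_trace")) trace$h_sequence else
    as.numeric(trace)
  if (length(h) == 0) stop("trace is empty")
  series <- data.frame(expansion = seq_along(h), h = h)
  slope <- if (length(h) > 1) {
    unname(coef(lm(h ~ expansion, data = series))[2])
  } else NA_real_
  structure(list(series = series,
                 oscillations = backtracking_score(h),
                 slope = slope),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat("<trajectory_report>", nrow(x$series), "expansions,",
      x$oscillations, "oscillations, slope",
      format(x$slope, digits = 4), "\n")
  invisible(x)
}

#' Sample a cohort of virtual subjects
#'
#' Draws per-subject trait asymmetry and state gain from normal
#' distributions (gains truncated at zero), with shared noise and fatigue
#' parameters; each subject receives a derived seed.  The defaults encode
#' the study conditions used throughout the package's experiments: zero-mean
#' trait variation, a moderate volitional gain against channel noise of
#' comparable scale (per-block standardised effects near 1 for responders),
#' and mild per-block fatigue.
#'
#' @param n Number of subjects.
#' @param responder Logical (recycled): responder status per subject.
#' @param trait_mean,trait_sd Trait asymmetry distribution.
#' @param gain_mean,gain_sd State gain distribution (responders only).
#' @param noise_sd Per-channel noise standard deviation.
#' @param fatigue_decay Per-block fatigue factor.
#' @param drift_slope Common linear drift (units/s).
#' @param seed Integer seed.
#' @return A list of [virtual_subject()]s.
#' @export
sample_subjects <- function(n, responder = TRUE, trait_mean = 0,
                            trait_sd = 0.3, gain_mean = 0.5, gain_sd = 0.15,
                            noise_sd = 0.5, fatigue_decay = 0.95,
                            drift_slope = 0, seed = 1L) {
  responder <- rep_len(responder, n)
  withr::with_seed(seed, {
    traits <- rnorm(n, trait_mean, trait_sd)
    gains <- pmax(rnorm(n, gain_mean, gain_sd), 0)
  })
  lapply(seq_len(n), function(i) {
    virtual_subject(trait_asymmetry = traits[i],
                    state_gain = if (responder[i]) gains[i] else 0,
                    responder = responder[i],
                    fatigue_decay = fatigue_decay, noise_sd = noise_sd,
                    drift_slope = drift_slope,
                    seed = derive_seed(seed, i))
  })
}

# Mean of the saturating-exponential response profile over the scored
# neurofeedback window, on the protocol's sampling grid.
nf_profile_mean <- function(protocol) {
  pt <- protocol_times(protocol)
  fs <- protocol$sampling_rate
  n <- round(pt$total * fs)
  t <- (seq_len(n) - 1) / fs
  win <- t >= pt$nf_start + protocol$haemodynamic_delay - 1e-9 &
    t < pt$nf_end - 1e-9
  mean(response_profile(t, protocol)[win])
}

#' Virtual subject with a programmed standardised effect
#'
#' Chooses the state gain so that the expected asymmetry elevation of the
#' scored neurofeedback window over the baseline equals `d` times the
#' asymmetry noise standard deviation (`noise_sd / sqrt(2)` for 4+4
#' averaged channels), accounting for the saturating response profile.
#'
#' @param d Programmed standardised mean difference.
#' @param protocol The [block_protocol()] the blocks will follow.
#' @param noise_sd Per-channel noise standard deviation.
#' @param seed Integer seed.
#' @return A [virtual_subject()].
#' @export
subject_with_effect <- function(d, protocol = block_protocol(),
                                noise_sd = 0.5, seed = 1L) {
  stopifnot(d >= 0, noise_sd > 0)
  sigma_a <- noise_sd / sqrt(2)
  virtual_subject(trait_asymmetry = 0,
                  state_gain = d * sigma_a / nf_profile_mean(protocol),
                  responder = TRUE, fatigue_decay = 1, noise_sd = noise_sd,
                  seed = seed)
}

#' Cohort closed-loop study
#'
#' For each subject, simulates a session of `n_blocks` neurofeedback blocks,
#' scores them, applies the session-level success criterion (at least half
#' of blocks successful), and — when an instance is supplied — runs one
#' closed-loop puzzle search recording the applied weight and search-space
#' reduction.
#'
#' @param subjects A list of [virtual_subject()]s (see
#'   [sample_subjects()]).
#' @param protocol A [block_protocol()].
#' @param cfg A [mapping_config()].
#' @param n_blocks Blocks per session.
#' @param instance Optional puzzle instance for the closed-loop arm.
#' @param boot_reps Bootstrap resamples per block.
#' @return A `cohort_result`: a data frame with one row per subject
#'   (`subject`, `responder`, `blocks_successful`, `session_success`, and,
#'   with an instance, `omega_applied` and `reduction`), with the cohort
#'   success rate in `attr(, "success_rate")`.
#' @export
cohort_study <- function(subjects, protocol = block_protocol(),
                         cfg = mapping_config(), n_blocks = 4,
                         instance = NULL, boot_reps = 200) {
  stopifnot(length(subjects) >= 1)
  rows <- lapply(seq_along(subjects), function(i) {
    subj <- subjects[[i]]
    streams <- simulate_session(subj, protocol, n_blocks)
    stats <- lapply(seq_along(streams), function(k) {
      score_block(streams[[k]], protocol, boot_reps = boot_reps,
                  d_max = cfg$d_max, seed = derive_seed(subj$seed, 500L + k))
    })
    row <- data.frame(
      subject = i,
      responder = subj$responder,
      blocks_successful = sum(vapply(stats, `[[`, logical(1), "success")),
      session_success = session_success(stats))
    if (!is.null(instance)) {
      lr <- run_closed_loop_puzzle(instance, subj, protocol, cfg)
      row$omega_applied <- lr$omega_applied
      row$reduction <- lr$reduction
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "success_rate") <- mean(out$session_success)
  class(out) <- c("cohort_result", "data.frame")
  out
}

#' Write a study directory
#'
#' Emits `config.yaml` (the resolved configuration), `results.csv` and
#' `manifest.json` (seed and package version) into `dir`.
#'
#' @param results A data frame (e.g. a `cohort_result`) or a
#'   `sweep_result`.
#' @param dir Output directory.
#' @param config Named list written as the resolved configuration.
#' @param seed The study seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_study <- function(results, dir, config = list(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  df <- if (inherits(results, "sweep_result")) {
    data.frame(axis = results$axis,
               median_nodes = results$median_nodes,
               median_reduction = results$median_reduction)
  } else {
    as.data.frame(results)
  }
  write.csv(df, file.path(dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         package = "bcisearch",
         version = as.character(utils::packageVersion("bcisearch"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}
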