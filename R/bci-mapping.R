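# Translate block statistics into weighted-A* weighting changes and run the
# closed loop between simulated neurofeedback input and the search engine.

#' Mapping configuration
#'
#' Governs the linear mapping from the block effect size onto the weighting
#' coefficient: a non-significant block maps to `omega_base` (admissible
#' search preserved); a successful block maps to
#' `omega_base + min(max(d, 0), d_max) / d_max * (omega_max - omega_base)`,
#' saturating at `omega_max` for `d >= d_max`.
#'
#' @param omega_base Weight for no input; fixed at the admissible 0.5.
#' @param omega_max Ceiling weight in `(0.5, 1)` (default 0.6, bracketing
#'   the operative range of modest heuristic overweighting with headroom).
#' @param d_max Effect size at which `omega_max` is reached (default 1.5, a
#'   conventionally very large standardised effect).
#' @param require_significance If `TRUE`, non-successful blocks map to
#'   `omega_base` regardless of their effect size.
#' @param trigger_fraction Search-progress fraction at which the single
#'   puzzle-loop intervention is installed, within `[0, 0.25]` (the early
#'   stage of the search, where re-weighting has the most impact).
#' @return A `mapping_config` object.
#' @export
mapping_config <- function(omega_base = 0.5, omega_max = 0.6, d_max = 1.5,
                           require_significance = TRUE,
                           trigger_fraction = 0.1) {
  stopifnot(omega_base >= 0.5, omega_base < omega_max, omega_max < 1,
            d_max > 0)
  if (trigger_fraction < 0 || trigger_fraction > 0.25) {
    stop("trigger_fraction must lie in [0, 0.25]")
  }
  structure(list(omega_base = omega_base, omega_max = omega_max,
                 d_max = d_max,
                 require_significance = isTRUE(require_significance),
                 trigger_fraction = trigger_fraction),
            class = "mapping_config")
}

#' Map a block effect size onto the weighting coefficient
#'
#' @param stats A `block_stats` from [score_block()].
#' @param cfg A [mapping_config()].
#' @return The weighting coefficient in `[omega_base, omega_max]`;
#'   monotone non-decreasing in the effect size.
#' @examples
#' cfg <- mapping_config()
#' # d = d_max / 2 on a successful block maps to the interval midpoint 0.55
#' @export
map_effect_to_weight <- function(stats, cfg = mapping_config()) {
  stopifnot(inherits(cfg, "mapping_config"))
  if (cfg$require_significance && !isTRUE(stats$success)) {
    return(cfg$omega_base)
  }
  d <- min(max(stats$effect_size, 0), cfg$d_max)
  cfg$omega_base + d / cfg$d_max * (cfg$omega_max - cfg$omega_base)
}

#' Normalised neurofeedback display value
#'
#' The abstract feedback channel is a normalised focusing level: 0 at the
#' baseline, 1 (the narrowest search beam) once the asymmetry has risen a
#' full `target_gain` above the baseline, linear and clamped in between.
#'
#' @param current_asymmetry Current asymmetry sample(s).
#' @param baseline_mean Baseline asymmetry (the zero reference).
#' @param target_gain Asymmetry increase mapped to full focus (`> 0`).
#' @return Values in `[0, 1]`.
#' @examples
#' feedback_value(0.5, 0, 1) # 0.5
#' @export
feedback_value <- function(current_asymmetry, baseline_mean, target_gain) {
  if (!is.numeric(target_gain) || target_gain <= 0) {
    stop("target_gain must be positive")
  }
  pmin(pmax((current_asymmetry - baseline_mean) / target_gain, 0), 1)
}

#' Install candidate weights as a monotone sequence
#'
#' Repeated interventions only ever tighten the heuristic bias: the weight
#' installed at each update is the running maximum of the candidates so far.
#'
#' @param candidates Candidate weights in order of arrival.
#' @param monotone If `FALSE`, candidates are installed as-is.
#' @return The installed weight sequence.
#' @examples
#' install_weights(c(0.55, 0.52, 0.58)) # 0.55 0.55 0.58
#' @export
install_weights <- function(candidates, monotone = TRUE) {
  if (monotone) cummax(candidates) else candidates
}

loop_result <- function(...) structure(list(...), class = "loop_result")

#' @export
print.loop_result <- function(x, ...) {
  cat("<loop_result>", x$domain, "| omega applied",
      paste(round(x$omega_applied, 4), collapse = ", "),
      sprintf("| nodes %d/%d (reduction %.1f%%) | cost %.3f vs optimal %.3f\n",
              as.integer(x$trace$nodes_expanded),
              as.integer(x$reference_exploration),
              100 * x$reduction, x$trace$solution_cost,
              x$bound$optimal_cost))
  invisible(x)
}

resolve_instance <- function(instance) {
  if (inherits(instance, "search_problem")) return(instance)
  if (is.data.frame(instance)) instance <- as.list(instance[1, ])
  if (is.list(instance) && !is.null(instance$start)) {
    return(puzzle_problem(instance$start,
                          instance$goal %||% PUZZLE_GOAL))
  }
  if (is.character(instance)) return(puzzle_problem(instance))
  stop("cannot interpret the puzzle instance")
}

subject_for_run <- function(subject, seed) {
  if (is.null(seed)) return(subject)
  subject$seed <- as.integer(seed)
  subject
}

#' Closed-loop neurofeedback control of an 8-puzzle search
#'
#' One neurofeedback block is simulated and scored, its effect size mapped
#' to a weighting coefficient, and the result installed as a single
#' monotone trigger at `cfg$trigger_fraction` of the admissible reference
#' exploration; the weighted search then runs to completion.  The recorded
#' search-space reduction is `1 - nodes_expanded / reference_exploration`.
#'
#' @param instance A puzzle instance: a `search_problem`, a
#'   `list(start, goal)`, a row of [generate_puzzle_instances()] output, or
#'   a start-state string.
#' @param subject A [virtual_subject()].
#' @param protocol A [block_protocol()].
#' @param cfg A [mapping_config()].
#' @param seed Optional seed overriding the subject's (fixes the whole run).
#' @param node_budget Expansion budget for each search run.
#' @return A `loop_result` with the block statistics, applied weight,
#'   schedule, search trace, bound report, feedback series and reduction.
#' @export
run_closed_loop_puzzle <- function(instance, subject,
                                   protocol = block_protocol(),
                                   cfg = mapping_config(), seed = NULL,
                                   node_budget = 5e6) {
  problem <- resolve_instance(instance)
  subject <- subject_for_run(subject, seed)
  ref <- astar(problem, node_budget = node_budget, keep_trace = FALSE)
  if (!ref$found) stop("instance is unsolvable or exceeded the node budget")

  stream <- simulate_block(subject, protocol, block_index = 0L)
  stats <- score_block(stream, protocol, d_max = cfg$d_max,
                       seed = derive_seed(subject$seed, 1L))
  omega <- map_effect_to_weight(stats, cfg)
  schedule <- if (omega > cfg$omega_base + 1e-12) {
    weight_schedule(cfg$omega_base,
                    data.frame(fraction = cfg$trigger_fraction,
                               weight = omega),
                    monotone = TRUE)
  } else {
    weight_schedule(cfg$omega_base)
  }
  wa <- weighted_astar(problem, schedule,
                       reference_exploration = ref$nodes_expanded,
                       optimal_cost = ref$solution_cost,
                       node_budget = node_budget)
  nf_a <- asymmetry(stream)[stream$epoch_label == "nf"]
  target <- if (subject$state_gain > 0) subject$state_gain else 1
  loop_result(
    domain = "puzzle",
    block_stats = stats,
    omega_applied = omega,
    schedule = schedule,
    trace = wa$trace,
    bound = wa$bound,
    feedback_series = feedback_value(nf_a, stats$baseline_mean, target),
    reference_exploration = ref$nodes_expanded,
    reduction = 1 - wa$trace$nodes_expanded / ref$nodes_expanded)
}

#' Closed-loop neurofeedback control of grid path planning
#'
#' `n_updates` neurofeedback blocks are simulated and scored; each maps to a
#' candidate weight, and the installed schedule takes the running maximum
#' (the weighting factor only ever increases through time).  Triggers are
#' placed at progression fractions `0, 1/n, 2/n, ...` of the admissible
#' reference exploration.  The bound report is computed against the
#' independent Dijkstra oracle.
#'
#' @param map A [grid_map()].
#' @inheritParams run_closed_loop_puzzle
#' @param n_updates Number of neurofeedback scoring windows (`>= 1`).
#' @return A `loop_result`; `candidate_weights` and `installed_weights`
#'   record the mapping before and after the monotone constraint.
#' @export
run_closed_loop_grid <- function(map, subject, protocol = block_protocol(),
                                 cfg = mapping_config(), n_updates = 3,
                                 seed = NULL, node_budget = 5e6) {
  stopifnot(inherits(map, "grid_map"), n_updates >= 1)
  problem <- grid_problem(map)
  subject <- subject_for_run(subject, seed)
  ref <- astar(problem, node_budget = node_budget, keep_trace = FALSE)
  if (!ref$found) stop("map start and goal are not connected")
  optimal <- grid_optimal_cost(map)

  streams <- simulate_session(subject, protocol, n_updates)
  stats <- lapply(seq_along(streams), function(i) {
    score_block(streams[[i]], protocol, d_max = cfg$d_max,
                seed = derive_seed(subject$seed, 1000L + i))
  })
  candidates <- vapply(stats, map_effect_to_weight, numeric(1), cfg = cfg)
  installed <- install_weights(candidates, monotone = TRUE)
  fractions <- (seq_len(n_updates) - 1) / n_updates
  active <- installed > cfg$omega_base + 1e-12
  schedule <- if (any(active)) {
    weight_schedule(cfg$omega_base,
                    data.frame(fraction = fractions[active],
                               weight = installed[active]),
                    monotone = TRUE)
  } else {
    weight_schedule(cfg$omega_base)
  }
  wa <- weighted_astar(problem, schedule,
                       reference_exploration = ref$nodes_expanded,
                       optimal_cost = optimal, node_budget = node_budget)
  target <- if (subject$state_gain > 0) subject$state_gain else 1
  feedback <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    feedback_value(asymmetry(s)[s$epoch_label == "nf"],
                   stats[[i]]$baseline_mean, target)
  })
  loop_result(
    domain = "grid",
    block_stats = stats,
    candidate_weights = candidates,
    installed_weights = installed,
    omega_applied = max(installed),
    schedule = schedule,
    trace = wa$trace,
    bound = wa$bound,
    feedback_series = feedback,
    reference_exploration = ref$nodes_expanded,
    reduction = 1 - wa$trace$nodes_expanded / ref$nodes_expanded)
}

#' Plain-list summary of a closed-loop run
#'
#' A deterministic, JSON-serialisable digest of a `loop_result` (used for
#' manifests and reproducibility checks).
#'
#' @param x A `loop_result`.
#' @return A named list of scalars and short vectors.
#' @export
loop_summary <- function(x) {
  stopifnot(inherits(x, "loop_result"))
  list(domain = x$domain,
       omega_applied = x$omega_applied,
       candidate_weights = x$candidate_weights,
       installed_weights = x$installed_weights,
       p_value = if (x$domain == "puzzle") x$block_stats$p_value else
         vapply(x$block_stats, `[[`, numeric(1), "p_value"),
       effect_size = if (x$domain == "puzzle") x$block_stats$effect_size else
         vapply(x$block_stats, `[[`, numeric(1), "effect_size"),
       nodes_expanded = x$trace$nodes_expanded,
       reference_exploration = x$reference_exploration,
       reduction = x$reduction,
       solution_cost = x$trace$solution_cost,
       optimal_cost = x$bound$optimal_cost,
       bound_satisfied = x$bound$bound_satisfied,
       solution_path = x$trace$solution_path)
}

#' Write a closed-loop run to disk
#'
#' Emits `summary.json` (the [loop_summary()]) and, when the trace was kept,
#' `trace.csv`.
#'
#' @param x A `loop_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_loop_result <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(loop_summary(x), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(x$trace$expansions)) {
    write_trace_csv(x$trace, file.path(dir, "trace.csv"))
  }
  invisible(dir)
}
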