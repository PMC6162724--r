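# Best-first search engine: A*, weighted A* with mid-search dynamic
# re-weighting, and FOCAL (A*eps) selection, with full per-expansion tracing.

#' Weighted evaluation function
#'
#' Computes the weighted-A* node evaluation
#' \deqn{f = (1 - \omega)\,g + \omega\,h,}
#' where \eqn{g} is the accumulated path cost, \eqn{h} the heuristic estimate
#' of remaining cost, and \eqn{\omega} the weighting coefficient.
#' \eqn{\omega = 0.5} is a positive rescaling of the classical \eqn{g + h}
#' and preserves admissible A* ordering; \eqn{\omega > 0.5} biases selection
#' towards the heuristic, trading solution optimality for speed with the
#' suboptimality bounded by \eqn{\omega / (1 - \omega)}.
#'
#' @param g Non-negative accumulated cost (vectorised).
#' @param h Non-negative heuristic estimate (vectorised).
#' @param omega Weighting coefficient in `[0, 1]`.
#' @return The evaluation value `(1 - omega) * g + omega * h`.
#' @examples
#' evaluate_f(4, 6, 0.5)   # 5
#' evaluate_f(4, 6, 0.575) # 5.15
#' @export
evaluate_f <- function(g, h, omega) {
  if (any(!is.finite(omega)) || any(omega < 0) || any(omega > 1)) {
    stop("omega must lie in [0, 1]")
  }
  if (any(g < 0) || any(h < 0)) stop("g and h must be non-negative")
  (1 - omega) * g + omega * h
}

#' Weight schedule for dynamic re-weighting
#'
#' A schedule is an initial weight plus an ordered list of triggers
#' `(fraction, weight)`: once the number of expanded nodes reaches
#' `fraction * reference_exploration` (the admissible-A* node count for the
#' same instance), the trigger's weight takes effect and every OPEN-list
#' evaluation is recomputed.  With `monotone = TRUE` the applied weight is the
#' running maximum, so it can only increase through time.
#'
#' @param initial_weight Weight in effect from the onset, in `[0.5, 1)`.
#'   `0.5` encodes unmodified A* ordering.
#' @param triggers `NULL`, or a data frame with columns `fraction` (strictly
#'   increasing, in `[0, 1]`) and `weight` (each in `[0.5, 1)`).
#' @param monotone If `TRUE`, applied weights may only increase.
#' @return An object of class `weight_schedule`.
#' @examples
#' weight_schedule(0.5, data.frame(fraction = 0.1, weight = 0.575))
#' @export
weight_schedule <- function(initial_weight = 0.5, triggers = NULL,
                            monotone = FALSE) {
  if (!is.numeric(initial_weight) || length(initial_weight) != 1 ||
      initial_weight < 0.5 || initial_weight >= 1) {
    stop("initial_weight must lie in [0.5, 1)")
  }
  if (is.null(triggers)) {
    triggers <- data.frame(fraction = numeric(), weight = numeric())
  }
  triggers <- as.data.frame(triggers)
  if (!all(c("fraction", "weight") %in% names(triggers))) {
    stop("triggers must have columns 'fraction' and 'weight'")
  }
  if (nrow(triggers) > 0) {
    if (any(triggers$fraction < 0 | triggers$fraction > 1)) {
      stop("trigger fractions must lie in [0, 1]")
    }
    if (any(diff(triggers$fraction) <= 0)) {
      stop("trigger fractions must be strictly increasing")
    }
    if (any(triggers$weight < 0.5 | triggers$weight >= 1)) {
      stop("trigger weights must lie in [0.5, 1)")
    }
    if (monotone &&
        any(diff(c(initial_weight, triggers$weight)) < 0)) {
      stop("monotone schedules require non-decreasing weights")
    }
  }
  structure(list(initial_weight = initial_weight, triggers = triggers,
                 monotone = isTRUE(monotone)),
            class = "weight_schedule")
}

#' @export
print.weight_schedule <- function(x, ...) {
  cat("<weight_schedule> initial omega =", x$initial_weight,
      if (x$monotone) "(monotone)" else "", "\n")
  if (nrow(x$triggers)) {
    cat("  triggers:\n")
    print(x$triggers, row.names = FALSE)
  } else {
    cat("  no triggers (trivial schedule)\n")
  }
  invisible(x)
}

# Convert a search_problem S3 object into the payload the C++ engine expects.
problem_payload <- function(problem) {
  if (!inherits(problem, "search_problem")) {
    stop("expected a search_problem (see puzzle_problem(), grid_problem(), search_problem())")
  }
  switch(problem$kind,
    puzzle = list(kind = "puzzle", start = problem$start, goal = problem$goal),
    grid = {
      m <- problem$map
      list(kind = "grid", blocked = m$blocked,
           start = as.integer(m$start), goal = as.integer(m$goal),
           connectivity = as.integer(m$connectivity))
    },
    custom = list(kind = "custom", initial = problem$initial,
                  successors = problem$successors,
                  heuristic = problem$heuristic,
                  goal_test = problem$goal_test),
    stop("unknown problem kind")
  )
}

#' Define a search problem over an arbitrary state space
#'
#' States are opaque character tokens.  `successors(state)` must return a
#' `data.frame(state = character, cost = numeric)` with strictly positive
#' costs, in a deterministic order (the order fixes tie-breaking);
#' `heuristic(state)` a non-negative estimate of remaining cost with
#' `heuristic(goal) == 0`; `goal_test(state)` a single logical.
#'
#' @param initial Initial state token.
#' @param goal_test Predicate on states.
#' @param successors Successor function.
#' @param heuristic Heuristic function.
#' @return A `search_problem` object.
#' @seealso [puzzle_problem()], [grid_problem()] for the built-in benchmark
#'   domains (which run without R callbacks and are much faster).
#' @export
search_problem <- function(initial, goal_test, successors, heuristic) {
  stopifnot(is.character(initial), length(initial) == 1,
            is.function(goal_test), is.function(successors),
            is.function(heuristic))
  structure(list(kind = "custom", initial = initial, goal_test = goal_test,
                 successors = successors, heuristic = heuristic),
            class = c("custom_problem", "search_problem"))
}

new_search_trace <- function(res, problem) {
  structure(list(
    expansions = res$expansions,
    nodes_expanded = res$nodes_expanded,
    nodes_explored = res$nodes_explored,
    found = res$found,
    solution_path = res$solution_path,
    solution_cost = res$solution_cost,
    h_sequence = res$h_sequence,
    max_omega = res$max_omega,
    budget_exhausted = res$budget_exhausted,
    problem_kind = problem$kind
  ), class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat("<search_trace>", x$problem_kind, "problem:",
      format(x$nodes_expanded, big.mark = ","), "nodes expanded;",
      if (x$found) paste0("solution cost ", format(x$solution_cost),
                          " (", length(x$solution_path), " states)")
      else if (x$budget_exhausted) "node budget exhausted"
      else "no solution (state space exhausted)", "\n")
  invisible(x)
}

#' Admissible A* search
#'
#' Complete A* over the problem's state space using the evaluation
#' `f = 0.5 * (g + h)` (an exact positive scaling of the classical `g + h`,
#' so node ordering is the unmodified admissible ordering).  Ties on `f` are
#' broken by larger `g`, then by first-in insertion order; closed states are
#' re-opened when rediscovered with a lower `g`, so the returned cost is
#' optimal even for admissible-but-inconsistent heuristics.
#'
#' @param problem A `search_problem`.
#' @param node_budget Maximum number of expansions before the run is
#'   abandoned with `budget_exhausted = TRUE`.
#' @param keep_trace Keep the full per-expansion trace data frame (the
#'   per-expansion `h` sequence is always kept).
#' @return A `search_trace`: `expansions` (data frame with columns
#'   `expansion`, `state`, `g`, `h`, `f`, `omega`, `open_size`),
#'   `nodes_expanded` (expansion events, re-expansions of re-opened states
#'   included), `nodes_explored` (distinct states expanded; equals
#'   `nodes_expanded` for consistent heuristics), `found`, `solution_path`,
#'   `solution_cost`, `h_sequence`, `max_omega`, `budget_exhausted`.  A
#'   search that exhausts the reachable space returns `found = FALSE` rather
#'   than an error.
#' @examples
#' p <- puzzle_problem("123456708")
#' astar(p)
#' @export
astar <- function(problem, node_budget = 5e6, keep_trace = TRUE) {
  res <- cpp_search(problem_payload(problem), list(
    mode = "weighted", initial_omega = 0.5,
    trigger_fraction = numeric(), trigger_weight = numeric(),
    monotone = FALSE, reference = 1, epsilon = 0,
    secondary = "h", secondary_fn = NULL,
    node_budget = node_budget, keep_trace = keep_trace))
  new_search_trace(res, problem)
}

#' Suboptimality bound report
#'
#' For a maximum applied weight \eqn{\omega}, weighted A* with an admissible
#' heuristic returns a solution whose cost is at most
#' \eqn{\omega / (1 - \omega)} times the optimal cost (epsilon-admissibility).
#'
#' @param weight_used Maximum weight applied during the run.
#' @param optimal_cost Optimal cost from an admissible reference run or an
#'   exhaustive oracle (may be `NA`).
#' @param achieved_cost Cost of the returned solution.
#' @return A `bound_report` with the bound `weight_used / (1 - weight_used)`
#'   and whether `achieved_cost <= bound * optimal_cost`.
#' @export
bound_report <- function(weight_used, optimal_cost, achieved_cost) {
  b <- weight_used / (1 - weight_used)
  sat <- if (is.na(optimal_cost) || is.na(achieved_cost)) NA
         else achieved_cost <= b * optimal_cost + 1e-9
  structure(list(weight_used = weight_used, suboptimality_bound = b,
                 optimal_cost = optimal_cost, achieved_cost = achieved_cost,
                 bound_satisfied = sat),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat("<bound_report> max omega", x$weight_used,
      "-> bound", format(x$suboptimality_bound, digits = 4),
      "; achieved", format(x$achieved_cost), "vs optimal",
      format(x$optimal_cost), "->",
      if (isTRUE(x$bound_satisfied)) "bound satisfied" else
        if (isFALSE(x$bound_satisfied)) "BOUND VIOLATED" else "bound unknown",
      "\n")
  invisible(x)
}

#' Weighted A* with dynamic re-weighting
#'
#' Best-first search under `f = (1 - omega) * g + omega * h` where `omega`
#' follows a [weight_schedule()].  Trigger fractions are converted to
#' expansion counts against `reference_exploration` (the admissible-A*
#' nodes-expanded count for the same instance); when a trigger fires, the
#' whole OPEN list is re-evaluated and its priority queue rebuilt.  With the
#' trivial schedule the expansion sequence is identical to [astar()]'s.
#'
#' @inheritParams astar
#' @param schedule A [weight_schedule()].
#' @param reference_exploration Expected nodes-expanded of the admissible run
#'   on this problem, used to convert trigger fractions into expansion
#'   counts.  If `NULL` it (and, if needed, `optimal_cost`) is computed by an
#'   internal admissible reference run.
#' @param optimal_cost Optimal cost for the bound report; computed by an
#'   admissible run when `NULL`.
#' @return A list with components `trace` (a `search_trace`) and `bound`
#'   (a [bound_report()]).
#' @examples
#' p <- puzzle_problem("123456708")
#' res <- weighted_astar(p, weight_schedule(0.575))
#' res$bound
#' @export
weighted_astar <- function(problem, schedule = weight_schedule(),
                           reference_exploration = NULL, optimal_cost = NULL,
                           node_budget = 5e6, keep_trace = TRUE) {
  if (!inherits(schedule, "weight_schedule")) {
    stop("schedule must be a weight_schedule")
  }
  needs_ref <- nrow(schedule$triggers) > 0
  if ((is.null(reference_exploration) && needs_ref) || is.null(optimal_cost)) {
    ref <- astar(problem, node_budget = node_budget, keep_trace = FALSE)
    if (!ref$found) stop("admissible reference run found no solution")
    if (is.null(reference_exploration)) {
      reference_exploration <- ref$nodes_expanded
    }
    if (is.null(optimal_cost)) optimal_cost <- ref$solution_cost
  }
  if (needs_ref && (!is.numeric(reference_exploration) ||
                    reference_exploration <= 0)) {
    stop("reference_exploration must be a positive count")
  }
  res <- cpp_search(problem_payload(problem), list(
    mode = "weighted", initial_omega = schedule$initial_weight,
    trigger_fraction = as.numeric(schedule$triggers$fraction),
    trigger_weight = as.numeric(schedule$triggers$weight),
    monotone = schedule$monotone,
    reference = as.numeric(reference_exploration %||% 1),
    epsilon = 0, secondary = "h", secondary_fn = NULL,
    node_budget = node_budget, keep_trace = keep_trace))
  trace <- new_search_trace(res, problem)
  bound <- bound_report(res$max_omega, optimal_cost, trace$solution_cost)
  list(trace = trace, bound = bound)
}

#' FOCAL (A*-epsilon) search
#'
#' At each step the FOCAL subset of OPEN contains every node whose
#' `f = 0.5 * (g + h)` is within a factor `(1 + epsilon)` of the best `f`;
#' the expanded node minimises the secondary heuristic within FOCAL.  With an
#' admissible primary heuristic the returned cost is at most
#' `(1 + epsilon)` times optimal.
#'
#' @inheritParams astar
#' @param epsilon Relative slack, `>= 0`.  `epsilon = 0` reduces FOCAL to the
#'   argmin set of `f`.
#' @param secondary_h `"h"` (the primary heuristic), `"constant"` (FOCAL
#'   tie-breaking only), or a function `state -> score`.
#' @return A `search_trace`.
#' @export
focal_search <- function(problem, epsilon = 0, secondary_h = "h",
                         node_budget = 5e6, keep_trace = TRUE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0) {
    stop("epsilon must be a single non-negative number")
  }
  if (is.function(secondary_h)) {
    sec <- "custom"
    fn <- secondary_h
  } else {
    sec <- match.arg(secondary_h, c("h", "constant"))
    fn <- NULL
  }
  res <- cpp_search(problem_payload(problem), list(
    mode = "focal", initial_omega = 0.5,
    trigger_fraction = numeric(), trigger_weight = numeric(),
    monotone = FALSE, reference = 1, epsilon = epsilon,
    secondary = sec, secondary_fn = fn,
    node_budget = node_budget, keep_trace = keep_trace))
  new_search_trace(res, problem)
}

#' Backtracking (oscillation) score of a search trace
#'
#' Counts the expansion steps at which the heuristic value of the expanded
#' node exceeds that of the previously expanded node — an operational proxy
#' for the oscillations of the expanded-node heuristic trajectory that
#' indicate backtracking away from the solution path.
#'
#' @param trace A `search_trace`, or a numeric vector of per-expansion
#'   heuristic values.
#' @return The number of increases in the expanded-node `h` sequence.
#' @examples
#' backtracking_score(c(3, 2, 3, 1)) # 1
#' @export
backtracking_score <- function(trace) {
  h <- if (inherits(trace, "search_trace")) trace$h_sequence else
    as.numeric(trace)
  if (length(h) == 0) stop("trace is empty")
  sum(diff(h) > 1e-9)
}

#' Export a search trace as CSV
#'
#' One row per expansion with columns `expansion_index`, `state_id`, `g`,
#' `h`, `f`, `omega`, `open_size`.
#'
#' @param trace A `search_trace` produced with `keep_trace = TRUE`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  stopifnot(inherits(trace, "search_trace"))
  if (is.null(trace$expansions)) {
    stop("trace was produced with keep_trace = FALSE")
  }
  df <- trace$expansions
  names(df)[names(df) == "expansion"] <- "expansion_index"
  names(df)[names(df) == "state"] <- "state_id"
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a run summary as JSON
#'
#' @param trace A `search_trace`.
#' @param file Output path.
#' @param bound Optional [bound_report()] to embed.
#' @return `file`, invisibly.
#' @export
write_run_summary <- function(trace, file, bound = NULL) {
  stopifnot(inherits(trace, "search_trace"))
  x <- list(nodes_expanded = trace$nodes_expanded,
            found = trace$found,
            solution_cost = trace$solution_cost,
            solution_length = if (trace$found) length(trace$solution_path)
                              else NA_integer_,
            max_omega = trace$max_omega,
            budget_exhausted = trace$budget_exhausted)
  if (!is.null(bound)) x$bound <- unclass(bound)
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file)
}
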