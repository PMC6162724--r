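# Benchmark problem domains: the 8-puzzle and occupancy-grid path planning,
# with instance generators and exhaustive oracles.

PUZZLE_GOAL <- "123456780"
PUZZLE_DIAMETER <- 31L

validate_puzzle_state <- function(state, what = "state") {
  if (!is.character(state) || length(state) != 1 || nchar(state) != 9 ||
      !setequal(strsplit(state, "")[[1]], as.character(0:8))) {
    stop(sprintf("%s must be a 9-character string containing each digit 0-8 once", what))
  }
  invisible(state)
}

#' 8-puzzle search problem
#'
#' States are 9-character digit strings in row-major order, `0` marking the
#' blank (row 0 at the top).  Moves slide a tile into the blank at unit cost;
#' the heuristic is the Manhattan distance of misplaced tiles, which is
#' admissible and consistent.
#'
#' @param start,goal Puzzle states.
#' @return A `search_problem`.
#' @examples
#' p <- puzzle_problem("123456708")
#' astar(p)$solution_cost
#' @export
puzzle_problem <- function(start, goal = PUZZLE_GOAL) {
  validate_puzzle_state(start, "start")
  validate_puzzle_state(goal, "goal")
  structure(list(kind = "puzzle", start = start, goal = goal),
            class = c("puzzle_problem", "search_problem"))
}

#' Manhattan-distance heuristic for the 8-puzzle
#'
#' Sum over non-blank tiles of `|delta row| + |delta col|` between the tile's
#' current cell and its goal cell; zero exactly at the goal, and a lower
#' bound on the number of unit-cost moves remaining.
#'
#' @param state,goal Puzzle states.
#' @return The heuristic value (non-negative integer-valued double).
#' @examples
#' puzzle_heuristic("123456780", "123456780") # 0
#' @export
puzzle_heuristic <- function(state, goal = PUZZLE_GOAL) {
  validate_puzzle_state(state, "state")
  validate_puzzle_state(goal, "goal")
  cpp_puzzle_manhattan(state, goal)
}

#' Is an 8-puzzle instance solvable?
#'
#' The blank's moves do not change the permutation parity of the eight tiles
#' read in row-major order on a width-3 board, so `state` can reach `goal`
#' iff the relative permutation (blank excluded) is even.
#'
#' @param state,goal Puzzle states.
#' @return `TRUE` or `FALSE`.
#' @export
puzzle_solvable <- function(state, goal = PUZZLE_GOAL) {
  validate_puzzle_state(state, "state")
  validate_puzzle_state(goal, "goal")
  s <- strsplit(state, "")[[1]]
  g <- strsplit(goal, "")[[1]]
  s <- s[s != "0"]
  g <- g[g != "0"]
  perm <- match(s, g)
  inv <- 0L
  for (i in seq_len(7L)) inv <- inv + sum(perm[(i + 1L):8L] < perm[i])
  inv %% 2L == 0L
}

# Cache of exhaustive BFS distance tables, keyed by goal state.
.bfs_cache <- new.env(parent = emptyenv())

#' Exhaustive BFS distance table for the 8-puzzle
#'
#' Breadth-first search from `goal` over the full reachable half of the
#' 362,880-permutation space.  Entry `rank + 1` holds the optimal move count
#' for the state with lexicographic permutation rank `rank`, or `-1` for
#' unreachable states.  The table is the package's optimality oracle and is
#' cached per goal.
#'
#' @param goal Goal state.
#' @return An integer vector of length 362,880.
#' @export
puzzle_distance_table <- function(goal = PUZZLE_GOAL) {
  validate_puzzle_state(goal, "goal")
  if (is.null(.bfs_cache[[goal]])) {
    .bfs_cache[[goal]] <- cpp_bfs_distances(goal)
  }
  .bfs_cache[[goal]]
}

#' Oracle-optimal solution length of an 8-puzzle instance
#'
#' @param state,goal Puzzle states.
#' @return The optimal number of moves, or `NA` if `state` cannot reach
#'   `goal`.
#' @export
puzzle_optimal_length <- function(state, goal = PUZZLE_GOAL) {
  validate_puzzle_state(state, "state")
  d <- puzzle_distance_table(goal)[cpp_rank_state(state) + 1L]
  if (d < 0) NA_integer_ else d
}

#' Random scramble of an 8-puzzle state
#'
#' Performs `k` random blank moves from `goal` (never undoing the previous
#' move), so the result is always solvable.
#'
#' @param goal Starting state of the walk.
#' @param k Number of moves.
#' @param seed Integer seed.
#' @return A puzzle state.
#' @export
random_scramble <- function(goal = PUZZLE_GOAL, k = 30, seed = 1L) {
  validate_puzzle_state(goal, "goal")
  withr::with_seed(seed, {
    cur <- strsplit(goal, "")[[1]]
    prev_blank <- -1L
    for (i in seq_len(k)) {
      b <- which(cur == "0")
      br <- (b - 1L) %/% 3L
      bc <- (b - 1L) %% 3L
      cand <- c(if (br > 0) b - 3L, if (br < 2) b + 3L,
                if (bc > 0) b - 1L, if (bc < 2) b + 1L)
      cand <- cand[cand != prev_blank]
      nb <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      prev_blank <- b
      cur[c(b, nb)] <- cur[c(nb, b)]
    }
    paste(cur, collapse = "")
  })
}

#' Generate solvable 8-puzzle instances of a minimum difficulty
#'
#' Samples uniformly from the states whose oracle-optimal solution length is
#' at least `difficulty`, using the exhaustive BFS distance table, so every
#' instance carries a verified difficulty label.
#'
#' @param n Number of instances.
#' @param difficulty Minimum optimal solution length (at most 31, the
#'   8-puzzle diameter).
#' @param seed Integer seed (same seed, same instances).
#' @param goal Goal state shared by all instances.
#' @return A data frame with columns `start`, `goal`, `optimal_length`.
#' @examples
#' generate_puzzle_instances(3, difficulty = 20, seed = 7)
#' @export
generate_puzzle_instances <- function(n, difficulty = 0, seed = 1L,
                                      goal = PUZZLE_GOAL) {
  if (difficulty > PUZZLE_DIAMETER) {
    stop("difficulty exceeds the 8-puzzle diameter (31 moves)")
  }
  tab <- puzzle_distance_table(goal)
  eligible <- which(tab >= difficulty) - 1L  # 0-based ranks, excludes -1
  if (!length(eligible)) stop("no states at the requested difficulty")
  ranks <- withr::with_seed(seed,
    eligible[sample.int(length(eligible), n, replace = n > length(eligible))])
  data.frame(start = cpp_unrank_states(ranks),
             goal = goal,
             optimal_length = tab[ranks + 1L],
             stringsAsFactors = FALSE)
}

# --- grids -----------------------------------------------------------------

#' Occupancy-grid map
#'
#' Cells are 0-based `(row, col)` pairs, row 0 at the top.  Moves are
#' 4-connected at unit cost by default, or 8-connected with `sqrt(2)`
#' diagonals (corner cutting through blocked orthogonal neighbours is
#' forbidden).
#'
#' @param width,height Cell counts.
#' @param blocked Logical `height x width` matrix (`TRUE` = blocked), or
#'   `NULL` for a fully free map.
#' @param start,goal Free cells as `c(row, col)`, 0-based.
#' @param connectivity 4 or 8.
#' @return A `grid_map` object.
#' @export
grid_map <- function(width, height, blocked = NULL,
                     start = c(0, 0), goal = c(height - 1, width - 1),
                     connectivity = 4) {
  stopifnot(width >= 1, height >= 1, connectivity %in% c(4, 8))
  if (is.null(blocked)) blocked <- matrix(FALSE, height, width)
  blocked <- as.matrix(blocked)
  storage.mode(blocked) <- "logical"
  if (!identical(dim(blocked), c(as.integer(height), as.integer(width)))) {
    stop("blocked must be a height x width logical matrix")
  }
  start <- as.integer(start)
  goal <- as.integer(goal)
  in_grid <- function(cell) {
    all(cell >= 0) && cell[1] < height && cell[2] < width
  }
  if (!in_grid(start) || !in_grid(goal)) stop("start/goal outside the grid")
  if (blocked[start[1] + 1, start[2] + 1] || blocked[goal[1] + 1, goal[2] + 1]) {
    stop("start and goal must be free cells")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 blocked = blocked, start = start, goal = goal,
                 connectivity = as.integer(connectivity)),
            class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat("<grid_map>", x$height, "x", x$width, "cells,",
      sum(x$blocked), "blocked,", x$connectivity, "-connected;",
      "start (", paste(x$start, collapse = ","), ") goal (",
      paste(x$goal, collapse = ","), ")\n")
  invisible(x)
}

#' Grid path-planning search problem
#'
#' @param map A [grid_map()].
#' @return A `search_problem` over the map's free cells, with the
#'   straight-line (Euclidean) distance to the goal as heuristic.
#' @export
grid_problem <- function(map) {
  stopifnot(inherits(map, "grid_map"))
  structure(list(kind = "grid", map = map),
            class = c("grid_problem", "search_problem"))
}

#' Straight-line heuristic between grid cells
#'
#' Euclidean distance in cell units; admissible for both 4-connected unit
#' moves and 8-connected unit/`sqrt(2)` moves.
#'
#' @param cell,goal_cell Cells as `c(row, col)`.
#' @return The Euclidean distance.
#' @examples
#' grid_heuristic(c(0, 0), c(3, 4)) # 5
#' @export
grid_heuristic <- function(cell, goal_cell) {
  sqrt(sum((as.numeric(cell) - as.numeric(goal_cell))^2))
}

# Build the igraph representation of a map's free cells.  Used only by the
# Dijkstra oracle, which is deliberately a separate code path from the A*
# engine.
grid_igraph <- function(map) {
  h <- map$height
  w <- map$width
  free <- !map$blocked
  id <- matrix(NA_integer_, h, w)
  id[free] <- seq_len(sum(free))
  edges <- integer(0)
  weights <- numeric(0)
  add_edges <- function(r1, c1, r2, c2, cost) {
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    r1 <- r1[ok]; c1 <- c1[ok]; r2 <- r2[ok]; c2 <- c2[ok]
    ok <- free[cbind(r1, c1)] & free[cbind(r2, c2)]
    if (cost > 1) {  # diagonal: forbid corner cutting
      ok <- ok & free[cbind(r1, c2)] & free[cbind(r2, c1)]
    }
    r1 <- r1[ok]; c1 <- c1[ok]; r2 <- r2[ok]; c2 <- c2[ok]
    if (length(r1)) {
      edges <<- c(edges, rbind(id[cbind(r1, c1)], id[cbind(r2, c2)]))
      weights <<- c(weights, rep(cost, length(r1)))
    }
  }
  rc <- which(free, arr.ind = TRUE)
  r <- rc[, 1]; cc <- rc[, 2]
  add_edges(r, cc, r, cc + 1L, 1)
  add_edges(r, cc, r + 1L, cc, 1)
  if (map$connectivity == 8) {
    add_edges(r, cc, r + 1L, cc + 1L, sqrt(2))
    add_edges(r, cc, r + 1L, cc - 1L, sqrt(2))
  }
  g <- igraph::make_empty_graph(n = sum(free), directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, edges, weight = weights)
  }
  list(graph = g, id = id)
}

#' Dijkstra-oracle optimal cost of a grid map
#'
#' Exhaustive shortest-path cost from start to goal computed with
#' `igraph::distances()` over the free-cell graph — an independent oracle for
#' the A* engine.
#'
#' @param map A [grid_map()].
#' @return The optimal cost, or `Inf` if the goal is unreachable.
#' @export
grid_optimal_cost <- function(map) {
  stopifnot(inherits(map, "grid_map"))
  gi <- grid_igraph(map)
  s <- gi$id[map$start[1] + 1, map$start[2] + 1]
  g <- gi$id[map$goal[1] + 1, map$goal[2] + 1]
  as.numeric(igraph::distances(gi$graph, v = s, to = g))
}

#' Generate a random grid map of a given obstacle density
#'
#' Cells are blocked independently with probability `obstacle_density`
#' (start and goal always free); maps are regenerated until start and goal
#' are connected, up to `max_retries` attempts.
#'
#' @param width,height Cell counts.
#' @param obstacle_density Blocking probability in `[0, 1)`.
#' @param seed Integer seed (same seed, same map).
#' @param connectivity 4 or 8.
#' @param start,goal Cells; default opposite corners.
#' @param max_retries Maximum regeneration attempts.
#' @return A connected [grid_map()].
#' @export
generate_grid <- function(width, height, obstacle_density = 0.2, seed = 1L,
                          connectivity = 4, start = c(0, 0),
                          goal = c(height - 1, width - 1), max_retries = 50) {
  stopifnot(obstacle_density >= 0, obstacle_density < 1)
  withr::with_seed(seed, {
    for (i in seq_len(max_retries)) {
      blocked <- matrix(stats::runif(height * width) < obstacle_density,
                        height, width)
      blocked[start[1] + 1, start[2] + 1] <- FALSE
      blocked[goal[1] + 1, goal[2] + 1] <- FALSE
      map <- grid_map(width, height, blocked, start, goal, connectivity)
      if (is.finite(grid_optimal_cost(map))) return(map)
    }
    stop("could not generate a connected map in ", max_retries, " attempts")
  })
}

# --- plain-text interchange -------------------------------------------------

#' Read/write grid maps as ASCII art
#'
#' One row per line: `#` blocked, `.` free, `S` start, `G` goal.
#'
#' @param map A [grid_map()].
#' @param file Path.
#' @param connectivity Connectivity to attach on read (not encoded in the
#'   ASCII format).
#' @return `write_grid_ascii()` returns `file` invisibly; `read_grid_ascii()`
#'   returns a [grid_map()].
#' @export
write_grid_ascii <- function(map, file) {
  stopifnot(inherits(map, "grid_map"))
  ch <- matrix(".", map$height, map$width)
  ch[map$blocked] <- "#"
  ch[map$start[1] + 1, map$start[2] + 1] <- "S"
  ch[map$goal[1] + 1, map$goal[2] + 1] <- "G"
  writeLines(apply(ch, 1, paste, collapse = ""), file)
  invisible(file)
}

#' @rdname write_grid_ascii
#' @export
read_grid_ascii <- function(file, connectivity = 4) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  ch <- do.call(rbind, strsplit(lines, ""))
  if (!all(ch %in% c("#", ".", "S", "G"))) {
    stop("grid characters must be one of '#', '.', 'S', 'G'")
  }
  start <- which(ch == "S", arr.ind = TRUE)
  goal <- which(ch == "G", arr.ind = TRUE)
  if (nrow(start) != 1 || nrow(goal) != 1) {
    stop("grid must contain exactly one 'S' and one 'G'")
  }
  grid_map(ncol(ch), nrow(ch), ch == "#",
           start = c(start[1, 1] - 1L, start[1, 2] - 1L),
           goal = c(goal[1, 1] - 1L, goal[1, 2] - 1L),
           connectivity = connectivity)
}

#' Read/write grid maps and puzzle instance lists as JSON
#'
#' @param map A [grid_map()].
#' @param instances A data frame as returned by
#'   [generate_puzzle_instances()].
#' @param file Path.
#' @return Writers return `file` invisibly; readers return the object.
#' @export
write_grid_json <- function(map, file) {
  stopifnot(inherits(map, "grid_map"))
  idx <- which(map$blocked, arr.ind = TRUE) - 1L
  jsonlite::write_json(list(
    width = map$width, height = map$height,
    blocked = lapply(seq_len(nrow(idx)),
                     function(i) c(idx[i, 1], idx[i, 2])),
    start = map$start, goal = map$goal,
    connectivity = map$connectivity
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  blocked <- matrix(FALSE, x$height, x$width)
  if (length(x$blocked)) {
    b <- if (is.matrix(x$blocked)) x$blocked else
      matrix(unlist(x$blocked), ncol = 2, byrow = TRUE)
    blocked[b + 1L] <- TRUE
  }
  grid_map(x$width, x$height, blocked, x$start, x$goal, x$connectivity)
}

#' @rdname write_grid_json
#' @export
write_puzzle_instances <- function(instances, file) {
  jsonlite::write_json(instances[c("start", "goal")], file, digits = NA)
  invisible(file)
}

#' @rdname write_grid_json
#' @export
read_puzzle_instances <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$optimal_length <- vapply(seq_len(nrow(x)), function(i) {
    as.integer(puzzle_optimal_length(x$start[i], x$goal[i]))
  }, integer(1))
  x
}
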