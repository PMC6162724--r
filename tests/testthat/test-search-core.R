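test_that("the weighted evaluation function is exact and validates omega", {
  expect_identical(evaluate_f(4, 6, 0.5), 5)
  expect_identical(evaluate_f(0, 0, 0.575), 0)
  expect_equal(evaluate_f(4, 6, 0.575), 5.15)
  expect_identical(evaluate_f(c(4, 0), c(6, 0), 0.575), c(5.15, 0))
  expect_error(evaluate_f(4, 6, 1.2), "omega")
  expect_error(evaluate_f(-1, 6, 0.5), "non-negative")
})

test_that("weight schedules enforce their invariants", {
  s <- weight_schedule(0.5, data.frame(fraction = c(0.1, 0.3),
                                       weight = c(0.55, 0.6)),
                       monotone = TRUE)
  expect_s3_class(s, "weight_schedule")
  expect_error(weight_schedule(0.4), "initial_weight")
  expect_error(weight_schedule(1.0), "initial_weight")
  expect_error(weight_schedule(0.5, data.frame(fraction = c(0.3, 0.1),
                                               weight = c(0.55, 0.6))),
               "strictly increasing")
  expect_error(weight_schedule(0.5, data.frame(fraction = 0.1, weight = 0.4)),
               "weights")
  expect_error(weight_schedule(0.6, data.frame(fraction = 0.1, weight = 0.55),
                               monotone = TRUE),
               "non-decreasing")
})

test_that("A* handles the identity instance and a free 3x3 grid", {
  tr <- astar(puzzle_problem("123456780"))
  expect_true(tr$found)
  expect_identical(tr$nodes_expanded, 1)
  expect_identical(tr$solution_cost, 0)
  expect_identical(tr$solution_path, "123456780")

  g <- astar(grid_problem(grid_map(3, 3)))
  expect_identical(g$solution_cost, 4)
  expect_identical(g$solution_path[1], "0,0")
  expect_identical(g$solution_path[length(g$solution_path)], "2,2")
})

test_that("A* matches the exhaustive BFS oracle on random solvable puzzles", {
  inst <- generate_puzzle_instances(60, difficulty = 0, seed = 101)
  for (i in seq_len(nrow(inst))) {
    tr <- astar(puzzle_problem(inst$start[i]), keep_trace = FALSE)
    expect_identical(tr$solution_cost, as.numeric(inst$optimal_length[i]))
  }
})

test_that("A* matches the Dijkstra oracle on random grids", {
  for (i in 1:8) {
    map <- generate_grid(15, 15, 0.25, seed = 200 + i,
                         connectivity = if (i %% 2) 4 else 8)
    tr <- astar(grid_problem(map), keep_trace = FALSE)
    expect_equal(tr$solution_cost, grid_optimal_cost(map), tolerance = 1e-9)
  }
})

test_that("closed states are re-opened when rediscovered with lower g", {
  tr <- astar(reopen_problem())
  expect_identical(tr$solution_cost, 12)
  expect_identical(tr$solution_path, c("S", "Y", "X", "G"))
  expect_identical(sum(tr$expansions$state == "X"), 2L)
})

test_that("an unsolvable puzzle exhausts its component without error", {
  # goal with tiles 1 and 2 swapped is in the other parity class
  tr <- astar(puzzle_problem("213456780"), keep_trace = FALSE)
  expect_false(tr$found)
  expect_false(tr$budget_exhausted)
  expect_identical(tr$nodes_expanded, 181440)
})

test_that("the node budget aborts the run with a signal, not an exception", {
  hard <- generate_puzzle_instances(1, difficulty = 28, seed = 5)
  tr <- astar(puzzle_problem(hard$start[1]), node_budget = 50,
              keep_trace = FALSE)
  expect_false(tr$found)
  expect_true(tr$budget_exhausted)
  expect_identical(tr$nodes_expanded, 50)
})

test_that("a trivial schedule reproduces the A* expansion sequence exactly", {
  fixtures <- c(
    lapply(generate_puzzle_instances(20, difficulty = 10, seed = 31)$start,
           puzzle_problem),
    lapply(1:3, function(i) grid_problem(
      generate_grid(12, 12, 0.25, seed = 300 + i))))
  for (p in fixtures) {
    a <- astar(p)
    w <- weighted_astar(p, weight_schedule(0.5))$trace
    expect_identical(a$expansions, w$expansions)
  }
})

test_that("weighted A* respects the omega/(1-omega) suboptimality bound", {
  inst <- generate_puzzle_instances(30, difficulty = 15, seed = 77)
  for (i in seq_len(nrow(inst))) {
    p <- puzzle_problem(inst$start[i])
    opt <- inst$optimal_length[i]
    for (w in c(0.55, 0.575, 0.6, 0.65)) {
      # fixed from the onset
      res <- weighted_astar(p, weight_schedule(w), optimal_cost = opt,
                            keep_trace = FALSE)
      expect_true(res$bound$bound_satisfied)
      expect_lte(res$trace$solution_cost, w / (1 - w) * opt + 1e-9)
      # dynamically triggered mid-search
      dyn <- weighted_astar(
        p, weight_schedule(0.5, data.frame(fraction = 0.25, weight = w),
                           monotone = TRUE),
        optimal_cost = opt, keep_trace = FALSE)
      expect_true(dyn$bound$bound_satisfied)
    }
  }
})

test_that("overweighting the heuristic shrinks the search on hard instances", {
  hard <- generate_puzzle_instances(10, difficulty = 30, seed = 13)
  wins <- vapply(seq_len(nrow(hard)), function(i) {
    p <- puzzle_problem(hard$start[i])
    a <- astar(p, keep_trace = FALSE)
    w <- weighted_astar(p, weight_schedule(0.575),
                        optimal_cost = hard$optimal_length[i],
                        keep_trace = FALSE)
    w$trace$nodes_expanded < a$nodes_expanded
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("every trace record satisfies f = (1-omega) g + omega h", {
  hard <- generate_puzzle_instances(2, difficulty = 25, seed = 19)
  for (i in 1:2) {
    res <- weighted_astar(
      puzzle_problem(hard$start[i]),
      weight_schedule(0.5, data.frame(fraction = c(0.1, 0.3),
                                      weight = c(0.55, 0.6)),
                      monotone = TRUE))
    e <- res$trace$expansions
    expect_equal(e$f, (1 - e$omega) * e$g + e$omega * e$h, tolerance = 1e-12)
    expect_true(any(e$omega > 0.5))       # the triggers actually fired
    expect_true(all(diff(e$omega) >= 0))  # monotone schedule
    expect_identical(nrow(e), as.integer(res$trace$nodes_expanded))
  }
})

test_that("identical inputs give byte-identical traces", {
  hard <- generate_puzzle_instances(1, difficulty = 26, seed = 23)
  sched <- weight_schedule(0.5, data.frame(fraction = 0.1, weight = 0.575))
  r1 <- weighted_astar(puzzle_problem(hard$start[1]), sched)
  r2 <- weighted_astar(puzzle_problem(hard$start[1]), sched)
  expect_identical(r1$trace, r2$trace)
})

test_that("FOCAL with zero slack and secondary h reproduces A*", {
  inst <- generate_puzzle_instances(8, difficulty = 12, seed = 41)
  for (s in inst$start) {
    p <- puzzle_problem(s)
    expect_identical(focal_search(p, epsilon = 0)$expansions,
                     astar(p)$expansions)
  }
})

test_that("FOCAL search is (1+epsilon)-admissible and complete", {
  inst <- generate_puzzle_instances(20, difficulty = 10, seed = 53)
  for (i in seq_len(nrow(inst))) {
    tr <- focal_search(puzzle_problem(inst$start[i]), epsilon = 0.5,
                       keep_trace = FALSE)
    expect_lte(tr$solution_cost, 1.5 * inst$optimal_length[i] + 1e-9)
  }
  # huge slack with an uninformative secondary still finds a solution
  tr <- focal_search(grid_problem(grid_map(3, 3)), epsilon = 10,
                     secondary_h = "constant")
  expect_true(tr$found)
  expect_gte(tr$solution_cost, 4)
  # custom secondary functions are honoured
  tr2 <- focal_search(grid_problem(grid_map(3, 3)), epsilon = 0.2,
                      secondary_h = function(s) 1)
  expect_true(tr2$found)
})

test_that("backtracking_score counts increases of the expanded-node h", {
  expect_identical(backtracking_score(c(5, 4, 3, 2)), 0L)
  expect_identical(backtracking_score(c(3, 2, 3, 1)), 1L)
  expect_error(backtracking_score(numeric()), "empty")
  hard <- generate_puzzle_instances(1, difficulty = 30, seed = 61)
  p <- puzzle_problem(hard$start[1])
  a <- astar(p)
  expect_identical(backtracking_score(a),
                   backtracking_score(a$h_sequence))
})

test_that("trace CSV and run-summary JSON exports round-trip the key fields", {
  tr <- astar(puzzle_problem("123456708"))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_trace_csv(tr, csv)
  df <- read.csv(csv)
  expect_identical(names(df), c("expansion_index", "state_id", "g", "h", "f",
                                "omega", "open_size"))
  expect_identical(nrow(df), as.integer(tr$nodes_expanded))
  write_run_summary(tr, js, bound = bound_report(0.5, 1, 1))
  x <- jsonlite::read_json(js)
  expect_identical(x$nodes_expanded, 2L)
  expect_identical(x$solution_cost, 1L)
})
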