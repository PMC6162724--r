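test_that("the effect-to-weight mapping is linear, gated and saturating", {
  cfg <- mapping_config()
  expect_identical(map_effect_to_weight(fake_stats(0), cfg), 0.5)
  expect_identical(map_effect_to_weight(fake_stats(2), cfg), 0.6)
  expect_identical(map_effect_to_weight(fake_stats(1.5), cfg), 0.6)
  expect_equal(map_effect_to_weight(fake_stats(0.75), cfg), 0.55)
  expect_identical(map_effect_to_weight(fake_stats(3, success = FALSE), cfg),
                   0.5)
  expect_identical(map_effect_to_weight(fake_stats(-1), cfg), 0.5)
  # without the significance gate the raw effect size drives the weight
  cfg2 <- mapping_config(require_significance = FALSE)
  expect_equal(map_effect_to_weight(fake_stats(0.75, success = FALSE), cfg2),
               0.55)
  # monotone non-decreasing and bounded
  ws <- vapply(seq(-0.5, 2.5, by = 0.25),
               function(d) map_effect_to_weight(fake_stats(d), cfg),
               numeric(1))
  expect_true(all(diff(ws) >= 0))
  expect_true(all(ws >= 0.5 & ws <= 0.6))
})

test_that("mapping configuration validates its bounds", {
  expect_error(mapping_config(omega_max = 1.1))
  expect_error(mapping_config(omega_max = 0.5))
  expect_error(mapping_config(d_max = 0))
  expect_error(mapping_config(trigger_fraction = 0.3), "0.25")
})

test_that("the feedback beam value is clamped linear focusing", {
  expect_identical(feedback_value(0, 0, 1), 0)
  expect_identical(feedback_value(1, 0, 1), 1)
  expect_identical(feedback_value(0.5, 0, 1), 0.5)
  expect_identical(feedback_value(5, 0, 1), 1)
  expect_identical(feedback_value(-3, 0, 1), 0)
  expect_equal(feedback_value(c(0.3, 0.9), 0.1, 0.4), c(0.5, 1))
  expect_error(feedback_value(1, 0, 0), "positive")
})

test_that("repeated interventions install the running-maximum weight", {
  expect_identical(install_weights(c(0.55, 0.52, 0.58)),
                   c(0.55, 0.55, 0.58))
  expect_identical(install_weights(c(0.55, 0.52, 0.58), monotone = FALSE),
                   c(0.55, 0.52, 0.58))
})

test_that("a non-responder closed loop preserves the admissible search", {
  prot <- block_protocol()
  inst <- generate_puzzle_instances(1, difficulty = 24, seed = 3)
  subj <- virtual_subject(state_gain = 0, responder = FALSE, noise_sd = 0.5,
                          seed = 12L)
  lr <- run_closed_loop_puzzle(inst, subj, prot)
  expect_identical(lr$omega_applied, 0.5)
  expect_identical(nrow(lr$schedule$triggers), 0L)
  expect_identical(lr$trace$nodes_expanded, lr$reference_exploration)
  expect_identical(lr$reduction, 0)
  expect_identical(lr$trace$solution_cost, as.numeric(inst$optimal_length))
})

test_that("a strong responder shrinks the search on a hard instance", {
  prot <- block_protocol()
  inst <- generate_puzzle_instances(1, difficulty = 30, seed = 8)
  subj <- virtual_subject(state_gain = 1, noise_sd = 0, seed = 5L)
  lr <- run_closed_loop_puzzle(inst, subj, prot)
  expect_identical(lr$omega_applied, 0.6)  # d capped at d_max
  expect_lt(lr$trace$nodes_expanded, lr$reference_exploration)
  expect_gt(lr$reduction, 0)
  expect_true(lr$bound$bound_satisfied)
  expect_true(all(lr$feedback_series >= 0 & lr$feedback_series <= 1))
})

test_that("closed-loop runs serialise identically under a fixed seed", {
  prot <- block_protocol()
  inst <- generate_puzzle_instances(1, difficulty = 26, seed = 15)
  subj <- virtual_subject(state_gain = 0.6, noise_sd = 0.5, seed = 44L)
  r1 <- run_closed_loop_puzzle(inst, subj, prot, seed = 2024L)
  r2 <- run_closed_loop_puzzle(inst, subj, prot, seed = 2024L)
  expect_identical(r1, r2)
  j1 <- jsonlite::toJSON(loop_summary(r1), auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(loop_summary(r2), auto_unbox = TRUE, digits = NA)
  expect_identical(j1, j2)
})

test_that("the grid loop applies monotone weights and stays within bound", {
  prot <- block_protocol()
  map <- generate_grid(30, 30, 0.3, seed = 4)
  subj <- virtual_subject(state_gain = 0.5, noise_sd = 0.5, seed = 21L)
  lr <- run_closed_loop_grid(map, subj, prot, n_updates = 3)
  expect_identical(lr$installed_weights, cummax(lr$candidate_weights))
  expect_true(all(diff(lr$installed_weights) >= 0))
  expect_true(lr$bound$bound_satisfied)
  expect_lte(lr$trace$solution_cost,
             max(lr$installed_weights) / (1 - max(lr$installed_weights)) *
               grid_optimal_cost(map) + 1e-9)
  # all-null input: the path is the admissible A* path
  null_subj <- virtual_subject(state_gain = 0, responder = FALSE,
                               noise_sd = 0.5, seed = 9L)
  lr0 <- run_closed_loop_grid(map, null_subj, prot, n_updates = 3)
  expect_identical(lr0$trace$solution_path,
                   astar(grid_problem(map))$solution_path)
  expect_identical(lr0$reduction, 0)
})

test_that("responder cohorts reduce the search more than non-responders", {
  prot <- block_protocol()
  inst <- generate_puzzle_instances(1, difficulty = 28, seed = 10)
  resp <- sample_subjects(8, responder = TRUE, seed = 71)
  nonr <- sample_subjects(8, responder = FALSE, seed = 72)
  red <- function(subjects) {
    mean(vapply(subjects, function(s) {
      run_closed_loop_puzzle(inst, s, prot)$reduction
    }, numeric(1)))
  }
  expect_gt(red(resp), red(nonr))
})

test_that("loop results write a summary and trace to disk", {
  prot <- block_protocol()
  inst <- generate_puzzle_instances(1, difficulty = 20, seed = 33)
  lr <- run_closed_loop_puzzle(inst, virtual_subject(seed = 2L), prot)
  d <- withr::local_tempdir()
  write_loop_result(lr, d)
  expect_true(file.exists(file.path(d, "summary.json")))
  expect_true(file.exists(file.path(d, "trace.csv")))
  x <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_identical(x$domain, "puzzle")
})
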