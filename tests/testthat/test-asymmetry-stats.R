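test_that("the asymmetry score is the left-right channel-mean difference", {
  prot <- block_protocol()
  n <- 50
  ch <- matrix(1, n, 8, dimnames = list(NULL, paste0("ch", 0:7)))
  df <- data.frame(time_s = seq_len(n) / 10, ch)
  expect_identical(asymmetry(df), rep(0, n))
  df[paste0("ch", 0:3)] <- 1.0
  df[paste0("ch", 4:7)] <- 0.5
  expect_identical(asymmetry(df), rep(0.5, n))
  expect_error(asymmetry(df[, -2]), "8 channels")
})

test_that("asymmetry matches a naive loop and is linear", {
  st <- simulate_block(virtual_subject(trait_asymmetry = 0.3, noise_sd = 0.4,
                                       seed = 17L),
                       block_protocol(), 0)
  a <- asymmetry(st)
  naive <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    left <- right <- 0
    for (k in 0:3) left <- left + st[[paste0("ch", k)]][i]
    for (k in 4:7) right <- right + st[[paste0("ch", k)]][i]
    naive[i] <- left / 4 - right / 4
  }
  expect_equal(a, naive, tolerance = 1e-12)
  st2 <- st
  st2[paste0("ch", 0:7)] <- st[paste0("ch", 0:7)] * 3
  expect_equal(asymmetry(st2), 3 * a, tolerance = 1e-12)
  st3 <- st
  st3[paste0("ch", 0:7)] <- st[paste0("ch", 0:7)] + 11
  expect_equal(asymmetry(st3), a, tolerance = 1e-10)
})

test_that("identical baseline and neurofeedback windows give d = 0, no success", {
  prot <- block_protocol(data.frame(label = c("rest", "nf", "washout"),
                                    duration = c(30, 17, 10)))
  vals <- withr::with_seed(5, rnorm(100))
  st <- identical_window_stream(vals, prot)
  bs <- score_block(st, prot, seed = 1)
  expect_equal(bs$effect_size, 0, tolerance = 1e-12)
  expect_equal(bs$t_statistic, 0, tolerance = 1e-12)
  expect_false(bs$success)
  expect_gte(bs$p_value, 0.5)
})

test_that("a zero-noise responder block is maximal evidence", {
  prot <- block_protocol()
  st <- simulate_block(virtual_subject(state_gain = 1, noise_sd = 0), prot, 0)
  bs <- score_block(st, prot, seed = 1)
  expect_true(bs$success)
  expect_lt(bs$p_value, 1e-6)
  expect_identical(bs$bootstrap_fraction, 1)
})

test_that("degenerate and undersized windows raise the documented errors", {
  prot <- block_protocol()
  st <- simulate_block(virtual_subject(state_gain = 0, noise_sd = 0), prot, 0)
  expect_error(score_block(st, prot), "undefined statistic")
  # zero variance in both windows but separated means: capped success
  prot17 <- block_protocol(data.frame(label = c("rest", "nf", "washout"),
                                      duration = c(30, 17, 10)))
  st2 <- identical_window_stream(rep(0, 100), prot17)
  nf_idx <- st2$time_s >= 37 - 1e-9 & st2$time_s < 47 - 1e-9
  st2$ch0[nf_idx] <- 4  # scored-window asymmetry = 1, baseline = 0
  bs2 <- score_block(st2, prot17, d_max = 1.5)
  expect_true(bs2$success)
  expect_identical(bs2$effect_size, 1.5)
  expect_identical(bs2$p_value, 0)
  prot_short <- block_protocol(data.frame(label = c("rest", "nf"),
                                          duration = c(30, 7.2)))
  st3 <- simulate_block(virtual_subject(noise_sd = 0.1), prot_short, 0)
  expect_error(score_block(st3, prot_short), "insufficient data")
})

test_that("type-I error is calibrated near alpha under the null", {
  prot <- block_protocol()
  rej <- vapply(1:300, function(i) {
    s <- virtual_subject(trait_asymmetry = 0.3, state_gain = 0,
                         responder = FALSE, noise_sd = 0.5, seed = 4000L + i)
    score_block(simulate_block(s, prot, 0), prot, boot_reps = 0)$p_value < 0.05
  }, logical(1))
  # binomial 99.9% band around 0.05 for n = 300
  expect_gt(mean(rej), 0.05 - 3.3 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(rej), 0.05 + 3.3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the bootstrap fraction is centred for nulls and saturates for signal", {
  prot <- block_protocol()
  fr <- vapply(1:40, function(i) {
    s <- virtual_subject(state_gain = 0, responder = FALSE, noise_sd = 0.5,
                         seed = 6000L + i)
    score_block(simulate_block(s, prot, 0), prot, boot_reps = 400,
                seed = i)$bootstrap_fraction
  }, numeric(1))
  expect_gt(mean(fr), 0.35)
  expect_lt(mean(fr), 0.65)
})

test_that("session success requires at least half successful blocks", {
  ok <- fake_stats(1, success = TRUE)
  no <- fake_stats(0, success = FALSE)
  expect_true(session_success(c(rep(list(ok), 3), rep(list(no), 3))))
  expect_false(session_success(c(rep(list(ok), 2), rep(list(no), 4))))
  expect_true(session_success(list(ok)))
  expect_false(session_success(list(no)))
  expect_error(session_success(list()), "at least one")
})

test_that("block statistics export as JSON and session CSV", {
  prot <- block_protocol()
  stats <- lapply(1:2, function(i) {
    score_block(simulate_block(virtual_subject(state_gain = 1, noise_sd = 0.4,
                                               seed = i), prot, 0),
                prot, seed = i)
  })
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_block_stats_json(stats, f1)
  x <- jsonlite::read_json(f1)
  expect_length(x, 2)
  expect_equal(x[[1]]$effect_size, stats[[1]]$effect_size, tolerance = 1e-9)
  write_session_csv(stats, f2)
  df <- read.csv(f2)
  expect_identical(names(df), c("block_index", "t", "p", "d",
                                "bootstrap_fraction", "success"))
  expect_identical(df$block_index, c(0L, 1L))
})
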