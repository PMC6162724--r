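# Small hand-built state spaces used across test files.

# A four-node graph with an admissible but inconsistent heuristic that makes
# the engine close state X with a suboptimal g before the cheaper route via Y
# is discovered, forcing a re-open.  Optimal: S -> Y -> X -> G, cost 12.
reopen_problem <- function() {
  edges <- list(
    S = data.frame(state = c("Y", "X"), cost = c(1, 3)),
    Y = data.frame(state = "X", cost = 1),
    X = data.frame(state = "G", cost = 10),
    G = data.frame(state = character(), cost = numeric())
  )
  h <- c(S = 0, Y = 11, X = 0, G = 0)  # true remaining: 12, 11, 10, 0
  search_problem("S",
                 goal_test = function(s) s == "G",
                 successors = function(s) edges[[s]],
                 heuristic = function(s) unname(h[s]))
}

# Deterministic fake block statistics for mapping tests.
fake_stats <- function(d, success = TRUE) {
  structure(list(t_statistic = NA_real_, p_value = if (success) 0.001 else 0.5,
                 effect_size = d, bootstrap_fraction = NA_real_,
                 success = success, baseline_mean = 0),
            class = "block_stats")
}

# A stream whose baseline and scored neurofeedback windows contain exactly
# the same asymmetry samples (ch0 carries 4x the asymmetry, other channels 0).
identical_window_stream <- function(values, protocol) {
  fs <- protocol$sampling_rate
  total <- sum(protocol$epochs$duration)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  onset <- cumsum(c(0, protocol$epochs$duration))
  epoch <- protocol$epochs$label[findInterval(t, onset[-length(onset)])]
  nf_start <- onset[which(protocol$epochs$label == "nf")]
  nf_end <- onset[which(protocol$epochs$label == "nf") + 1]
  asym <- numeric(n)
  base_idx <- which(t >= nf_start - protocol$baseline_window - 1e-9 &
                      t < nf_start - 1e-9)
  nf_idx <- which(t >= nf_start + protocol$haemodynamic_delay - 1e-9 &
                    t < nf_end - 1e-9)
  stopifnot(length(base_idx) == length(values), length(nf_idx) == length(values))
  asym[base_idx] <- values
  asym[nf_idx] <- values
  ch <- matrix(0, n, 8, dimnames = list(NULL, paste0("ch", 0:7)))
  ch[, 1] <- asym * 4  # asymmetry = mean(left) - mean(right) = ch0 / 4 * ... = asym
  df <- data.frame(time_s = t, ch, epoch_label = epoch,
                   stringsAsFactors = FALSE)
  structure(df, class = c("nirs_stream", "data.frame"),
            sampling_rate = fs, block_index = 0L)
}
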