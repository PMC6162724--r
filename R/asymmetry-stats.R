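# Asymmetry scoring, baseline referencing, real-time significance testing,
# effect size, and bootstrap post-hoc validation.

#' Per-sample prefrontal asymmetry score
#'
#' Averages HbO over the four left channels (`ch0`-`ch3`) and the four right
#' channels (`ch4`-`ch7`), and subtracts the right average from the left
#' average.  The score is linear: scaling all channels scales the score, and
#' any offset common to all eight channels cancels.
#'
#' @param stream A `nirs_stream` (or a data frame with columns
#'   `ch0`...`ch7`).
#' @return A numeric vector, one asymmetry value per sample.
#' @export
asymmetry <- function(stream) {
  if (!all(CHANNEL_NAMES %in% names(stream))) {
    stop("stream must carry exactly the 8 channels ch0..ch7")
  }
  left <- as.matrix(stream[paste0("ch", 0:3)])
  right <- as.matrix(stream[paste0("ch", 4:7)])
  unname(rowMeans(left) - rowMeans(right))
}

#' Score one neurofeedback block
#'
#' The baseline is the final `baseline_window` seconds of the epoch
#' preceding `nf` (its mean is the "zero asymmetry" reference regardless of
#' absolute value); the scored neurofeedback window is the `nf` epoch minus
#' its first `haemodynamic_delay` seconds.  A one-sided two-sample Welch
#' t-test asks whether neurofeedback asymmetry exceeds baseline asymmetry
#' (only left-dominant asymmetry is rewarded); the effect size is Cohen's d
#' with pooled standard deviation; both windows are then resampled with
#' replacement `boot_reps` times and `bootstrap_fraction` is the proportion
#' of resamples whose neurofeedback mean exceeds the baseline mean.
#' The block is successful when `p < alpha` and `bootstrap_fraction >=
#' boot_threshold`.  Degenerate blocks in which both windows have zero
#' variance but different means are treated as maximal evidence: success
#' with `d` capped at `d_max` (the mapping's saturation point).
#'
#' @param stream A `nirs_stream` covering the protocol.
#' @param protocol The [block_protocol()] the stream follows.
#' @param alpha One-sided significance level.
#' @param boot_reps Bootstrap resamples (`0` skips the bootstrap and gates
#'   success on the t-test alone).
#' @param boot_threshold Minimum bootstrap fraction for success.
#' @param d_max Cap applied to `|d|` in the degenerate zero-variance case.
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return A `block_stats` object with `t_statistic`, `p_value` (one-sided),
#'   `effect_size`, `bootstrap_fraction`, `success`, window sizes and
#'   baseline/neurofeedback summaries.
#' @export
score_block <- function(stream, protocol, alpha = 0.05, boot_reps = 1000,
                        boot_threshold = 0.95, d_max = 1.5, seed = NULL) {
  stopifnot(inherits(protocol, "block_protocol"))
  a <- asymmetry(stream)
  t <- stream$time_s
  pt <- protocol_times(protocol)
  base_win <- t >= pt$nf_start - protocol$baseline_window - 1e-9 &
    t < pt$nf_start - 1e-9
  nf_win <- t >= pt$nf_start + protocol$haemodynamic_delay - 1e-9 &
    t < pt$nf_end - 1e-9
  base <- a[base_win]
  nf <- a[nf_win]
  n1 <- length(base)
  n2 <- length(nf)
  if (n1 < 3 || n2 < 3) {
    stop("insufficient data: fewer than 3 samples in a scoring window")
  }
  m1 <- mean(base)
  m2 <- mean(nf)
  s1 <- sd(base)
  s2 <- sd(nf)
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    if (m2 == m1) {
      stop("undefined statistic: zero variance in both windows with equal means")
    }
    up <- m2 > m1
    tstat <- if (up) Inf else -Inf
    p <- if (up) 0 else 1
    d <- if (up) d_max else -d_max
    frac <- if (boot_reps > 0) as.numeric(up) else NA_real_
  } else {
    tt <- t.test(nf, base, alternative = "greater", var.equal = FALSE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
    d <- (m2 - m1) / pooled
    frac <- if (boot_reps > 0) {
      resample <- function() {
        mb <- rowMeans(matrix(sample(nf, boot_reps * n2, replace = TRUE),
                              boot_reps))
        bb <- rowMeans(matrix(sample(base, boot_reps * n1, replace = TRUE),
                              boot_reps))
        mean(mb > bb)
      }
      if (is.null(seed)) resample() else withr::with_seed(seed, resample())
    } else NA_real_
  }
  success <- p < alpha && (is.na(frac) || frac >= boot_threshold)
  structure(list(t_statistic = tstat, p_value = p, effect_size = d,
                 bootstrap_fraction = frac, success = success,
                 alpha = alpha, boot_threshold = boot_threshold,
                 n_baseline = n1, n_nf = n2,
                 baseline_mean = m1, baseline_sd = s1, nf_mean = m2),
            class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf(
    "<block_stats> t = %.3f, p = %.4g, d = %.3f, bootstrap = %s -> %s\n",
    x$t_statistic, x$p_value, x$effect_size,
    if (is.na(x$bootstrap_fraction)) "skipped"
    else sprintf("%.3f", x$bootstrap_fraction),
    if (x$success) "SUCCESS" else "no success"))
  invisible(x)
}

#' Session-level neurofeedback success
#'
#' A session is successful when at least half of its blocks are successful.
#'
#' @param blocks A non-empty list of `block_stats`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' # 3 successes out of 6 blocks meet the "at least half" criterion
#' @export
session_success <- function(blocks) {
  if (length(blocks) == 0) stop("at least one block is required")
  ok <- vapply(blocks, function(b) isTRUE(b$success), logical(1))
  sum(ok) >= length(ok) / 2
}

#' Export block statistics
#'
#' `write_block_stats_json()` writes one JSON object per block;
#' `write_session_csv()` writes a per-session summary with columns
#' `block_index`, `t`, `p`, `d`, `bootstrap_fraction`, `success`.
#'
#' @param blocks A list of `block_stats`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_block_stats_json <- function(blocks, file) {
  jsonlite::write_json(lapply(blocks, unclass), file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}

#' @rdname write_block_stats_json
#' @export
write_session_csv <- function(blocks, file) {
  df <- data.frame(
    block_index = seq_along(blocks) - 1L,
    t = vapply(blocks, `[[`, numeric(1), "t_statistic"),
    p = vapply(blocks, `[[`, numeric(1), "p_value"),
    d = vapply(blocks, `[[`, numeric(1), "effect_size"),
    bootstrap_fraction = vapply(blocks, `[[`, numeric(1),
                                "bootstrap_fraction"),
    success = vapply(blocks, `[[`, logical(1), "success"))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
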