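# Synthetic fNIRS generator: 8-channel HbO streams from parameterised
# virtual subjects under a block protocol, standing in for the human user.

CHANNEL_NAMES <- paste0("ch", 0:7)

#' Virtual neurofeedback subject
#'
#' Parameterises the simulated prefrontal-asymmetry response.  The asymmetry
#' (mean left minus mean right HbO) has a stable resting component
#' (`trait_asymmetry`) and, for responders, a volitional state component that
#' rises during neurofeedback epochs to `state_gain`, attenuated by
#' `fatigue_decay^block_index` to model the drop in performance towards the
#' later blocks of a session.
#'
#' @param trait_asymmetry Baseline left-minus-right HbO offset (signal
#'   units; baseline-relative arbitrary units throughout).
#' @param state_gain Peak volitional asymmetry increase during
#'   neurofeedback (signal units).
#' @param responder If `FALSE`, the effective state gain is zero.
#' @param fatigue_decay Multiplicative per-block attenuation in `(0, 1]`.
#' @param noise_sd Per-channel white-noise standard deviation (`>= 0`).
#' @param drift_slope Slow linear drift common to all channels (units/s);
#'   being common, it cancels in the asymmetry score.
#' @param seed Integer seed; together with the block index it fixes the
#'   noise realisation.
#' @return A `virtual_subject` object.
#' @export
virtual_subject <- function(trait_asymmetry = 0, state_gain = 0.5,
                            responder = TRUE, fatigue_decay = 1,
                            noise_sd = 0.5, drift_slope = 0, seed = 1L) {
  stopifnot(noise_sd >= 0, fatigue_decay > 0, fatigue_decay <= 1,
            is.logical(responder), length(responder) == 1)
  structure(list(trait_asymmetry = trait_asymmetry, state_gain = state_gain,
                 responder = responder, fatigue_decay = fatigue_decay,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 seed = as.integer(seed)),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat("<virtual_subject>",
      if (x$responder) "responder" else "non-responder",
      "| trait", x$trait_asymmetry, "| gain", x$state_gain,
      "| fatigue", x$fatigue_decay, "| noise sd", x$noise_sd,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Neurofeedback block protocol
#'
#' A block is an ordered sequence of epochs (`rest`, `count`, `nf`,
#' `washout`), exactly one of which is the neurofeedback (`nf`) epoch.  The
#' asymmetry baseline is measured over the final `baseline_window` seconds of
#' the epoch immediately preceding `nf` and is treated as zero asymmetry
#' regardless of its absolute value; the scored neurofeedback window starts
#' `haemodynamic_delay` seconds into the `nf` epoch to account for the onset
#' of the haemodynamic response.
#'
#' @param epochs Data frame with columns `label` and `duration` (seconds).
#' @param baseline_window Length of the baseline window (default 10 s).
#' @param haemodynamic_delay Onset delay (default 7 s).
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @return A `block_protocol` object.
#' @export
block_protocol <- function(epochs = data.frame(
                             label = c("rest", "nf", "washout"),
                             duration = c(30, 30, 20)),
                           baseline_window = 10, haemodynamic_delay = 7,
                           sampling_rate = 10) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("label", "duration") %in% names(epochs)),
            all(epochs$duration > 0), baseline_window > 0,
            haemodynamic_delay >= 0, sampling_rate > 0)
  if (!all(epochs$label %in% c("rest", "count", "nf", "washout"))) {
    stop("epoch labels must be one of 'rest', 'count', 'nf', 'washout'")
  }
  nf_i <- which(epochs$label == "nf")
  if (length(nf_i) != 1) stop("exactly one 'nf' epoch is required")
  if (nf_i == 1) stop("the 'nf' epoch needs a preceding baseline epoch")
  if (epochs$duration[nf_i] > 120) {
    stop("the 'nf' epoch may not exceed the 120 s block cap")
  }
  if (baseline_window > epochs$duration[nf_i - 1]) {
    stop("baseline_window exceeds the pre-nf epoch duration")
  }
  if (haemodynamic_delay >= epochs$duration[nf_i]) {
    stop("haemodynamic_delay leaves no scored samples in the nf epoch")
  }
  structure(list(epochs = epochs, baseline_window = baseline_window,
                 haemodynamic_delay = haemodynamic_delay,
                 sampling_rate = sampling_rate, nf_index = nf_i),
            class = "block_protocol")
}

#' @export
print.block_protocol <- function(x, ...) {
  cat("<block_protocol>",
      paste(sprintf("%s(%gs)", x$epochs$label, x$epochs$duration),
            collapse = " -> "),
      "| baseline", x$baseline_window, "s | delay",
      x$haemodynamic_delay, "s |", x$sampling_rate, "Hz\n")
  invisible(x)
}

# Epoch onset times, the nf window, and the saturating-exponential response
# profile evaluated on the sampling grid.
protocol_times <- function(protocol) {
  d <- protocol$epochs$duration
  onset <- cumsum(c(0, d))
  list(onset = onset[seq_along(d)], total = onset[length(onset)],
       nf_start = onset[protocol$nf_index],
       nf_end = onset[protocol$nf_index + 1])
}

response_profile <- function(t, protocol) {
  pt <- protocol_times(protocol)
  delay <- protocol$haemodynamic_delay
  tau <- max(delay, 1e-6)
  p <- numeric(length(t))
  in_nf <- t >= pt$nf_start & t < pt$nf_end
  u <- t[in_nf] - pt$nf_start - delay
  p[in_nf] <- ifelse(u > 0, 1 - exp(-u / tau), 0)
  after <- t >= pt$nf_end
  if (any(after)) {
    u_end <- pt$nf_end - pt$nf_start - delay
    r_end <- if (u_end > 0) 1 - exp(-u_end / tau) else 0
    p[after] <- r_end * exp(-(t[after] - pt$nf_end) / tau)
  }
  p
}

#' Simulate one neurofeedback block of 8-channel HbO
#'
#' Channels 0-3 are left-hemisphere, 4-7 right-hemisphere.  The left
#' channels carry `+trait_asymmetry/2` and the right channels
#' `-trait_asymmetry/2`; during the `nf` epoch, after the haemodynamic
#' delay, the left-right difference rises along a saturating exponential
#' (time constant equal to the delay) towards
#' `state_gain * fatigue_decay^block_index` for responders, and relaxes back
#' during the following epoch.  Per-channel white noise and a common linear
#' drift are added.  The noise realisation is fixed by the subject seed and
#' the block index.
#'
#' @param subject A [virtual_subject()].
#' @param protocol A [block_protocol()].
#' @param block_index 0-based block index within the session (drives
#'   fatigue).
#' @return A `nirs_stream`: a data frame with columns `time_s`,
#'   `ch0`...`ch7`, `epoch_label`.
#' @export
simulate_block <- function(subject, protocol, block_index = 0L) {
  stopifnot(inherits(subject, "virtual_subject"),
            inherits(protocol, "block_protocol"))
  fs <- protocol$sampling_rate
  pt <- protocol_times(protocol)
  n <- round(pt$total * fs)
  t <- (seq_len(n) - 1) / fs
  epoch <- protocol$epochs$label[
    findInterval(t, pt$onset, rightmost.closed = FALSE)]
  amp <- if (subject$responder) {
    subject$state_gain * subject$fatigue_decay^block_index
  } else 0
  resp <- amp * response_profile(t, protocol)
  drift <- subject$drift_slope * t
  half <- (subject$trait_asymmetry + resp) / 2
  base <- cbind(matrix(half, n, 4), matrix(-half, n, 4))
  noise <- withr::with_seed(derive_seed(subject$seed, block_index),
                            matrix(rnorm(n * 8, 0, subject$noise_sd), n, 8))
  ch <- base + drift + noise
  colnames(ch) <- CHANNEL_NAMES
  out <- data.frame(time_s = t, ch, epoch_label = epoch,
                    stringsAsFactors = FALSE)
  structure(out, class = c("nirs_stream", "data.frame"),
            sampling_rate = fs, block_index = block_index)
}

#' Simulate a session of neurofeedback blocks
#'
#' Blocks share the subject's parameters; noise is independent per block and
#' fatigue is applied through the block index, so block `k`'s effective gain
#' is `state_gain * fatigue_decay^k`.
#'
#' @inheritParams simulate_block
#' @param n_blocks Number of blocks (`>= 1`).
#' @return A list of `nirs_stream`s, one per block (indices 0 to
#'   `n_blocks - 1`).
#' @export
simulate_session <- function(subject, protocol, n_blocks) {
  stopifnot(n_blocks >= 1)
  lapply(seq_len(n_blocks) - 1L,
         function(k) simulate_block(subject, protocol, k))
}

#' Read/write HbO streams as CSV
#'
#' Columns `time_s`, `ch0`...`ch7`, `epoch_label`.
#'
#' @param stream A `nirs_stream`.
#' @param file Path.
#' @param sampling_rate Sampling rate to attach on read; inferred from the
#'   time stamps when `NULL`.
#' @return The writer returns `file` invisibly; the reader a `nirs_stream`.
#' @export
write_stream_csv <- function(stream, file) {
  stopifnot(inherits(stream, "nirs_stream"))
  write.csv(as.data.frame(stream), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(file, sampling_rate = NULL) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_s", CHANNEL_NAMES, "epoch_label")
  if (!all(need %in% names(df))) {
    stop("stream CSV must have columns time_s, ch0..ch7, epoch_label")
  }
  fs <- sampling_rate %||%
    (1 / median(diff(df$time_s)))
  structure(df[need], class = c("nirs_stream", "data.frame"),
            sampling_rate = fs, block_index = NA_integer_)
}
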