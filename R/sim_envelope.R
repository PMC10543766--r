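#' Deterministic child seed
#'
#' Derives a 31-bit child seed from a root seed and an index, so that
#' per-subject / per-block streams are reproducible and independent of
#' processing order.
#'
#' @param root Integer root seed.
#' @param index Nonnegative integer stream index.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root, index) {
  # splitmix-style integer hash, kept in double precision (exact below 2^53)
  x <- (as.numeric(root) * 2654435761 + as.numeric(index) * 40503 + 12345) %%
    2147483647
  as.integer(x)
}

# raised-cosine quasi-periodic modulator: one value in [-1, 1] per sample,
# cycle rates drawn independently per cycle, uniform over rate_range
quasi_modulator <- function(n, fs, rate_range) {
  q <- numeric(n)
  i <- 1
  while (i <= n) {
    r <- stats::runif(1, rate_range[1], rate_range[2])
    len <- max(1L, round(fs / r))
    idx <- i:min(n, i + len - 1L)
    u <- (seq_along(idx) - 1) / len
    q[idx] <- -cos(2 * pi * u)
    i <- i + len
  }
  q
}

#' Synthesise a quasi-rhythmic speech amplitude envelope
#'
#' Builds one familiarisation block's envelope as a train of sentences
#' (durations drawn from a truncated normal, separated by the configured
#' inter-sentence interval) whose within-sentence amplitude is
#' `(1 + m_stress * q_s(t)) * (1 + m_syll * q_y(t))`, with `q_s`, `q_y`
#' raised-cosine modulators whose instantaneous rates are redrawn each cycle,
#' uniformly over the stressed-syllable and syllable rate ranges. The
#' resulting modulation spectrum has local maxima inside both ranges.
#'
#' @param config An [sim_config()] object.
#' @param block_index Block number (used only to derive the RNG stream when
#'   `seed` is given).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return An `sbc_envelope`: list with `samples` (nonnegative), `rate` (Hz)
#'   and `t0` (seconds relative to block onset, always 0 here).
#' @export
synth_envelope <- function(config, block_index = 1L, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(child_seed(seed, block_index))
  fs <- config$sampling_rate
  n <- round(config$block_duration_s * fs)
  if (config$block_duration_s < 0.5)
    stop("block duration ", config$block_duration_s,
         " s is too short to fit one sentence")
  env <- numeric(n)
  gap <- round(config$inter_sentence_interval_s * fs)
  i <- 1L
  while (i <= n) {
    dur <- 0
    while (dur <= 0.5)
      dur <- stats::rnorm(1, config$sentence_duration_mean_s,
                          config$sentence_duration_sd_s)
    len <- min(round(dur * fs), n - i + 1L)
    if (len >= 1) {
      qs <- quasi_modulator(len, fs, config$stress_rate_range)
      qy <- quasi_modulator(len, fs, config$syllable_rate_range)
      env[i:(i + len - 1L)] <-
        (1 + config$mod_depth_stress * qs) *
        (1 + config$mod_depth_syllable * qy)
    }
    i <- i + len + gap
  }
  structure(list(samples = pmax(env, 0), rate = fs, t0 = 0),
            class = "sbc_envelope")
}

#' @export
print.sbc_envelope <- function(x, ...) {
  cat(sprintf("<sbc_envelope> %d samples at %g Hz (%.2f s), t0 = %.3f s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate, x$t0))
  invisible(x)
}
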