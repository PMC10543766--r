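beta_from_moments <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  if (k <= 0)
    stop("Beta moments infeasible: sd too large for mean ", mean)
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Synthesise CDI vocabulary scores with known coefficients
#'
#' Ten-month receptive and expressive proportions are drawn from Beta
#' distributions matched to the configured means/SDs. Eighteen-month scores
#' follow the generating linear models: the square root of the expressive
#' proportion is `intercept + b_syll * z_syllable + b_stress * z_stress +
#' b_base * expressive_10 + noise`, and the receptive proportion is
#' `intercept + b_stress * z_stress + b_syll * z_syllable +
#' b_base * receptive_10 + noise`. Proportions are clipped to `[0, 1]`
#' (the square-rooted expressive outcome is clipped before squaring).
#'
#' @param config An [sim_config()]; the model lives in `config$vocab`.
#' @param z_syllable,z_stress Per-subject band coherence z-scores.
#' @param seed Optional seed.
#' @return Data frame with one row per subject: proportions
#'   (`receptive_10`, `expressive_10`, `receptive_18`, `expressive_18`),
#'   integer raw scores and maxima. Attribute `generating` stores the
#'   coefficients used.
#' @export
synth_vocab <- function(config, z_syllable, z_stress, seed = NULL) {
  if (length(z_syllable) != length(z_stress))
    stop("need one z-score pair per subject")
  vb <- config$vocab
  for (m in c("receptive_18", "expressive_18"))
    if (vb[[m]]["noise_sd"] < 0) stop("negative noise SD in ", m)
  if (!is.null(seed)) set.seed(child_seed(seed, 2L))
  n <- length(z_syllable)

  rec10 <- beta_from_moments(n, vb$receptive_10["mean"], vb$receptive_10["sd"])
  exp10 <- beta_from_moments(n, vb$expressive_10["mean"], vb$expressive_10["sd"])

  r18 <- vb$receptive_18
  rec18 <- r18["intercept"] + r18["z_stress"] * z_stress +
    r18["z_syllable"] * z_syllable + r18["baseline"] * rec10 +
    stats::rnorm(n, 0, r18["noise_sd"])
  rec18 <- pmin(pmax(rec18, 0), 1)

  e18 <- vb$expressive_18
  sqrt_e <- e18["intercept"] + e18["z_stress"] * z_stress +
    e18["z_syllable"] * z_syllable + e18["baseline"] * exp10 +
    stats::rnorm(n, 0, e18["noise_sd"])
  sqrt_e <- pmin(pmax(sqrt_e, 0), 1)
  exp18 <- sqrt_e^2

  out <- data.frame(subject = seq_len(n),
                    receptive_10 = rec10, expressive_10 = exp10,
                    receptive_18 = rec18, expressive_18 = exp18,
                    receptive_10_raw = round(rec10 * vb$max_10),
                    expressive_10_raw = round(exp10 * vb$max_10),
                    receptive_18_raw = round(rec18 * vb$max_18),
                    expressive_18_raw = round(exp18 * vb$max_18),
                    max_10 = vb$max_10, max_18 = vb$max_18)
  attr(out, "generating") <- vb[c("receptive_18", "expressive_18")]
  out
}
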