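#' Reduced study configuration
#'
#' A scaled-down cohort used by the package's calibration and power studies:
#' a 7-channel montage, 4 blocks of 10 s per gaze condition (28 four-second
#' epochs per condition on the 1 s sliding grid), no artifacts, high
#' attention, and coupling/background as requested. Block count and duration
#' are chosen so each subject still clears the 25-epochs-per-condition mark
#' after gating while keeping whole-cohort studies fast.
#'
#' @param coupling Coupling list (default: none, i.e. the null model).
#' @param background Background oscillation list.
#' @param channels Montage labels.
#' @param n_subjects Cohort size.
#' @param seed Root seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return An `sbc_config`.
#' @export
study_config <- function(coupling = list(), background = list(),
                         channels = c("Fp1", "F3", "Fz", "F4",
                                      "C3", "Cz", "C4"),
                         n_subjects = 8, seed = 1, ...) {
  sim_config(n_subjects = n_subjects,
             n_blocks_per_condition = 4,
             block_duration_s = 10,
             channel_labels = channels,
             coupling = coupling,
             background = background,
             noise_scale = 15,
             artifact_spec = list(blink_rate_per_min = 0,
                                  blink_amplitude_uv = 0,
                                  movement_rate_per_min = 0,
                                  movement_amplitude_uv = 0),
             attention = list(direct = c(mean = 0.95, concentration = 30),
                              averted = c(mean = 0.95, concentration = 30)),
             seed = seed, ...)
}

#' Syllable-band coupling used by the detection studies
#'
#' A single coupling band covering the syllable rate with gain 3 uV per
#' unit envelope on every channel: strong enough that a 20-subject cohort
#' detects the observed-vs-surrogate effect essentially always, while
#' keeping single-subject coherence in a realistic range.
#'
#' @param gain Coupling gain, uV per unit envelope.
#' @return Coupling list for [sim_config()].
#' @export
detection_coupling <- function(gain = 3) {
  list(list(band = c(2.5, 3.5), gain = gain, phase_lag = 1.88,
            direct_minus_averted = 0))
}

# the studies omit the 0.1-30 Hz filter: zero-phase filtering rescales every
# epoch identically per frequency bin, so coherence, z-scores and the paired
# t-maps are exactly invariant to it (no artifacts are simulated here)
process_cohort <- function(config, n_surrogate = 100,
                           surrogate_conditions = "overall",
                           min_per_condition = 5, filter = FALSE) {
  lapply(seq_len(config$n_subjects), function(i) {
    sub <- simulate_subject(config, i)
    process_subject(sub, n_surrogate = n_surrogate,
                    surrogate_conditions = surrogate_conditions,
                    min_per_condition = min_per_condition, filter = filter)
  })
}

#' Null-calibration study of the surrogate z-scores
#'
#' Simulates coupling-free cohorts and collects the per-subject,
#' per-band overall coherence z-scores. With a correctly calibrated
#' surrogate null their grand mean is near 0 and their SD near 1.
#'
#' @param n_cohorts Number of cohorts (default 50).
#' @param n_subjects Subjects per cohort.
#' @param n_surrogate Surrogate permutations per subject.
#' @param seed Root seed.
#' @return List with `mean`, `sd` and the per-subject `z` table.
#' @export
study_null_calibration <- function(n_cohorts = 50, n_subjects = 4,
                                   n_surrogate = 100, seed = 1) {
  zs <- NULL
  for (c_i in seq_len(n_cohorts)) {
    cfg <- study_config(n_subjects = n_subjects,
                        seed = child_seed(seed, c_i))
    proc <- process_cohort(cfg, n_surrogate = n_surrogate)
    zs <- rbind(zs, t(vapply(proc, function(p)
      p$overall$bandz$summary[c("stress", "syllable")], numeric(2))))
  }
  list(mean = mean(zs), sd = stats::sd(as.numeric(zs)), z = zs)
}

#' False-positive rate of the gaze-condition cluster test under the null
#'
#' Simulates cohorts with identical coupling in both gaze conditions,
#' runs the band-averaged direct-vs-averted cluster permutation test on the
#' syllable band per cohort, and reports the proportion of cohorts with any
#' cluster p below `alpha` (the family-wise error rate).
#'
#' @param n_cohorts Number of null cohorts (default 200).
#' @param n_subjects Subjects per cohort (default 10, so the sign-flip
#'   group of 2^10 assignments is large relative to the permutation count
#'   and discreteness does not mask the nominal level).
#' @param n_perm Cluster permutations per test (escalation disabled so the
#'   stated permutation count is what runs).
#' @param alpha Significance level.
#' @param seed Root seed.
#' @return List with `fpr`, per-cohort `p`, and `n_cohorts`.
#' @export
study_cluster_fpr <- function(n_cohorts = 200, n_subjects = 10,
                              n_perm = 200, alpha = 0.05, seed = 1) {
  freqs <- analysis_freqs()
  band <- analysis_bands()$syllable
  ps <- numeric(n_cohorts)
  for (c_i in seq_len(n_cohorts)) {
    cfg <- study_config(coupling = detection_coupling(1.5),
                        n_subjects = n_subjects,
                        seed = child_seed(seed, c_i))
    proc <- process_cohort(cfg, surrogate_conditions = character(0))
    labels <- rownames(proc[[1]]$direct$coherence$coh)
    adj <- build_adjacency(channel_layout(labels))
    a <- t(vapply(proc, function(p)
      band_average(p$direct$coherence$coh, freqs, band),
      numeric(length(labels))))
    b <- t(vapply(proc, function(p)
      band_average(p$averted$coherence$coh, freqs, band),
      numeric(length(labels))))
    dimnames(a) <- dimnames(b) <- list(NULL, labels)
    res <- permutation_test(a, b, adj, n_perm = n_perm,
                            escalate_to = n_perm)
    ps[c_i] <- min_cluster_p(res)
  }
  list(fpr = mean(ps < alpha), p = ps, n_cohorts = n_cohorts)
}

#' Detection rate of the observed-vs-surrogate coherence test
#'
#' Simulates cohorts with the documented syllable-band coupling and runs
#' the band-averaged observed-vs-surrogate cluster test; a detection is a
#' positive cluster with p below `alpha`.
#'
#' @param n_cohorts Number of cohorts (default 20).
#' @param n_subjects Subjects per cohort (default 20).
#' @param gain Syllable-band coupling gain.
#' @param n_surrogate Surrogate permutations per subject.
#' @param n_perm Cluster permutations.
#' @param alpha Significance level.
#' @param seed Root seed.
#' @return List with `rate` and per-cohort `p`.
#' @export
study_detection <- function(n_cohorts = 20, n_subjects = 20, gain = 3,
                            n_surrogate = 100, n_perm = 200,
                            alpha = 0.05, seed = 1) {
  freqs <- analysis_freqs()
  band <- analysis_bands()$syllable
  ps <- numeric(n_cohorts)
  for (c_i in seq_len(n_cohorts)) {
    cfg <- study_config(coupling = detection_coupling(gain),
                        n_subjects = n_subjects,
                        seed = child_seed(seed, 1000 + c_i))
    proc <- process_cohort(cfg, n_surrogate = n_surrogate)
    labels <- rownames(proc[[1]]$overall$coherence$coh)
    adj <- build_adjacency(channel_layout(labels))
    a <- t(vapply(proc, function(p)
      band_average(p$overall$coherence$coh, freqs, band),
      numeric(length(labels))))
    b <- t(vapply(proc, function(p)
      band_average(p$overall$surrogate$mean, freqs, band),
      numeric(length(labels))))
    dimnames(a) <- dimnames(b) <- list(NULL, labels)
    res <- permutation_test(a, b, adj, n_perm = n_perm,
                            escalate_to = n_perm)
    ps[c_i] <- min_cluster_p(res, sign = 1)
  }
  list(rate = mean(ps < alpha), p = ps)
}

#' Frontal theta background used by the theta detection study
#'
#' A 3-6 Hz oscillatory background with larger amplitude under direct gaze
#' on the frontal electrodes (8 vs 4 uV RMS), emulating an
#' attention-related frontal theta increase.
#'
#' @param channels Frontal channel labels carrying the effect.
#' @return Background list for [sim_config()].
#' @export
frontal_theta_background <- function(channels = c("Fp1", "F3", "Fz", "F4")) {
  amp <- stats::setNames(rep(6, length(channels)), channels)
  d <- stats::setNames(rep(4, length(channels)), channels)
  list(list(band = c(3, 6), amplitude_uv = amp, direct_minus_averted = d))
}

#' Detection rate of the theta-power condition contrast
#'
#' Simulates cohorts with an injected frontal theta-power increase under
#' direct gaze and counts runs in which the theta cluster test finds a
#' significant positive cluster touching a frontal electrode.
#'
#' @param n_runs Number of cohorts.
#' @param n_subjects Subjects per cohort.
#' @param n_perm Cluster permutations.
#' @param alpha Significance level.
#' @param seed Root seed.
#' @return List with `rate` and per-run `p`.
#' @export
study_theta_detection <- function(n_runs = 20, n_subjects = 20,
                                  n_perm = 200, alpha = 0.05, seed = 1) {
  frontal <- c("Fp1", "F3", "Fz", "F4")
  ps <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- study_config(background = frontal_theta_background(frontal),
                        n_subjects = n_subjects,
                        seed = child_seed(seed, 2000 + r))
    proc <- process_cohort(cfg, surrogate_conditions = character(0))
    labels <- rownames(proc[[1]]$power$direct$power)
    adj <- build_adjacency(channel_layout(labels))
    res <- theta_contrast(
      stack_subjects(proc, function(p) p$power$direct$power),
      stack_subjects(proc, function(p) p$power$averted$power),
      adj, n_perm = n_perm, escalate_to = n_perm)
    hit <- Filter(function(cl) cl$sign > 0 && cl$p < alpha &&
                    any(cl$members$channel %in% frontal), res$clusters)
    ps[r] <- if (length(hit) > 0) min(vapply(hit, `[[`, numeric(1), "p")) else 1
  }
  list(rate = mean(ps < alpha), p = ps)
}

#' Parameter recovery of the vocabulary generating model
#'
#' Draws cohorts of band z-scores from the observed z distribution
#' (stress mean 1.71, SD 0.97; syllable mean 1.47, SD 0.86), generates
#' vocabulary scores with [synth_vocab()] at the default coefficients, and
#' refits the generating expressive model (square-root outcome) by OLS.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n Subjects per cohort.
#' @param config Config carrying the vocabulary model.
#' @param seed Root seed.
#' @return List with per-rep `estimate` (syllable coefficient), `covered`
#'   (95% CI covers the generating value), `mean_estimate`, `coverage`,
#'   and the generating `truth`.
#' @export
study_vocab_recovery <- function(n_reps = 100, n = 200,
                                 config = sim_config(n_subjects = n),
                                 seed = 1) {
  truth <- config$vocab$expressive_18["z_syllable"]
  est <- numeric(n_reps); cov <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(child_seed(seed, 3000 + r))
    zs <- stats::rnorm(n, 1.71, 0.97)
    zy <- stats::rnorm(n, 1.47, 0.86)
    sc <- synth_vocab(config, zy, zs)
    fit <- fit_linear(sqrt(sc$expressive_18),
                      data.frame(z_stress = zs, z_syllable = zy,
                                 expressive_10 = sc$expressive_10),
                      transform = "sqrt")
    row <- fit$coefficients[fit$coefficients$term == "z_syllable", ]
    est[r] <- row$estimate
    cov[r] <- row$ci_lo <= truth && truth <= row$ci_hi
  }
  list(estimate = est, covered = cov,
       mean_estimate = mean(est), coverage = mean(cov),
       truth = unname(truth))
}

#' Log-log spectral slope of a signal
#'
#' Least-squares slope of the periodogram on log-log axes over a frequency
#' band; used to check the 1/f noise generator.
#'
#' @param x Signal vector.
#' @param fs Sampling rate, Hz.
#' @param band Frequency band for the fit, Hz.
#' @return Slope (a 1/f^a process gives about `-a`).
#' @export
spectral_slope <- function(x, fs, band = c(1, 30)) {
  n <- length(x)
  pxx <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2]
  # average the periodogram in log-spaced bins to stabilise the fit
  lf <- log(f[sel]); lp <- log(pxx[sel])
  bins <- cut(lf, breaks = 30)
  mf <- tapply(lf, bins, mean); mp <- tapply(lp, bins, mean)
  ok <- !is.na(mf)
  unname(stats::coef(stats::lm(mp[ok] ~ mf[ok]))[2])
}
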