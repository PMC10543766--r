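#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic study: stimulus timing, the
#' rhythm bands of infant-directed speech, the EEG forward model
#' (envelope-to-channel coupling), noise and artifact levels, the looking
#' (attention) process, and the vocabulary-outcome model. Defaults follow the
#' stimulus statistics and cohort structure of the audiovisual familiarisation
#' design the package analyses: ~3.2 s sentences separated by 1.5 s pauses in
#' 18.9 s blocks, stressed syllables at 0.87-1.72 Hz and syllables at
#' 2.62-3.57 Hz, 30 blocks per gaze condition, EEG at 500 Hz.
#'
#' @param sampling_rate EEG/envelope sampling rate in Hz.
#' @param n_subjects Number of infants in the cohort.
#' @param n_blocks_per_condition Familiarisation blocks per gaze condition.
#' @param block_duration_s Familiarisation block duration, seconds.
#' @param sentence_duration_mean_s,sentence_duration_sd_s Normal distribution
#'   of sentence durations (truncated at 0.5 s).
#' @param inter_sentence_interval_s Silent gap between sentences, seconds.
#' @param stress_rate_range,syllable_rate_range Hz ranges of the stressed
#'   syllable and syllable rhythms.
#' @param mod_depth_stress,mod_depth_syllable Envelope modulation depths of
#'   the two rhythms, in `[0, 1)`.
#' @param channel_labels EEG channel labels (must exist in the 10-20 template).
#' @param coupling List of coupling bands. Each element is a list with
#'   `band` (Hz range), `gain` (uV per unit envelope; scalar, or named vector
#'   over channels), `phase_lag` (radians at band centre) and optional
#'   `direct_minus_averted` (gain difference between gaze conditions,
#'   default 0; the direct-gaze gain is `gain + d/2`, averted `gain - d/2`).
#' @param background Optional list of condition-dependent oscillatory
#'   background components, each a list with `band` (Hz), `amplitude_uv`
#'   (RMS; scalar or named vector over channels) and optional
#'   `direct_minus_averted`. Independent of the envelope; used e.g. to inject
#'   a frontal theta-power difference.
#' @param noise_exponent Spectral slope of the 1/f background noise.
#' @param noise_scale RMS of the 1/f noise per channel, uV.
#' @param noise_spatial Fraction of the noise variance shared across
#'   channels (volume-conduction-like common structure), in `[0, 1]`.
#' @param noise_modulation SD of the slow log-normal amplitude modulation of
#'   the noise (common to all channels, ~10 s timescale), emulating arousal
#'   and movement-state nonstationarity; 0 disables.
#' @param artifact_spec List with `blink_rate_per_min`, `blink_amplitude_uv`,
#'   `movement_rate_per_min`, `movement_amplitude_uv`.
#' @param attention Per-condition Beta parameters of the long-run looking
#'   proportion: list with elements `direct` and `averted`, each
#'   `c(mean = , concentration = )`.
#' @param look_cycle_s Mean duration of one look+away cycle, seconds.
#' @param inter_block_interval_s Silence between consecutive blocks, seconds.
#' @param vocab Vocabulary-generation model; see [synth_vocab()].
#' @param seed Root RNG seed for the cohort.
#'
#' @return A validated `sbc_config` object (list).
#' @export
sim_config <- function(sampling_rate = 500,
                       n_subjects = 50,
                       n_blocks_per_condition = 30,
                       block_duration_s = 18.9,
                       sentence_duration_mean_s = 3.197,
                       sentence_duration_sd_s = 0.507,
                       inter_sentence_interval_s = 1.5,
                       stress_rate_range = c(0.87, 1.72),
                       syllable_rate_range = c(2.62, 3.57),
                       mod_depth_stress = 0.5,
                       mod_depth_syllable = 0.5,
                       channel_labels = analysis_channels(),
                       coupling = default_coupling(),
                       background = list(),
                       noise_exponent = 1.0,
                       noise_scale = 15,
                       noise_spatial = 0.7,
                       noise_modulation = 0.5,
                       artifact_spec = list(blink_rate_per_min = 4,
                                            blink_amplitude_uv = 200,
                                            movement_rate_per_min = 2,
                                            movement_amplitude_uv = 120),
                       attention = list(direct = c(mean = 0.9, concentration = 12),
                                        averted = c(mean = 0.9, concentration = 12)),
                       look_cycle_s = 8,
                       inter_block_interval_s = 3,
                       vocab = default_vocab_model(),
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate,
              n_subjects = n_subjects,
              n_blocks_per_condition = n_blocks_per_condition,
              block_duration_s = block_duration_s,
              sentence_duration_mean_s = sentence_duration_mean_s,
              sentence_duration_sd_s = sentence_duration_sd_s,
              inter_sentence_interval_s = inter_sentence_interval_s,
              stress_rate_range = stress_rate_range,
              syllable_rate_range = syllable_rate_range,
              mod_depth_stress = mod_depth_stress,
              mod_depth_syllable = mod_depth_syllable,
              channel_labels = channel_labels,
              coupling = coupling,
              background = background,
              noise_exponent = noise_exponent,
              noise_scale = noise_scale,
              noise_spatial = noise_spatial,
              noise_modulation = noise_modulation,
              artifact_spec = artifact_spec,
              attention = attention,
              look_cycle_s = look_cycle_s,
              inter_block_interval_s = inter_block_interval_s,
              vocab = vocab,
              seed = seed)
  class(cfg) <- "sbc_config"
  validate_config(cfg)
  cfg
}

#' Default envelope-to-EEG coupling
#'
#' One coupling band per stimulus rhythm, uniform over channels, with gains
#' chosen so that subject-level band coherence z-scores under the default
#' cohort land near the magnitudes reported for real ten-month-olds
#' (means ~1.7 at the stress rate and ~1.5 at the syllable rate), and phase
#' lags corresponding to roughly a 100 ms neural delay at the band centre.
#'
#' @return List of coupling-band specifications.
#' @export
default_coupling <- function() {
  list(
    list(band = c(1.0, 1.75), gain = 1.1, phase_lag = 0.86,
         direct_minus_averted = 0),
    list(band = c(2.5, 3.5),  gain = 0.7, phase_lag = 1.88,
         direct_minus_averted = 0)
  )
}

#' Default vocabulary-outcome model
#'
#' Ten-month proportions are Beta-distributed with mean/SD 0.26/0.18
#' (receptive) and 0.02/0.03 (expressive). Eighteen-month outcomes follow the
#' linear models relating them to band coherence z-scores and 10-month
#' vocabulary: the square root of the expressive proportion has intercept
#' 0.20, syllable-rate coefficient 0.09, stress-rate coefficient 0.00 and
#' 10-month-expressive coefficient 2.75; the receptive proportion has
#' intercept 0.43, 10-month-receptive coefficient 0.62 and near-zero
#' coherence coefficients.
#'
#' @return List of vocabulary model parameters.
#' @export
default_vocab_model <- function() {
  list(receptive_10 = c(mean = 0.26, sd = 0.18),
       expressive_10 = c(mean = 0.02, sd = 0.03),
       receptive_18 = c(intercept = 0.43, z_stress = -0.02, z_syllable = 0.01,
                        baseline = 0.62, noise_sd = 0.12),
       expressive_18 = c(intercept = 0.20, z_stress = 0.00, z_syllable = 0.09,
                         baseline = 2.75, noise_sd = 0.08),
       max_10 = 103, max_18 = 112)
}

validate_config <- function(cfg) {
  stopifnot(cfg$sampling_rate > 0,
            cfg$n_subjects >= 1,
            cfg$n_blocks_per_condition >= 1,
            cfg$block_duration_s > 0,
            cfg$sentence_duration_mean_s > 0,
            cfg$sentence_duration_sd_s >= 0,
            cfg$inter_sentence_interval_s >= 0,
            cfg$look_cycle_s > 0)
  for (rng in list(cfg$stress_rate_range, cfg$syllable_rate_range)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] > rng[2])
      stop("rate ranges must be positive and ordered (lo <= hi)")
  }
  if (cfg$mod_depth_stress < 0 || cfg$mod_depth_stress >= 1 ||
      cfg$mod_depth_syllable < 0 || cfg$mod_depth_syllable >= 1)
    stop("modulation depths must lie in [0, 1)")
  if (anyDuplicated(cfg$channel_labels))
    stop("channel labels must be unique")
  for (cp in cfg$coupling) {
    if (any(expand_per_channel(cp$gain, cfg$channel_labels) < 0))
      stop("coupling gains must be >= 0")
    if (length(cp$band) != 2 || cp$band[1] >= cp$band[2] || cp$band[1] <= 0)
      stop("coupling band must be an ordered positive Hz range")
  }
  for (cond in c("direct", "averted")) {
    a <- cfg$attention[[cond]]
    if (is.null(a) || a["mean"] < 0 || a["mean"] > 1 || a["concentration"] <= 0)
      stop("attention parameters need 0 <= mean <= 1, concentration > 0")
  }
  if (cfg$noise_scale < 0) stop("noise_scale must be >= 0")
  if (cfg$noise_spatial < 0 || cfg$noise_spatial > 1)
    stop("noise_spatial must lie in [0, 1]")
  if ((cfg$noise_modulation %||% 0) < 0)
    stop("noise_modulation must be >= 0")
  invisible(cfg)
}

# expand a scalar or (partially) named per-channel quantity to the full
# channel vector; unnamed channels get 0 when a named vector is given
expand_per_channel <- function(x, labels) {
  if (length(x) == 1 && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), length(labels)), labels))
  if (!is.null(names(x))) {
    out <- stats::setNames(numeric(length(labels)), labels)
    known <- intersect(names(x), labels)
    if (length(setdiff(names(x), labels)) > 0)
      stop("per-channel value names unknown: ",
           paste(setdiff(names(x), labels), collapse = ", "))
    out[known] <- x[known]
    return(out)
  }
  if (length(x) != length(labels))
    stop("per-channel vector length ", length(x),
         " does not match ", length(labels), " channels")
  stats::setNames(as.numeric(x), labels)
}

#' @export
print.sbc_config <- function(x, ...) {
  cat("<sbc_config>\n")
  cat(sprintf("  %d subjects, %d blocks/condition of %.1f s at %g Hz\n",
              x$n_subjects, x$n_blocks_per_condition, x$block_duration_s,
              x$sampling_rate))
  cat(sprintf("  channels: %d; coupling bands: %d; noise: 1/f^%.2g x %g uV\n",
              length(x$channel_labels), length(x$coupling),
              x$noise_exponent, x$noise_scale))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may be set in the file; unset fields keep
#' their defaults. `coupling` and `background` entries are lists as in the
#' constructor.
#'
#' @param path YAML file path.
#' @return An `sbc_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (nm in c("attention", "vocab", "artifact_spec")) {
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- lapply(raw[[nm]], function(el) unlist(el))
  }
  do.call(sim_config, raw)
}

#' Write a simulation configuration to YAML
#'
#' @param cfg An `sbc_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_portable(cfg), path)
  invisible(path)
}

# convert named atomic vectors to named lists so YAML/JSON keep the names
config_portable <- function(cfg) {
  f <- unclass(cfg)
  for (nm in c("attention", "vocab", "artifact_spec"))
    f[[nm]] <- lapply(f[[nm]], function(el)
      if (is.atomic(el) && !is.null(names(el))) as.list(el) else el)
  f
}
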