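#' Simulate one subject's raw data
#'
#' Derives a per-subject RNG stream from the cohort root seed, then draws
#' block envelopes, the coupled EEG recording with its ground truth, and the
#' frame-coded looking records.
#'
#' @param config An [sim_config()].
#' @param subject Subject index (1-based).
#' @param seed Root seed (defaults to `config$seed`).
#' @return List with `subject`, `seed`, `envelopes`, `recording`,
#'   `ground_truth`, `looks`.
#' @export
simulate_subject <- function(config, subject = 1L, seed = config$seed) {
  sseed <- child_seed(seed, subject)
  set.seed(sseed)
  n_blocks <- 2L * config$n_blocks_per_condition
  envelopes <- lapply(seq_len(n_blocks), function(b)
    synth_envelope(config, b))
  simrec <- synth_recording(config, envelopes)
  looks <- synth_looking(config, simrec$recording$events)
  list(subject = subject, seed = sseed, envelopes = envelopes,
       recording = simrec$recording, ground_truth = simrec$ground_truth,
       looks = looks)
}

# envelope epochs matching the kept epochs of an epoch set
matched_env_epochs <- function(es, envelopes) {
  len <- round(es$epoch_s * es$rate)
  out <- matrix(NA_real_, n_epochs(es), len)
  for (k in seq_len(n_epochs(es)))
    out[k, ] <- epoch_envelope(envelopes[[es$block_id[k]]],
                               es$start_rel_s[k], es$epoch_s)
  out
}

#' Preprocess and spectrally analyse one subject
#'
#' Runs the full single-subject chain: band filtering, channel drops,
#' 4 s / 1 s sliding epoching, looking-time gating, amplitude rejection,
#' (linked-mastoid) re-referencing with demeaning, the inclusion decision,
#' Fourier analysis, observed and surrogate coherence with z-scoring
#' (overall and per condition), and absolute power per condition.
#'
#' @param sub Output of [simulate_subject()] (or an equivalent list with
#'   `envelopes`, `recording`, `looks`).
#' @param n_surrogate Surrogate permutations per condition (default 100).
#' @param filter Apply the 0.1-30 Hz band filter first (default TRUE).
#' @param drop Channels to drop before analysis (default P7/P8 where
#'   present).
#' @param refs Reference labels; defaults to the mastoids when present,
#'   otherwise no re-referencing (epochs are still demeaned).
#' @param components Optional artifact topographies passed to
#'   [remove_components()].
#' @param bad_channels Channels to repair by spherical spline interpolation.
#' @param min_per_condition Inclusion threshold (default 30).
#' @param surrogate_conditions Conditions for which the surrogate
#'   distribution and z-scores are computed (subset of overall / direct /
#'   averted); coherence itself is always computed for all three.
#' @param taper Spectral taper.
#' @return List with the epoch set, inclusion decision, spectra, coherence
#'   (`overall`, `direct`, `averted`), surrogates, band z-scores, power per
#'   condition, and per-condition mean looking seconds.
#' @export
process_subject <- function(sub, n_surrogate = 100, filter = TRUE,
                            drop = c("P7", "P8"), refs = NULL,
                            components = NULL, bad_channels = NULL,
                            min_per_condition = 30,
                            surrogate_conditions = c("overall", "direct",
                                                     "averted"),
                            taper = "hanning") {
  rec <- sub$recording
  if (filter) rec <- bandpass(rec)
  if (!is.null(components)) rec <- remove_components(rec, components)
  rec <- drop_channels(rec, drop)
  es <- segment(rec)
  es <- add_looking(es, sub$looks)
  es <- gate_epochs(es)
  es <- reject_amplitude(es)
  if (!is.null(bad_channels) && length(bad_channels) > 0)
    es <- interpolate_channels(es, bad_channels,
                               channel_layout(es$labels))
  if (is.null(refs)) refs <- intersect(c("TP9", "TP10"), es$labels)
  if (length(refs) > 0) {
    es <- rereference(es, refs)
    es <- drop_channels(es, refs)
  } else {
    for (k in seq_len(n_epochs(es))) {
      mat <- matrix(es$epochs[k, , ], nrow = dim(es$epochs)[2])
      es$epochs[k, , ] <- mat - rowMeans(mat)
    }
  }
  decision <- include_subject(es, min_per_condition)
  keep <- kept_epochs(es)
  env_ep <- matched_env_epochs(keep, sub$envelopes)
  spec <- fft_epochs(keep, env_ep, taper = taper)

  res <- list(subject = sub$subject, epochs = es, include = decision,
              spectra = spec)
  for (cond in c("overall", "direct", "averted")) {
    coh <- compute_coherence(spec, cond)
    res[[cond]] <- list(coherence = coh)
    if (cond %in% surrogate_conditions) {
      surr <- surrogate_distribution(spec, n_perm = n_surrogate,
                                     condition = cond)
      res[[cond]]$surrogate <- surr
      res[[cond]]$bandz <- zscore_coherence(coh, surr)
    }
  }
  res$power <- list(direct = power_spectra(spec, "direct"),
                    averted = power_spectra(spec, "averted"))
  res$looking_s <- c(
    direct = mean(keep$looking_proportion[keep$condition == "direct"]) *
      keep$epoch_s,
    averted = mean(keep$looking_proportion[keep$condition == "averted"]) *
      keep$epoch_s)
  res
}

stack_subjects <- function(processed, extract) {
  mats <- lapply(processed, extract)
  arr <- array(NA_real_, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])),
               dimnames = list(NULL, rownames(mats[[1]]), NULL))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

band_average <- function(mat, freqs, band) {
  cols <- match(band, freqs)
  rowMeans(mat[, cols, drop = FALSE])
}

#' Group-level statistics for a processed cohort
#'
#' Runs the cluster-based permutation tests (observed vs surrogate over
#' 1-10 Hz and band-averaged at the stress and syllable rates; direct vs
#' averted band-averaged; theta power direct vs averted), the looking-time
#' paired t-test, and the vocabulary regressions.
#'
#' @param processed List of [process_subject()] results (included subjects).
#' @param scores Vocabulary data frame aligned with `processed` (or `NULL`
#'   to skip the regressions).
#' @param adj An `sbc_adjacency`; built from the subjects' montage when
#'   `NULL`.
#' @param n_perm Cluster permutations.
#' @param escalate_to Escalated permutation count (see [permutation_test()]).
#' @param seed Seed for the permutation draws.
#' @return List of test results plus the per-subject band z-score table.
#' @export
group_analysis <- function(processed, scores = NULL, adj = NULL,
                           n_perm = 1000, escalate_to = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- analysis_freqs()
  bands <- analysis_bands()
  labels <- rownames(processed[[1]]$overall$coherence$coh)
  if (is.null(adj)) adj <- build_adjacency(channel_layout(labels))

  coh_all <- stack_subjects(processed, function(p) p$overall$coherence$coh)
  surr_all <- stack_subjects(processed, function(p) p$overall$surrogate$mean)
  overall_test <- permutation_test(coh_all, surr_all, adj, n_perm,
                                   escalate_to)
  band_tests <- lapply(bands, function(bd) {
    a <- t(apply(coh_all, 1, band_average, freqs = freqs, band = bd))
    b <- t(apply(surr_all, 1, band_average, freqs = freqs, band = bd))
    dimnames(a) <- dimnames(b) <- list(NULL, labels)
    permutation_test(a, b, adj, n_perm, escalate_to)
  })
  gaze_tests <- lapply(bands, function(bd) {
    a <- t(vapply(processed, function(p)
      band_average(p$direct$coherence$coh, freqs, bd),
      numeric(length(labels))))
    b <- t(vapply(processed, function(p)
      band_average(p$averted$coherence$coh, freqs, bd),
      numeric(length(labels))))
    dimnames(a) <- dimnames(b) <- list(NULL, labels)
    permutation_test(a, b, adj, n_perm, escalate_to)
  })
  theta <- theta_contrast(
    stack_subjects(processed, function(p) p$power$direct$power),
    stack_subjects(processed, function(p) p$power$averted$power),
    adj, n_perm = n_perm, escalate_to = escalate_to)
  looking <- looking_ttest(
    vapply(processed, function(p) p$looking_s["direct"], numeric(1)),
    vapply(processed, function(p) p$looking_s["averted"], numeric(1)))

  ztab <- data.frame(
    subject = vapply(processed, `[[`, numeric(1), "subject"),
    z_stress = vapply(processed, function(p)
      p$overall$bandz$summary["stress"], numeric(1)),
    z_syllable = vapply(processed, function(p)
      p$overall$bandz$summary["syllable"], numeric(1)))

  vocab <- NULL
  if (!is.null(scores))
    vocab <- run_vocab_models(scores, ztab$z_stress, ztab$z_syllable)

  list(overall = overall_test,
       stress = band_tests$stress, syllable = band_tests$syllable,
       gaze_stress = gaze_tests$stress, gaze_syllable = gaze_tests$syllable,
       theta = theta, looking = looking, band_z = ztab, vocab = vocab,
       n_perm = n_perm, adjacency = adj)
}

#' Write a synthetic cohort to disk
#'
#' Simulates every subject and writes the documented formats: per-subject
#' BrainVision EEG with block annotations, per-block envelope WAVs (float,
#' at the EEG rate), looking TSVs, a cohort vocabulary CSV (scores generated
#' from each subject's measured band z via [synth_vocab()]), and a JSON run
#' manifest with the config snapshot, per-subject seeds and a file registry.
#'
#' @param config An `sbc_config` or path to a YAML config file.
#' @param out_dir Output directory (created).
#' @param n_surrogate Surrogate permutations for the z-scores that drive the
#'   vocabulary generator.
#' @return The manifest, invisibly.
#' @export
run_simulation <- function(config, out_dir, n_surrogate = 100) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  subjects <- list()
  zs <- matrix(NA_real_, config$n_subjects, 2,
               dimnames = list(NULL, c("stress", "syllable")))
  for (i in seq_len(config$n_subjects)) {
    sdir <- file.path(out_dir, sprintf("sub-%02d", i))
    dir.create(sdir, showWarnings = FALSE)
    sub <- simulate_subject(config, i)
    bv <- write_brainvision(sub$recording, file.path(sdir, "eeg"))
    files <- c(files, bv)
    for (b in seq_along(sub$envelopes)) {
      wp <- file.path(sdir, sprintf("envelope-block-%03d.wav", b))
      write_wav(sub$envelopes[[b]]$samples, sub$envelopes[[b]]$rate, wp)
      files <- c(files, wp)
    }
    lp <- file.path(sdir, "looks.tsv")
    write_looks(sub$looks, lp)
    files <- c(files, lp)
    proc <- process_subject(sub, n_surrogate = n_surrogate)
    zs[i, ] <- proc$overall$bandz$summary[c("stress", "syllable")]
    subjects[[i]] <- list(subject = i, seed = sub$seed,
                          include = proc$include$include,
                          kept = as.list(proc$include$counts))
  }
  scores <- synth_vocab(config, zs[, "syllable"], zs[, "stress"],
                        seed = child_seed(config$seed, 999L))
  vp <- file.path(out_dir, "vocab.csv")
  write_vocab(scores, vp)
  files <- c(files, vp)
  manifest <- list(package_version = as.character(utils::packageVersion("sbcoh")),
                   config = config_portable(config),
                   subjects = subjects,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyse a simulated cohort directory
#'
#' Reads the files written by [run_simulation()], reruns the per-subject
#' preprocessing and spectral analysis, performs the group statistics, and
#' writes the reports: an epoch report TSV, per-subject coherence TSV and
#' band-summary CSV, cluster/test results and a versioned summary JSON, and
#' the regression tables as CSV.
#'
#' @param data_dir Directory from [run_simulation()].
#' @param out_dir Report directory (created).
#' @param n_perm Cluster permutations (default 1000).
#' @param n_surrogate Surrogate permutations (default 100).
#' @param seed Seed for permutation draws (default: config seed from the
#'   manifest).
#' @param min_per_condition Subject inclusion threshold (default 30).
#' @return The summary list, invisibly.
#' @export
run_analysis <- function(data_dir, out_dir, n_perm = 1000,
                         n_surrogate = 100, seed = NULL,
                         min_per_condition = 30) {
  mpath <- file.path(data_dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing manifest: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cfg_fields <- manifest$config
  cfg_fields <- cfg_fields[setdiff(names(cfg_fields), character(0))]
  config <- do.call(sim_config, restore_config_fields(cfg_fields))
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  processed <- list()
  reports <- list(); cohtabs <- list()
  for (i in seq_len(config$n_subjects)) {
    sdir <- file.path(data_dir, sprintf("sub-%02d", i))
    vhdr <- file.path(sdir, "eeg.vhdr")
    if (!file.exists(vhdr)) stop("missing input file: ", vhdr)
    rec <- read_brainvision(vhdr)
    wavs <- sort(list.files(sdir, "^envelope-block-.*\\.wav$",
                            full.names = TRUE))
    envelopes <- lapply(wavs, function(w) {
      a <- read_wav(w)
      structure(list(samples = a$samples, rate = a$rate, t0 = 0),
                class = "sbc_envelope")
    })
    looks <- read_looks(file.path(sdir, "looks.tsv"))
    sub <- list(subject = i, recording = rec, envelopes = envelopes,
                looks = looks)
    set.seed(child_seed(seed, 5000L + i))  # reproducible surrogate draws
    proc <- process_subject(sub, n_surrogate = n_surrogate,
                            min_per_condition = min_per_condition)
    reports[[i]] <- epoch_report(proc$epochs, subject = i)
    cohtabs[[i]] <- coherence_table(proc$overall$coherence,
                                    proc$overall$surrogate,
                                    proc$overall$bandz, subject = i)
    if (proc$include$include) processed[[length(processed) + 1L]] <- proc
  }
  if (length(processed) < 2)
    stop("fewer than 2 subjects pass the inclusion rule")
  scores_all <- read_vocab(file.path(data_dir, "vocab.csv"))
  kept_ids <- vapply(processed, `[[`, numeric(1), "subject")
  scores <- scores_all[match(kept_ids, scores_all$subject), ]
  res <- group_analysis(processed, scores = scores, n_perm = n_perm,
                        seed = seed)

  utils::write.table(do.call(rbind, reports),
                     file.path(out_dir, "epoch_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, cohtabs),
                     file.path(out_dir, "coherence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(res$band_z, file.path(out_dir, "band_z.csv"),
                   row.names = FALSE)
  for (m in c("receptive", "expressive")) {
    f <- res$vocab[[m]]
    tab <- cbind(f$coefficients,
                 r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
                 transform = f$transform)
    utils::write.csv(tab, file.path(out_dir, paste0("model_", m, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    schema_version = "1.0",
    n_subjects_included = length(processed),
    seed = seed, n_perm = res$overall$n_perm,
    cluster_p = list(
      overall = min_cluster_p(res$overall),
      stress = min_cluster_p(res$stress),
      syllable = min_cluster_p(res$syllable),
      gaze_stress = min_cluster_p(res$gaze_stress),
      gaze_syllable = min_cluster_p(res$gaze_syllable),
      theta = min_cluster_p(res$theta)),
    looking = list(t = res$looking$t, p = res$looking$p,
                   mean_direct_s = unname(res$looking$mean["direct"]),
                   mean_averted_s = unname(res$looking$mean["averted"])),
    vocab_syllable_beta =
      res$vocab$expressive$coefficients$estimate[
        res$vocab$expressive$coefficients$term == "z_syllable"])
  cluster_json <- lapply(
    res[c("overall", "stress", "syllable", "gaze_stress",
          "gaze_syllable", "theta")],
    function(ct) list(
      n_perm = ct$n_perm, threshold_alpha = ct$threshold_alpha,
      clusters = lapply(ct$clusters, function(cl)
        list(mass = cl$mass, sign = cl$sign, p = cl$p,
             members = cl$members))))
  jsonlite::write_json(cluster_json, file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tmaps <- do.call(rbind, lapply(
    c("overall", "stress", "syllable", "gaze_stress",
      "gaze_syllable", "theta"),
    function(nm) {
      tm <- res[[nm]]$tmap$t
      data.frame(test = nm, channel = rep(rownames(tm), ncol(tm)),
                 bin = rep(seq_len(ncol(tm)), each = nrow(tm)),
                 t = as.numeric(tm))
    }))
  utils::write.table(tmaps, file.path(out_dir, "tmaps.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# manifest JSON round-trips config lists as data frames / named lists;
# restore the structures sim_config() expects
restore_config_fields <- function(f) {
  relist <- function(x) {
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    lapply(x, function(el) {
      el <- as.list(el)
      el$band <- as.numeric(unlist(el$band))
      el
    })
  }
  if (!is.null(f$coupling)) f$coupling <- relist(f$coupling)
  if (!is.null(f$background)) f$background <- relist(f$background)
  for (nm in c("attention", "vocab", "artifact_spec"))
    if (!is.null(f[[nm]]))
      f[[nm]] <- lapply(f[[nm]], function(el)
        if (is.list(el)) unlist(el) else el)
  f$channel_labels <- unlist(f$channel_labels)
  f
}
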