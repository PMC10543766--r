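# small fixtures shared across test files; everything is generated in code

# minimal three-channel config with short blocks, no artifacts
tiny_config <- function(..., coupling = list(),
                        n_blocks_per_condition = 2,
                        block_duration_s = 8,
                        attention = list(direct = c(mean = 1, concentration = 10),
                                         averted = c(mean = 1, concentration = 10))) {
  sim_config(n_subjects = 1,
             n_blocks_per_condition = n_blocks_per_condition,
             block_duration_s = block_duration_s,
             channel_labels = c("Fz", "Cz", "Pz"),
             coupling = coupling,
             artifact_spec = list(blink_rate_per_min = 0,
                                  blink_amplitude_uv = 0,
                                  movement_rate_per_min = 0,
                                  movement_amplitude_uv = 0),
             attention = attention,
             ...)
}

# recording with hand-set channel data and a single block event
toy_recording <- function(data, rate = 500, labels = NULL,
                          offset_s = ncol(data) / rate) {
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  structure(list(data = `dimnames<-`(data, list(labels, NULL)),
                 labels = labels,
                 types = sbcoh::channel_types(labels),
                 rate = rate,
                 events = data.frame(block_id = 1L, onset_s = 0,
                                     offset_s = offset_s,
                                     condition = "direct")),
            class = "sbc_recording")
}

# epoch set with hand-set epochs array (n x channels x samples)
toy_epochs <- function(ep, rate = 500, labels = NULL,
                       condition = rep("direct", dim(ep)[1]),
                       looking = rep(1, dim(ep)[1])) {
  labels <- labels %||% paste0("ch", seq_len(dim(ep)[2]))
  dimnames(ep) <- list(NULL, labels, NULL)
  n <- dim(ep)[1]
  structure(list(epochs = ep, labels = labels,
                 types = sbcoh::channel_types(labels),
                 rate = rate, epoch_s = dim(ep)[3] / rate,
                 start_s = seq_len(n) - 1, start_rel_s = seq_len(n) - 1,
                 block_id = rep(1L, n), condition = condition,
                 looking_proportion = looking,
                 kept = rep(TRUE, n), reason = rep(NA_character_, n)),
            class = "sbc_epochs")
}

# spectra object built from a hand-set complex array (epochs x (ch+env) x bins)
toy_spectra <- function(arr, freqs = analysis_freqs(),
                        condition = rep("direct", dim(arr)[1]),
                        block = seq_len(dim(arr)[1])) {
  structure(arr, freqs = freqs, taper = "hanning",
            condition = condition, block = block, class = "sbc_spectra")
}

# independent brute-force coherence for the oracle tests
brute_coherence <- function(arr) {
  ne <- dim(arr)[1]; nch <- dim(arr)[2] - 1L; nb <- dim(arr)[3]
  out <- matrix(0, nch, nb, dimnames = list(dimnames(arr)[[2]][1:nch], NULL))
  for (ch in seq_len(nch)) for (b in seq_len(nb)) {
    sxy <- 0; sxx <- 0; syy <- 0
    for (k in seq_len(ne)) {
      x <- arr[k, dim(arr)[2], b]; y <- arr[k, ch, b]
      sxy <- sxy + x * Conj(y); sxx <- sxx + Mod(x)^2; syy <- syy + Mod(y)^2
    }
    den <- sqrt((sxx / ne) * (syy / ne))
    out[ch, b] <- if (den > 0) Mod(sxy / ne) / den else 0
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
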