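# zero-phase band-pass by frequency-domain masking with raised-cosine edges
# (IIR filters are numerically unstable at the very low normalised
# frequencies these bands sit at); transition width trans Hz
fft_bandpass <- function(x, fs, band, trans = 0.25) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)  # mirror for negative frequencies
  ramp <- function(d) 0.5 - 0.5 * cos(pi * pmin(pmax(d / trans, 0), 1))
  mask <- ramp(f - (band[1] - trans)) * ramp((band[2] + trans) - f)
  X <- stats::fft(c(x, numeric(m - n)))
  Re(stats::fft(X * mask, inverse = TRUE))[seq_len(n)] / m
}

# 1/f^alpha Gaussian noise via spectral shaping, unit RMS;
# synthesised at the next highly composite length (fast FFT) and truncated
pink_noise <- function(n, alpha) {
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n_out)] / n
  x / stats::sd(x)
}

# slow band-limited Gaussian process (unit variance) used to modulate the
# noise amplitude on ~10 s timescales
slow_gauss <- function(n, fs, f_c = 0.1) {
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- m %/% 2
  f <- seq_len(nf) * fs / m
  amp <- exp(-(f / f_c)^2)
  phase <- stats::runif(nf, 0, 2 * pi)
  full <- complex(real = numeric(m))
  full[2:(nf + 1)] <- complex(modulus = amp, argument = phase)
  full[m:(m - nf + 2)] <- Conj(full[2:nf])
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# biphasic blink template: positive lobe followed by a smaller negative lobe,
# peak amplitude 1, duration dur_s
blink_template <- function(fs, dur_s = 0.4) {
  n <- round(dur_s * fs)
  t <- seq(0, 1, length.out = n)
  w <- sin(pi * t)^2
  shape <- w * (1.3 * sin(pi * t) - 0.5 * sin(2 * pi * t))
  shape / max(abs(shape))
}

#' Synthesise a multichannel EEG recording coupled to speech envelopes
#'
#' Lays the supplied block envelopes out on a continuous timeline (blocks in
#' alternating gaze conditions, separated by the configured inter-block
#' interval) and builds each EEG channel as the sum of (i) band-filtered,
#' phase-delayed copies of the envelope scaled by the per-channel coupling
#' gain of that band (gains may differ between gaze conditions), (ii)
#' condition-scalable narrowband oscillatory background components, (iii)
#' `1/f` noise, and (iv) stereotyped blink and movement artifacts. The
#' returned ground truth records the gains actually applied.
#'
#' @param config An [sim_config()].
#' @param envelopes List of `sbc_envelope` covering all
#'   `2 * n_blocks_per_condition` blocks.
#' @param seed Optional seed (`NULL`: current RNG stream).
#' @return List with elements `recording` (an `sbc_recording`: `data`
#'   channels x time matrix in uV, `labels`, `types`, `rate`, `events`) and
#'   `ground_truth` (per-band per-channel gains, condition differences and
#'   the vocabulary coefficients in force).
#' @export
synth_recording <- function(config, envelopes, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(child_seed(seed, 0L))
  fs <- config$sampling_rate
  labels <- config$channel_labels
  nch <- length(labels)
  n_blocks <- 2L * config$n_blocks_per_condition
  if (length(envelopes) < n_blocks)
    stop("need ", n_blocks, " envelopes (both conditions), got ",
         length(envelopes))
  conditions <- rep(c("direct", "averted"), length.out = n_blocks)

  gap <- round(config$inter_block_interval_s * fs)
  lead <- fs  # 1 s of silence before the first and after the last block
  block_len <- vapply(envelopes[seq_len(n_blocks)],
                      function(e) length(e$samples), integer(1))
  onsets <- integer(n_blocks)
  pos <- lead + 1L
  for (b in seq_len(n_blocks)) {
    onsets[b] <- pos
    pos <- pos + block_len[b] + gap
  }
  n <- pos - gap + lead
  env_line <- numeric(n)
  for (b in seq_len(n_blocks))
    env_line[onsets[b]:(onsets[b] + block_len[b] - 1L)] <-
      envelopes[[b]]$samples

  events <- data.frame(block_id = seq_len(n_blocks),
                       onset_s = (onsets - 1L) / fs,
                       offset_s = (onsets - 1L + block_len) / fs,
                       condition = conditions,
                       stringsAsFactors = FALSE)

  data <- matrix(0, nch, n, dimnames = list(labels, NULL))

  # per-block condition scaling helper: multiply a timeline piecewise
  cond_scale <- function(sig, base, diff) {
    out <- matrix(0, nch, n, dimnames = list(labels, NULL))
    for (b in seq_len(n_blocks)) {
      g <- base + (if (conditions[b] == "direct") diff / 2 else -diff / 2)
      idx <- onsets[b]:(onsets[b] + block_len[b] - 1L)
      out[, idx] <- g %o% sig[idx]
    }
    out
  }

  gains <- matrix(0, length(config$coupling), nch,
                  dimnames = list(NULL, labels))
  gdiff <- gains
  band_names <- character(length(config$coupling))
  for (k in seq_along(config$coupling)) {
    cp <- config$coupling[[k]]
    band_names[k] <- paste0(cp$band[1], "-", cp$band[2], "Hz")
    base <- expand_per_channel(cp$gain, labels)
    d <- expand_per_channel(cp$direct_minus_averted %||% 0, labels)
    gains[k, ] <- base
    gdiff[k, ] <- d
    if (all(base == 0) && all(d == 0)) next
    fc <- mean(cp$band)
    delay <- round(cp$phase_lag / (2 * pi * fc) * fs)
    xb <- fft_bandpass(env_line, fs, cp$band)
    if (delay > 0) xb <- c(numeric(delay), xb[seq_len(n - delay)])
    data <- data + cond_scale(xb, base, d)
  }
  rownames(gains) <- rownames(gdiff) <- band_names

  bg_truth <- list()
  for (bg in config$background) {
    amp <- expand_per_channel(bg$amplitude_uv, labels)
    d <- expand_per_channel(bg$direct_minus_averted %||% 0, labels)
    bg_truth[[paste0(bg$band[1], "-", bg$band[2], "Hz")]] <-
      list(amplitude = amp, direct_minus_averted = d)
    if (all(amp == 0) && all(d == 0)) next
    for (ch in seq_len(nch)) {
      if (amp[ch] == 0 && d[ch] == 0) next
      z <- fft_bandpass(stats::rnorm(n), fs, bg$band)
      z <- z / stats::sd(z)
      sc <- rep(amp[ch], n)  # base amplitude outside blocks
      for (b in seq_len(n_blocks)) {
        g <- amp[ch] + (if (conditions[b] == "direct") d[ch] / 2 else -d[ch] / 2)
        sc[onsets[b]:(onsets[b] + block_len[b] - 1L)] <- g
      }
      data[ch, ] <- data[ch, ] + sc * z
    }
  }

  if (config$noise_scale > 0) {
    rho <- config$noise_spatial %||% 0
    sig_m <- config$noise_modulation %||% 0
    mod <- if (sig_m > 0) exp(sig_m * slow_gauss(n, fs)) / exp(sig_m^2 / 2)
           else 1
    shared <- if (rho > 0) pink_noise(n, config$noise_exponent) else 0
    for (ch in seq_len(nch))
      data[ch, ] <- data[ch, ] + config$noise_scale * mod *
        (sqrt(rho) * shared +
         sqrt(1 - rho) * pink_noise(n, config$noise_exponent))
  }

  # artifacts
  art <- config$artifact_spec
  minutes <- n / fs / 60
  if ((art$blink_rate_per_min %||% 0) > 0) {
    tmpl <- blink_template(fs)
    ylab <- channel_layout(labels)
    front <- pmax(ylab$y, 0)
    front <- (front / max(front, 1e-9))^3
    n_blinks <- stats::rpois(1, art$blink_rate_per_min * minutes)
    if (n_blinks > 0) {
      at <- sort(sample.int(n - length(tmpl), n_blinks, replace = TRUE))
      for (t0 in at) {
        idx <- t0:(t0 + length(tmpl) - 1L)
        data[, idx] <- data[, idx] +
          (art$blink_amplitude_uv * front) %o% tmpl
      }
    }
  }
  if ((art$movement_rate_per_min %||% 0) > 0) {
    n_mov <- stats::rpois(1, art$movement_rate_per_min * minutes)
    len <- fs  # 1-s bursts
    w <- sin(pi * seq(0, 1, length.out = len))^2
    for (m in seq_len(n_mov)) {
      t0 <- sample.int(n - len, 1)
      chs <- sample.int(nch, max(1L, round(nch / 3)))
      for (ch in chs)
        data[ch, t0:(t0 + len - 1L)] <- data[ch, t0:(t0 + len - 1L)] +
          art$movement_amplitude_uv * w * stats::rnorm(len, sd = 0.5)
    }
  }

  rec <- structure(list(data = data, labels = labels,
                        types = channel_types(labels),
                        rate = fs, events = events),
                   class = "sbc_recording")
  gt <- list(gains = gains, direct_minus_averted = gdiff,
             background = bg_truth,
             vocab = config$vocab[c("receptive_18", "expressive_18")])
  list(recording = rec, ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Channel types inferred from labels
#'
#' Mastoid labels (TP9/TP10 and their linked variants) are typed `mastoid`,
#' EOG labels `EOG`, everything else `EEG`.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of types, same length.
#' @export
channel_types <- function(labels) {
  ifelse(labels %in% c("TP9", "TP10", "TP9L", "TP10L"), "mastoid",
         ifelse(grepl("^EOG|^FT9$|^FT10$", labels), "EOG", "EEG"))
}

#' @export
print.sbc_recording <- function(x, ...) {
  cat(sprintf("<sbc_recording> %d channels x %d samples at %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              nrow(x$events)))
  invisible(x)
}
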