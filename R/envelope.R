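#' Analytic signal via the FFT half-spectrum construction
#'
#' @param x Real-valued vector.
#' @return Complex vector whose modulus is the instantaneous amplitude.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Extract the speech amplitude envelope
#'
#' Computes the magnitude of the analytic (Hilbert) signal, smooths it with a
#' zero-phase low-pass Butterworth filter (default second order, 30 Hz), and
#' resamples to the EEG rate by polyphase anti-aliased resampling. Negative
#' excursions introduced by filtering are clipped to zero.
#'
#' @param audio List with `samples` and `rate` (Hz), e.g. from [read_wav()].
#' @param lowpass_hz Low-pass cutoff applied to the rectified envelope.
#' @param order Butterworth order (applied forward and backward).
#' @param target_rate Output rate in Hz (the EEG rate).
#' @return An `sbc_envelope` (`samples` >= 0, `rate = target_rate`, `t0 = 0`).
#' @export
extract_envelope <- function(audio, lowpass_hz = 30, order = 2,
                             target_rate = 500) {
  if (length(audio$samples) == 0) stop("empty audio")
  if (lowpass_hz >= audio$rate / 2)
    stop("lowpass cutoff ", lowpass_hz, " Hz is at or above Nyquist (",
         audio$rate / 2, " Hz)")
  env <- Mod(analytic_signal(as.numeric(audio$samples)))
  bf <- signal::butter(order, lowpass_hz / (audio$rate / 2), type = "low")
  env <- as.numeric(signal::filtfilt(bf, env))
  if (audio$rate != target_rate)
    env <- resample_fft(env, audio$rate, target_rate)
  structure(list(samples = pmax(env, 0), rate = target_rate, t0 = 0),
            class = "sbc_envelope")
}

#' Fourier-domain resampling
#'
#' Anti-aliased resampling by spectrum truncation (downsampling) or
#' zero-padding (upsampling); amplitude-preserving and zero-phase.
#'
#' @param x Signal vector.
#' @param from,to Original and target sampling rates, Hz.
#' @return Resampled vector of length `round(length(x) * to / from)`.
#' @export
resample_fft <- function(x, from, to) {
  n <- length(x)
  m <- round(n * to / from)
  X <- stats::fft(x)
  Y <- complex(real = numeric(m))
  k <- min(n, m) %/% 2
  Y[1:(k + 1)] <- X[1:(k + 1)]
  if (k > 1) Y[m:(m - k + 2)] <- X[n:(n - k + 2)]
  if (min(n, m) %% 2 == 0) Y[k + 1] <- Re(Y[k + 1])  # shared Nyquist bin
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Cut an envelope into 4-second epochs
#'
#' Slices the envelope on exactly the EEG epoching grid: half-open windows
#' `[start, start + epoch_s)` in seconds relative to the envelope's `t0`.
#'
#' @param env An `sbc_envelope`.
#' @param starts_s Window start times, seconds.
#' @param epoch_s Window length, seconds (default 4).
#' @return Matrix of `length(starts_s)` rows x `epoch_s * rate` columns.
#' @export
epoch_envelope <- function(env, starts_s, epoch_s = 4) {
  fs <- env$rate
  len <- round(epoch_s * fs)
  n <- length(env$samples)
  out <- matrix(NA_real_, length(starts_s), len)
  for (i in seq_along(starts_s)) {
    i0 <- round((starts_s[i] - env$t0) * fs) + 1L
    if (i0 < 1 || i0 + len - 1L > n)
      stop(sprintf("window [%g, %g) s lies outside the envelope extent",
                   starts_s[i], starts_s[i] + epoch_s))
    out[i, ] <- env$samples[i0:(i0 + len - 1L)]
  }
  out
}

#' Enumerate sliding epoch windows within a block
#'
#' Windows start at the block onset, advance by `step_s`, and the last
#' window must end at or before the block offset.
#'
#' @param duration_s Block duration, seconds.
#' @param epoch_s Window length (default 4 s).
#' @param step_s Step (default 1 s).
#' @return Numeric vector of start times (possibly empty), seconds from onset.
#' @export
epoch_starts <- function(duration_s, epoch_s = 4, step_s = 1) {
  if (duration_s < epoch_s - 1e-9) return(numeric(0))
  seq(0, duration_s - epoch_s + 1e-9, by = step_s)
}
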