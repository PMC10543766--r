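#' Frequency bins of the coherence analysis
#'
#' 1 to 10 Hz in 0.25 Hz steps (37 bins), the resolution given by 4-second
#' epochs.
#'
#' @return Numeric vector of bin frequencies, Hz.
#' @export
analysis_freqs <- function() seq(1, 10, by = 0.25)

#' Analysis bands
#'
#' Stressed-syllable (1-1.75 Hz, 4 bins) and syllable (2.5-3.5 Hz, 5 bins)
#' rates at 0.25 Hz resolution, endpoints inclusive.
#'
#' @return Named list of bin-frequency vectors.
#' @export
analysis_bands <- function() {
  list(stress = seq(1, 1.75, by = 0.25),
       syllable = seq(2.5, 3.5, by = 0.25))
}

#' Fourier-transform epochs at the analysis bins
#'
#' Tapers every epoch (single Hanning taper by default) and evaluates the
#' DFT at exactly the 37 analysis bins; the speech envelope is carried as an
#' extra channel named `"envelope"`.
#'
#' @param es An `sbc_epochs` (pass only kept epochs, e.g. via
#'   [kept_epochs()]).
#' @param env_epochs Envelope epochs on the identical grid
#'   (matrix, epochs x samples, from [epoch_envelope()]).
#' @param taper `"hanning"` or `"boxcar"`.
#' @return An `sbc_spectra`: complex array epochs x (channels + 1) x 37 with
#'   attributes `freqs`, `taper` and `condition` (per epoch).
#' @export
fft_epochs <- function(es, env_epochs, taper = c("hanning", "boxcar")) {
  taper <- match.arg(taper)
  n <- n_epochs(es)
  if (nrow(env_epochs) != n)
    stop("envelope epoch count (", nrow(env_epochs),
         ") does not match EEG epoch count (", n, ")")
  len <- dim(es$epochs)[3]
  if (ncol(env_epochs) != len)
    stop("envelope and EEG epochs are on different grids")
  freqs <- analysis_freqs()
  idx <- freqs * len / es$rate
  if (any(abs(idx - round(idx)) > 1e-9))
    stop("epoch length does not give 0.25 Hz resolution at rate ", es$rate)
  idx <- round(idx) + 1L
  w <- if (taper == "hanning") 0.5 - 0.5 * cos(2 * pi * (0:(len - 1)) / (len - 1))
       else rep(1, len)
  nch <- dim(es$epochs)[2]
  out <- array(complex(real = 0), c(n, nch + 1L, length(freqs)),
               dimnames = list(NULL, c(es$labels, "envelope"), NULL))
  for (k in seq_len(n)) {
    for (ch in seq_len(nch))
      out[k, ch, ] <- stats::fft(es$epochs[k, ch, ] * w)[idx]
    out[k, nch + 1L, ] <- stats::fft(env_epochs[k, ] * w)[idx]
  }
  structure(out, freqs = freqs, taper = taper, condition = es$condition,
            block = es$block_id, class = "sbc_spectra")
}

spectra_condition <- function(spec, condition = NULL) {
  cond <- attr(spec, "condition")
  if (is.null(condition) || identical(condition, "overall"))
    seq_len(dim(spec)[1])
  else which(cond == condition)
}

#' Speech-brain coherence across epochs
#'
#' `coh_xy(w) = |<X(w) Y*(w)>| / sqrt(<|X|^2> <|Y|^2>)` with `X` the envelope
#' and `Y` each EEG channel, the averages running over epochs. Bins where
#' either signal has zero power get coherence 0.
#'
#' @param spec An `sbc_spectra`.
#' @param condition `NULL`/`"overall"` for all epochs, or a condition label.
#' @return An `sbc_coherence`: list with `coh` (channels x bins, in
#'   `[0, 1]`), `n_epochs`, `condition`, `freqs`.
#' @export
compute_coherence <- function(spec, condition = NULL) {
  sel <- spectra_condition(spec, condition)
  if (length(sel) < 1) stop("no epochs for condition ", condition)
  chs <- utils::head(dimnames(spec)[[2]], -1L)
  X <- matrix(spec[sel, "envelope", ], nrow = length(sel))
  Sxx <- colMeans(Mod(X)^2)
  coh <- matrix(0, length(chs), dim(spec)[3],
                dimnames = list(chs, NULL))
  for (ch in seq_along(chs)) {
    Y <- matrix(spec[sel, ch, ], nrow = length(sel))
    Sxy <- colMeans(X * Conj(Y))
    Syy <- colMeans(Mod(Y)^2)
    den <- sqrt(Sxx * Syy)
    ok <- den > 0
    coh[ch, ok] <- Mod(Sxy[ok]) / den[ok]
  }
  structure(list(coh = coh, n_epochs = length(sel),
                 condition = condition %||% "overall",
                 freqs = attr(spec, "freqs")),
            class = "sbc_coherence")
}

#' @export
print.sbc_coherence <- function(x, ...) {
  cat(sprintf("<sbc_coherence> %d channels x %d bins (%s, %d epochs); mean coh %.3f\n",
              nrow(x$coh), ncol(x$coh), x$condition, x$n_epochs,
              mean(x$coh)))
  invisible(x)
}

#' Surrogate coherence distribution by envelope shuffling
#'
#' For each of `n_perm` permutations the envelope epochs are reassigned at
#' random to EEG epochs and coherence is recomputed, destroying
#' envelope-EEG alignment while preserving the marginal spectra. With
#' `unit = "block"` (the default) whole envelope blocks are permuted across
#' EEG blocks with the within-block window order preserved, so the
#' dependence structure induced by the 1 s sliding windows is identical in
#' observed and surrogate data; `unit = "epoch"` permutes envelope epochs
#' freely (identity permutation allowed in both cases). The free epoch
#' shuffle is biased towards lower coherence when epochs overlap, which
#' inflates observed-vs-surrogate z-scores; see the package vignette.
#'
#' @param spec An `sbc_spectra`.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional seed.
#' @param condition `NULL`/`"overall"` or a condition label; the shuffle is
#'   confined to the selected epochs.
#' @param unit `"block"` or `"epoch"` (see above).
#' @return An `sbc_surrogate`: list with `perms` (n_perm x channels x bins),
#'   `mean` and `sd` (channels x bins, across permutations), `n_perm`,
#'   `seed`, `condition`, `unit`.
#' @export
surrogate_distribution <- function(spec, n_perm = 100, seed = NULL,
                                   condition = NULL,
                                   unit = c("block", "epoch")) {
  unit <- match.arg(unit)
  if (n_perm < 2) stop("n_perm must be at least 2")
  sel <- spectra_condition(spec, condition)
  ne <- length(sel)
  if (ne < 3) stop("need at least 3 epochs to shuffle")
  if (!is.null(seed)) set.seed(seed)
  chs <- utils::head(dimnames(spec)[[2]], -1L)
  nb <- dim(spec)[3]
  X <- matrix(spec[sel, "envelope", ], nrow = ne)
  blocks <- attr(spec, "block")[sel]
  if (unit == "block" && is.null(blocks))
    stop("spectra carry no block labels; use unit = \"epoch\"")
  Ys <- lapply(seq_along(chs), function(ch)
    Conj(matrix(spec[sel, ch, ], nrow = ne)))
  Syy <- lapply(Ys, function(Y) colMeans(Mod(Y)^2))
  perms <- array(0, c(n_perm, length(chs), nb),
                 dimnames = list(NULL, chs, NULL))
  for (p in seq_len(n_perm)) {
    idx <- if (unit == "epoch") sample.int(ne)
           else block_shuffle_index(blocks)
    Xp <- X[idx, , drop = FALSE]
    Sxx <- colMeans(Mod(Xp)^2)
    for (ch in seq_along(chs)) {
      den <- sqrt(Sxx * Syy[[ch]])
      den[den == 0] <- Inf
      perms[p, ch, ] <- Mod(colMeans(Xp * Ys[[ch]])) / den
    }
  }
  mu <- apply(perms, c(2, 3), mean)
  sdv <- apply(perms, c(2, 3), stats::sd)
  structure(list(perms = perms, mean = mu, sd = sdv, n_perm = n_perm,
                 seed = seed, condition = condition %||% "overall",
                 unit = unit),
            class = "sbc_surrogate")
}

# random envelope-block reassignment: permute block labels, preserve the
# within-block window order, wrap when the source block has fewer windows
block_shuffle_index <- function(blocks) {
  ub <- unique(blocks)
  pi_b <- stats::setNames(if (length(ub) == 1) ub else sample(ub), ub)
  idx_of <- split(seq_along(blocks), blocks)
  out <- integer(length(blocks))
  for (b in ub) {
    tgt <- idx_of[[as.character(b)]]
    src <- idx_of[[as.character(pi_b[[as.character(b)]])]]
    out[tgt] <- src[(seq_along(tgt) - 1L) %% length(src) + 1L]
  }
  out
}

#' Standardise coherence against its surrogate distribution
#'
#' `z = (coh - surrogate mean) / surrogate SD` per channel and bin, followed
#' by band averaging: a per-channel scalar per band (mean over member bins)
#' and a per-subject summary (mean over channels). Bins with zero surrogate
#' SD are undefined and dropped from band averages.
#'
#' @param coh An `sbc_coherence`.
#' @param surr An `sbc_surrogate` of matching shape.
#' @param bands Named list of band bin frequencies (default
#'   [analysis_bands()]).
#' @return An `sbc_bandz`: list with `z` (channels x bins), `band_channel`
#'   (channels x bands), `summary` (named per-band scalars), `freqs`,
#'   `condition`.
#' @export
zscore_coherence <- function(coh, surr, bands = analysis_bands()) {
  if (!all(dim(coh$coh) == dim(surr$mean)))
    stop("coherence and surrogate shapes differ")
  z <- (coh$coh - surr$mean) / surr$sd
  z[surr$sd == 0] <- NA_real_
  bc <- sapply(bands, function(fr) {
    cols <- match(fr, coh$freqs)
    rowMeans(z[, cols, drop = FALSE], na.rm = TRUE)
  })
  if (is.null(dim(bc))) bc <- matrix(bc, nrow = 1,
                                     dimnames = list(rownames(z), names(bands)))
  structure(list(z = z, band_channel = bc,
                 summary = colMeans(bc, na.rm = TRUE),
                 freqs = coh$freqs, condition = coh$condition),
            class = "sbc_bandz")
}
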