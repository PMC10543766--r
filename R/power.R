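#' Theta-band bins (3-6 Hz inclusive, 13 bins at 0.25 Hz)
#'
#' @return Numeric vector of bin frequencies, Hz.
#' @export
theta_bins <- function() seq(3, 6, by = 0.25)

#' Absolute EEG power spectra
#'
#' Mean over epochs of the squared Fourier coefficient magnitudes at the
#' analysis bins, per channel, for the requested condition. Uses the same
#' spectral decomposition (and taper) as the coherence analysis.
#'
#' @param spec An `sbc_spectra`.
#' @param condition `NULL`/`"overall"` or a condition label.
#' @return An `sbc_power`: list with `power` (channels x bins, uV^2),
#'   `n_epochs`, `condition`, `freqs`.
#' @export
power_spectra <- function(spec, condition = NULL) {
  sel <- spectra_condition(spec, condition)
  if (length(sel) == 0) stop("no epochs for condition ", condition)
  chs <- utils::head(dimnames(spec)[[2]], -1L)
  pw <- t(vapply(seq_along(chs), function(ch)
    colMeans(matrix(Mod(spec[sel, ch, ])^2, nrow = length(sel))),
    numeric(dim(spec)[3])))
  rownames(pw) <- chs
  structure(list(power = pw, n_epochs = length(sel),
                 condition = condition %||% "overall",
                 freqs = attr(spec, "freqs")),
            class = "sbc_power")
}

#' Theta-power condition contrast
#'
#' Cluster-based permutation comparison of absolute power between the two
#' gaze conditions in the 3-6 Hz band, over all electrodes without
#' averaging over frequencies.
#'
#' @param power_direct,power_averted Subjects x channels x bins arrays of
#'   absolute power at the full analysis bins (one slice per subject, e.g.
#'   stacked `sbc_power$power`).
#' @param adj An `sbc_adjacency`.
#' @param n_perm Permutations.
#' @param seed Optional seed.
#' @param ... Passed to [permutation_test()].
#' @return An `sbc_clustertest` over channels x 13 theta bins.
#' @export
theta_contrast <- function(power_direct, power_averted, adj,
                           n_perm = 1000, seed = NULL, ...) {
  cols <- match(theta_bins(), analysis_freqs())
  a <- as_subj_array(power_direct)[, , cols, drop = FALSE]
  b <- as_subj_array(power_averted)[, , cols, drop = FALSE]
  permutation_test(a, b, adj, n_perm = n_perm, seed = seed, ...)
}

#' Paired t-test on mean looking times
#'
#' Compares per-subject mean looking seconds (proportion x 4 s per epoch)
#' between the gaze conditions.
#'
#' @param direct,averted Per-subject mean looking seconds.
#' @return An `sbc_pairedtest`: list with `t`, `df`, `p`, per-condition
#'   `mean` and `sd`, and a `degenerate` flag (TRUE when the difference
#'   variance is zero, in which case `p` is `NA`).
#' @export
looking_ttest <- function(direct, averted) {
  if (length(direct) != length(averted) || length(direct) < 2)
    stop("need paired vectors of length >= 2")
  out <- list(mean = c(direct = mean(direct), averted = mean(averted)),
              sd = c(direct = stats::sd(direct), averted = stats::sd(averted)),
              df = length(direct) - 1L)
  if (stats::sd(direct - averted) == 0) {
    out$t <- if (all(direct == averted)) 0 else NA_real_
    out$p <- NA_real_
    out$degenerate <- TRUE
  } else {
    tt <- stats::t.test(direct, averted, paired = TRUE)
    out$t <- unname(tt$statistic)
    out$p <- tt$p.value
    out$degenerate <- FALSE
  }
  structure(out, class = "sbc_pairedtest")
}

#' @export
print.sbc_pairedtest <- function(x, ...) {
  cat(sprintf("<sbc_pairedtest> t(%d) = %.3f, p = %.4g (direct %.3f, averted %.3f)\n",
              x$df, x$t, x$p, x$mean["direct"], x$mean["averted"]))
  invisible(x)
}
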