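#' Proportion vocabulary scores
#'
#' Raw CDI counts divided by the maximum attainable score of the form
#' (103 per category at 10 months, 112 at 18 months).
#'
#' @param raw Raw score(s).
#' @param max Maximum possible score(s).
#' @return Proportions in `[0, 1]`.
#' @export
proportion_scores <- function(raw, max) {
  if (any(raw < 0) || any(raw > max)) stop("raw scores must lie in [0, max]")
  raw / max
}

#' Ordinary least squares with the diagnostics used downstream
#'
#' Fits `y ~ predictors` with an intercept via [stats::lm()] and collects
#' coefficients with classical SEs, two-sided t-based p-values and 95% CIs,
#' R-squared values, per-predictor variance inflation factors, and the
#' non-constant-variance score test.
#'
#' @param y Outcome vector.
#' @param predictors Numeric matrix or data frame of predictors.
#' @param names Optional predictor names.
#' @param transform Label recorded in the result (`"none"` or `"sqrt"`).
#' @return An `sbc_fit`: list with `coefficients` (data frame: estimate, se,
#'   t, p, ci_lo, ci_hi), `r_squared`, `adj_r_squared`, `vif`, `ncv_p`,
#'   `transform`, `n`, and the underlying `lm` object.
#' @export
fit_linear <- function(y, predictors, names = NULL, transform = "none") {
  X <- as.data.frame(predictors)
  if (!is.null(names)) colnames(X) <- names
  if (nrow(X) <= ncol(X) + 1) stop("need n > p + 1 observations")
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (fit$rank < ncol(X) + 1) stop("rank-deficient design")
  sm <- summary(fit)
  ci <- stats::confint(fit)
  co <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   se = sm$coefficients[, 2],
                   t = sm$coefficients[, 3],
                   p = sm$coefficients[, 4],
                   ci_lo = ci[, 1], ci_hi = ci[, 2],
                   row.names = NULL)
  structure(list(coefficients = co,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 vif = if (ncol(X) >= 2) vif(X) else NULL,
                 ncv_p = ncv_test(fit),
                 transform = transform,
                 n = nrow(X), lm = fit),
            class = "sbc_fit")
}

#' Non-constant-variance score test
#'
#' Breusch-Pagan / Cook-Weisberg score test of the squared residuals
#' against the fitted values (chi-squared, 1 df), as used to decide the
#' square-root transform of the expressive outcome.
#'
#' @param fit An `lm` object or an `sbc_fit`.
#' @return p-value (NA when the fitted values are constant).
#' @export
ncv_test <- function(fit) {
  if (inherits(fit, "sbc_fit")) fit <- fit$lm
  if (stats::sd(stats::fitted(fit)) < 1e-12) return(NA_real_)
  unname(car::ncvTest(fit)$p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on the remaining predictors. Perfect collinearity yields `Inf`.
#'
#' @param predictors Matrix or data frame with at least two columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(predictors) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[[j]] ~ ., data = X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Vocabulary-outcome regression models
#'
#' Fits the two linear models linking later vocabulary to band-averaged
#' coherence: receptive proportion at 18 months on the stress- and
#' syllable-rate z-scores plus 10-month receptive vocabulary, and the
#' analogous expressive model. The expressive outcome is square-root
#' transformed if (and only if) the non-constant-variance test on the
#' untransformed fit rejects at `ncv_alpha`. Subjects with missing 18-month
#' data are dropped listwise.
#'
#' @param scores Data frame with columns `receptive_10`, `expressive_10`,
#'   `receptive_18`, `expressive_18` (proportions; `NA` allowed at 18
#'   months).
#' @param z_stress,z_syllable Per-subject band coherence z-scores, aligned
#'   with `scores` rows.
#' @param ncv_alpha Decision level for the transform (default 0.05).
#' @return List with `receptive` and `expressive` (`sbc_fit`s) and
#'   `n_complete`.
#' @export
run_vocab_models <- function(scores, z_stress, z_syllable,
                             ncv_alpha = 0.05) {
  stopifnot(nrow(scores) == length(z_stress),
            nrow(scores) == length(z_syllable))
  complete <- !(is.na(scores$receptive_18) | is.na(scores$expressive_18))
  if (sum(complete) < 10)
    stop("fewer than 10 subjects with complete 18-month data")
  sc <- scores[complete, ]
  zs <- z_stress[complete]; zy <- z_syllable[complete]

  rec <- fit_linear(sc$receptive_18,
                    data.frame(z_stress = zs, z_syllable = zy,
                               receptive_10 = sc$receptive_10))

  Xe <- data.frame(z_stress = zs, z_syllable = zy,
                   expressive_10 = sc$expressive_10)
  raw_fit <- fit_linear(sc$expressive_18, Xe)
  expf <- if (!is.na(raw_fit$ncv_p) && raw_fit$ncv_p < ncv_alpha)
    fit_linear(sqrt(sc$expressive_18), Xe, transform = "sqrt")
  else raw_fit
  list(receptive = rec, expressive = expf, n_complete = sum(complete))
}

#' @export
print.sbc_fit <- function(x, ...) {
  cat(sprintf("<sbc_fit> n = %d, R2 = %.3f (adj %.3f), transform = %s, ncv p = %.3g\n",
              x$n, x$r_squared, x$adj_r_squared, x$transform, x$ncv_p))
  print(x$coefficients, digits = 3)
  invisible(x)
}
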