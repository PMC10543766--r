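# apply an IIR filter b/a along the rows of a channels x time matrix
# (columnwise on the transpose) in one stats::filter call per stage
filt_ba_t <- function(b, a, Xt) {
  k <- length(b)
  pad <- matrix(0, k - 1, ncol(Xt))
  v <- stats::filter(rbind(pad, Xt), b / a[1], method = "convolution",
                     sides = 1)
  v <- v[k:(nrow(Xt) + k - 1), , drop = FALSE]
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1] / a[1], method = "recursive")
  }
  matrix(v, nrow = nrow(Xt))
}

filt_ba_mat <- function(b, a, X) t(filt_ba_t(b, a, t(X)))

# zero-phase (forward-backward) application, as in filtfilt
filtfilt_mat <- function(flt, X) {
  y <- filt_ba_mat(flt$b, flt$a, X)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- filt_ba_mat(flt$b, flt$a, y)
  y[, rev(seq_len(ncol(y))), drop = FALSE]
}

#' Band-pass filter a recording
#'
#' Zero-phase Butterworth band filter: second-order high-pass (-12 dB/oct)
#' cascaded with a low-pass (default order 4), each applied forward and
#' backward so no phase delay is introduced into the envelope-EEG lag.
#'
#' @param rec An `sbc_recording`.
#' @param hp,lp High-/low-pass corner frequencies, Hz.
#' @param hp_order,lp_order Filter orders (before the zero-phase doubling).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, hp = 0.1, lp = 30, hp_order = 2, lp_order = 4) {
  fs <- rec$rate
  if (!(hp < lp && lp < fs / 2) || hp <= 0)
    stop("need 0 < hp < lp < rate/2")
  bh <- signal::butter(hp_order, hp / (fs / 2), type = "high")
  bl <- signal::butter(lp_order, lp / (fs / 2), type = "low")
  Xt <- t(rec$data)
  rv <- rev(seq_len(nrow(Xt)))
  for (flt in list(bh, bl)) {
    Xt <- filt_ba_t(flt$b, flt$a, Xt)[rv, , drop = FALSE]
    Xt <- filt_ba_t(flt$b, flt$a, Xt)[rv, , drop = FALSE]
  }
  rec$data <- t(Xt)
  dimnames(rec$data) <- list(rec$labels, NULL)
  rec
}

#' Segment a recording into sliding 4-second epochs
#'
#' Within every event block, windows start at the block onset and advance in
#' 1 s steps; the last window ends at or before the block offset. Blocks
#' shorter than one window contribute zero epochs.
#'
#' @param rec An `sbc_recording` with an `events` table.
#' @param epoch_s,step_s Window length and step, seconds.
#' @return An `sbc_epochs` object: array `epochs` (n x channels x samples),
#'   per-epoch `block_id`, `condition`, `start_s` (recording time) and
#'   `start_rel_s` (time from block onset), `looking_proportion` (NA until
#'   [add_looking()]), and `kept`/`reason` flags.
#' @export
segment <- function(rec, epoch_s = 4, step_s = 1) {
  if (is.null(rec$events) || nrow(rec$events) == 0)
    stop("recording has no events")
  fs <- rec$rate
  len <- round(epoch_s * fs)
  starts_abs <- numeric(0); starts_rel <- numeric(0)
  block_id <- integer(0); condition <- character(0)
  for (i in seq_len(nrow(rec$events))) {
    ev <- rec$events[i, ]
    rel <- epoch_starts(ev$offset_s - ev$onset_s, epoch_s, step_s)
    starts_abs <- c(starts_abs, ev$onset_s + rel)
    starts_rel <- c(starts_rel, rel)
    block_id <- c(block_id, rep(ev$block_id, length(rel)))
    condition <- c(condition, rep(ev$condition, length(rel)))
  }
  n <- length(starts_abs)
  ep <- array(NA_real_, c(n, nrow(rec$data), len),
              dimnames = list(NULL, rec$labels, NULL))
  for (k in seq_len(n)) {
    i0 <- round(starts_abs[k] * fs) + 1L
    ep[k, , ] <- rec$data[, i0:(i0 + len - 1L)]
  }
  structure(list(epochs = ep, labels = rec$labels, types = rec$types,
                 rate = fs, epoch_s = epoch_s,
                 start_s = starts_abs, start_rel_s = starts_rel,
                 block_id = block_id, condition = condition,
                 looking_proportion = rep(NA_real_, n),
                 kept = rep(TRUE, n), reason = rep(NA_character_, n)),
            class = "sbc_epochs")
}

#' @export
print.sbc_epochs <- function(x, ...) {
  cat(sprintf("<sbc_epochs> %d epochs (%d kept) x %d channels x %d samples at %g Hz\n",
              dim(x$epochs)[1], sum(x$kept), dim(x$epochs)[2],
              dim(x$epochs)[3], x$rate))
  invisible(x)
}

n_epochs <- function(es) dim(es$epochs)[1]

mark_rejected <- function(es, which, reason) {
  which <- which & es$kept
  es$kept[which] <- FALSE
  es$reason[which & is.na(es$reason)] <- reason
  es
}

#' Proportion of screen-looking within a window
#'
#' @param look A look record (list with `intervals`: `start_s`, `end_s`,
#'   `state`), times relative to block onset.
#' @param start_s Window start relative to block onset.
#' @param epoch_s Window length, seconds.
#' @return Proportion in `[0, 1]` of the window spent in the `screen` state.
#' @export
looking_proportion <- function(look, start_s, epoch_s = 4) {
  iv <- look$intervals
  lo <- start_s; hi <- start_s + epoch_s
  if (lo < min(iv$start_s) - 1e-9 || hi > max(iv$end_s) + 1e-9)
    stop(sprintf("window [%g, %g) s outside the coded block", lo, hi))
  scr <- iv[iv$state == "screen", , drop = FALSE]
  if (nrow(scr) == 0) return(0)
  ov <- pmin(scr$end_s, hi) - pmax(scr$start_s, lo)
  sum(pmax(ov, 0)) / epoch_s
}

#' Attach per-epoch looking proportions
#'
#' @param es An `sbc_epochs`.
#' @param looks List of look records (one per block, as from
#'   [synth_looking()] or [read_looks()]).
#' @return The epoch set with `looking_proportion` filled in.
#' @export
add_looking <- function(es, looks) {
  ids <- vapply(looks, function(l) l$block_id, numeric(1))
  for (k in seq_len(n_epochs(es))) {
    l <- looks[[match(es$block_id[k], ids)]]
    es$looking_proportion[k] <-
      looking_proportion(l, es$start_rel_s[k], es$epoch_s)
  }
  es
}

#' Gate epochs on attention to the screen
#'
#' Epochs in which the infant attended to the screen for strictly less than
#' `min_proportion` of the window (1 s of a 4 s epoch at the default 25%)
#' are marked not-kept with reason `"looking"`. A proportion exactly at the
#' criterion is kept.
#'
#' @param es An `sbc_epochs` with looking proportions attached.
#' @param min_proportion Inclusion criterion.
#' @return The gated epoch set.
#' @export
gate_epochs <- function(es, min_proportion = 0.25) {
  if (anyNA(es$looking_proportion))
    stop("looking_proportion not populated; run add_looking() first")
  mark_rejected(es, es$looking_proportion < min_proportion, "looking")
}

#' Reject epochs by amplitude
#'
#' An epoch is marked not-kept (reason `"amplitude"`) iff any sample of an
#' EEG-typed channel strictly exceeds +/- `eeg_limit` uV. Samples exactly at
#' the limit survive. EOG channels are screened at the continuous stage (see
#' [flag_bad_segments()]), not here.
#'
#' @param es An `sbc_epochs`.
#' @param eeg_limit Absolute amplitude limit for EEG channels, uV.
#' @return The epoch set with rejections applied.
#' @export
reject_amplitude <- function(es, eeg_limit = 150) {
  eeg <- which(es$types == "EEG")
  bad <- vapply(seq_len(n_epochs(es)), function(k)
    max(abs(es$epochs[k, eeg, , drop = FALSE])) > eeg_limit, logical(1))
  mark_rejected(es, bad, "amplitude")
}

#' Flag high-amplitude 1-second segments in a continuous recording
#'
#' Screens consecutive snippets of the continuous data against the EEG and
#' EOG amplitude limits, as done before component identification. Epochs
#' overlapping flagged segments can be dropped with [mark_bad_segments()].
#'
#' @param rec An `sbc_recording`.
#' @param eeg_limit,eog_limit Absolute limits, uV.
#' @param segment_s Snippet length, seconds.
#' @return Data frame of flagged segments (`start_s`, `end_s`).
#' @export
flag_bad_segments <- function(rec, eeg_limit = 150, eog_limit = 250,
                              segment_s = 1) {
  fs <- rec$rate
  len <- round(segment_s * fs)
  lim <- ifelse(rec$types == "EOG", eog_limit,
                ifelse(rec$types == "EEG", eeg_limit, Inf))
  n_seg <- floor(ncol(rec$data) / len)
  bad <- logical(n_seg)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1L) * len + 1L):(s * len)
    bad[s] <- any(abs(rec$data[, idx]) > lim)
  }
  w <- which(bad)
  data.frame(start_s = (w - 1) * segment_s, end_s = w * segment_s)
}

#' Mark epochs overlapping flagged continuous segments
#'
#' @param es An `sbc_epochs`.
#' @param segments Data frame from [flag_bad_segments()].
#' @return The epoch set with overlapping epochs marked (reason
#'   `"continuous"`).
#' @export
mark_bad_segments <- function(es, segments) {
  if (nrow(segments) == 0) return(es)
  hit <- vapply(seq_len(n_epochs(es)), function(k) {
    lo <- es$start_s[k]; hi <- lo + es$epoch_s
    any(segments$start_s < hi & segments$end_s > lo)
  }, logical(1))
  mark_rejected(es, hit, "continuous")
}

#' Remove artifact components by subspace projection
#'
#' Projects the data onto the orthogonal complement of the span of the given
#' component topographies (channels x k mixing columns), cancelling any
#' signal lying in that subspace while leaving the complement untouched.
#'
#' @param x An `sbc_recording` or `sbc_epochs`.
#' @param topographies Numeric matrix, channels x k. `k = 0` returns the
#'   input unchanged.
#' @return Same class as `x`, with the component subspace removed.
#' @export
remove_components <- function(x, topographies) {
  if (is.null(topographies) || NCOL(topographies) == 0) return(x)
  A <- as.matrix(topographies)
  if (qr(A)$rank < ncol(A)) stop("topographies are rank-deficient")
  P <- diag(nrow(A)) - A %*% solve(crossprod(A), t(A))
  if (inherits(x, "sbc_recording")) {
    x$data <- P %*% x$data
    dimnames(x$data) <- list(x$labels, NULL)
  } else if (inherits(x, "sbc_epochs")) {
    for (k in seq_len(n_epochs(x)))
      x$epochs[k, , ] <- P %*% x$epochs[k, , ]
  } else stop("unsupported input")
  x
}

# sum of Legendre polynomials for the spherical spline kernel
# g(x) = (1/4pi) sum_n (2n+1) / (n (n+1))^m  P_n(x)
spline_g <- function(x, m = 4, n_terms = 20) {
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Repair channels by spherical spline interpolation
#'
#' Replaces the listed bad channels by spherical-spline estimates computed
#' from the remaining good channels on the unit-sphere template (Perrin-style
#' kernel, order m = 4). Good channels are untouched; a constant field is
#' reproduced exactly.
#'
#' @param es An `sbc_epochs`.
#' @param bad Labels of channels to repair.
#' @param layout A `sbc_layout` covering all channels of `es`.
#' @return The epoch set with bad channels replaced.
#' @export
interpolate_channels <- function(es, bad, layout) {
  if (length(bad) == 0) return(es)
  miss <- setdiff(bad, es$labels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  good <- setdiff(es$labels, bad)
  if (length(good) < 3) stop("need at least 3 good channels")
  pos <- layout_matrix(layout)
  pos <- pos / sqrt(rowSums(pos^2))
  Eg <- pos[good, , drop = FALSE]
  Eb <- pos[bad, , drop = FALSE]
  G <- spline_g(pmin(pmax(tcrossprod(Eg), -1), 1))
  Gb <- spline_g(pmin(pmax(Eb %*% t(Eg), -1), 1))
  ng <- length(good)
  M <- rbind(cbind(G, rep(1, ng)), c(rep(1, ng), 0))
  gi <- match(good, es$labels)
  bi <- match(bad, es$labels)
  for (k in seq_len(n_epochs(es))) {
    V <- es$epochs[k, gi, , drop = TRUE]
    if (is.null(dim(V))) V <- matrix(V, nrow = ng)
    sol <- solve(M, rbind(V, 0))
    c_coef <- sol[seq_len(ng), , drop = FALSE]
    c0 <- sol[ng + 1, ]
    es$epochs[k, bi, ] <- Gb %*% c_coef +
      matrix(c0, length(bad), ncol(V), byrow = TRUE)
  }
  es
}

#' Re-reference to (linked) mastoids and demean
#'
#' Subtracts the mean of the reference channels from every channel; epoch
#' sets are additionally demeaned per epoch and channel. With a single
#' reference label this is plain subtraction of that channel.
#'
#' @param x An `sbc_recording` or `sbc_epochs`.
#' @param refs Reference channel labels (present in the data).
#' @return Same class as `x`, re-referenced.
#' @export
rereference <- function(x, refs) {
  miss <- setdiff(refs, x$labels)
  if (length(miss)) stop("reference channel(s) missing: ",
                         paste(miss, collapse = ", "))
  ri <- match(refs, x$labels)
  if (inherits(x, "sbc_recording")) {
    ref <- colMeans(x$data[ri, , drop = FALSE])
    x$data <- sweep(x$data, 2, ref)
  } else if (inherits(x, "sbc_epochs")) {
    for (k in seq_len(n_epochs(x))) {
      mat <- matrix(x$epochs[k, , ], nrow = dim(x$epochs)[2])
      ref <- colMeans(mat[ri, , drop = FALSE])
      ep <- sweep(mat, 2, ref)
      x$epochs[k, , ] <- ep - rowMeans(ep)
    }
  } else stop("unsupported input")
  x
}

#' Subject inclusion decision
#'
#' A subject enters the final dataset only with at least `min_per_condition`
#' kept epochs in each gaze condition (30 + 30 = 60 overall at the default).
#'
#' @param es An `sbc_epochs` with final `kept` flags.
#' @param min_per_condition Minimum kept epochs per condition.
#' @return List with `include` (logical) and `counts` (kept per condition).
#' @export
include_subject <- function(es, min_per_condition = 30) {
  counts <- c(direct = sum(es$kept & es$condition == "direct"),
              averted = sum(es$kept & es$condition == "averted"))
  list(include = all(counts >= min_per_condition), counts = counts)
}

#' Keep only the retained epochs
#'
#' @param es An `sbc_epochs`.
#' @param condition Optional condition filter.
#' @return The epoch set restricted to kept epochs (and condition).
#' @export
kept_epochs <- function(es, condition = NULL) {
  sel <- es$kept
  if (!is.null(condition)) sel <- sel & es$condition == condition
  idx <- which(sel)
  es$epochs <- es$epochs[idx, , , drop = FALSE]
  for (f in c("start_s", "start_rel_s", "block_id", "condition",
              "looking_proportion", "kept", "reason"))
    es[[f]] <- es[[f]][idx]
  es
}

#' Drop channels from an epoch set or recording
#'
#' Used for the declarative removal of channels identified as too noisy
#' across datasets (e.g. P7/P8) before analysis.
#'
#' @param x An `sbc_recording` or `sbc_epochs`.
#' @param drop Labels to remove (absent labels are ignored).
#' @return Same class as `x` without the dropped channels.
#' @export
drop_channels <- function(x, drop = c("P7", "P8")) {
  keep <- !(x$labels %in% drop)
  if (inherits(x, "sbc_recording")) {
    x$data <- x$data[keep, , drop = FALSE]
  } else if (inherits(x, "sbc_epochs")) {
    x$epochs <- x$epochs[, keep, , drop = FALSE]
  } else stop("unsupported input")
  x$labels <- x$labels[keep]
  x$types <- x$types[keep]
  x
}

#' Per-epoch report table
#'
#' @param es An `sbc_epochs`.
#' @param subject Subject identifier to attach.
#' @return Data frame mirroring the epoch bookkeeping (one row per epoch).
#' @export
epoch_report <- function(es, subject = 1L) {
  data.frame(subject = subject, epoch = seq_len(n_epochs(es)),
             block_id = es$block_id, condition = es$condition,
             start_s = es$start_s,
             looking_proportion = es$looking_proportion,
             kept = es$kept,
             reason = ifelse(is.na(es$reason), "", es$reason))
}
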