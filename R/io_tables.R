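#' Write look records as TSV
#'
#' One row per interval: `block_id`, `start_s`, `end_s`, `state`
#' (screen/away), times relative to the block onset.
#'
#' @param looks List of look records (see [synth_looking()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_looks <- function(looks, path) {
  rows <- do.call(rbind, lapply(looks, function(l)
    cbind(block_id = l$block_id, l$intervals)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read look records from TSV
#'
#' @param path TSV written by [write_looks()].
#' @return List of look records, one per block.
#' @export
read_looks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$block_id), function(b)
    list(block_id = b$block_id[1],
         intervals = data.frame(start_s = b$start_s, end_s = b$end_s,
                                state = b$state,
                                stringsAsFactors = FALSE)))
}

#' Write vocabulary scores as CSV
#'
#' Long format, two rows per subject: `subject`, `age_months`,
#' `receptive_raw`, `receptive_max`, `expressive_raw`, `expressive_max`.
#'
#' @param scores Data frame from [synth_vocab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(scores, path) {
  long <- rbind(
    data.frame(subject = scores$subject, age_months = 10,
               receptive_raw = scores$receptive_10_raw,
               receptive_max = scores$max_10,
               expressive_raw = scores$expressive_10_raw,
               expressive_max = scores$max_10),
    data.frame(subject = scores$subject, age_months = 18,
               receptive_raw = scores$receptive_18_raw,
               receptive_max = scores$max_18,
               expressive_raw = scores$expressive_18_raw,
               expressive_max = scores$max_18))
  utils::write.csv(long[order(long$subject, long$age_months), ], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read vocabulary scores from CSV
#'
#' @param path CSV written by [write_vocab()].
#' @return Wide data frame of proportion scores (one row per subject).
#' @export
read_vocab <- function(path) {
  long <- utils::read.csv(path)
  w10 <- long[long$age_months == 10, ]
  w18 <- long[long$age_months == 18, ]
  out <- data.frame(subject = w10$subject,
                    receptive_10 = proportion_scores(w10$receptive_raw,
                                                     w10$receptive_max),
                    expressive_10 = proportion_scores(w10$expressive_raw,
                                                      w10$expressive_max))
  m <- match(out$subject, w18$subject)
  ok <- !is.na(m)
  out$receptive_18 <- out$expressive_18 <- NA_real_
  out$receptive_18[ok] <- proportion_scores(w18$receptive_raw[m[ok]],
                                            w18$receptive_max[m[ok]])
  out$expressive_18[ok] <- proportion_scores(w18$expressive_raw[m[ok]],
                                             w18$expressive_max[m[ok]])
  out
}

#' Per-subject coherence table
#'
#' @param coh An `sbc_coherence`.
#' @param surr Matching `sbc_surrogate`.
#' @param bandz Matching `sbc_bandz`.
#' @param subject Subject identifier.
#' @return Long data frame (subject, condition, channel, freq_hz, coh,
#'   surr_mean, surr_sd, z).
#' @export
coherence_table <- function(coh, surr, bandz, subject = 1L) {
  nb <- length(coh$freqs)
  nch <- nrow(coh$coh)
  data.frame(subject = subject,
             condition = coh$condition,
             channel = rep(rownames(coh$coh), nb),
             freq_hz = rep(coh$freqs, each = nch),
             coh = as.numeric(coh$coh),
             surr_mean = as.numeric(surr$mean),
             surr_sd = as.numeric(surr$sd),
             z = as.numeric(bandz$z))
}
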