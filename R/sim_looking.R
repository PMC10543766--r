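FRAME_S <- 0.040  # video frame duration used for look coding (25 fps)

#' Synthesise frame-coded looking records
#'
#' For every block in `events`, draws the infant's long-run looking
#' proportion from the condition's Beta attention distribution, then
#' generates alternating screen/away intervals with exponential durations
#' whose means are chosen so the stationary screen proportion equals the
#' drawn value. Interval boundaries are quantised to 40 ms video frames;
#' the final interval is clipped to the block offset.
#'
#' @param config An [sim_config()].
#' @param events Event table as produced by [synth_recording()] (columns
#'   `block_id`, `onset_s`, `offset_s`, `condition`).
#' @param seed Optional seed.
#' @return List of look records, one per block: list with `block_id`,
#'   `condition` and `intervals` (data frame `start_s`, `end_s`, `state`
#'   with state in screen/away), times relative to block onset.
#' @export
synth_looking <- function(config, events, seed = NULL) {
  if (nrow(events) == 0) stop("events must be nonempty")
  if (!is.null(seed)) set.seed(child_seed(seed, 1L))
  lapply(seq_len(nrow(events)), function(i) {
    dur <- events$offset_s[i] - events$onset_s[i]
    a <- config$attention[[events$condition[i]]]
    p <- draw_beta(1, a["mean"], a["concentration"])
    ints <- looking_intervals(dur, p, config$look_cycle_s)
    list(block_id = events$block_id[i],
         condition = events$condition[i],
         intervals = ints)
  })
}

draw_beta <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

looking_intervals <- function(dur, p, cycle_s) {
  if (p >= 1 - 1e-9)
    return(data.frame(start_s = 0, end_s = dur, state = "screen",
                      stringsAsFactors = FALSE))
  if (p <= 1e-9)
    return(data.frame(start_s = 0, end_s = dur, state = "away",
                      stringsAsFactors = FALSE))
  mean_look <- cycle_s * p
  mean_away <- cycle_s * (1 - p)
  state <- if (stats::runif(1) < p) "screen" else "away"
  start <- numeric(0); end <- numeric(0); st <- character(0)
  t <- 0
  while (t < dur - 1e-9) {
    m <- if (state == "screen") mean_look else mean_away
    d <- FRAME_S * max(1L, round(stats::rexp(1, 1 / m) / FRAME_S))
    e <- min(t + d, dur)
    start <- c(start, t); end <- c(end, e); st <- c(st, state)
    t <- e
    state <- if (state == "screen") "away" else "screen"
  }
  data.frame(start_s = start, end_s = end, state = st,
             stringsAsFactors = FALSE)
}
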