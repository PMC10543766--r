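test_that("the band filter passes 5 Hz, suppresses 50 Hz, and preserves silence", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  rec <- toy_recording(rbind(sin(2 * pi * 5 * t),
                             sin(2 * pi * 50 * t),
                             0 * t), rate = fs)
  out <- bandpass(rec)
  rms <- function(x) sqrt(mean(x^2))
  core <- 1000:(length(t) - 1000)
  expect_equal(rms(out$data[1, core]), rms(rec$data[1, core]),
               tolerance = 0.05)
  expect_lt(rms(out$data[2, core]) / rms(rec$data[2, core]), 0.10)
  expect_equal(out$data[3, ], rec$data[3, ])
  expect_error(bandpass(rec, hp = 40, lp = 30), "hp < lp")
})

test_that("sliding-window segmentation enumerates admissible 4-s windows", {
  fs <- 500
  mk <- function(dur) {
    rec <- toy_recording(matrix(rnorm(2 * round((dur + 2) * fs)), nrow = 2),
                         rate = fs)
    rec$events <- data.frame(block_id = 1L, onset_s = 1, offset_s = 1 + dur,
                             condition = "averted")
    rec
  }
  expect_equal(dim(segment(mk(4.0))$epochs)[1], 1)
  expect_equal(dim(segment(mk(3.9))$epochs)[1], 0)
  es <- segment(mk(18.9))
  expect_equal(dim(es$epochs)[1], 15)
  # epoch grid: starts are whole seconds from block onset, windows 2000 samples
  expect_equal(es$start_rel_s, 0:14)
  expect_equal(dim(es$epochs)[3], 2000)
  expect_true(all(es$condition == "averted"))
})

test_that("looking proportion is the screen-state overlap of the window", {
  look <- list(block_id = 1,
               intervals = data.frame(
                 start_s = c(0, 2, 6), end_s = c(2, 6, 10),
                 state = c("screen", "away", "screen")))
  expect_equal(looking_proportion(look, 0), 0.5)
  expect_equal(looking_proportion(look, 6), 1.0)
  expect_equal(looking_proportion(look, 2), 0.0)
  expect_equal(looking_proportion(look, 1), 0.25)
  expect_error(looking_proportion(look, 8), "outside")
})

test_that("the attention gate applies a strict less-than criterion", {
  ep <- array(0, c(3, 2, 2000))
  es <- toy_epochs(ep, looking = c(0.24, 0.25, 1.0))
  out <- gate_epochs(es)
  expect_equal(out$kept, c(FALSE, TRUE, TRUE))
  expect_equal(out$reason, c("looking", NA, NA))
})

test_that("amplitude rejection strictly exceeds +/-150 uV on EEG channels only", {
  ep <- array(0, c(3, 2, 2000))
  ep[1, 1, 77] <- 151     # rejected
  ep[2, 1, 77] <- 150     # boundary: kept
  ep[3, 2, 5] <- -150.5   # rejected (negative excursion)
  es <- toy_epochs(ep)
  out <- reject_amplitude(es)
  expect_equal(out$kept, c(FALSE, TRUE, FALSE))
  expect_equal(out$reason[1], "amplitude")
  # mastoid-typed channels are not screened here
  ep2 <- array(0, c(1, 2, 2000))
  ep2[1, 2, 1] <- 500
  es2 <- toy_epochs(ep2, labels = c("Cz", "TP9"))
  expect_true(reject_amplitude(es2)$kept)
})

test_that("attention gating and amplitude rejection commute", {
  set.seed(8)
  ep <- array(rnorm(20 * 2 * 2000, sd = 60), c(20, 2, 2000))
  es <- toy_epochs(ep, looking = runif(20))
  a <- reject_amplitude(gate_epochs(es))
  b <- gate_epochs(reject_amplitude(es))
  expect_equal(a$kept, b$kept)
})

test_that("component removal projects onto the orthogonal complement", {
  set.seed(9)
  rec <- toy_recording(matrix(rnorm(4 * 1000), 4))
  expect_identical(remove_components(rec, NULL), rec)
  # a recording that is exactly one injected component vanishes
  topo <- c(1, -2, 0.5, 3)
  src <- sin(2 * pi * 3 * seq_len(1000) / 500)
  rec1 <- toy_recording(topo %o% src)
  out1 <- remove_components(rec1, matrix(topo))
  expect_lt(sqrt(mean(out1$data^2)) / sqrt(mean(rec1$data^2)), 1e-6)
  # component + orthogonal signal: the orthogonal part survives intact
  ortho <- c(2, 1, 0, 0)   # orthogonal to topo
  expect_equal(sum(ortho * topo), 0)
  sig <- cos(2 * pi * 5 * seq_len(1000) / 500)
  rec2 <- toy_recording(topo %o% src + ortho %o% sig)
  out2 <- remove_components(rec2, matrix(topo))
  # oracle: least-squares projection residual computed independently
  oracle <- stats::resid(stats::lm(rec2$data ~ 0 + topo))
  expect_equal(unname(out2$data), unname(oracle), tolerance = 1e-8)
  expect_error(remove_components(rec2, cbind(topo, 2 * topo)),
               "rank-deficient")
})

test_that("spherical spline repair reproduces constant and smooth fields", {
  lay <- channel_layout()
  labs <- lay$label
  # constant field: interpolation is exact
  ep <- array(5, c(2, length(labs), 10))
  es <- toy_epochs(ep, labels = labs)
  out <- interpolate_channels(es, "Cz", lay)
  expect_equal(max(abs(out$epochs[, labs == "Cz", ] - 5)), 0,
               tolerance = 1e-6)
  expect_identical(interpolate_channels(es, character(0), lay), es)
  # dipolar (linear) field: leave-one-out error within 15% RMS
  d <- c(0.3, 0.8, 0.52)
  pos <- as.matrix(lay[, c("x", "y", "z")])
  field <- as.numeric(pos %*% d)
  ep2 <- array(rep(field, each = 1), c(1, length(labs), 8))
  for (k in 1:8) ep2[1, , k] <- field * k
  es2 <- toy_epochs(ep2, labels = labs)
  drop_ch <- "C3"
  truth <- es2$epochs[1, labs == drop_ch, ]
  es2$epochs[1, labs == drop_ch, ] <- 0
  out2 <- interpolate_channels(es2, drop_ch, lay)
  err <- out2$epochs[1, labs == drop_ch, ] - truth
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(truth^2)), 0.15)
})

test_that("mastoid re-referencing matches hand arithmetic and is idempotent", {
  ep <- array(0, c(1, 3, 4))
  ep[1, 1, ] <- c(4, 8, 12, 16)
  ep[1, 2, ] <- c(2, 2, 2, 2)
  ep[1, 3, ] <- c(0, 2, 4, 6)
  es <- toy_epochs(ep, labels = c("Cz", "TP9", "TP10"))
  out <- rereference(es, c("TP9", "TP10"))
  # hand computation: Cz minus (TP9+TP10)/2, then demeaned per epoch
  ref <- (ep[1, 2, ] + ep[1, 3, ]) / 2
  expect_equal(out$epochs[1, 1, ],
               (ep[1, 1, ] - ref) - mean(ep[1, 1, ] - ref))
  out2 <- rereference(out, c("TP9", "TP10"))
  expect_equal(out$epochs, out2$epochs, tolerance = 1e-12)
  # identical data on every channel cancels completely
  same <- toy_epochs(array(7, c(1, 3, 4)), labels = c("Cz", "TP9", "TP10"))
  expect_true(all(rereference(same, c("TP9", "TP10"))$epochs == 0))
  # single-mastoid reference is plain subtraction of that channel
  single <- rereference(es, "TP9")
  expect_equal(single$epochs[1, 1, ],
               (ep[1, 1, ] - ep[1, 2, ]) - mean(ep[1, 1, ] - ep[1, 2, ]))
  expect_error(rereference(es, "TP99"), "missing")
})

test_that("subject inclusion needs 30 kept epochs in each condition", {
  mk <- function(nd, na) {
    ep <- array(0, c(nd + na, 1, 8))
    toy_epochs(ep, condition = c(rep("direct", nd), rep("averted", na)))
  }
  expect_true(include_subject(mk(31, 32))$include)
  expect_true(include_subject(mk(30, 30))$include)
  d <- include_subject(mk(29, 300))
  expect_false(d$include)
  expect_equal(unname(d$counts), c(29, 300))
})

test_that("channel drops preserve the remaining order and bookkeeping", {
  labs <- c("F3", "P7", "Cz", "P8", "Pz")
  rec <- toy_recording(matrix(seq_len(5 * 10), 5), labels = labs)
  out <- drop_channels(rec)
  expect_equal(out$labels, c("F3", "Cz", "Pz"))
  expect_equal(out$data[2, ], rec$data[3, ])
})
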