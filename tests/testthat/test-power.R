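test_that("power spectra match a direct periodogram and scale quadratically", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 3 * t)
  ep <- array(0, c(2, 1, 2000)); ep[1, 1, ] <- x; ep[2, 1, ] <- x
  es <- toy_epochs(ep)
  spec <- fft_epochs(es, matrix(0, 2, 2000), taper = "boxcar")
  pw <- power_spectra(spec)
  i3 <- match(3, pw$freqs)
  expect_equal(which.max(pw$power[1, ]), i3)
  # oracle: direct periodogram value |DFT|^2 at the 3 Hz bin
  oracle <- Mod(sum(x * exp(-2i * pi * 12 * (0:1999) / 2000)))^2
  expect_equal(unname(pw$power[1, i3]), oracle, tolerance = 1e-9)
  # doubling the signal quadruples the power
  es2 <- toy_epochs(2 * ep)
  pw2 <- power_spectra(fft_epochs(es2, matrix(0, 2, 2000), taper = "boxcar"))
  expect_equal(pw2$power, 4 * pw$power, tolerance = 1e-9)
})

test_that("power is additive over orthogonal components at distinct bins", {
  fs <- 500
  t <- (0:(4 * fs - 1)) / fs
  x3 <- sin(2 * pi * 3 * t); x5 <- sin(2 * pi * 5 * t)
  mk <- function(x) {
    es <- toy_epochs(array(x, c(1, 1, 2000)))
    power_spectra(fft_epochs(es, matrix(0, 1, 2000), taper = "boxcar"))$power
  }
  expect_equal(mk(x3 + x5), mk(x3) + mk(x5), tolerance = 1e-6)
})

test_that("the theta band is 13 bins from 3 to 6 Hz", {
  tb <- theta_bins()
  expect_equal(length(tb), 13)
  expect_equal(tb, seq(3, 6, by = 0.25))
  expect_true(all(tb %in% analysis_freqs()))
})

test_that("identical conditions give no significant theta cluster", {
  set.seed(61)
  labels <- c("Fz", "Cz")
  adj <- build_adjacency(channel_layout(labels), 1)
  pw <- array(abs(rnorm(6 * 2 * 37)) + 1, c(6, 2, 37),
              dimnames = list(NULL, labels, NULL))
  res <- theta_contrast(pw, pw, adj, n_perm = 200)
  expect_equal(min_cluster_p(res), 1)
  # an injected theta difference is found
  pw2 <- pw
  cols <- match(theta_bins(), analysis_freqs())
  pw2[, , cols] <- pw2[, , cols] + 3
  res2 <- theta_contrast(pw2, pw, adj, n_perm = 200, escalate_to = 200,
                         seed = 3)
  expect_lt(min_cluster_p(res2, sign = 1), 0.05)
  expect_true(all(vapply(res2$clusters, function(cl)
    all(cl$members$bin %in% seq_len(13)), logical(1))))
})

test_that("the looking-time t-test matches hand computation", {
  d <- c(3.5, 3.7, 3.6, 3.9)
  a <- c(3.4, 3.8, 3.5, 3.6)
  res <- looking_ttest(d, a)
  diffs <- d - a
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(4))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3))
  expect_equal(unname(res$mean["direct"]), mean(d))
  # identical means per subject: t = 0
  expect_equal(looking_ttest(d, d)$t, 0)
  expect_true(looking_ttest(d, d)$degenerate)
})

test_that("the looking t-test rejects at the nominal rate under the null", {
  cfg <- tiny_config(attention = list(direct = c(mean = 0.9, concentration = 12),
                                      averted = c(mean = 0.9, concentration = 12)))
  ev <- data.frame(block_id = 1:10, onset_s = (0:9) * 12,
                   offset_s = (0:9) * 12 + 10,
                   condition = rep(c("direct", "averted"), 5))
  screen_time <- function(l)
    sum(l$intervals$end_s[l$intervals$state == "screen"] -
        l$intervals$start_s[l$intervals$state == "screen"])
  rejections <- vapply(1:100, function(r) {
    per <- vapply(1:6, function(s) {
      looks <- synth_looking(cfg, ev, seed = child_seed(r, s))
      c(mean(vapply(looks[ev$condition == "direct"], screen_time, numeric(1))),
        mean(vapply(looks[ev$condition == "averted"], screen_time, numeric(1))))
    }, numeric(2))
    looking_ttest(per[1, ], per[2, ])$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.11)
})
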