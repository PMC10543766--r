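sin_epochs <- function(freq, n_ep = 3, nch = 1, amp = 1, fs = 500,
                       phase = 0) {
  ep <- array(0, c(n_ep, nch, 4 * fs))
  t <- (0:(4 * fs - 1)) / fs
  for (k in seq_len(n_ep)) for (ch in seq_len(nch))
    ep[k, ch, ] <- amp * sin(2 * pi * freq * t + phase)
  ep
}

test_that("4-second epochs give exactly the 37 analysis bins at 0.25 Hz", {
  es <- toy_epochs(sin_epochs(3))
  spec <- fft_epochs(es, matrix(1, 3, 2000))
  f <- attr(spec, "freqs")
  expect_equal(length(f), 37)
  expect_equal(unique(round(diff(f), 10)), 0.25)
  expect_equal(range(f), c(1, 10))
})

test_that("spectral coefficients match a direct DFT sum and are linear", {
  es <- toy_epochs(sin_epochs(3, n_ep = 1))
  env <- matrix(rnorm(2000), 1)
  spec <- fft_epochs(es, env, taper = "boxcar")
  mags <- Mod(spec[1, 1, ])
  expect_equal(which.max(mags), match(3, attr(spec, "freqs")))
  # oracle: direct DFT sum at 3 Hz (bin k = f * T = 12)
  x <- es$epochs[1, 1, ]
  k <- 3 * 4
  oracle <- sum(x * exp(-2i * pi * k * (0:1999) / 2000))
  expect_equal(unname(spec[1, 1, match(3, attr(spec, "freqs"))]), oracle,
               tolerance = 1e-9)
  # zero input gives zero coefficients
  z <- fft_epochs(toy_epochs(array(0, c(2, 1, 2000))), matrix(0, 2, 2000))
  expect_true(all(Mod(z[, 1, ]) == 0))
})

test_that("self-coherence and the single-epoch degeneracy both give 1", {
  set.seed(3)
  ep <- array(rnorm(3 * 1 * 2000), c(3, 1, 2000))
  es <- toy_epochs(ep)
  spec <- fft_epochs(es, matrix(ep[, 1, ], nrow = 3))  # envelope == channel
  expect_equal(unname(compute_coherence(spec)$coh),
               matrix(1, 1, 37), tolerance = 1e-9)
  # a single epoch yields coherence 1 whatever the signals
  es1 <- toy_epochs(array(rnorm(2000), c(1, 1, 2000)))
  spec1 <- fft_epochs(es1, matrix(rnorm(2000), 1))
  expect_equal(unname(compute_coherence(spec1)$coh),
               matrix(1, 1, 37), tolerance = 1e-9)
})

test_that("coherence equals a brute-force evaluation of its formula", {
  set.seed(3)
  arr <- array(complex(real = rnorm(5 * 3 * 37), imaginary = rnorm(5 * 3 * 37)),
               c(5, 3, 37), dimnames = list(NULL, c("A", "B", "envelope"), NULL))
  spec <- toy_spectra(arr)
  expect_equal(compute_coherence(spec)$coh, brute_coherence(arr),
               tolerance = 1e-10)
})

test_that("coherence is bounded, scale-invariant and phase-rotation-invariant", {
  set.seed(17)
  for (i in 1:20) {
    ne <- sample(2:8, 1)
    arr <- array(complex(real = rnorm(ne * 2 * 37) * 10^runif(1, -3, 3),
                         imaginary = rnorm(ne * 2 * 37)),
                 c(ne, 2, 37), dimnames = list(NULL, c("A", "envelope"), NULL))
    coh <- compute_coherence(toy_spectra(arr))$coh
    expect_true(all(coh >= 0 & coh <= 1 + 1e-12))
    scaled <- arr; scaled[, 1, ] <- 7.3 * scaled[, 1, ]
    expect_equal(compute_coherence(toy_spectra(scaled))$coh, coh,
                 tolerance = 1e-9)
    rot <- arr * exp(1i * 0.7)
    expect_equal(compute_coherence(toy_spectra(rot))$coh, coh,
                 tolerance = 1e-9)
  }
})

test_that("the surrogate default is 100 permutations and the seed fixes the draw", {
  set.seed(5)
  arr <- array(complex(real = rnorm(6 * 2 * 37), imaginary = rnorm(6 * 2 * 37)),
               c(6, 2, 37), dimnames = list(NULL, c("A", "envelope"), NULL))
  spec <- toy_spectra(arr, block = c(1, 1, 2, 2, 3, 3))
  surr <- surrogate_distribution(spec, seed = 2)
  expect_equal(surr$n_perm, 100)
  surr2 <- surrogate_distribution(spec, seed = 2)
  expect_identical(surr$perms, surr2$perms)
  expect_error(surrogate_distribution(spec, n_perm = 1), "at least 2")
})

test_that("the epoch shuffle converges to the exhaustive 3-epoch average", {
  set.seed(6)
  arr <- array(complex(real = rnorm(3 * 2 * 37), imaginary = rnorm(3 * 2 * 37)),
               c(3, 2, 37), dimnames = list(NULL, c("A", "envelope"), NULL))
  spec <- toy_spectra(arr)
  # oracle: enumerate all 3! = 6 envelope permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  exact <- Reduce(`+`, lapply(perms, function(p) {
    shuf <- arr; shuf[, 2, ] <- arr[p, 2, ]
    brute_coherence(shuf)
  })) / 6
  surr <- surrogate_distribution(spec, n_perm = 600, seed = 4,
                                 unit = "epoch")
  se <- surr$sd / sqrt(600)
  expect_true(all(abs(surr$mean - exact) <= 3 * se + 1e-12))
})

test_that("for independent signals the surrogate mean matches observed coherence", {
  set.seed(9)
  diffs <- replicate(50, {
    arr <- array(complex(real = rnorm(8 * 2 * 5), imaginary = rnorm(8 * 2 * 5)),
                 c(8, 2, 5), dimnames = list(NULL, c("A", "envelope"), NULL))
    spec <- toy_spectra(arr, freqs = seq(1, 2, 0.25))
    obs <- compute_coherence(spec)$coh
    surr <- surrogate_distribution(spec, n_perm = 60, unit = "epoch")
    mean(obs - surr$mean)
  })
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("z-scoring centres on the surrogate and averages the stated bands", {
  bands <- analysis_bands()
  expect_equal(bands$stress, c(1.00, 1.25, 1.50, 1.75))
  expect_equal(bands$syllable, c(2.50, 2.75, 3.00, 3.25, 3.50))
  freqs <- analysis_freqs()
  coh <- structure(list(coh = matrix(seq_len(2 * 37) / 80, 2, 37,
                                     dimnames = list(c("A", "B"), NULL)),
                        n_epochs = 10, condition = "overall", freqs = freqs),
                   class = "sbc_coherence")
  surr <- list(mean = coh$coh, sd = matrix(0.1, 2, 37))
  bz <- zscore_coherence(coh, surr)
  expect_true(all(bz$z == 0))
  # hand-built toy: z = (coh - mean)/sd, band scalar = mean of member bins
  surr2 <- list(mean = matrix(0.2, 2, 37), sd = matrix(0.05, 2, 37))
  bz2 <- zscore_coherence(coh, surr2)
  expect_equal(bz2$z, (coh$coh - 0.2) / 0.05)
  hand_stress_A <- mean((coh$coh[1, match(bands$stress, freqs)] - 0.2) / 0.05)
  expect_equal(unname(bz2$band_channel["A", "stress"]), hand_stress_A)
  expect_equal(unname(bz2$summary["stress"]),
               mean(bz2$band_channel[, "stress"]))
  # zero surrogate SD drops the bin from the band average
  surr3 <- surr2
  surr3$sd[1, match(1, freqs)] <- 0
  bz3 <- zscore_coherence(coh, surr3)
  expect_true(is.na(bz3$z[1, match(1, freqs)]))
  expect_equal(unname(bz3$band_channel["A", "stress"]),
               mean((coh$coh[1, match(c(1.25, 1.5, 1.75), freqs)] - 0.2) / 0.05))
})
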