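test_that("Slepian tapers match the reference implementation and are orthonormal", {
  v <- dpss_tapers(64, 4, 4)
  ## frozen reference values from scipy.signal.windows.dpss(64, 4, 4)
  expect_equal(max(v[, 1]), 0.2473371865596643, tolerance = 1e-10)
  expect_equal(v[1:3, 1], c(3.106368300718e-05, 9.977397693674e-05,
                            2.392140563208e-04), tolerance = 1e-8)
  expect_equal(v[1:3, 2], c(0.00024711146, 0.000700089413, 0.001528953751),
               tolerance = 1e-8)
  expect_lt(max(abs(crossprod(v) - diag(4))), 1e-12)
  expect_error(dpss_tapers(64, 4, 8), "Slepian bound")
  expect_error(spectrogram_config(time_bandwidth = 7, n_tapers = 14),
               "n_tapers")
  expect_error(spectrogram_config(window_s = 0.1, step_s = 0.2), "step_s")
})

test_that("a pure tone yields a stationary peak at its frequency", {
  fs <- 1000
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  ep <- epoch_array(cbind(sin(2 * pi * 140 * t)), fs = fs, t0 = -1)
  sp <- multitaper_spectrogram(ep, 1, spectrogram_config(step_s = 0.1))
  peak_freq <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(peak_freq - 140) <= sp$freqs[2] - sp$freqs[1]))
  peaks <- apply(sp$power, 1, max)
  expect_lt(diff(range(peaks)) / mean(peaks), 0.05)
})

test_that("white-noise spectrograms are flat and satisfy Parseval", {
  fs <- 1000
  sigma2 <- 4
  set.seed(77)
  stats <- t(replicate(100, {
    x <- rnorm(fs, sd = sqrt(sigma2))
    ep <- epoch_array(cbind(x), fs = fs, t0 = 0)
    sp <- multitaper_spectrogram(ep, 1, spectrogram_config(step_s = 0.25))
    df <- sp$freqs[2] - sp$freqs[1]
    lohalf <- sp$freqs < fs / 4
    c(total = mean(rowSums(sp$power)) * df,
      lo = mean(sp$power[, lohalf]), hi = mean(sp$power[, !lohalf]))
  }))
  expect_equal(mean(stats[, "total"]), sigma2, tolerance = 0.05)
  expect_equal(mean(stats[, "lo"]) / mean(stats[, "hi"]), 1, tolerance = 0.05)
})

test_that("zero input gives zero power and short epochs error", {
  ep <- epoch_array(cbind(numeric(1000)), fs = 1000, t0 = 0)
  sp <- multitaper_spectrogram(ep, 1, spectrogram_config(step_s = 0.25))
  expect_true(all(sp$power == 0))
  short <- epoch_array(cbind(rnorm(100)), fs = 1000, t0 = 0)
  expect_error(multitaper_spectrogram(short, 1), "too short")
})

test_that("band normalization is a per-frequency baseline z-score", {
  P <- matrix(10, 8, 3)
  P[5, 3] <- 30
  P[1:4, 3] <- c(8, 12, 8, 12)                  # baseline mean 10, sd ~2.31
  P[, 2] <- seq(2, 16, by = 2)
  sp <- toy_spectrogram(P)                      # times -2, -1.75, ... -0.25
  z <- normalize_by_band(sp, baseline = c(-2, -1.25))
  expect_true(z$normalized)
  expect_true(all(z$power[, 1] == 0))           # constant band -> zeros
  sd3 <- sd(c(8, 12, 8, 12))
  expect_equal(z$power[5, 3], (30 - 10) / sd3)
  expect_error(normalize_by_band(z), "already normalized")
  ## zero baseline variance with later deviation names the band
  P2 <- matrix(1, 8, 2)
  P2[6, 2] <- 5
  expect_error(normalize_by_band(toy_spectrogram(P2), c(-2, -1.25)),
               "zero baseline variance.*20")
  ## random spectrogram: baseline-restricted rows have mean 0, sd 1
  set.seed(3)
  sp3 <- toy_spectrogram(matrix(rexp(20 * 6), 20, 6), dt = 0.1)
  z3 <- normalize_by_band(sp3, baseline = c(-2, -1))
  bidx <- z3$times <= -1
  expect_lt(max(abs(colMeans(z3$power[bidx, ]))), 1e-12)
  expect_equal(unname(apply(z3$power[bidx, ], 2, sd)), rep(1, 6))
})

test_that("band power averages the selected rectangle", {
  P <- matrix(3, 6, 4)
  sp <- toy_spectrogram(P)
  expect_equal(band_power(sp, 10, 40, -2, -0.5), 3)
  P2 <- matrix(0, 6, 4)
  P2[, 4] <- 5                                   # power only at 40 Hz
  sp2 <- toy_spectrogram(P2)
  expect_equal(band_power(sp2, 10, 30, -2, -0.5), 0)
  expect_error(band_power(sp2, 100, 200, -2, -0.5), "empty")
  expect_error(band_power(normalize_by_band(sp, c(-2, -1.25)),
                          10, 40, -2, -0.5), "un-normalized")
})

test_that("the difference-spectrogram statistic matches a brute-force oracle", {
  set.seed(11)
  A <- toy_spectrogram(matrix(runif(25), 5, 5), t0 = -1.25, dt = 0.6)
  B <- toy_spectrogram(matrix(runif(25), 5, 5), t0 = -1.25, dt = 0.6)
  ti <- A$times >= -1 & A$times <= 1
  brute <- 0; nc <- 0
  for (i in which(ti)) for (j in 1:5) {
    brute <- brute + abs(A$power[i, j] - B$power[i, j]); nc <- nc + 1
  }
  expect_equal(difference_spectrogram_stat(A, B), brute / nc)
  expect_equal(difference_spectrogram_stat(B, A),
               difference_spectrogram_stat(A, B))
  expect_equal(difference_spectrogram_stat(A, A), 0)
  C <- toy_spectrogram(A$power + 2.5, t0 = -1.25, dt = 0.6)
  expect_equal(difference_spectrogram_stat(A, C), 2.5)
  D <- toy_spectrogram(matrix(runif(25), 5, 5), t0 = -1.4, dt = 0.6)
  expect_error(difference_spectrogram_stat(A, D), "grids")
})

test_that("averaging requires a common grid and averages cell-wise", {
  A <- toy_spectrogram(matrix(1, 4, 2), t0 = -1.5, dt = 1)
  B <- toy_spectrogram(matrix(3, 4, 2), t0 = -1.5, dt = 1)
  M <- average_spectrograms(list(A, B))
  expect_true(all(M$power == 2))
  C <- toy_spectrogram(matrix(1, 5, 2), t0 = -1.5, dt = 1)
  expect_error(average_spectrograms(list(A, C)), "share")
})
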