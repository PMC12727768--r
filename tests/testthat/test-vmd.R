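# FFT peak-frequency oracle: location of the largest periodogram bin, Hz
fft_peak_hz <- function(x, fs) {
  p <- Mod(stats::fft(x)[1:(length(x) %/% 2)])^2
  (which.max(p) - 1) * fs / length(x)
}

test_that("mode update matches an element-wise evaluation of the formula", {
  set.seed(1)
  H <- 64
  grid <- (0:(H - 1)) / (2 * H)
  f <- complex(real = rnorm(H), imaginary = rnorm(H))
  others <- complex(real = rnorm(H), imaginary = rnorm(H))
  lam <- complex(real = rnorm(H), imaginary = rnorm(H))
  wn <- 0.13
  alpha <- 2000
  # brute-force element-wise oracle
  expected <- vapply(seq_len(H), function(i)
    (f[i] - others[i] + lam[i] / 2) / (1 + 2 * alpha * (grid[i] - wn)^2),
    complex(1))
  got <- update_mode(f, others, lam, wn, alpha, grid)
  expect_equal(got, expected, tolerance = 1e-12)

  # single mode, zero dual, vanishing penalty -> passthrough
  got0 <- update_mode(f, complex(H), complex(H), wn, 1e-12, grid)
  expect_equal(got0, f, tolerance = 1e-6)

  # strong penalty far from the center shrinks the magnitude
  far <- update_mode(f, complex(H), complex(H), 0.45, 1e6, grid)
  expect_true(all(Mod(far[1:10]) <=
                    Mod(f[1:10]) / (1 + 2 * 1e6 * (grid[1:10] - 0.45)^2) +
                    1e-12))

  expect_error(update_mode(f, others[1:10], lam, wn, alpha, grid), "grid")
})

test_that("center-frequency update is the spectral center of mass", {
  H <- 128
  grid <- (0:(H - 1)) / (2 * H)

  one_bin <- complex(H); one_bin[40] <- 3 + 2i
  expect_equal(update_center_frequency(one_bin, grid), grid[40])

  two_bins <- complex(H); two_bins[20] <- 1i; two_bins[60] <- 1
  expect_equal(update_center_frequency(two_bins, grid),
               (grid[20] + grid[60]) / 2)

  set.seed(2)
  spec <- complex(real = rnorm(H), imaginary = rnorm(H))
  p <- Mod(spec)^2
  expect_equal(update_center_frequency(spec, grid),
               sum(grid * p) / sum(p), tolerance = 1e-12)

  expect_true(is.na(update_center_frequency(complex(H), grid)))
})

test_that("a single tone is recovered as one mode at its frequency", {
  fs <- 1000
  t <- (0:(fs - 1)) / fs
  x <- cos(2 * pi * 50 * t)
  fit <- vmd_decompose(x, K = 1, alpha = 2000, fs = fs)
  expect_lt(abs(fit$center_freqs_hz - fft_peak_hz(x, fs)), 1)
  expect_gt(cor(fit$modes[1, ], x), 0.99)
})

test_that("the tri-harmonic signal splits into its three tones", {
  fs <- 1000
  x <- make_triharmonic(fs, 1, c(10, 60, 200), c(1, 0.5, 0.25))
  fit <- vmd_decompose(x, K = 3, alpha = 2000, fs = fs)
  expect_equal(fit$center_freqs_hz, c(10, 60, 200), tolerance = 2 / 10)
  expect_true(all(abs(fit$center_freqs_hz - c(10, 60, 200)) < 2))
  # ascending order contract
  expect_true(!is.unsorted(fit$center_freqs))

  # spectral compactness: >= 90% of each mode's energy within +/- 10 Hz
  for (n in 1:3) {
    p <- Mod(stats::fft(fit$modes[n, ])[1:(fs %/% 2)])^2
    hz <- 0:(fs %/% 2 - 1)
    inband <- abs(hz - fit$center_freqs_hz[n]) <= 10
    expect_gt(sum(p[inband]) / sum(p), 0.9)
  }
})

test_that("added noise barely moves the recovered center frequencies", {
  fs <- 1000
  xn <- make_triharmonic(fs, 1, c(10, 60, 200), c(1, 0.5, 0.25),
                         noise_sigma = 0.1, seed = 7)
  fit <- vmd_decompose(xn, K = 3, alpha = 2000, fs = fs)
  expect_true(all(abs(fit$center_freqs_hz - c(10, 60, 200)) < 5))
})

test_that("dual ascent drives reconstruction error to ~0 in-band", {
  fs <- 1000
  x <- make_triharmonic(fs, 1, c(10, 60, 200), c(1, 0.5, 0.25))
  fit <- vmd_decompose(x, K = 3, alpha = 2000, tau = 1, fs = fs)
  expect_lte(fit$reconstruction_error, 1e-2)
  # stored error equals an independent recomputation
  err <- sqrt(sum((x - colSums(fit$modes))^2)) / sqrt(sum(x^2))
  expect_equal(fit$reconstruction_error, err)

  # band-limited random input whose band the K-mode bank can cover
  # (each mode's Wiener half-width is ~1/sqrt(2*alpha) cycles/sample)
  set.seed(3)
  w <- rnorm(2000)
  filt <- signal::butter(4, c(0.05, 0.15) * 2, "pass")
  xb <- signal::filtfilt(filt, w)
  fb <- vmd_decompose(xb, K = 4, alpha = 2000, tau = 1)
  expect_lte(fb$reconstruction_error, 1e-2)
})

test_that("degenerate and invalid inputs are handled", {
  fz <- vmd_decompose(rep(0, 100), K = 3)
  expect_equal(max(abs(fz$modes)), 0)
  expect_equal(fz$reconstruction_error, 0)

  expect_error(vmd_decompose(c(1, NA, 3, 4), K = 1), "finite")
  expect_error(vmd_decompose(rnorm(4), K = 3), "short|bins")
})

test_that("decomposition is deterministic, including random init", {
  x <- make_triharmonic(500, 1, c(10, 60, 200), c(1, 0.5, 0.25),
                        noise_sigma = 0.05, seed = 1)
  a <- vmd_decompose(x, K = 3, init = "random", seed = 42)
  b <- vmd_decompose(x, K = 3, init = "random", seed = 42)
  expect_identical(a, b)

  # odd-length signals go through the edge-padding path unharmed
  o <- vmd_decompose(x[1:499], K = 2)
  expect_equal(ncol(o$modes), 499)
})
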