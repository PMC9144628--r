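# direct double-loop evaluation of the discrete STFT magnitude, the
# independent oracle for the vectorized implementation
stft_bruteforce <- function(x, taper, hop) {
  L <- length(x)
  K <- length(taper)
  n_frames <- (L - K) %/% hop + 1
  n_bins <- K %/% 2 + 1
  out <- matrix(0, n_bins, n_frames)
  for (fr in seq_len(n_frames)) {
    seg <- x[((fr - 1) * hop + 1):((fr - 1) * hop + K)] * taper
    for (k in seq_len(n_bins)) {
      w <- exp(-2i * pi * (k - 1) * (0:(K - 1)) / K)
      out[k, fr] <- Mod(sum(seg * w))
    }
  }
  out
}

as_sample <- function(window, fs = 1000) {
  structure(list(window = window, fs = fs, gesture = 1L, subject = 1L),
            class = "semg_sample")
}

test_that("spectrogram geometry matches the Hanning-64 / hop-29 design", {
  s <- as_sample(matrix(stats::rnorm(2 * 1000), 2))
  sp <- stft_spectrogram(s)
  expect_equal(dim(sp$values), c(2L, 33L, 33L))
  expect_true(all(sp$values >= 0))
  z <- stft_spectrogram(as_sample(matrix(0, 1, 1000)))
  expect_equal(z$values, array(0, c(1, 33, 33)))
  expect_error(stft_spectrogram(as_sample(matrix(0, 1, 50))), "shorter")
})

test_that("spectrogram equals the direct transform on random inputs", {
  cfg <- stft_config()
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rnorm(1000)
    sp <- stft_spectrogram(as_sample(matrix(x, 1)), cfg)
    expect_lt(max(abs(sp$values[1, , ] - stft_bruteforce(x, cfg$taper, cfg$hop))), 1e-9)
  }
})

test_that("a sinusoid at a bin frequency peaks at its bin in every frame", {
  fs <- 1000
  for (k in c(3, 8, 16)) { # bin frequencies k * fs / 64
    x <- sin(2 * pi * (k * fs / 64) * seq_len(1000) / fs)
    sp <- stft_spectrogram(as_sample(matrix(x, 1)))
    peaks <- apply(sp$values[1, , ], 2, which.max)
    expect_true(all(peaks == k + 1)) # bin k is row k+1 (DC = row 1)
  }
})

test_that("spectrogram magnitude scales linearly with input amplitude", {
  set.seed(7)
  x <- matrix(stats::rnorm(1000), 1)
  a <- stft_spectrogram(as_sample(x))$values
  b <- stft_spectrogram(as_sample(2 * x))$values
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("FFT spectrum: impulse is flat, sinusoids peak at their frequency", {
  imp <- matrix(0, 1, 1000); imp[1, 1] <- 1
  sp <- fft_spectrum(as_sample(imp))
  expect_equal(dim(sp$values), c(1L, 501L))
  expect_true(all(abs(sp$values - 1) < 1e-12))
  x <- matrix(sin(2 * pi * 50 * seq_len(1000) / 1000), 1)
  expect_equal(which.max(fft_spectrum(as_sample(x))$values[1, ]), 51L) # 50 Hz bin
  z <- fft_spectrum(as_sample(matrix(0, 2, 1000)))
  expect_equal(z$values, matrix(0, 2, 501))
})

test_that("MAV features follow the 200 ms / 25 ms sliding-window count", {
  s <- as_sample(matrix(3, 2, 1000)) # constant |x| = 3
  mv <- mav_features(s)
  expect_equal(dim(mv$values), c(2L, 33L)) # floor((1000-200)/25) + 1
  expect_true(all(mv$values == 3))
  alt <- as_sample(matrix(rep(c(1, -1), 500), 1, 1000))
  expect_true(all(mav_features(alt)$values == 1))
  expect_error(mav_features(as_sample(matrix(0, 1, 100))), "longer")
})

test_that("raw-image mode transposes to a time-by-electrode image", {
  s <- as_sample(matrix(stats::rnorm(3 * 1000), 3))
  ri <- raw_image(s)
  expect_equal(dim(ri$values), c(1000L, 3L))
  expect_equal(ri$values, t(s$window))
})
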