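test_that("band-stop filter suppresses 50 Hz and passes 10 Hz as designed", {
  # frequency-response oracle: squared magnitude of the designed filter
  # (forward-backward application), via direct polynomial evaluation
  bs <- signal::butter(2, c(45, 55) / 500, type = "stop")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / 1000 * (seq_along(bs$b) - 1))
    Mod(sum(bs$b * z) / sum(bs$a * z))^2
  }

  r50 <- bandstop_filter(sine_recording(50))
  mid <- 1001:2000 # interior, away from the filtfilt transient
  ratio50 <- sqrt(mean(r50$signal[1, mid]^2)) / sqrt(0.5)
  expect_lt(ratio50, 10^(-20 / 20)) # at least 20 dB attenuation
  expect_lt(H(50), 1e-2)

  r10 <- bandstop_filter(sine_recording(10))
  ratio10 <- sqrt(mean(r10$signal[1, mid]^2)) / sqrt(0.5)
  expect_equal(ratio10, H(10), tolerance = 1e-3)
  expect_equal(ratio10, 1, tolerance = 0.01)
})

test_that("all-zero signals stay zero through the filter", {
  rec <- recording(matrix(0, 3, 2000), 1000, 1L, 1L)
  expect_equal(bandstop_filter(rec)$signal, matrix(0, 3, 2000))
  expect_error(bandstop_filter(rec, band = c(45, 600)), "fs/2")
})

test_that("middle-window extraction picks the centered 1000 samples", {
  sig <- rbind(seq_len(3000), 2 * seq_len(3000))
  rec <- recording(sig, 1000, 2L, 3L)
  s <- extract_middle_window(rec)
  # index-arithmetic oracle: start = floor((3000 - 1000)/2) = 1000 (0-based)
  expect_equal(dim(s$window), c(2L, 1000L))
  expect_equal(s$window[1, ], 1001:2000)
  expect_equal(s$gesture, 2L)

  # T = L is the identity
  rec2 <- recording(sig[, 1:1000], 1000, 1L, 1L)
  expect_equal(extract_middle_window(rec2)$window, sig[, 1:1000])

  # odd leftover: start floor-ties toward the earlier sample
  rec3 <- recording(sig[, 1:1001], 1000, 1L, 1L)
  expect_equal(extract_middle_window(rec3)$window[1, ], 1:1000)

  expect_error(extract_middle_window(recording(sig[, 1:900], 1000, 1L, 1L)),
               "shorter than")
})

test_that("normalization z-scores channels and fixes degenerate ones", {
  set.seed(1)
  s <- extract_middle_window(recording(rbind(rnorm(1500, 5, 3), rep(7, 1500)), 1000, 1L, 1L))
  z <- normalize_sample(s)
  expect_lt(abs(mean(z$window[1, ])), 1e-9)
  psd <- sqrt(mean((z$window[1, ] - mean(z$window[1, ]))^2))
  expect_lt(abs(psd - 1), 1e-6)
  expect_equal(z$window[2, ], rep(0, 1000)) # constant channel -> zeros
  z2 <- normalize_sample(z)
  expect_equal(z2$window[1, ], z$window[1, ], tolerance = 1e-9) # idempotent
  s$window[1, 1] <- NA
  expect_error(normalize_sample(s), "non-finite")
})

test_that("the full pipeline yields valid samples and commutes with windowing", {
  rec <- easy_dataset()[[1]]
  s <- preprocess_recording(rec)
  expect_s3_class(s, "semg_sample")
  expect_equal(dim(s$window), c(16L, 1000L))
  expect_true(all(is.finite(s$window)))
  mu <- rowMeans(s$window)
  expect_true(all(abs(mu) < 1e-9))

  # filtering then windowing equals windowing after filtering with margin:
  # compare the interior of filter->window vs window(filtered full signal)
  long <- recording(matrix(stats::rnorm(2 * 3000), 2), 1000, 1L, 1L)
  a <- extract_middle_window(bandstop_filter(long))$window
  full <- bandstop_filter(long)$signal[, 1001:2000]
  expect_equal(a, full)
})
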