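test_that("generation is bit-reproducible given the seed", {
  cfg <- synth_config(n_subjects = 2, n_gestures = 3, n_repetitions = 2, seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_length(a, 2 * 3 * 2)
})

test_that("clean, well-separated envelopes give perfect channel-RMS separability", {
  cfg <- synth_config(n_subjects = 2, n_gestures = 8, n_repetitions = 4,
                      noise_sd = 0, powerline_amp = 0, subject_gain_sd = 0,
                      subject_shift_max = 0, seed = 2)
  recs <- generate_dataset(cfg)
  rms <- t(vapply(recs, function(r) sqrt(rowMeans(r$signal^2)), numeric(cfg$n_channels)))
  lab <- vapply(recs, function(r) r$gesture, integer(1))
  # oracle: nearest-centroid classifier on the channel-RMS vectors
  cent <- vapply(sort(unique(lab)), function(g) colMeans(rms[lab == g, , drop = FALSE]),
                 numeric(cfg$n_channels))
  pred <- apply(rms, 1, function(v) which.min(colSums((cent - v)^2)))
  expect_equal(mean(pred == lab), 1)
})

test_that("powerline interference concentrates spectral power at 50 Hz", {
  cfg <- synth_config(n_subjects = 1, n_gestures = 2, n_repetitions = 1,
                      powerline_amp = 1, noise_sd = 0.05, seed = 3)
  recs <- generate_dataset(cfg)
  for (r in recs) {
    # periodogram oracle: |DFT|^2 at exact-bin frequencies (1 s -> 1 Hz bins)
    for (ch in seq_len(nrow(r$signal))) {
      spec <- Mod(stats::fft(r$signal[ch, ]))^2
      expect_gt(spec[51], spec[61]) # 50 Hz bin vs 60 Hz bin (1-based)
    }
  }
})

test_that("subject-disjoint splits partition recordings 16:1:1-style", {
  cfg <- synth_config(n_subjects = 18, n_gestures = 2, n_repetitions = 1,
                      duration = 1, seed = 5)
  recs <- generate_dataset(cfg)
  sp <- make_fewshot_splits(recs, 1:16, 17, 18)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 16 * 2, val = 2, test = 2))
  subj <- lapply(sp, function(p) unique(vapply(p, function(r) r$subject, integer(1))))
  expect_length(intersect(subj$train, subj$val), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$val, subj$test), 0)
})

test_that("overlapping subject sets are rejected and empty pools allowed", {
  recs <- easy_dataset()[1:20]
  expect_error(make_fewshot_splits(recs, 1:2, 2, 3), "appear in both")
  sp <- make_fewshot_splits(recs, 1, integer(0), 2)
  expect_length(sp$val, 0)
})

test_that("datasets round-trip through the bundle directory format", {
  recs <- generate_dataset(synth_config(n_subjects = 1, n_gestures = 2,
                                        n_repetitions = 2, seed = 1))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(recs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_named(manifest, c("file", "subject", "gesture", "repetition", "fs"))
  back <- read_dataset(dir)
  expect_identical(back, recs)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(n_gestures = 1), "n_gestures")
  expect_error(synth_config(duration = 0.5), "1000 samples")
  expect_error(synth_config(noise_sd = -1), "SDs")
  expect_error(synth_config(carrier_band = c(100, 600)), "carrier_band")
  expect_error(synth_config(subject_shift_max = 4), "shift_max")
})
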