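# Shared fixtures, built once per test session. The "easy" profile is the
# package's default small study condition: 8 subjects, 8 gestures, 10
# repetitions, a 4x4 electrode grid, 1 s at 1000 Hz, mild subject effects.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

easy_dataset <- function() fixture("easy_dataset", function() {
  generate_dataset(synth_config(seed = 10))
})

# the full easy-profile study pool (25 repetitions, log1p spectrograms)
study_pool <- function() fixture("study_pool", function() {
  build_study_pool(synth_profile("easy"))
})

# a lighter pool for unit tests: first 10 repetitions per subject x gesture
easy_pool <- function() fixture("easy_pool", function() {
  pool <- study_pool()
  grp <- interaction(pool$subject, pool$gesture, drop = TRUE)
  keep <- stats::ave(seq_along(grp), grp, FUN = seq_along) <= 10
  semgmeta:::subset_pool(pool, keep)
})

easy_net_cfg <- function(n_classes = 5) {
  network_config(c(33, 33, 16), n_classes = n_classes, cell_channels = c(8, 8, 8))
}

# tiny pool with distinguishable dummy features, for protocol-level tests
# (task sampling, splitting) where the feature content is irrelevant
dummy_pool <- function(n_classes = 8, n_subjects = 4, per_cell = 5) {
  feats <- list()
  k <- 0
  for (s in seq_len(n_subjects)) for (g in seq_len(n_classes)) for (r in seq_len(per_cell)) {
    k <- k + 1
    feats[[k]] <- structure(list(values = array(k, c(2, 3, 3)), mode = "stft",
                                 gesture = g, subject = s, fs = 1000),
                            class = "semg_features")
  }
  make_pool(feats)
}

# a quick sine-carrier recording for filter tests
sine_recording <- function(freq, fs = 1000, dur = 3, channels = 2) {
  tvec <- seq_len(dur * fs) / fs
  sig <- matrix(rep(sin(2 * pi * freq * tvec), channels), nrow = channels, byrow = TRUE)
  recording(sig, fs, gesture = 1L, subject = 1L)
}

expect_param_equal <- function(a, b, tol = 0) {
  expect_equal(semgmeta:::param_flatten(a), semgmeta:::param_flatten(b), tolerance = tol)
}
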