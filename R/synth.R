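#' Configuration for the synthetic high-density sEMG generator
#'
#' Builds a validated configuration for [generate_dataset()]. The generator
#' emulates the structure of grid-electrode (HD-sEMG) gesture recordings:
#' each gesture excites a fixed, smooth spatial activation pattern over the
#' electrode grid; each subject perturbs that pattern by a log-normal gain, a
#' circular shift of the electrode columns (electrode-donning offset) and
#' independent sensor noise; all channels share a 50 Hz powerline component.
#'
#' @param n_subjects number of subjects.
#' @param n_gestures number of gesture classes (>= 2).
#' @param n_repetitions repetitions of each gesture per subject.
#' @param grid integer `c(rows, cols)` of the electrode grid; the channel
#'   count is `prod(grid)`. The full-scale geometry is `c(8, 16)` (128
#'   channels); the default small profile is `c(4, 4)`.
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds (`duration * fs >= 1000`).
#' @param carrier_band `c(low, high)` Hz band of the stochastic sEMG carrier.
#' @param powerline_amp amplitude of the 50 Hz interference relative to the
#'   unit-amplitude activation envelope.
#' @param subject_gain_sd SD of the per-subject log-gain.
#' @param subject_shift_max maximum per-subject circular electrode-column
#'   shift (integer, in columns).
#' @param subject_jitter_sd SD (in electrode units) of a continuous
#'   per-subject 2-D displacement of every gesture's activation center —
#'   fractional electrode-placement offset; unlike the integer column
#'   shift, it is never repeated across subjects. 0 disables.
#' @param noise_sd SD of additive white sensor noise.
#' @param envelope_width width (SD, in electrodes) of the Gaussian activation
#'   bump of each gesture.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return an object of class `semg_synth_config`.
#' @export
synth_config <- function(n_subjects = 8, n_gestures = 8, n_repetitions = 10,
                         grid = c(4, 4), fs = 1000, duration = 1,
                         carrier_band = c(20, 150), powerline_amp = 0.2,
                         subject_gain_sd = 0.2, subject_shift_max = 1,
                         subject_jitter_sd = 0, noise_sd = 0.3,
                         envelope_width = 2, seed = 1L) {
  grid <- as.integer(grid)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_gestures = as.integer(n_gestures),
    n_repetitions = as.integer(n_repetitions), grid = grid,
    n_channels = prod(grid), fs = fs, duration = duration,
    carrier_band = carrier_band, powerline_amp = powerline_amp,
    subject_gain_sd = subject_gain_sd, subject_shift_max = as.integer(subject_shift_max),
    subject_jitter_sd = subject_jitter_sd, noise_sd = noise_sd,
    envelope_width = envelope_width, seed = as.integer(seed)
  )
  class(cfg) <- "semg_synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "semg_synth_config"))
  if (cfg$n_gestures < 2) stop("synth_config: n_gestures must be >= 2")
  if (cfg$n_subjects < 1 || cfg$n_repetitions < 1)
    stop("synth_config: n_subjects and n_repetitions must be >= 1")
  if (cfg$n_channels != prod(cfg$grid))
    stop("synth_config: n_channels must equal rows * cols of the grid")
  if (cfg$duration * cfg$fs < 1000)
    stop("synth_config: duration * fs must be >= 1000 samples")
  if (cfg$powerline_amp < 0 || cfg$subject_gain_sd < 0 || cfg$noise_sd < 0 ||
      cfg$subject_jitter_sd < 0)
    stop("synth_config: amplitudes and SDs must be >= 0")
  if (length(cfg$carrier_band) != 2 || cfg$carrier_band[1] <= 0 ||
      cfg$carrier_band[2] <= cfg$carrier_band[1] || cfg$carrier_band[2] >= cfg$fs / 2)
    stop("synth_config: carrier_band must satisfy 0 < low < high < fs/2")
  if (cfg$subject_shift_max < 0 || cfg$subject_shift_max >= cfg$grid[2])
    stop("synth_config: subject_shift_max must lie in [0, cols - 1]")
  invisible(cfg)
}

#' Construct a raw multichannel recording
#'
#' @param signal C x T numeric matrix (channels x samples).
#' @param fs sampling rate in Hz.
#' @param gesture integer gesture class (1-based).
#' @param subject integer subject index.
#' @param repetition integer repetition index.
#' @return an object of class `semg_recording`.
#' @export
recording <- function(signal, fs, gesture, subject, repetition = 1L) {
  stopifnot(is.matrix(signal), all(is.finite(signal)))
  structure(list(signal = signal, fs = fs, gesture = as.integer(gesture),
                 subject = as.integer(subject), repetition = as.integer(repetition)),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("<semg_recording> %d channels x %d samples @ %g Hz | gesture %d, subject %d, rep %d\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$gesture, x$subject, x$repetition))
  invisible(x)
}

# deterministic gesture activation centers spread on a grid sub-lattice
gesture_centers <- function(n_gestures, grid) {
  rows <- grid[1]; cols <- grid[2]
  nr <- max(1L, round(sqrt(n_gestures * rows / cols)))
  nc <- ceiling(n_gestures / nr)
  rc <- expand.grid(
    r = seq(1, rows, length.out = nr + 2)[-c(1, nr + 2)],
    c = seq(1, cols, length.out = nc + 2)[-c(1, nc + 2)]
  )
  rc[seq_len(n_gestures), , drop = FALSE]
}

# Gesture-specific spatial envelopes: Gaussian bumps of unit amplitude at
# centers spread deterministically over the grid, so classes are smooth,
# distinct, and sensitive to column shifts. Returns n_gestures x n_channels.
gesture_envelopes <- function(n_gestures, grid, width = 2, offset = NULL) {
  rows <- grid[1]; cols <- grid[2]
  rc <- gesture_centers(n_gestures, grid)
  env <- matrix(0, n_gestures, rows * cols)
  pos <- expand.grid(r = seq_len(rows), c = seq_len(cols)) # channel = r + rows*(c-1)
  for (g in seq_len(n_gestures)) {
    if (is.null(offset)) {
      d2 <- (pos$r - rc$r[g])^2 + (pos$c - rc$c[g])^2
    } else {
      # jittered centers may cross the band edge: wrap the column distance
      dr <- pos$r - (rc$r[g] + offset[1])
      dc <- abs(pos$c - (rc$c[g] + offset[2]))
      dc <- pmin(dc, cols - dc)
      d2 <- dr^2 + dc^2
    }
    env[g, ] <- exp(-d2 / (2 * width^2))
  }
  env
}

# circularly shift the envelope's grid columns by `shift`
shift_envelope <- function(env_row, grid, shift) {
  if (shift == 0) return(env_row)
  m <- matrix(env_row, grid[1], grid[2])
  idx <- ((seq_len(grid[2]) - 1 - shift) %% grid[2]) + 1
  as.numeric(m[, idx])
}

#' Generate a labelled synthetic HD-sEMG dataset
#'
#' Each recording is built as
#' `signal[c, ] = gain_s * E_g(shift_s(c)) * carrier_c(t) + noise + powerline`,
#' where `E_g` is the gesture's Gaussian spatial envelope over the grid,
#' `carrier_c` is Gaussian white noise band-passed to `carrier_band` by a
#' 4th-order Butterworth filter (independent per channel), `gain_s` is the
#' subject's log-normal gain, `shift_s` a per-subject circular column shift,
#' and the powerline term is `powerline_amp * sin(2 pi 50 t + phase)` with a
#' per-recording phase common to all channels.
#'
#' Generation is deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list of [recording()] objects, one per
#'   subject x gesture x repetition.
#' @export
generate_dataset <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  fs <- config$fs
  nT <- round(config$duration * fs)
  env <- gesture_envelopes(config$n_gestures, config$grid, config$envelope_width)
  bp <- signal::butter(4, config$carrier_band / (fs / 2), type = "pass")
  tvec <- seq_len(nT) / fs

  gains <- exp(stats::rnorm(config$n_subjects, 0, config$subject_gain_sd))
  shifts <- if (config$subject_shift_max > 0)
    sample(-config$subject_shift_max:config$subject_shift_max, config$n_subjects, replace = TRUE)
  else rep(0L, config$n_subjects)
  jitter <- if (config$subject_jitter_sd > 0)
    matrix(stats::rnorm(2 * config$n_subjects, 0, config$subject_jitter_sd), 2)
  else NULL

  out <- vector("list", config$n_subjects * config$n_gestures * config$n_repetitions)
  k <- 0L
  for (s in seq_len(config$n_subjects)) {
    env_s <- if (is.null(jitter)) env
             else gesture_envelopes(config$n_gestures, config$grid,
                                    config$envelope_width, offset = jitter[, s])
    for (g in seq_len(config$n_gestures)) {
      e_sg <- shift_envelope(env_s[g, ], config$grid, shifts[s])
      for (r in seq_len(config$n_repetitions)) {
        carriers <- matrix(stats::rnorm(config$n_channels * nT), config$n_channels, nT)
        carriers <- t(apply(carriers, 1, function(x) signal::filter(bp, x)))
        # rescale carriers to unit RMS so the envelope sets channel energy
        rms <- sqrt(rowMeans(carriers^2))
        carriers <- carriers / pmax(rms, 1e-12)
        sig <- (gains[s] * e_sg) * carriers
        if (config$noise_sd > 0)
          sig <- sig + matrix(stats::rnorm(config$n_channels * nT, 0, config$noise_sd),
                              config$n_channels, nT)
        if (config$powerline_amp > 0) {
          phase <- stats::runif(1, 0, 2 * pi)
          pl <- config$powerline_amp * sin(2 * pi * 50 * tvec + phase)
          sig <- sig + matrix(pl, config$n_channels, nT, byrow = TRUE)
        }
        k <- k + 1L
        out[[k]] <- recording(sig, fs, g, s, r)
      }
    }
  }
  out
}

#' Partition recordings into subject-disjoint meta-learning pools
#'
#' Splits a dataset into meta-train / meta-validation / meta-test pools such
#' that no subject appears in more than one pool (the inter-subject protocol:
#' meta-test subjects are never seen during meta-training).
#'
#' @param recordings list of [recording()] objects.
#' @param train_subjects,val_subjects,test_subjects pairwise-disjoint integer
#'   vectors of subject indices; `val_subjects` may be empty.
#' @return named list `train`, `val`, `test` of recording lists.
#' @export
make_fewshot_splits <- function(recordings, train_subjects, val_subjects, test_subjects) {
  pools <- list(train = as.integer(train_subjects),
                val = as.integer(val_subjects),
                test = as.integer(test_subjects))
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(pools[[i]], pools[[j]])
    if (length(ov))
      stop(sprintf("make_fewshot_splits: subject(s) %s appear in both '%s' and '%s'",
                   paste(ov, collapse = ","), names(pools)[i], names(pools)[j]))
  }
  subj <- vapply(recordings, function(r) r$subject, integer(1))
  lapply(pools, function(p) recordings[subj %in% p])
}

#' Write a dataset as an RDS bundle directory with a CSV manifest
#'
#' Each recording's arrays are stored in one RDS bundle; `manifest.csv` lists
#' `file, subject, gesture, repetition, fs`.
#'
#' @param recordings list of recordings.
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_dataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    f <- sprintf("rec_%05d.rds", i)
    saveRDS(r, file.path(dir, f))
    data.frame(file = f, subject = r$subject, gesture = r$gesture,
               repetition = r$repetition, fs = r$fs)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return list of recordings in manifest order.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("read_dataset: no manifest.csv in ", dir)
  manifest <- utils::read.csv(mf)
  lapply(manifest$file, function(f) readRDS(file.path(dir, f)))
}
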