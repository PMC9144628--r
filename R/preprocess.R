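#' Remove powerline interference with a Butterworth band-stop filter
#'
#' Applies a zero-phase (forward-backward) Butterworth band-stop filter to
#' every channel. The default 45-55 Hz second-order design suppresses 50 Hz
#' mains interference while leaving the rest of the sEMG band essentially
#' untouched; forward-backward application squares the magnitude response and
#' cancels phase distortion.
#'
#' @param rec a [recording()].
#' @param band `c(low, high)` stop band in Hz.
#' @param order filter order of the underlying low-pass prototype.
#' @return a filtered [recording()] of identical shape.
#' @export
bandstop_filter <- function(rec, band = c(45, 55), order = 2) {
  stopifnot(inherits(rec, "semg_recording"))
  nyq <- rec$fs / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("bandstop_filter: band must satisfy 0 < low < high < fs/2")
  bs <- signal::butter(order, band / nyq, type = "stop")
  sig <- t(apply(rec$signal, 1, function(x) signal::filtfilt(bs, x)))
  recording(sig, rec$fs, rec$gesture, rec$subject, rec$repetition)
}

#' Cut out the centered fixed-duration window of a recording
#'
#' Extracts the middle `duration`-second block of every channel; with the
#' default 1 s at 1000 Hz this yields the standard 1000-sample analysis
#' window. The start index is `floor((T - L) / 2)` (0-based), breaking ties
#' toward the earlier sample.
#'
#' @param rec a [recording()].
#' @param duration window length in seconds.
#' @return an object of class `semg_sample` with fields `window` (C x L),
#'   `fs`, `gesture`, `subject`.
#' @export
extract_middle_window <- function(rec, duration = 1.0) {
  stopifnot(inherits(rec, "semg_recording"))
  L <- round(duration * rec$fs)
  Tn <- ncol(rec$signal)
  if (Tn < L) stop(sprintf("extract_middle_window: recording (%d) shorter than window (%d)", Tn, L))
  start <- floor((Tn - L) / 2) # 0-based
  w <- rec$signal[, (start + 1):(start + L), drop = FALSE]
  structure(list(window = w, fs = rec$fs, gesture = rec$gesture, subject = rec$subject),
            class = "semg_sample")
}

#' Standardize a sample channel-wise
#'
#' Per-channel z-score: subtract the channel mean and divide by the channel
#' SD (floored at 1e-12). Constant channels map to zeros.
#'
#' @param sample a `semg_sample`.
#' @return the normalized `semg_sample`.
#' @export
normalize_sample <- function(sample) {
  stopifnot(inherits(sample, "semg_sample"))
  if (!all(is.finite(sample$window))) stop("normalize_sample: non-finite values in sample")
  w <- sample$window
  mu <- rowMeans(w)
  sdv <- sqrt(rowMeans((w - mu)^2))
  sample$window <- (w - mu) / pmax(sdv, 1e-12)
  sample
}

#' Full preprocessing pipeline: filter, window, normalize
#'
#' @param rec a [recording()].
#' @param band,order passed to [bandstop_filter()].
#' @param duration passed to [extract_middle_window()].
#' @return a normalized `semg_sample`.
#' @export
preprocess_recording <- function(rec, band = c(45, 55), order = 2, duration = 1.0) {
  normalize_sample(extract_middle_window(bandstop_filter(rec, band, order), duration))
}

#' @export
print.semg_sample <- function(x, ...) {
  cat(sprintf("<semg_sample> %d channels x %d samples @ %g Hz | gesture %d, subject %d\n",
              nrow(x$window), ncol(x$window), x$fs, x$gesture, x$subject))
  invisible(x)
}
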