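#' Configuration of the short-time Fourier transform feature
#'
#' Frames start at sample 1 and advance by `hop` with no centering and no
#' padding, so a 1000-sample channel with a 64-sample window and hop 29
#' yields `floor((1000 - 64) / 29) + 1 = 33` frames and `64/2 + 1 = 33`
#' one-sided frequency bins: a 33 x 33 time-frequency image per channel.
#'
#' @param window_kind taper name; `"hann"` (Hanning) is the default and the
#'   only built-in alongside `"hamming"` and `"rect"`.
#' @param window_len window length in samples.
#' @param hop frame advance in samples.
#' @param log1p if `TRUE`, return `log1p(magnitude)` instead of magnitude.
#' @return an object of class `semg_stft_config`.
#' @export
stft_config <- function(window_kind = "hann", window_len = 64, hop = 29, log1p = FALSE) {
  if (window_len < 2) stop("stft_config: window_len must be >= 2")
  if (hop < 1 || hop > window_len) stop("stft_config: need 1 <= hop <= window_len")
  w <- switch(window_kind,
    hann = 0.5 * (1 - cos(2 * pi * (0:(window_len - 1)) / (window_len - 1))),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(window_len - 1)) / (window_len - 1)),
    rect = rep(1, window_len),
    stop("stft_config: unknown window_kind '", window_kind, "'"))
  structure(list(window_kind = window_kind, window_len = as.integer(window_len),
                 hop = as.integer(hop), taper = w, log1p = isTRUE(log1p)),
            class = "semg_stft_config")
}

#' STFT magnitude spectrogram of a preprocessed sample
#'
#' Per channel, the magnitude of the one-sided discrete STFT
#' `sum_n x[n] w[n - m] e^{-j omega n}` evaluated on full-support frames.
#' With the defaults on a 1000-sample window the output is C x 33 x 33
#' (channels x frequency bins x frames).
#'
#' @param sample a `semg_sample`.
#' @param cfg an [stft_config()].
#' @return `semg_features` with `values` array C x F x Tf, `mode = "stft"`.
#' @export
stft_spectrogram <- function(sample, cfg = stft_config()) {
  stopifnot(inherits(sample, "semg_sample"), inherits(cfg, "semg_stft_config"))
  L <- ncol(sample$window)
  if (L < cfg$window_len)
    stop("stft_spectrogram: sample shorter than the analysis window")
  C <- nrow(sample$window)
  n_frames <- (L - cfg$window_len) %/% cfg$hop + 1L
  n_bins <- cfg$window_len %/% 2L + 1L
  starts <- (seq_len(n_frames) - 1L) * cfg$hop
  vals <- array(0, c(C, n_bins, n_frames))
  for (ch in seq_len(C)) {
    frames <- vapply(starts, function(s) sample$window[ch, (s + 1):(s + cfg$window_len)],
                     numeric(cfg$window_len))
    spec <- stats::mvfft(frames * cfg$taper)
    vals[ch, , ] <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  }
  if (cfg$log1p) vals <- log1p(vals)
  feature_tensor(vals, "stft", sample)
}

#' One-sided FFT magnitude spectrum of a sample
#'
#' Per channel, magnitude of DFT bins `0 .. floor(L/2)` (501 bins for a
#' 1000-sample window), stacked into a single-channel C x F image.
#'
#' @param sample a `semg_sample`.
#' @return `semg_features` with `values` matrix C x F, `mode = "fft"`.
#' @export
fft_spectrum <- function(sample) {
  stopifnot(inherits(sample, "semg_sample"))
  L <- ncol(sample$window)
  n_bins <- L %/% 2L + 1L
  spec <- Mod(stats::mvfft(t(sample$window)))[seq_len(n_bins), , drop = FALSE]
  feature_tensor(t(spec), "fft", sample)
}

#' Raw-signal image representation
#'
#' The sample as a single-channel L x C image (time x electrodes), the
#' time-domain input form.
#'
#' @param sample a `semg_sample`.
#' @return `semg_features` with `values` matrix L x C, `mode = "raw"`.
#' @export
raw_image <- function(sample) {
  stopifnot(inherits(sample, "semg_sample"))
  feature_tensor(t(sample$window), "raw", sample)
}

#' Sliding-window mean-absolute-value features
#'
#' Classical sEMG time-domain feature: per channel, the mean absolute value
#' over windows of `window_ms` advanced by `step_ms` (33 windows for the
#' default 200 ms / 25 ms on a 1 s sample at 1000 Hz). Although sometimes
#' printed without the modulus, MAV is by definition computed on `|x|`.
#'
#' @param sample a `semg_sample`.
#' @param window_ms window length in milliseconds.
#' @param step_ms window advance in milliseconds.
#' @return `semg_features` with `values` matrix C x W, `mode = "mav"`.
#' @export
mav_features <- function(sample, window_ms = 200, step_ms = 25) {
  stopifnot(inherits(sample, "semg_sample"))
  L <- ncol(sample$window)
  N <- round(window_ms * sample$fs / 1000)
  S <- round(step_ms * sample$fs / 1000)
  if (N > L) stop("mav_features: window longer than the sample")
  n_win <- (L - N) %/% S + 1L
  starts <- (seq_len(n_win) - 1L) * S
  absw <- abs(sample$window)
  vals <- vapply(starts, function(s) rowMeans(absw[, (s + 1):(s + N), drop = FALSE]),
                 numeric(nrow(absw)))
  vals <- matrix(vals, nrow = nrow(absw)) # C x W even for C = 1
  feature_tensor(vals, "mav", sample)
}

feature_tensor <- function(values, mode, sample) {
  structure(list(values = values, mode = mode, gesture = sample$gesture,
                 subject = sample$subject, fs = sample$fs),
            class = "semg_features")
}

#' @export
print.semg_features <- function(x, ...) {
  cat(sprintf("<semg_features mode=%s> dims [%s] | gesture %d, subject %d\n",
              x$mode, paste(dim2(x$values), collapse = " x "), x$gesture, x$subject))
  invisible(x)
}

dim2 <- function(v) if (is.null(dim(v))) length(v) else dim(v)

#' Featurize a list of samples
#'
#' @param samples list of `semg_sample` objects.
#' @param mode one of `"stft"`, `"fft"`, `"raw"`, `"mav"`.
#' @param cfg [stft_config()] used in `"stft"` mode.
#' @return list of `semg_features`.
#' @export
featurize_samples <- function(samples, mode = c("stft", "fft", "raw", "mav"),
                              cfg = stft_config()) {
  mode <- match.arg(mode)
  lapply(samples, function(s) switch(mode,
    stft = stft_spectrogram(s, cfg),
    fft = fft_spectrum(s),
    raw = raw_image(s),
    mav = mav_features(s)))
}

# model-input array (H, W, C) for one feature object:
# stft: H=freq bins, W=frames, C=channels; fft: H=channels, W=bins, C=1;
# raw: H=time, W=electrodes, C=1.
feature_hwc <- function(feat) {
  v <- feat$values
  switch(feat$mode,
    stft = aperm(v, c(2, 3, 1)),
    fft = array(v, c(dim(v), 1L)),
    raw = array(v, c(dim(v), 1L)),
    stop("feature mode '", feat$mode, "' is not a model input"))
}

# stack a list of features into an (H, W, C, B) batch array
feature_batch <- function(feats) {
  a1 <- feature_hwc(feats[[1]])
  d <- dim(a1)
  out <- array(0, c(d, length(feats)))
  out[, , , 1] <- a1
  if (length(feats) > 1)
    for (i in 2:length(feats)) out[, , , i] <- feature_hwc(feats[[i]])
  out
}
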