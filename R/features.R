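#' Symmetric Hamming window
#'
#' Window weights \eqn{w_n = 0.54 - 0.46 \cos(2\pi n / (N-1))}, n = 0..N-1.
#' Endpoints equal 0.08; an odd-length window peaks at exactly 1.
#'
#' @param N number of points (>= 2).
#' @return Numeric vector of N weights in \[0.08, 1\].
#' @export
hamming_window <- function(N) {
  if (!is.finite(N) || N < 2) stop("window needs at least 2 points", call. = FALSE)
  n <- seq.int(0L, N - 1L)
  0.54 - 0.46 * cos(2 * pi * n / (N - 1))
}

#' Window normalization constant U
#'
#' Mean squared window weight, \eqn{U = (1/L) \sum_n w_n^2}, which corrects
#' periodogram power for the taper (U = 1 for a rectangular window of ones).
#'
#' @param w window weights.
#' @param L segment length; must equal `length(w)`.
#' @return Positive scalar.
#' @export
window_normalization <- function(w, L = length(w)) {
  if (length(w) == 0L) stop("empty window", call. = FALSE)
  if (L != length(w)) stop("L must equal the window length", call. = FALSE)
  sum(w^2) / L
}

#' PSD estimation configuration
#'
#' Geometry of the per-chunk periodogram: a 250 ms chunk is split into
#' `n_windows` contiguous non-overlapping segments of `window_len` samples
#' (default 4 x 8 = 32 samples, i.e. 4 windows of 62.5 ms at 128 Hz), each
#' tapered by a Hamming window. `U` is precomputed from the window.
#'
#' @param n_windows segments per chunk (default 4).
#' @param window_len samples per segment (default 8).
#' @param fs sampling rate in Hz (default 128).
#' @return A `psd_config` list with `n_windows`, `window_len`, `fs`, `L`,
#'   `window` (the Hamming weights) and `U`.
#' @export
psd_config <- function(n_windows = 4L, window_len = 8L, fs = default_fs) {
  stopifnot(n_windows >= 1, window_len >= 2, fs > 0)
  w <- hamming_window(window_len)
  structure(list(n_windows = as.integer(n_windows),
                 window_len = as.integer(window_len),
                 fs = fs, L = as.integer(window_len),
                 window = w, U = window_normalization(w)),
            class = "psd_config")
}

#' Hamming-windowed periodogram of one segment
#'
#' Multiplies the segment by the Hamming taper, takes the L-point discrete
#' Fourier transform X(k), and returns the two-sided periodogram
#' \deqn{p_{xx}(k) = |X(k)|^2 / (F_s \, L \, U)}
#' for all L bins (power per unit frequency; with L = 8 at 128 Hz the bins
#' sit 16 Hz apart).
#'
#' @param segment numeric signal of exactly `cfg$window_len` samples.
#' @param cfg a [psd_config].
#' @return Numeric vector of `cfg$window_len` non-negative spectral values.
#' @export
periodogram <- function(segment, cfg = psd_config()) {
  stopifnot(inherits(cfg, "psd_config"))
  segment <- as.numeric(segment)
  if (length(segment) != cfg$window_len) {
    stop("segment length ", length(segment), " != window_len ", cfg$window_len,
         call. = FALSE)
  }
  X <- fft(segment * cfg$window)
  Mod(X)^2 / (cfg$fs * cfg$L * cfg$U)
}

#' Band power of one filtered channel chunk
#'
#' The per-channel feature of the decoder. A 32-sample chunk (already
#' band-passed to 8-30 Hz) is split into 4 contiguous 8-sample segments;
#' the Hamming periodogram of each is computed, the 8 bins are averaged
#' across segments, each averaged bin is divided by \eqn{2\pi} (the
#' decoder's scale convention), and the mean over bins is returned.
#'
#' @param x numeric signal of `cfg$n_windows * cfg$window_len` samples
#'   (default 32).
#' @param cfg a [psd_config].
#' @return Single non-negative band-power value (quadratic in signal
#'   amplitude).
#' @export
channel_band_power <- function(x, cfg = psd_config()) {
  stopifnot(inherits(cfg, "psd_config"))
  x <- as.numeric(x)
  n <- cfg$n_windows * cfg$window_len
  if (length(x) != n) {
    stop("chunk channel must have ", n, " samples, got ", length(x), call. = FALSE)
  }
  segs <- matrix(x, nrow = cfg$window_len)  # one segment per column
  pxx <- rowMeans(apply(segs, 2L, periodogram, cfg = cfg))
  mean(pxx / (2 * pi))
}

#' Extract the 14-value band-power feature vector from a chunk
#'
#' Per channel, applies the 8-30 Hz zero-phase band-pass
#' ([bandpass_8_30()]) and then [channel_band_power()], preserving the
#' canonical channel order. This is the feature vector F consumed by the
#' two-stage classifier.
#'
#' @param chunk a chunk from [stream_chunks()] (or any list with a 14 x 32
#'   `data` matrix).
#' @param cfg a [psd_config].
#' @param profile filter profile passed to [bandpass_8_30()].
#' @return Named numeric vector of 14 non-negative band powers, names =
#'   [emotiv_channels].
#' @export
extract_features <- function(chunk, cfg = psd_config(),
                             profile = c("embedded", "design")) {
  profile <- match.arg(profile)
  data <- chunk$data
  if (is.null(data)) data <- as.matrix(chunk)
  if (nrow(data) != length(emotiv_channels)) {
    stop("chunk must have ", length(emotiv_channels), " channels", call. = FALSE)
  }
  f <- apply(data, 1L, function(ch) {
    channel_band_power(bandpass_8_30(ch, profile = profile), cfg = cfg)
  })
  names(f) <- emotiv_channels
  f
}

#' Feature table over a set of trials
#'
#' Streams every trial as 250 ms chunks and extracts the band-power feature
#' vector of each, producing the flat table the classifier trains on (and
#' the CSV interchange format: one row per chunk with trial id, chunk
#' index, label, then 14 feature columns named by channel).
#'
#' @param trials list of [eeg_trial] objects.
#' @param cfg a [psd_config].
#' @param trial_ids identifiers, one per trial (default `trial_1`, ...).
#' @param profile filter profile passed to [bandpass_8_30()].
#' @return data.frame with columns `trial_id`, `chunk_index`, `label`, and
#'   one numeric column per channel.
#' @export
feature_table <- function(trials, cfg = psd_config(), trial_ids = NULL,
                          profile = c("embedded", "design")) {
  profile <- match.arg(profile)
  if (inherits(trials, "eeg_trial")) trials <- list(trials)
  if (is.null(trial_ids)) trial_ids <- sprintf("trial_%d", seq_along(trials))
  rows <- lapply(seq_along(trials), function(i) {
    chunks <- stream_chunks(trials[[i]], trial_id = trial_ids[[i]])
    feats <- t(vapply(chunks, extract_features, numeric(length(emotiv_channels)),
                      cfg = cfg, profile = profile))
    data.frame(trial_id = trial_ids[[i]],
               chunk_index = vapply(chunks, `[[`, 1L, "index"),
               label = trials[[i]]$label,
               feats, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname feature_table
#' @param features a feature table from `feature_table()`.
#' @param path CSV destination.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

# 14-column numeric matrix of features from a feature table
feature_matrix <- function(features) {
  as.matrix(features[, emotiv_channels, drop = FALSE])
}
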