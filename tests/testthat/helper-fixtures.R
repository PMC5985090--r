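# programmatic fixtures

make_trial <- function(n = 1280, label = "thumb", fs = 128, seed = 42,
                       category = "unknown") {
  set.seed(seed)
  data <- matrix(rnorm(14 * n, sd = 10), nrow = 14,
                 dimnames = list(emotiv_channels))
  eeg_trial(data, fs = fs, label = label, subject_category = category)
}

# one 14 x 32 chunk with an optional pure tone on a single channel
make_chunk <- function(tone_hz = NULL, channel = "F3", amp = 10,
                       noise_sd = 1, seed = 7) {
  set.seed(seed)
  data <- matrix(rnorm(14 * 32, sd = noise_sd), nrow = 14,
                 dimnames = list(emotiv_channels))
  if (!is.null(tone_hz)) {
    t <- (0:31) / 128
    data[channel, ] <- data[channel, ] + amp * sin(2 * pi * tone_hz * t)
  }
  list(data = data, trial_id = "fixture", index = 1L, label = "thumb")
}

# published confusion matrices of the two acquisition regimes (test sets)
category1_cm <- function() as_confusion_matrix(
  matrix(c(13, 12, 6, 8, 16, 7, 8, 9, 14), nrow = 3, byrow = TRUE))

category2_cm <- function() as_confusion_matrix(
  matrix(c(20, 9, 2, 4, 24, 3, 5, 5, 21), nrow = 3, byrow = TRUE))
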