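# Independent reference implementations used as test oracles. These stay
# deliberately naive (explicit loops, explicit sums) and never call the
# package's own code paths.

# Eq-style order-2 recursion, plain R loop
oracle_difference_equation <- function(x, b, a) {
  n <- length(x)
  y <- numeric(n)
  xp <- function(k) if (k >= 1) x[k] else 0
  yp <- function(k) if (k >= 1) y[k] else 0
  for (i in seq_len(n)) {
    y[i] <- (b[1] * xp(i) + b[2] * xp(i - 1) + b[3] * xp(i - 2) -
               a[2] * yp(i - 1) - a[3] * yp(i - 2)) / a[1]
  }
  y
}

# forward-backward filtering with odd-reflection padding, built on
# signal::filter (direct-form-II-transposed) as the independent filter core
oracle_filtfilt <- function(x, b, a, pad_len = 9L) {
  n <- length(x)
  left <- 2 * x[1] - x[(pad_len + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad_len)]
  ext <- c(left, x, right)
  fwd <- as.numeric(signal::filter(signal::Arma(b = b, a = a), ext))
  bwd <- rev(as.numeric(signal::filter(signal::Arma(b = b, a = a), rev(fwd))))
  bwd[(pad_len + 1):(pad_len + n)]
}

# straight-line band power of one 32-sample channel: Hamming weights by
# formula, DFT by explicit double sum, periodogram scaling, window
# averaging, 2*pi scaling, mean over bins
oracle_band_power <- function(x, fs = 128) {
  L <- 8L
  w <- sapply(0:(L - 1), function(n) 0.54 - 0.46 * cos(2 * pi * n / (L - 1)))
  U <- sum(w^2) / L
  pxx_sum <- numeric(L)
  for (seg in 1:4) {
    s <- x[((seg - 1) * L + 1):(seg * L)] * w
    X <- sapply(0:(L - 1), function(k) {
      sum(s * exp(-1i * 2 * pi * k * (0:(L - 1)) / L))
    })
    pxx_sum <- pxx_sum + Mod(X)^2 / (fs * L * U)
  }
  mean((pxx_sum / 4) / (2 * pi))
}

# straight-line full feature extraction (band-pass by oracle_filtfilt with
# the shipped 4-decimal constants, then oracle_band_power per channel)
oracle_extract_features <- function(chunk_data) {
  b_hp <- c(0.7571, -1.5142, 0.7571); a_hp <- c(1, -1.4542, 0.5741)
  b_lp <- c(0.2647, 0.5294, 0.2647); a_lp <- c(1, -0.1151, 0.1739)
  apply(chunk_data, 1, function(ch) {
    y <- oracle_filtfilt(oracle_filtfilt(ch, b_hp, a_hp), b_lp, a_lp)
    oracle_band_power(y)
  })
}

oracle_sigmoid <- function(B, f) {
  z <- sum(B * c(1, f))
  exp(z) / (exp(z) + 1)
}

oracle_confusion_count <- function(true, pred, classes) {
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(classes, classes))
  for (i in seq_along(true)) {
    cm[true[i], pred[i]] <- cm[true[i], pred[i]] + 1L
  }
  cm
}
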