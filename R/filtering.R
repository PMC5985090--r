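#' Design an order-2 digital Butterworth filter
#'
#' Designs the second-order high-pass or low-pass digital Butterworth filter
#' by bilinear transform of the analog prototype \eqn{s^2 + \sqrt{2} s + 1}
#' with frequency prewarping, normalised so the leading denominator
#' coefficient is 1. At (order 2, 8 Hz, 128 Hz, high-pass) and (order 2,
#' 30 Hz, 128 Hz, low-pass) this reproduces, to 4 decimals, the Matlab
#' `butter` coefficients the embedded decoder ships as constants (see
#' [butter_table_coefficients()]).
#'
#' @param order filter order; only 2 is supported (the pipeline's order).
#' @param cutoff_hz -3 dB cutoff frequency in Hz, strictly between 0 and
#'   `fs/2`.
#' @param fs sampling rate in Hz.
#' @param kind `"highpass"` or `"lowpass"`.
#' @return A `filter_coefficients` object: list with numerator triple `b`,
#'   denominator triple `a` (a\[1\] = 1), and the design metadata `kind`,
#'   `cutoff_hz`, `fs`, `order`.
#' @examples
#' design_butterworth(2, 8, 128, "highpass")
#' @export
design_butterworth <- function(order, cutoff_hz, fs, kind = c("highpass", "lowpass")) {
  kind <- match.arg(kind)
  if (!identical(as.integer(order), 2L)) {
    stop("unsupported order: only order-2 sections are implemented", call. = FALSE)
  }
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must satisfy 0 < cutoff_hz < fs/2 (Nyquist)", call. = FALSE)
  }
  # prewarped analog cutoff folded into K = tan(pi * fc / fs); bilinear
  # transform of 1/(s^2 + sqrt(2) s + 1) with s -> s/wc (LP) or wc/s (HP)
  K <- tan(pi * cutoff_hz / fs)
  K2 <- K * K
  norm <- 1 + sqrt(2) * K + K2
  a <- c(1, 2 * (K2 - 1) / norm, (1 - sqrt(2) * K + K2) / norm)
  b <- if (kind == "lowpass") {
    c(K2, 2 * K2, K2) / norm
  } else {
    c(1, -2, 1) / norm
  }
  filter_coefficients(b, a, kind = kind, cutoff_hz = cutoff_hz, fs = fs)
}

#' @rdname design_butterworth
#' @param b,a numeric coefficient triples; `a` is normalised so `a[1] = 1`.
#' @export
filter_coefficients <- function(b, a, kind = c("highpass", "lowpass"),
                                cutoff_hz = NA_real_, fs = NA_real_) {
  kind <- match.arg(kind)
  b <- as.numeric(b); a <- as.numeric(a)
  if (length(b) != 3L || length(a) != 3L) {
    stop("order-2 section requires coefficient triples", call. = FALSE)
  }
  if (!all(is.finite(b)) || !all(is.finite(a)) || a[1] == 0) {
    stop("coefficients must be finite with a[1] != 0", call. = FALSE)
  }
  b <- b / a[1]; a <- a / a[1]
  # poles are roots of z^2 + a2 z + a3
  if (any(Mod(polyroot(c(a[3], a[2], 1))) >= 1)) {
    stop("unstable filter: poles on or outside the unit circle", call. = FALSE)
  }
  structure(list(b = b, a = a, kind = kind, cutoff_hz = cutoff_hz, fs = fs,
                 order = 2L),
            class = "filter_coefficients")
}

#' @export
print.filter_coefficients <- function(x, ...) {
  cat(sprintf("<filter_coefficients> order-2 %s, cutoff %g Hz @ fs %g Hz\n",
              x$kind, x$cutoff_hz, x$fs))
  cat("  b:", paste(formatC(x$b, digits = 6, format = "g"), collapse = ", "), "\n")
  cat("  a:", paste(formatC(x$a, digits = 6, format = "g"), collapse = ", "), "\n")
  invisible(x)
}

#' The embedded decoder's shipped filter constants
#'
#' The 4-decimal order-2 Butterworth coefficients burned into the embedded
#' implementation: high-pass at 8 Hz and low-pass at 30 Hz, both for 128 Hz
#' sampling. [design_butterworth()] rederives them; this accessor returns
#' the rounded constants the "embedded" profile uses.
#'
#' @param kind `"highpass"` (8 Hz) or `"lowpass"` (30 Hz).
#' @return A `filter_coefficients` object.
#' @export
butter_table_coefficients <- function(kind = c("highpass", "lowpass")) {
  kind <- match.arg(kind)
  if (kind == "highpass") {
    filter_coefficients(b = c(0.7571, -1.5142, 0.7571),
                        a = c(1, -1.4542, 0.5741),
                        kind = "highpass", cutoff_hz = 8, fs = 128)
  } else {
    filter_coefficients(b = c(0.2647, 0.5294, 0.2647),
                        a = c(1, -0.1151, 0.1739),
                        kind = "lowpass", cutoff_hz = 30, fs = 128)
  }
}

#' Apply the IIR difference equation
#'
#' Runs the second-order recursion
#' \deqn{a_1 y_n = b_1 x_n + b_2 x_{n-1} + b_3 x_{n-2} - a_2 y_{n-1} - a_3 y_{n-2}}
#' sample by sample with zero initial conditions (x and y taken as 0 before
#' the first sample). Single forward pass; no padding.
#'
#' @param x numeric signal, length >= 1.
#' @param coef a `filter_coefficients` object.
#' @return Filtered signal, same length as `x`.
#' @export
apply_difference_equation <- function(x, coef) {
  stopifnot(inherits(coef, "filter_coefficients"))
  x <- as.numeric(x)
  if (length(x) < 1L) stop("empty signal", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  diff_eq_order2(x, coef$b, coef$a)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies [apply_difference_equation()] forward and then backward so phase
#' distortion cancels and the effective magnitude response is the square of
#' the single-pass response. Before filtering, the signal is extended at
#' each end by odd (antisymmetric) reflection of `pad_len` samples — the
#' standard transient-absorbing extension for forward-backward IIR
#' filtering — and truncated back to its original length afterwards.
#'
#' @param x numeric signal; must be longer than `pad_len`.
#' @param coef a `filter_coefficients` object.
#' @param pad_len samples reflected at each end; default `3 * (order + 1)`
#'   = 9.
#' @return Zero-phase filtered signal, same length as `x`.
#' @export
zero_phase_filter <- function(x, coef, pad_len = 3L * (2L + 1L)) {
  stopifnot(inherits(coef, "filter_coefficients"))
  x <- as.numeric(x)
  n <- length(x)
  if (n <= pad_len) {
    stop("signal too short to pad: need more than ", pad_len, " samples, got ",
         n, call. = FALSE)
  }
  left <- 2 * x[1L] - x[(pad_len + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad_len)]
  ext <- c(left, x, right)
  y <- apply_difference_equation(ext, coef)
  y <- rev(apply_difference_equation(rev(y), coef))
  y[(pad_len + 1L):(pad_len + n)]
}

#' Mu/Beta band-pass: 8-30 Hz
#'
#' The pipeline's band limiter: zero-phase high-pass at 8 Hz followed by
#' zero-phase low-pass at 30 Hz, retaining the sensorimotor Mu and Beta
#' rhythms. The `"embedded"` profile (default) uses the shipped 4-decimal
#' constants; the `"design"` profile rederives full-precision coefficients
#' with [design_butterworth()].
#'
#' @param x numeric signal (length > 9).
#' @param profile `"embedded"` (table constants) or `"design"`.
#' @return Band-pass filtered signal, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 128)
#' y <- bandpass_8_30(sin(2 * pi * 15 * t))  # in-band tone passes
#' @export
bandpass_8_30 <- function(x, profile = c("embedded", "design")) {
  profile <- match.arg(profile)
  if (profile == "embedded") {
    hp <- butter_table_coefficients("highpass")
    lp <- butter_table_coefficients("lowpass")
  } else {
    hp <- design_butterworth(2, 8, 128, "highpass")
    lp <- design_butterworth(2, 30, 128, "lowpass")
  }
  zero_phase_filter(zero_phase_filter(x, hp), lp)
}

#' Magnitude response of an order-2 section
#'
#' Single-pass magnitude \eqn{|H(e^{i 2 \pi f / f_s})|} of a coefficient
#' set; the zero-phase cascade realises the square of this.
#'
#' @param coef a `filter_coefficients` object.
#' @param freq_hz frequencies at which to evaluate, in Hz.
#' @param fs sampling rate; defaults to the design rate stored in `coef`.
#' @return Numeric vector of magnitudes.
#' @export
filter_magnitude <- function(coef, freq_hz, fs = coef$fs) {
  stopifnot(inherits(coef, "filter_coefficients"), is.finite(fs))
  w <- 2 * pi * freq_hz / fs
  z1 <- exp(-1i * w)
  num <- coef$b[1] + coef$b[2] * z1 + coef$b[3] * z1^2
  den <- coef$a[1] + coef$a[2] * z1 + coef$a[3] * z1^2
  Mod(num / den)
}

#' Filter coefficient JSON interchange
#'
#' Coefficients travel between tools as a small JSON document with fields
#' `kind`, `cutoff_hz`, `fs`, `order`, `b`, `a`.
#'
#' @param coef a `filter_coefficients` object.
#' @param path JSON file path.
#' @return `write_filter_json()` returns `path` invisibly;
#'   `read_filter_json()` the reconstructed `filter_coefficients`.
#' @export
write_filter_json <- function(coef, path) {
  stopifnot(inherits(coef, "filter_coefficients"))
  jsonlite::write_json(
    list(kind = coef$kind, cutoff_hz = coef$cutoff_hz, fs = coef$fs,
         order = coef$order, b = coef$b, a = coef$a),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_json
#' @export
read_filter_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_coefficients(doc$b, doc$a, kind = doc$kind,
                      cutoff_hz = as.numeric(doc$cutoff_hz),
                      fs = as.numeric(doc$fs))
}
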