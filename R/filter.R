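#' Design a digital Butterworth bandpass filter (second-order sections)
#'
#' Classic bilinear-transform design: analog lowpass Butterworth prototype,
#' lowpass-to-bandpass transform with pre-warped edges, bilinear mapping to
#' the z-plane. The 2n poles are paired into n biquad sections, each with one
#' zero at z = 1 and one at z = -1; the overall gain is normalized so the
#' magnitude response equals 1 at the geometric mean of the band edges.
#'
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param fs sampling rate in Hz.
#' @param order prototype order n (the bandpass filter has 2n poles;
#'   default 4).
#' @return a matrix with n rows and columns b0 b1 b2 a0 a1 a2, class
#'   `butter_sos` with attributes `fs`, `band`, `order`.
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (low <= 0 || high >= fs / 2 || low >= high)
    input_error("butter_bandpass",
                "band edges must satisfy 0 < low < high < fs/2 (got %g, %g at fs %g)",
                low, high, fs)
  n <- as.integer(order)
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)    # pre-warped analog edges (rad/s)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # prototype poles, Re < 0
  # lowpass -> bandpass: each prototype pole maps to a conjugate-free pair
  a <- bw * p_lp / 2
  root <- sqrt(a^2 - w0^2)
  p_bp <- c(a + root, a - root)                      # 2n analog poles
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)                 # bilinear transform
  # z_p holds all 2n digital poles, closed under conjugation. Each complex
  # conjugate pair gives one biquad denominator; real poles (possible for
  # extreme bands) are paired with each other in sorted order.
  cplx <- z_p[Im(z_p) > 1e-12]
  reals <- sort(Re(z_p[abs(Im(z_p)) <= 1e-12]))
  den <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(reals) >= 2)
    for (j in seq(1, length(reals) - 1, by = 2)) {
      p1 <- reals[j]; p2 <- reals[j + 1]
      den <- c(den, list(c(1, -(p1 + p2), p1 * p2)))
    }
  if (length(den) != n)
    input_error("butter_bandpass", "internal pole-pairing failure")
  sos <- matrix(0, n, 6, dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(n))
    sos[i, ] <- c(1, 0, -1, den[[i]])  # zeros at +1 and -1

  g <- Mod(sos_response(sos, sqrt(low * high), fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  structure(sos, class = c("butter_sos", "matrix"),
            fs = fs, band = c(low, high), order = n)
}

#' Frequency response of a second-order-section cascade
#'
#' Evaluates the cascade transfer function at `freq` Hz. This is the
#' independent oracle used to bound stopband attenuation in the tests: the
#' zero-phase (forward-backward) magnitude response is `Mod(H)^2`.
#'
#' @param sos an SOS matrix as returned by [butter_bandpass()].
#' @param freq frequencies in Hz (vectorized).
#' @param fs sampling rate in Hz; defaults to the design rate stored on `sos`.
#' @return complex response values.
#' @export
sos_response <- function(sos, freq, fs = attr(sos, "fs")) {
  z <- exp(-1i * 2 * pi * freq / fs)
  h <- rep(1 + 0i, length(freq))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z + sos[i, 3] * z^2
    den <- sos[i, 4] + sos[i, 5] * z + sos[i, 6] * z^2
    h <- h * num / den
  }
  h
}

# Zero-phase filtering of one numeric vector: odd-reflection padding, forward
# pass, backward pass, unpad. padlen chosen long relative to the filter's
# transient at EEG band edges.
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  padlen <- min(n - 1L, 512L)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  y <- cpp_sosfilt(ext, unclass(sos))
  y <- rev(cpp_sosfilt(rev(y), unclass(sos)))
  y[(padlen + 1L):(padlen + n)]
}

#' Zero-phase bandpass filter
#'
#' Applies a Butterworth bandpass forward and backward (zero phase, squared
#' magnitude response) independently to each channel. Methods exist for bare
#' numeric vectors/matrices, single recordings and recording sets.
#'
#' @param x a numeric vector, channels-by-time matrix, `eeg_recording`, or
#'   `recording_set`.
#' @param low,high band edges in Hz (defaults 8 and 40).
#' @param fs sampling rate in Hz (taken from the recording when present).
#' @param order Butterworth prototype order (default 4).
#' @return an object of the same shape/class as `x`, filtered.
#' @export
bandpass <- function(x, low = 8, high = 40, fs = NULL, order = 4) {
  UseMethod("bandpass")
}

#' @export
bandpass.numeric <- function(x, low = 8, high = 40, fs = NULL, order = 4) {
  if (is.null(fs)) input_error("bandpass", "fs is required for bare numeric input")
  sos <- butter_bandpass(low, high, fs, order)
  sos_filtfilt(x, sos)
}

#' @export
bandpass.matrix <- function(x, low = 8, high = 40, fs = NULL, order = 4) {
  if (is.null(fs)) input_error("bandpass", "fs is required for bare matrix input")
  sos <- butter_bandpass(low, high, fs, order)
  t(apply(x, 1, sos_filtfilt, sos = sos))
}

#' @export
bandpass.eeg_recording <- function(x, low = 8, high = 40, fs = NULL, order = 4) {
  sos <- butter_bandpass(low, high, x$fs, order)
  x$samples <- t(apply(x$samples, 1, sos_filtfilt, sos = sos))
  rownames(x$samples) <- x$channel_labels
  x
}

#' @export
bandpass.recording_set <- function(x, low = 8, high = 40, fs = NULL, order = 4) {
  x$recordings <- lapply(x$recordings, bandpass, low = low, high = high, order = order)
  x
}
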