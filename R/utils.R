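#' Deterministic 31-bit hash of a character key
#'
#' Used to derive independent per-recording seeds from a master seed plus
#' identifying metadata, so any single recording can be regenerated in
#' isolation. Polynomial rolling hash modulo 2^31 - 1.
#'
#' @param ... components pasted into the key (coerced to character).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
hash_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  h <- 7
  m <- 2147483647
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  as.integer(h + 1L)
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# stop() with a consistent labelled-error prefix so callers/tests can match
# the failing contract by name.
input_error <- function(label, ...) {
  stop(sprintf("[%s] %s", label, sprintf(...)), call. = FALSE)
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, 50\%-overlap averaged periodogram. Used by the synthetic
#' generator's tests and the band-power baseline; intentionally independent of
#' the CNN code path.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples (default 1024, capped at
#'   `length(x)`).
#' @return list with `freq` (Hz) and `psd` (power density, unit^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / nperseg)
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(fft(seg))^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  nf <- floor(nperseg / 2) + 1L
  psd <- psd[seq_len(nf)]
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- seq_len(nf) > 1L
  if (nperseg %% 2 == 0) dbl[nf] <- FALSE
  psd[dbl] <- 2 * psd[dbl]
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Mean band power of a signal
#'
#' Integrates the Welch PSD over `[low, high]` Hz.
#'
#' @inheritParams welch_psd
#' @param low,high band edges in Hz.
#' @return scalar power.
#' @export
band_power <- function(x, fs, low, high, nperseg = 1024) {
  p <- welch_psd(x, fs, nperseg)
  sel <- p$freq >= low & p$freq <= high
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[sel]) * df
}
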