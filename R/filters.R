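## Zero-phase Butterworth filtering and Hilbert envelopes.
##
## Zero-phase filtering is defined by the squared-magnitude response of a
## 4th-order digital Butterworth bandpass (the steady-state response of
## forward-backward filtering).  The default implementation applies that
## response in the frequency domain, which is exactly zero-phase and lets the
## analytic signal be obtained in the same FFT pass; "filtfilt" delegates to
## signal::filtfilt.  The two agree away from the epoch edges, which are
## excluded from all statistics by the edge mask.

# |H(e^{i w})|^2 of a Butterworth bandpass at the n FFT bin frequencies
.butterResponse2 <- function(lo, hi, sfreq, n, order = 4) {
  nyq <- sfreq / 2
  if (lo <= 0 || hi >= nyq)
    stop("band (", lo, ", ", hi, ") Hz must lie strictly inside (0, ",
         nyq, ") Hz (the Nyquist frequency)")
  flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  ew <- exp(complex(imaginary = -w))
  num <- 0+0i; den <- 0+0i; p <- rep(1+0i, n)
  nb <- length(flt$b); na <- length(flt$a)
  for (k in seq_len(max(nb, na))) {
    if (k <= nb) num <- num + flt$b[k] * p
    if (k <= na) den <- den + flt$a[k] * p
    p <- p * ew
  }
  Mod(num / den)^2
}

# analytic-signal spectrum multiplier of length n
.analyticMask <- function(n) {
  m <- numeric(n)
  if (n %% 2 == 0) {
    m[1] <- 1; m[n / 2 + 1] <- 1
    m[2:(n / 2)] <- 2
  } else {
    m[1] <- 1
    m[2:((n + 1) / 2)] <- 2
  }
  m
}

#' Zero-phase Butterworth bandpass
#'
#' Applies a 4th-order Butterworth bandpass with zero phase shift.  The
#' default method applies the forward-backward (squared-magnitude) response
#' of the filter in the frequency domain; `"filtfilt"` runs
#' [signal::filtfilt()] per series.  Both are zero-phase; they differ only in
#' edge transients, which downstream statistics exclude.
#'
#' @param x numeric vector, or matrix with time in rows (each column one
#'   series).
#' @param lo,hi band edges, Hz; must lie strictly inside (0, sfreq/2).
#' @param sfreq sampling rate, Hz.
#' @param order filter order (of the one-pass prototype).
#' @param method "fft" or "filtfilt".
#' @return filtered data with the shape of `x`.
#' @export
zeroPhaseBandpass <- function(x, lo, hi, sfreq, order = 4,
                              method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (method == "fft") {
    n <- nrow(X)
    r2 <- .butterResponse2(lo, hi, sfreq, n, order)
    out <- Re(mvfft(mvfft(X) * r2, inverse = TRUE)) / n
  } else {
    nyq <- sfreq / 2
    if (lo <= 0 || hi >= nyq)
      stop("band (", lo, ", ", hi, ") Hz must lie strictly inside (0, ",
           nyq, ") Hz (the Nyquist frequency)")
    flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
    out <- apply(X, 2, function(col) signal::filtfilt(flt, col))
  }
  if (vec) drop(out) else out
}

#' Hilbert envelope in a narrow band
#'
#' Zero-phase Butterworth bandpass of width `bandwidth` centred at `center`,
#' followed by the magnitude of the analytic signal: the instantaneous
#' amplitude of the band-limited oscillation.
#'
#' @param ts single-trial time series (numeric vector).
#' @param center centre frequency, Hz.
#' @param bandwidth filter bandwidth, Hz (the band is centre +/- bandwidth/2).
#' @param sfreq sampling rate, Hz.
#' @param order Butterworth order.
#' @return envelope time series, same length as `ts`.
#' @examples
#' sf <- 600; t <- seq(0, 2, by = 1 / sf)
#' env <- hilbertEnvelope(3 * sin(2 * pi * 55 * t), 55, 8, sf)
#' mean(env[200:1000]) # ~3
#' @export
hilbertEnvelope <- function(ts, center, bandwidth = 8, sfreq, order = 4) {
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  n <- length(ts)
  r2 <- .butterResponse2(lo, hi, sfreq, n, order)
  Mod(fft(fft(ts) * r2 * .analyticMask(n), inverse = TRUE)) / n
}

# envelopes of all columns of X (time x K) at many centre frequencies;
# returns array (K, nfreq, ntime)
.bandEnvelopes <- function(X, centers, bandwidth, sfreq, order = 4) {
  n <- nrow(X); K <- ncol(X); nf <- length(centers)
  Fx <- mvfft(X)
  msk <- .analyticMask(n)
  out <- array(0, dim = c(K, nf, n))
  for (ci in seq_len(nf)) {
    r2 <- .butterResponse2(centers[ci] - bandwidth / 2,
                           centers[ci] + bandwidth / 2, sfreq, n, order)
    E <- Mod(mvfft(Fx * (r2 * msk), inverse = TRUE)) / n   # time x K
    out[, ci, ] <- t(E)
  }
  out
}
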