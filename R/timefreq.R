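## Hilbert-envelope time-frequency analysis of the virtual sensor.
##
## Per trial, the series is bandpass-filtered (zero-phase Butterworth, 8 Hz
## bandwidth) at 121 centre frequencies 30, 30.5, ..., 90 Hz and the
## magnitude of the analytic signal taken; per-trial envelopes are
## normalised to percent change from that trial's own baseline mean and
## averaged over trials (an induced measure: phase alignment across trials
## is never required).  Samples within `edgePad` of the epoch edges carry
## filter/Hilbert transients and are excluded from statistics.

#' Per-trial envelope spectrograms
#'
#' @param vs a [VirtualSensor-class].
#' @param cfg an [AnalysisConfig-class].
#' @return a [TrialSpectrograms-class] (trial x frequency x time raw
#'   envelope, with the epoch-edge mask).
#' @export
trialSpectrograms <- function(vs, cfg) {
  centers <- tfFrequencyGrid(cfg)
  if (centers[length(centers)] + cfg@tfBandwidth / 2 >= vs@sfreq / 2)
    stop("top analysis band exceeds the Nyquist frequency")
  vals <- .bandEnvelopes(t(vs@data), centers, cfg@tfBandwidth, vs@sfreq,
                         order = cfg@tfFilterOrder)
  tt <- vs@times
  edgeOK <- tt >= tt[1] + cfg@edgePad & tt <= tt[length(tt)] - cfg@edgePad
  new("TrialSpectrograms", values = vals, freqs = centers, times = tt,
      edgeOK = edgeOK)
}

# per-trial percent-change maps as a (freq*time-in-sel, trial) matrix;
# rows ordered time-fastest within frequency so that which.max ties break
# by lower frequency first, then earlier time
.pctMatrix <- function(tmaps, baselineWindow, timeSel) {
  d <- dim(tmaps@values)
  bidx <- .windowIdx(tmaps@times, baselineWindow, keep = tmaps@edgeOK)
  ntr <- d[1]; nf <- d[2]
  base <- apply(tmaps@values[, , bidx, drop = FALSE], c(1, 2), mean)
  mx <- max(tmaps@values)
  if (any(base < 1e-15 * mx))
    stop("near-zero baseline envelope; percent change undefined")
  nt <- length(timeSel)
  out <- matrix(0, nt * nf, ntr)
  for (tr in seq_len(ntr)) {
    env <- tmaps@values[tr, , timeSel, drop = FALSE]   # 1 x nf x nt
    pct <- 100 * (matrix(env, nf, nt) / base[tr, ] - 1)
    out[, tr] <- as.vector(t(pct))                     # time-fastest per freq
  }
  out
}

#' Induced percent-change map
#'
#' Per trial and frequency, the envelope is expressed as percent change
#' from that trial's mean baseline envelope; the induced map is the mean of
#' the per-trial maps.
#'
#' @param tmaps a [TrialSpectrograms-class].
#' @param baselineWindow `c(lo, hi)` baseline window, s.
#' @return a [TFMap-class] of kind "induced".
#' @export
inducedPercentChange <- function(tmaps, baselineWindow = c(-1.5, 0)) {
  d <- dim(tmaps@values)
  M <- .pctMatrix(tmaps, baselineWindow, seq_along(tmaps@times))
  avg <- rowMeans(M)
  nf <- d[2]; nt <- d[3]
  vals <- t(matrix(avg, nt, nf))                       # freq x time
  new("TFMap", values = vals, freqs = tmaps@freqs, times = tmaps@times,
      edgeOK = tmaps@edgeOK, kind = "induced")
}

#' Extract the gamma peak from an induced map
#'
#' Arg-max of the induced percent change over the band x window rectangle
#' (edge-masked samples excluded).  Ties break deterministically: lower
#' frequency first, then earlier time.
#'
#' @param induced an induced [TFMap-class].
#' @param window `c(lo, hi)` extraction window, s.
#' @param band `c(lo, hi)` frequency range, Hz.
#' @return a [GammaPeak-class].
#' @export
extractGammaPeak <- function(induced, window = c(0, 0.3), band = c(30, 90)) {
  tidx <- .windowIdx(induced@times, window, keep = induced@edgeOK)
  fidx <- which(induced@freqs >= band[1] - 1e-9 & induced@freqs <= band[2] + 1e-9)
  sub <- induced@values[fidx, tidx, drop = FALSE]
  if (all(is.na(sub))) stop("no finite values in the extraction window")
  flat <- as.vector(t(sub))                            # time-fastest per freq
  j <- which.max(flat)
  nt <- length(tidx)
  fi <- (j - 1) %/% nt + 1
  ti <- (j - 1) %% nt + 1
  new("GammaPeak", frequency = induced@freqs[fidx[fi]], amplitude = flat[j],
      latency = induced@times[tidx[ti]], window = as.numeric(window))
}

#' Window-averaged spectrum as percent change from baseline
#'
#' Per trial and frequency bin, the envelope is averaged over the active
#' window and over the baseline window; the percent change of the former
#' from the latter is computed per trial and then averaged over trials.
#'
#' @param tmaps a [TrialSpectrograms-class].
#' @param activeWindow `c(lo, hi)` active window, s.
#' @param baselineWindow `c(lo, hi)` baseline window, s.
#' @return a [SpectrumSummary-class].
#' @export
windowSpectrum <- function(tmaps, activeWindow, baselineWindow = c(-1.5, 0)) {
  aidx <- .windowIdx(tmaps@times, activeWindow, keep = tmaps@edgeOK)
  bidx <- .windowIdx(tmaps@times, baselineWindow, keep = tmaps@edgeOK)
  act <- apply(tmaps@values[, , aidx, drop = FALSE], c(1, 2), mean)
  base <- apply(tmaps@values[, , bidx, drop = FALSE], c(1, 2), mean)
  if (any(base <= 1e-15 * max(tmaps@values)))
    stop("near-zero baseline envelope; percent change undefined")
  pct <- colMeans(100 * (act / base - 1))
  new("SpectrumSummary", freqs = tmaps@freqs, pctChange = pct,
      activeWindow = as.numeric(activeWindow),
      baselineWindow = as.numeric(baselineWindow))
}
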