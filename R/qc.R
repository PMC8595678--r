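## Bootstrap reliability gate for the subject-level gamma peak.
##
## Trials are resampled with replacement B times; for each resample the
## induced percent-change map is recomputed and the gamma peak re-extracted.
## Because filtering and baseline normalisation are per-trial operations,
## resampling the precomputed per-trial maps is mathematically identical to
## re-running the whole chain per resample.  A subject passes when (a) a
## 4 Hz-wide window holds at least half of the bootstrap peak frequencies
## and (b) the bootstrap amplitude z-score (mean/sd of the peak amplitudes)
## is at least 2.

#' Bootstrap distribution of the gamma peak
#'
#' @param tmaps a [TrialSpectrograms-class].
#' @param cfg an [AnalysisConfig-class]; `bootstrapB`, `baselineWindow` and
#'   the peak-extraction window are taken from it.
#' @param seed RNG seed (defaults to `cfg@seed`).
#' @param window peak-extraction window, s (default: the spike window).
#' @param B number of resamples (defaults to `cfg@bootstrapB`).
#' @return a [BootstrapDistribution-class].
#' @export
bootstrapPeaks <- function(tmaps, cfg, seed = cfg@seed,
                           window = cfg@spikeWindow, B = cfg@bootstrapB) {
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1")
  ntr <- dim(tmaps@values)[1]
  if (ntr < 2L) stop("need at least 2 trials to bootstrap")
  tidx <- .windowIdx(tmaps@times, window, keep = tmaps@edgeOK)
  M <- .pctMatrix(tmaps, cfg@baselineWindow, tidx)   # (time|freq) x trial
  nt <- length(tidx)
  nf <- length(tmaps@freqs)
  set.seed(seed)
  counts <- matrix(0, ntr, B)
  for (b in seq_len(B))
    counts[, b] <- tabulate(sample.int(ntr, ntr, replace = TRUE), ntr)
  boot <- M %*% counts / ntr                          # resampled induced maps
  j <- apply(boot, 2, which.max)                      # ties: low freq, early time
  fi <- (j - 1) %/% nt + 1
  new("BootstrapDistribution",
      peakFreqs = tmaps@freqs[fi],
      peakAmps = boot[cbind(j, seq_len(B))],
      B = B, seed = as.integer(seed))
}

#' Evaluate the reliability criteria
#'
#' The distribution mode is operationalised as the centre (on the 0.5 Hz
#' analysis grid) of the `2*qcHalfwidth`-wide window holding the largest
#' fraction of bootstrap peak frequencies; `coverage` is that fraction.
#' `ampZ` is mean/sd of the bootstrap peak amplitudes.  A zero-spread
#' amplitude distribution with positive mean is maximally reliable
#' (z = +Inf, pass); with non-positive mean it fails.
#'
#' @param dist a [BootstrapDistribution-class].
#' @param cfg an [AnalysisConfig-class].
#' @return a [QCResult-class].
#' @export
qcEvaluate <- function(dist, cfg) {
  grid <- tfFrequencyGrid(cfg)
  hw <- cfg@qcHalfwidth
  frac <- vapply(grid, function(cc)
    mean(dist@peakFreqs >= cc - hw - 1e-9 & dist@peakFreqs <= cc + hw + 1e-9),
    numeric(1))
  best <- which.max(frac)                             # tie: lowest centre
  coverage <- frac[best]
  m <- mean(dist@peakAmps)
  s <- stats::sd(dist@peakAmps)
  if (is.na(s)) s <- 0                               # B = 1: no spread
  ampZ <- if (s == 0) (if (m > 0) Inf else -Inf) else m / s
  passCov <- coverage >= cfg@qcCoverage
  passZ <- ampZ >= cfg@qcZmin
  new("QCResult", modeFreq = grid[best], coverage = coverage, ampZ = ampZ,
      passCoverage = passCov, passZ = passZ, pass = passCov && passZ)
}
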