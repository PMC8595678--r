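## Nonparametric group contrasts.
##
## Groups are independent samples (low-risk vs high-risk subjects), so the
## two-sample Wilcoxon rank-sum (Mann-Whitney) statistic is used at every
## (frequency, time) point or frequency bin, as a z with tie-corrected
## normal approximation and no continuity correction.  Multiple comparisons
## are handled by Benjamini-Hochberg adjustment; significance is
## adjusted-p < pThreshold.  Effect sizes are Cohen's d with pooled SD.
## Positive z / positive d always mean group A (low risk) exceeds group B.

# rank-sum z and two-sided p per column of a pooled (nA+nB) x m matrix
.rankSumZ <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B); N <- nA + nB
  pooled <- rbind(A, B)
  m <- ncol(pooled)
  z <- numeric(m); p <- rep(1, m)
  for (j in seq_len(m)) {
    r <- rank(pooled[, j])
    W <- sum(r[seq_len(nA)])
    mu <- nA * (N + 1) / 2
    tj <- table(pooled[, j])
    tie <- sum(tj^3 - tj)
    s2 <- nA * nB / 12 * ((N + 1) - tie / (N * (N - 1)))
    if (s2 <= 0) { z[j] <- 0; p[j] <- 1; next }
    z[j] <- (W - mu) / sqrt(s2)
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  list(z = z, p = p)
}

#' Rank-sum z/p map over matched subject maps
#'
#' At every point of a common grid, the two-sample rank-sum statistic
#' across subjects.  z > 0 means group A (low risk) exceeds group B.
#'
#' @param groupA,groupB lists of equally shaped matrices (or vectors), one
#'   per subject.
#' @return list of `z` and `pRaw` arrays shaped like the inputs.
#' @export
rankSumMap <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("need at least 2 subjects per group")
  shp <- dim(groupA[[1]])
  npt <- if (is.null(shp)) length(groupA[[1]]) else prod(shp)
  flat <- function(g) {
    m <- vapply(g, as.numeric, numeric(npt))
    if (is.null(dim(m))) matrix(m, ncol = 1) else t(m)
  }
  rs <- .rankSumZ(flat(groupA), flat(groupB))
  reshape <- function(v) if (is.null(shp)) v else array(v, shp)
  list(z = reshape(rs$z), pRaw = reshape(rs$p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone-enforced); the rejection mask is
#' adjusted-p < `pThreshold`.
#'
#' @param pRaw raw p-values (any shape).
#' @param pThreshold threshold on the adjusted p-values.
#' @return list of `pAdj` and `reject`, shaped like `pRaw`.
#' @export
fdrBH <- function(pRaw, pThreshold = 0.05) {
  if (length(pRaw) == 0) return(list(pAdj = pRaw, reject = logical(0)))
  adj <- stats::p.adjust(as.numeric(pRaw), method = "BH")
  dim(adj) <- dim(pRaw)
  list(pAdj = adj, reject = adj < pThreshold)
}

#' Cohen's d with pooled standard deviation
#'
#' d = (meanA - meanB)/s_pooled with
#' s_pooled^2 = ((nA-1)sA^2 + (nB-1)sB^2)/(nA+nB-2).  Positive values mean
#' group A (low risk) larger.
#'
#' @param valsA,valsB numeric vectors (>= 2 values each).
#' @return Cohen's d.
#' @export
cohensD <- function(valsA, valsB) {
  nA <- length(valsA); nB <- length(valsB)
  if (nA < 2L || nB < 2L) stop("need at least 2 values per group")
  sp2 <- ((nA - 1) * stats::var(valsA) + (nB - 1) * stats::var(valsB)) /
    (nA + nB - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(valsA) - mean(valsB)) / sqrt(sp2)
}

#' Maximal contiguous significant frequency bands
#'
#' @param reject logical mask over the frequency grid.
#' @param freqs frequency grid, Hz.
#' @return k x 2 matrix of closed intervals (lo, hi) in Hz, ascending.
#' @export
significantBands <- function(reject, freqs) {
  if (!any(reject)) return(matrix(numeric(0), 0, 2))
  r <- rle(as.logical(reject))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  cbind(freqs[starts[sel]], freqs[ends[sel]])
}

#' Group contrast of window-averaged spectra
#'
#' Per-bin rank-sum z/p across subjects, BH adjustment across the frequency
#' bins, Cohen's d per bin, and the maximal runs of contiguous significant
#' bins as bands.
#'
#' @param spectraA,spectraB lists of [SpectrumSummary-class] (one per
#'   subject) on a common frequency grid.
#' @param cfg an [AnalysisConfig-class] (`pThreshold` is used; `fdrQ` is
#'   recorded upstream).
#' @param window label for the contrast (e.g. "spike").
#' @return a [GroupContrast-class].
#' @export
spectrumContrast <- function(spectraA, spectraB, cfg = analysisConfig(),
                             window = "spectrum") {
  freqs <- spectraA[[1]]@freqs
  A <- lapply(spectraA, function(s) s@pctChange)
  B <- lapply(spectraB, function(s) s@pctChange)
  rs <- rankSumMap(A, B)
  bh <- fdrBH(rs$pRaw, cfg@pThreshold)
  Am <- do.call(rbind, A); Bm <- do.call(rbind, B)
  d <- vapply(seq_along(freqs), function(j) cohensD(Am[, j], Bm[, j]),
              numeric(1))
  new("GroupContrast", freqs = freqs, times = numeric(0),
      z = matrix(rs$z, ncol = 1), pRaw = matrix(rs$pRaw, ncol = 1),
      pAdj = matrix(bh$pAdj, ncol = 1), sigMask = matrix(bh$reject, ncol = 1),
      d = d, bands = significantBands(bh$reject, freqs), window = window,
      nA = length(A), nB = length(B))
}

# block-average an induced map to ~nPoints time points over the edge-valid
# samples; returns list(values = freq x nPoints, times = block centres)
.decimateMap <- function(map, nPoints) {
  sel <- which(map@edgeOK)
  nb <- min(nPoints, length(sel))
  grp <- pmin(nb, ceiling(seq_along(sel) / (length(sel) / nb)))
  vals <- t(apply(map@values[, sel, drop = FALSE], 1, function(row)
    tapply(row, grp, mean)))
  list(values = vals, times = as.numeric(tapply(map@times[sel], grp, mean)))
}

#' Time-frequency group contrast
#'
#' Induced maps are block-averaged over the edge-valid samples to the
#' configured number of time points (720 by default), then rank-sum z/p are
#' computed at every (frequency, time) point and BH-adjusted across the
#' whole map.
#'
#' @param mapsA,mapsB lists of induced [TFMap-class], one per subject.
#' @param cfg an [AnalysisConfig-class].
#' @return a [GroupContrast-class] with matrices frequency x time.
#' @export
tfContrast <- function(mapsA, mapsB, cfg = analysisConfig()) {
  decA <- lapply(mapsA, .decimateMap, nPoints = cfg@statsTimePoints)
  decB <- lapply(mapsB, .decimateMap, nPoints = cfg@statsTimePoints)
  rs <- rankSumMap(lapply(decA, `[[`, "values"),
                   lapply(decB, `[[`, "values"))
  bh <- fdrBH(rs$pRaw, cfg@pThreshold)
  new("GroupContrast", freqs = mapsA[[1]]@freqs, times = decA[[1]]$times,
      z = rs$z, pRaw = rs$pRaw, pAdj = bh$pAdj, sigMask = bh$reject,
      d = numeric(0), bands = matrix(numeric(0), 0, 2), window = "tf",
      nA = length(mapsA), nB = length(mapsB))
}

#' Group comparison of gamma-peak parameters
#'
#' Rank-sum p per parameter (frequency, amplitude, latency) plus group
#' means, SDs and medians.
#'
#' @param peaksA,peaksB lists of [GammaPeak-class], one per subject.
#' @return data.frame with one row per parameter.
#' @export
peakGroupComparison <- function(peaksA, peaksB) {
  getp <- function(lst, f) vapply(lst, f, numeric(1))
  pars <- list(frequency = function(p) p@frequency,
               amplitude = function(p) p@amplitude,
               latency = function(p) p@latency)
  rows <- lapply(names(pars), function(nm) {
    a <- getp(peaksA, pars[[nm]]); b <- getp(peaksB, pars[[nm]])
    rs <- .rankSumZ(matrix(a, ncol = 1), matrix(b, ncol = 1))
    data.frame(parameter = nm, meanA = mean(a), sdA = stats::sd(a),
               meanB = mean(b), sdB = stats::sd(b),
               medianA = stats::median(a), medianB = stats::median(b),
               z = rs$z, p = rs$p)
  })
  do.call(rbind, rows)
}
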