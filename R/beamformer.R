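## Scalar (SAM-style) beamformer.
##
## Weights are linearly constrained minimum-variance filters with unit gain
## at the target voxel; the source orientation is optimised in the
## tangential plane in closed form (2x2 generalised eigenproblem), and the
## stimulus-versus-baseline contrast is expressed as a pseudo-t: the
## difference of projected source powers normalised by the projected
## sensor-noise power.

#' Bandpass-filter epochs
#'
#' Applies the zero-phase Butterworth bandpass per trial and channel.
#'
#' @param epochs an [EpochsData-class].
#' @param band `c(lo, hi)` band edges, Hz; must lie inside (0, sfreq/2).
#' @param method see [zeroPhaseBandpass()].
#' @return a new [EpochsData-class] with filtered data.
#' @export
bandFilter <- function(epochs, band, method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  d <- dim(epochs@data)
  # time in rows, (trial, channel) pairs in columns
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), nrow = d[3])
  Y <- zeroPhaseBandpass(X, band[1], band[2], epochs@sfreq, method = method)
  out <- aperm(array(Y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  initialize(epochs, data = out)
}

#' Band-limited sensor covariance
#'
#' Sample covariance over all (trial, sample) pairs in a time window, with
#' channel means removed and diagonal loading lambda =
#' `regularizationFraction` x trace/n added.
#'
#' @param epochs band-filtered [EpochsData-class].
#' @param window `c(lo, hi)` window, s.
#' @param regularizationFraction diagonal loading fraction (of the mean
#'   eigenvalue); 0 disables loading.
#' @param band the band the epochs were filtered to (metadata only).
#' @return a [CovarianceMatrix-class].
#' @export
computeCovariance <- function(epochs, window, regularizationFraction = 0.05,
                              band = c(NA_real_, NA_real_)) {
  idx <- .windowIdx(epochs@times, window)
  if (length(idx) < 2L) stop("window must contain at least 2 samples")
  d <- dim(epochs@data)
  # samples x channels
  X <- matrix(aperm(epochs@data[, , idx, drop = FALSE], c(1, 3, 2)),
              ncol = d[2])
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / (nrow(X) - 1)
  C <- (C + t(C)) / 2
  lam <- regularizationFraction * sum(diag(C)) / ncol(C)
  new("CovarianceMatrix", matrix = C + diag(lam, ncol(C)), raw = C,
      window = as.numeric(window), band = as.numeric(band),
      nSamples = as.integer(nrow(X)), lambda = lam)
}

# orientation maximising the unit-gain output SNR: the generalised
# eigenvector with the largest eigenvalue of (L'C^-1 L, L'C^-2 L); for a
# degenerate pencil (e.g. identity covariance) the dominant gain direction
.samOrientation <- function(gain2, Cinv) {
  CL <- Cinv %*% gain2
  S1 <- crossprod(gain2, CL)          # L' C^-1 L
  S2 <- crossprod(CL)                 # L' C^-2 L
  if (!all(is.finite(S1)) || !all(is.finite(S2)))
    stop("non-finite projected matrices")
  dt <- S2[1, 1] * S2[2, 2] - S2[1, 2] * S2[2, 1]
  if (dt <= 0 || min(diag(S2)) <= 0) stop("singular projected matrix")
  M <- solve(S2, S1)
  ev <- eigen(M)
  vals <- Re(ev$values)
  if (abs(vals[1] - vals[2]) <= 1e-9 * max(abs(vals))) {
    u <- svd(gain2)$v[, 1]            # degenerate: dominant gain direction
  } else {
    u <- Re(ev$vectors[, which.max(vals)])
  }
  u <- u / sqrt(sum(u^2))
  # deterministic sign: largest-magnitude component positive
  j <- which.max(abs(u))
  if (u[j] < 0) u <- -u
  u
}

#' Scalar beamformer weights at one voxel
#'
#' Optimises the source orientation in the tangential plane (closed-form
#' generalised eigenproblem, no iterative search) and returns the
#' unit-gain minimum-variance weights w = C^-1 l / (l' C^-1 l) for the
#' oriented lead field l.
#'
#' @param gain2 channel x 2 tangential gain matrix of the voxel.
#' @param cov a [CovarianceMatrix-class] (the regularised matrix is used).
#' @return list with `weights` (channel vector), `orientation2` (unit
#'   2-vector in the tangential basis), and `leadfield` (the oriented gain).
#' @export
scalarWeights <- function(gain2, cov) {
  Cinv <- tryCatch(chol2inv(chol(cov@matrix)),
                   error = function(e) stop("covariance is not positive definite"))
  u <- .samOrientation(gain2, Cinv)
  l <- drop(gain2 %*% u)
  Cl <- drop(Cinv %*% l)
  denom <- sum(l * Cl)
  if (denom <= 0) stop("singular projected matrix")
  list(weights = Cl / denom, orientation2 = u, leadfield = l)
}

# dual-state orientation: the unit tangential direction extremising the
# pseudo-t, T(u) = (u'Au) / (u'Bu) with A = L'C^-1 (Ca - Cb) C^-1 L and
# B = 2 sigma^2 L'C^-2 L; of the two generalised eigenvectors the one with
# the larger |T| is taken, so the choice is invariant under swapping the
# active and baseline windows (T itself changes sign exactly).  Degenerate
# pencils fall back to the all-data SNR orientation.
.dualStateOrientation <- function(gain2, Cinv, dC) {
  CL <- Cinv %*% gain2
  A <- crossprod(CL, dC %*% CL)
  A <- (A + t(A)) / 2
  B <- crossprod(CL)
  dt <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
  if (dt <= 0 || min(diag(B)) <= 0) stop("singular projected matrix")
  if (max(abs(A)) <= 1e-14 * max(abs(B)) * max(abs(dC), 1e-300))
    return(.samOrientation(gain2, Cinv))
  ev <- eigen(solve(B, A))
  vals <- Re(ev$values)
  j <- which.max(abs(vals))
  if (abs(abs(vals[1]) - abs(vals[2])) <= 1e-12 * max(abs(vals)))
    return(.samOrientation(gain2, Cinv))
  u <- Re(ev$vectors[, j])
  u <- u / sqrt(sum(u^2))
  k <- which.max(abs(u))
  if (u[k] < 0) u <- -u
  u
}

#' Pseudo-t source image
#'
#' Beamformer weights are computed per voxel from the all-data covariance
#' (active and baseline combined); the statistic is
#' T = (P_a - P_b) / (N_a + N_b), where P_x = w' C_x w is the projected
#' power in window x and N_x = sigma^2 w'w the projected sensor-noise power,
#' with sigma^2 the smallest eigenvalue of the unregularised all-data
#' covariance.  The per-voxel source orientation is the dual-state (SAM)
#' optimum: the tangential direction extremising this statistic, solved as
#' a 2x2 generalised eigenproblem (no iterative search).
#'
#' @param leadfield a [LeadField-class].
#' @param covAll all-data covariance (weights and noise floor).
#' @param covActive,covBaseline window covariances.
#' @return a [StatImage-class].
#' @export
pseudoTImage <- function(leadfield, covAll, covActive, covBaseline) {
  nch <- nChannels(leadfield)
  stopifnot(nrow(covActive@matrix) == nch, nrow(covBaseline@matrix) == nch)
  Cinv <- tryCatch(chol2inv(chol(covAll@matrix)),
                   error = function(e) stop("covariance is not positive definite"))
  sigma2 <- min(eigen(covAll@raw, symmetric = TRUE, only.values = TRUE)$values)
  dC <- covActive@raw - covBaseline@raw
  nv <- nVoxels(leadfield)
  W <- matrix(0, nch, nv)
  ori <- matrix(0, nv, 3)
  for (v in seq_len(nv)) {
    g <- leadfield@gain[, , v]
    u <- tryCatch(.dualStateOrientation(g, Cinv, dC),
                  error = function(e) stop("voxel ", leadfield@keep[v], ": ",
                                           conditionMessage(e)))
    l <- drop(g %*% u)
    Cl <- drop(Cinv %*% l)
    W[, v] <- Cl / sum(l * Cl)
    ori[v, ] <- drop(leadfield@basis[, , v] %*% u)
  }
  Pa <- colSums(W * (covActive@raw %*% W))
  Pb <- colSums(W * (covBaseline@raw %*% W))
  Nw <- sigma2 * colSums(W^2)
  new("StatImage", grid = leadfield@grid, keep = leadfield@keep,
      pseudoT = (Pa - Pb) / (2 * Nw), orientation = ori, weights = W,
      sigma2 = sigma2)
}

#' Select the occipital peak voxel
#'
#' Returns the voxel with the largest positive pseudo-t inside the posterior
#' mask (ties broken by the lowest voxel index).  If no strictly positive
#' value exists in the mask, an error of class `vgammaNoPositivePeak` is
#' raised: the subject's gamma response could not be source-localised and
#' the subject is excluded from further analysis.
#'
#' @param image a [StatImage-class].
#' @param useMask restrict the search to the posterior mask (default TRUE).
#' @return a [PeakVoxel-class].
#' @export
findPeakVoxel <- function(image, useMask = TRUE) {
  mask <- if (useMask) image@grid@posteriorMask[image@keep]
          else rep(TRUE, length(image@keep))
  cand <- which(mask)
  if (length(cand) == 0 || max(image@pseudoT[cand]) <= 0)
    stop(structure(class = c("vgammaNoPositivePeak", "error", "condition"),
                   list(message = "no positive pseudo-t peak in the occipital search region",
                        call = sys.call())))
  best <- cand[which.max(image@pseudoT[cand])]   # first max: lowest index
  new("PeakVoxel", index = as.integer(image@keep[best]),
      location = as.numeric(image@grid@voxels[image@keep[best], ]),
      pseudoT = image@pseudoT[best], weights = image@weights[, best],
      orientation = as.numeric(image@orientation[best, ]))
}

# second SAM pass at the selected peak: recompute the unit-gain weights for
# the stored orientation under heavier diagonal loading, which approaches
# the distortionless matched-filter limit and is robust to the mismatch
# between the true source and the voxel centre on coarse grids
.reweightPeak <- function(peak, leadfield, covAll, vsFraction) {
  v <- match(peak@index, leadfield@keep)
  if (is.na(v)) stop("peak voxel not present in the lead field")
  g <- leadfield@gain[, , v]
  u2 <- drop(crossprod(leadfield@basis[, , v], peak@orientation))
  u2 <- u2 / sqrt(sum(u2^2))
  lam <- vsFraction * sum(diag(covAll@raw)) / ncol(covAll@raw)
  C2 <- covAll@raw + diag(lam, ncol(covAll@raw))
  l <- drop(g %*% u2)
  Cl <- solve(C2, l)
  initialize(peak, weights = Cl / sum(l * Cl))
}

#' Extract the virtual sensor time series
#'
#' Applies the peak voxel's unit-gain weights to the (unfiltered) epochs,
#' yielding the source amplitude per trial and sample.  The unit-gain
#' constraint fixes the scale: Am at the source, reported in nAm.
#'
#' @param epochs the original (broadband) [EpochsData-class].
#' @param peak a [PeakVoxel-class] whose weights match the epochs' channels.
#' @return a [VirtualSensor-class] (trial x time, nAm).
#' @export
extractVirtualSensor <- function(epochs, peak) {
  d <- dim(epochs@data)
  if (length(peak@weights) != d[2])
    stop("peak weights do not match the epochs' channel count")
  X <- matrix(aperm(epochs@data, c(2, 1, 3)), nrow = d[2])  # ch x (trial*time)
  vs <- matrix(crossprod(peak@weights, X), nrow = d[1])     # trial x time
  new("VirtualSensor", data = vs * 1e9, sfreq = epochs@sfreq,
      times = epochs@times)
}
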