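test_that("band filtering preserves the passband and rejects the stopband", {
  sf <- 300
  t <- (0:(6 * sf - 1)) / sf
  mid <- seq(sf, 5 * sf)                    # steady-state region
  x45 <- sin(2 * pi * 45 * t)
  y45 <- zeroPhaseBandpass(x45, 30, 90, sf)
  expect_lt(abs(max(abs(y45[mid])) - 1), 0.01)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- zeroPhaseBandpass(x10, 30, 90, sf)
  atten_db <- -20 * log10(max(abs(y10[mid])))
  expect_gt(atten_db, 20)
  # oracle: the designed two-pass transfer function also predicts >= 20 dB
  flt <- signal::butter(4, c(30, 90) / (sf / 2), type = "pass")
  w <- 2 * pi * 10 / sf
  H1 <- Mod(sum(flt$b * exp(-1i * w * (seq_along(flt$b) - 1))) /
            sum(flt$a * exp(-1i * w * (seq_along(flt$a) - 1))))
  expect_gt(-20 * log10(H1^2), 20)      # amplitude response of two passes
  expect_identical(zeroPhaseBandpass(numeric(600), 30, 90, sf),
                   numeric(600))
  expect_error(zeroPhaseBandpass(x45, 30, 160, sf), "Nyquist")
})

test_that("frequency-domain and filtfilt zero-phase filtering agree", {
  set.seed(1)
  sf <- 300
  x <- rnorm(6 * sf)
  a <- zeroPhaseBandpass(x, 30, 90, sf, method = "fft")
  b <- zeroPhaseBandpass(x, 30, 90, sf, method = "filtfilt")
  mid <- seq(sf, 5 * sf)
  expect_lt(max(abs(a[mid] - b[mid])) / sd(a[mid]), 0.02)
})

test_that("band filtering epochs acts per trial and channel", {
  ep <- tinyEpochs()
  f <- bandFilter(ep, c(30, 90))
  expect_identical(dim(f@data), dim(ep@data))
  one <- zeroPhaseBandpass(ep@data[2, 3, ], 30, 90, ep@sfreq)
  expect_equal(f@data[2, 3, ], one, tolerance = 1e-12)
})

test_that("covariance estimates white noise and respects loading", {
  set.seed(2)
  sens <- makeSensorArray(8L, 2L)
  nt <- 4 * 400
  data <- array(rnorm(20 * 8 * nt), c(20L, 8L, nt))
  ep <- epochsData(sens, data, 400, tmin = -2)
  cov <- computeCovariance(ep, c(-1.5, 1.5), 0.05)
  N <- cov@nSamples
  offd <- cov@matrix[upper.tri(cov@matrix)]
  expect_lt(max(abs(offd)), 3 / sqrt(N))
  expect_equal(mean(diag(cov@matrix)), 1 + cov@lambda, tolerance = 0.02)
  ev <- eigen(cov@matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= cov@lambda - 1e-10))
  expect_error(computeCovariance(ep, c(5, 6), 0), "no samples")
})

test_that("a single noiseless source gives a rank-1 covariance", {
  sens <- makeSensorArray(8L, 2L)
  nt <- 4 * 400
  tt <- -2 + (0:(nt - 1)) / 400
  L <- leadfieldDipole(c(-0.04, 0, 0.05), c(0, 1, 0), sens,
                       defaultHeadSphere())
  src <- sin(2 * pi * 40 * tt)
  data <- aperm(outer(rbind(src, src), L), c(1, 3, 2))
  ep <- epochsData(sens, data, 400, tmin = -2)
  cov <- computeCovariance(ep, c(-1.5, 1.5), 0)
  ev <- eigen(cov@raw, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-6)
})

test_that("scalar weights satisfy the closed forms", {
  lf <- unitLeadfield()
  g <- lf@gain[, , 5]
  nch <- nrow(g)
  # identity covariance: w proportional to l/(l'l), dominant gain direction
  covI <- new("CovarianceMatrix", matrix = diag(nch), raw = diag(nch),
              window = c(0, 1), band = c(30, 90), nSamples = 100L,
              lambda = 0)
  sw <- scalarWeights(g, covI)
  udom <- svd(g)$v[, 1]
  expect_equal(abs(sum(sw$orientation2 * udom)), 1, tolerance = 1e-9)
  l <- drop(g %*% sw$orientation2)
  expect_equal(sw$weights, l / sum(l * l), tolerance = 1e-12)
  # unit gain for random positive-definite covariances
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(rnorm(nch * nch), nch)
    C <- crossprod(A) / nch + diag(nch)
    cv <- new("CovarianceMatrix", matrix = C, raw = C, window = c(0, 1),
              band = c(30, 90), nSamples = 100L, lambda = 0)
    swi <- scalarWeights(g, cv)
    expect_lt(abs(sum(swi$weights * swi$leadfield) - 1), 1e-10)
  }
})

test_that("the optimised orientation recovers a planted source", {
  lf <- unitLeadfield()
  v <- 10L
  g <- lf@gain[, , v]
  set.seed(4)
  u0 <- rnorm(2); u0 <- u0 / sqrt(sum(u0^2))
  l0 <- drop(g %*% u0)
  nch <- length(l0)
  C <- 1e-4 * mean(l0^2) * diag(nch) + 50 * tcrossprod(l0)
  cv <- new("CovarianceMatrix", matrix = C, raw = C, window = c(0, 1),
            band = c(30, 90), nSamples = 1000L, lambda = 0)
  sw <- scalarWeights(g, cv)
  ang <- acos(min(1, abs(sum(sw$orientation2 * u0)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("pseudo-t is zero under equal covariances and antisymmetric", {
  lf <- unitLeadfield()
  ep <- unitSubject()$epochs
  filt <- bandFilter(ep, c(30, 90))
  covAll <- computeCovariance(filt, c(-1.5, 1.5), 0.5)
  covA <- computeCovariance(filt, c(0, 1.5), 0)
  covB <- computeCovariance(filt, c(-1.5, 0), 0)
  img0 <- pseudoTImage(lf, covAll, covA, covA)
  expect_true(all(img0@pseudoT == 0))
  img <- pseudoTImage(lf, covAll, covA, covB)
  imgSwap <- pseudoTImage(lf, covAll, covB, covA)
  expect_identical(imgSwap@pseudoT, -img@pseudoT)
})

test_that("a planted occipital source is localised on the grid", {
  s <- unitSubject()
  res <- unitResult()
  err <- sqrt(sum((res@peak@location - s$truth@sourceLocation)^2))
  expect_lt(err, 2 * 0.015)
  expect_true(res@peak@pseudoT > 0)
})

test_that("peak selection respects the mask, sign and tie-breaks", {
  lf <- unitLeadfield()
  nv <- nVoxels(lf)
  mk <- function(vals) new("StatImage", grid = lf@grid, keep = lf@keep,
                           pseudoT = vals,
                           orientation = matrix(0, nv, 3),
                           weights = matrix(0, nChannels(lf), nv),
                           sigma2 = 1)
  mask <- lf@grid@posteriorMask[lf@keep]
  vals <- rep(-1, nv)
  j <- which(mask)[3]
  vals[j] <- 2
  pk <- findPeakVoxel(mk(vals))
  expect_identical(pk@index, lf@keep[j])
  expect_error(findPeakVoxel(mk(rep(-1, nv))), class = "vgammaNoPositivePeak")
  # equal maxima: the lowest voxel index wins
  vals2 <- rep(0.5, nv)
  pk2 <- findPeakVoxel(mk(vals2))
  expect_identical(pk2@index, lf@keep[which(mask)[1]])
})

test_that("virtual sensors reconstruct a noiseless source exactly", {
  cc <- unitCohort(nBackgroundDipoles = 0L, sensorNoiseLevel = 1e-30,
                   nTrials = 2L)
  tr <- makeSubjectTruth(cc, "low", "nl", seed = 9L)
  sim <- simulateSubject(tr, cc, unitSensors(), defaultHeadSphere(),
                         seed = 9L)
  set.seed(9L)
  src <- sourceTimecourses(tr, cc, sim$epochs@times, 2L)
  L <- leadfieldDipole(tr@sourceLocation, tr@sourceOrientation,
                       unitSensors(), defaultHeadSphere())
  pk <- new("PeakVoxel", index = 1L, location = tr@sourceLocation,
            pseudoT = 1, weights = L / sum(L * L),
            orientation = tr@sourceOrientation)
  vs <- extractVirtualSensor(sim$epochs, pk)
  expect_identical(dim(vs@data), c(2L, length(sim$epochs@times)))
  for (i in 1:2) expect_gt(cor(vs@data[i, ], src[i, ]), 0.999)
  zero <- sim$epochs
  zero@data[] <- 0
  expect_true(all(extractVirtualSensor(zero, pk)@data == 0))
})

test_that("heavier diagonal loading shrinks the weights", {
  lf <- unitLeadfield()
  ep <- unitSubject()$epochs
  filt <- bandFilter(ep, c(30, 90))
  g <- lf@gain[, , 12]
  norms <- vapply(c(0.01, 0.1, 1, 10), function(fr) {
    cv <- computeCovariance(filt, c(-1.5, 1.5), fr)
    sqrt(sum(scalarWeights(g, cv)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})
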