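test_that("rank-sum maps behave at the identities", {
  A <- replicate(3, matrix(1:6, 2), simplify = FALSE)
  rs <- rankSumMap(A, A)
  expect_true(all(rs$z == 0))
  expect_true(all(rs$pRaw == 1))
  set.seed(1)
  B <- lapply(1:4, function(i) matrix(rnorm(6), 2))
  A2 <- lapply(B, function(m) m + 5)
  rs2 <- rankSumMap(A2, B)
  expect_true(all(rs2$z > 0))              # low-risk group larger => z > 0
  expect_error(rankSumMap(A[1], A), "at least 2")
})

test_that("the normal approximation tracks the exact permutation law", {
  # brute force over all 252 group assignments; the mid-p convention
  # (half-weight on ties with the observed statistic) is the discrete
  # quantity a continuous approximation estimates
  set.seed(2)
  for (rep in 1:6) {
    a <- rnorm(5); b <- rnorm(5, mean = rep / 4)
    rs <- rankSumMap(as.list(a), as.list(b))
    pooled <- c(a, b)
    r <- rank(pooled)
    W <- apply(utils::combn(10, 5), 2, function(idx) sum(r[idx]))
    Wobs <- sum(r[1:5])
    dev <- abs(W - mean(W)); dobs <- abs(Wobs - mean(W))
    pExact <- mean(dev > dobs + 1e-9) + 0.5 * mean(abs(dev - dobs) < 1e-9)
    expect_lt(abs(rs$pRaw - pExact), 0.02)
  }
})

test_that("rank statistics are invariant under monotone transforms and
           antisymmetric under label swap", {
  set.seed(3)
  A <- lapply(1:5, function(i) rnorm(8))
  B <- lapply(1:6, function(i) rnorm(8, 0.5))
  rs <- rankSumMap(A, B)
  mono <- function(x) exp(3 * x) - 5
  rsM <- rankSumMap(lapply(A, mono), lapply(B, mono))
  expect_equal(rsM$z, rs$z, tolerance = 1e-12)
  rsSwap <- rankSumMap(B, A)
  expect_equal(rsSwap$z, -rs$z, tolerance = 1e-12)
  expect_equal(rsSwap$pRaw, rs$pRaw, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-worked step-up oracle", {
  out <- fdrBH(c(0.01, 0.02, 0.04, 0.6), pThreshold = 0.05)
  expect_equal(out$pAdj, c(0.04, 0.04, 0.04 * 4 / 3, 0.6),
               tolerance = 1e-12)
  expect_identical(out$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(fdrBH(rep(1, 7))$reject, rep(FALSE, 7))
  expect_identical(fdrBH(0.03)$pAdj, 0.03)       # m = 1 reduces to raw
  expect_length(fdrBH(numeric(0))$reject, 0)
  set.seed(4)
  p <- runif(50)
  adj <- fdrBH(p)$pAdj
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("Cohen's d matches the pooled-SD textbook formula", {
  set.seed(5)
  a <- rnorm(12, 1); b <- rnorm(17)
  d <- cohensD(a, b)
  ref <- (mean(a) - mean(b)) /
    sqrt(((12 - 1) * var(a) + (17 - 1) * var(b)) / (12 + 17 - 2))
  expect_equal(d, ref, tolerance = 1e-12)
  expect_equal(cohensD(c(0, 1, 2), c(-1, 0, 1)), 1, tolerance = 1e-12)
  expect_equal(cohensD(a, a), 0, tolerance = 1e-12)
  expect_error(cohensD(rep(1, 5), rep(1, 4)), "pooled")
})

test_that("significant bands are the maximal contiguous runs", {
  freqs <- seq(30, 90, by = 0.5)
  mask <- freqs >= 30 & freqs <= 40
  expect_equal(significantBands(mask, freqs), cbind(30, 40))
  expect_identical(nrow(significantBands(rep(FALSE, 121), freqs)), 0L)
  mask2 <- (freqs >= 54 & freqs <= 56.5) | (freqs >= 75 & freqs <= 86)
  bands <- significantBands(mask2, freqs)
  expect_equal(bands, rbind(c(54, 56.5), c(75, 86)))
})

test_that("spectrum contrasts find planted band differences where planted", {
  cfg <- analysisConfig()
  freqs <- tfFrequencyGrid(cfg)
  mk <- function(base) new("SpectrumSummary", freqs = freqs,
                           pctChange = base, activeWindow = c(0, 0.3),
                           baselineWindow = c(-1.5, 0))
  set.seed(6)
  inBand <- freqs >= 30 & freqs <= 40
  A <- lapply(1:15, function(i) mk(rnorm(121, 50, 5) + 25 * inBand))
  B <- lapply(1:15, function(i) mk(rnorm(121, 50, 5)))
  ct <- spectrumContrast(A, B, cfg, window = "spike")
  expect_true(any(ct@sigMask))
  sig <- freqs[as.logical(ct@sigMask)]
  expect_true(all(sig >= 28 & sig <= 42))
  expect_gt(mean(ct@d[inBand]), 1)
  # identical spectra: d = 0, no bands
  ct0 <- spectrumContrast(A, A, cfg)
  expect_true(all(ct0@d == 0))
  expect_identical(nrow(ct0@bands), 0L)
})

test_that("peak parameter comparisons are calibrated and specific", {
  mkpeak <- function(f, a, l) new("GammaPeak", frequency = f, amplitude = a,
                                  latency = l, window = c(0, 0.3))
  set.seed(7)
  A <- lapply(1:20, function(i) mkpeak(rnorm(1, 53, 2), rnorm(1, 40, 4),
                                       rnorm(1, 0.12, 0.01)))
  same <- peakGroupComparison(A, A)
  expect_true(all(same$p == 1))
  B <- lapply(A, function(p) mkpeak(p@frequency + 10, p@amplitude +
                                    rnorm(1, 0, 0.5), p@latency))
  shift <- peakGroupComparison(B, A)
  expect_lt(shift$p[shift$parameter == "frequency"], 0.01)
  expect_gt(shift$p[shift$parameter == "latency"], 0.05)
  expect_gt(shift$z[shift$parameter == "frequency"], 0)
})

test_that("time-frequency contrasts run on the decimated edge-free grid", {
  cfg <- unitConfig()
  freqs <- seq(30, 90, by = 0.5)
  nt <- 360
  times <- -1.8 + (0:(nt - 1)) / 100
  edgeOK <- times >= -1.6 & times <= 1.6
  mk <- function(shift) new("TFMap",
                            values = matrix(rnorm(121 * nt, shift), 121, nt),
                            freqs = freqs, times = times, edgeOK = edgeOK,
                            kind = "induced")
  set.seed(8)
  A <- lapply(1:4, function(i) mk(1))
  B <- lapply(1:4, function(i) mk(0))
  ct <- tfContrast(A, B, cfg)
  expect_identical(dim(ct@z), c(121L, cfg@statsTimePoints))
  expect_true(all(ct@times >= -1.6 & ct@times <= 1.6))
  expect_gt(mean(ct@z), 0)
  expect_identical(dim(ct@pAdj), dim(ct@z))
})
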