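test_that("the Hilbert envelope tracks known amplitudes", {
  sf <- 300
  t <- (0:(4 * sf - 1)) / sf
  mid <- t > 0.2 & t < max(t) - 0.2
  env <- hilbertEnvelope(3 * sin(2 * pi * 55 * t), 55, 8, sf)
  expect_lt(max(abs(env[mid] - 3)) / 3, 0.02)
  # amplitude-modulated carrier: envelope follows the modulator
  m <- 1 + 0.5 * sin(2 * pi * 2 * t)
  env2 <- hilbertEnvelope(m * sin(2 * pi * 55 * t), 55, 8, sf)
  expect_gt(cor(env2[mid], m[mid]), 0.99)
  # off-band tone is strongly attenuated
  env3 <- hilbertEnvelope(sin(2 * pi * 75 * t), 55, 8, sf)
  expect_lt(max(env3[mid]), 0.05)
  expect_error(hilbertEnvelope(t, 148, 8, sf), "inside")
})

test_that("trial spectrograms have the documented shape and equivariance", {
  cfg <- unitConfig()
  sf <- 300
  nt <- 4 * sf
  tt <- -2 + (0:(nt - 1)) / sf
  set.seed(1)
  dat <- rbind(sin(2 * pi * 40 * tt), sin(2 * pi * 60 * tt),
               rnorm(nt, sd = 0.1))
  vs <- new("VirtualSensor", data = dat, sfreq = sf, times = tt)
  tm <- trialSpectrograms(vs, cfg)
  expect_identical(dim(tm@values), c(3L, 121L, as.integer(nt)))
  prof1 <- rowMeans(tm@values[1, , tm@edgeOK])
  expect_equal(tm@freqs[which.max(prof1)], 40, tolerance = 0.51)
  # permuting trials permutes the maps identically
  vs2 <- new("VirtualSensor", data = dat[c(2, 3, 1), ], sfreq = sf,
             times = tt)
  tm2 <- trialSpectrograms(vs2, cfg)
  expect_identical(tm2@values[3, , ], tm@values[1, , ])
})

test_that("percent change obeys its arithmetic", {
  tm <- flatSpectrograms(10)
  ind <- inducedPercentChange(tm)
  expect_true(all(abs(ind@values) < 1e-12))
  # baseline 10, active 15 -> +50%
  tm2 <- flatSpectrograms(10)
  act <- tm2@times >= 0
  tm2@values[, , act] <- 15
  ind2 <- inducedPercentChange(tm2)
  sel <- ind2@times > 0.1
  expect_equal(unique(as.numeric(round(ind2@values[, sel], 10))), 50)
  # trial-wise average equals the direct formula when trials are identical
  expect_equal(ind2@values[1, sel][1], 50, tolerance = 1e-12)
  # zero baseline is refused
  tm3 <- flatSpectrograms(0)
  tm3@values[, , tm3@times >= 0] <- 1
  expect_error(inducedPercentChange(tm3), "baseline")
})

test_that("gamma peaks are extracted with deterministic tie-breaks", {
  tm <- flatSpectrograms(10, nTrials = 1L)
  tm@values[1, 41, 251] <- 20           # 50 Hz, some time in the window
  ind <- inducedPercentChange(tm)
  tsel <- ind@times[251]
  pk <- extractGammaPeak(ind, c(-2, 2), c(30, 90))
  expect_equal(pk@frequency, 50)
  expect_equal(pk@latency, tsel)
  expect_equal(pk@amplitude, 100, tolerance = 1e-9)
  # two equal maxima: lower frequency, then earlier time
  tm@values[1, 61, 100] <- 20
  tm@values[1, 61, 90] <- 20
  ind2 <- inducedPercentChange(tm)
  pk2 <- extractGammaPeak(ind2, c(-2, 2), c(30, 90))
  expect_equal(pk2@frequency, 50)
  tm@values[1, 41, 251] <- 10
  ind3 <- inducedPercentChange(tm)
  pk3 <- extractGammaPeak(ind3, c(-2, 2), c(30, 90))
  expect_equal(pk3@frequency, 60)
  expect_equal(pk3@latency, ind3@times[90])
})

test_that("the planted sustained frequency is recovered from the map", {
  s <- unitSubject()
  maps <- unitMaps()
  pk <- extractGammaPeak(maps$induced, c(0.3, 1.5), c(30, 90))
  expect_lt(abs(pk@frequency - s$truth@gammaPeakFreq), 1)
})

test_that("window spectra match a naive dual implementation", {
  maps <- unitMaps()
  tm <- maps$tmaps
  sp <- windowSpectrum(tm, c(0.3, 1.5), c(-1.5, 0))
  # brute-force loop over bins and trials, independent indexing
  naive <- numeric(length(tm@freqs))
  # same half-open windows with the floating-point guard
  aidx <- which(tm@times >= 0.3 - 1e-9 & tm@times < 1.5 - 1e-9 & tm@edgeOK)
  bidx <- which(tm@times >= -1.5 - 1e-9 & tm@times < 0 - 1e-9 & tm@edgeOK)
  ntr <- dim(tm@values)[1]
  for (f in seq_along(tm@freqs)) {
    acc <- 0
    for (tr in seq_len(ntr)) {
      a <- mean(tm@values[tr, f, aidx])
      b <- mean(tm@values[tr, f, bidx])
      acc <- acc + 100 * (a - b) / b
    }
    naive[f] <- acc / ntr
  }
  expect_lt(max(abs(sp@pctChange - naive)), 1e-12)
  # flat maps -> 0 everywhere; single-bin doubling -> +100% there only
  flat <- flatSpectrograms(7)
  expect_true(all(abs(windowSpectrum(flat, c(0, 1.5))@pctChange) < 1e-12))
  one <- flatSpectrograms(7)
  one@values[, 30, one@times >= 0] <- 14
  spc <- windowSpectrum(one, c(0.1, 1.4))
  expect_equal(spc@pctChange[30], 100, tolerance = 1e-9)
  expect_lt(max(abs(spc@pctChange[-30])), 1e-9)
})

test_that("percent-change results are invariant to virtual-sensor scale", {
  maps <- unitMaps()
  cfg <- unitConfig()
  vs2 <- maps$vs
  vs2@data <- vs2@data * 1234.5
  tm2 <- trialSpectrograms(vs2, cfg)
  ind2 <- inducedPercentChange(tm2)
  expect_lt(max(abs(ind2@values - maps$induced@values)), 1e-10)
  sp1 <- windowSpectrum(maps$tmaps, c(0.3, 1.5))
  sp2 <- windowSpectrum(tm2, c(0.3, 1.5))
  expect_lt(max(abs(sp1@pctChange - sp2@pctChange)), 1e-10)
})
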