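# Shared fixtures.  Heavy objects are built lazily once per test run and
# cached in this environment; all simulated data are generated in code with
# fixed seeds.

.fix <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# small, fast study conditions for unit tests: 24 channels, 300 Hz,
# 12 trials, 15 mm grid
unitCohort <- function(nTrials = 12L, nChannels = 24L, sfreq = 300, ...) {
  cohortConfig(nTrials = nTrials, nChannels = nChannels, sfreq = sfreq, ...)
}

unitConfig <- function(gridSpacing = 0.015, bootstrapB = 60L,
                       regularizationFraction = 0.5,
                       statsTimePoints = 120L, ...) {
  analysisConfig(gridSpacing = gridSpacing, bootstrapB = bootstrapB,
                 regularizationFraction = regularizationFraction,
                 statsTimePoints = statsTimePoints, ...)
}

unitSensors <- function() .memo("sens24", makeSensorArray(24L, seed = 1L))

unitLeadfield <- function() .memo("lf24", {
  grid <- buildGrid(defaultHeadSphere(), 0.015)
  suppressMessages(computeLeadfields(grid, unitSensors(), defaultHeadSphere()))
})

# one cached simulated subject (signal) at unit scale
unitSubject <- function() .memo("subj1", {
  cc <- unitCohort()
  tr <- makeSubjectTruth(cc, "low", "unit-01", seed = 42L)
  sim <- simulateSubject(tr, cc, unitSensors(), defaultHeadSphere(), seed = 42L)
  list(cohort = cc, truth = tr, epochs = sim$epochs)
})

# the cached subject taken through the subject-level pipeline
unitResult <- function() .memo("res1", {
  s <- unitSubject()
  suppressMessages(runSubject(s$epochs, unitConfig(), "unit-01", "low",
                              head = defaultHeadSphere(),
                              leadfield = unitLeadfield()))
})

# virtual sensor + trial spectrograms for the cached subject
unitMaps <- function() .memo("maps1", {
  s <- unitSubject()
  res <- unitResult()
  vs <- extractVirtualSensor(s$epochs, res@peak)
  tmaps <- trialSpectrograms(vs, unitConfig())
  list(vs = vs, tmaps = tmaps, induced = inducedPercentChange(tmaps))
})

# tiny deterministic epochs for I/O tests (8 channels, covers the analysis
# windows at 200 Hz)
tinyEpochs <- function(nTrials = 2L, seed = 7L) {
  set.seed(seed)
  sens <- makeSensorArray(8L, seed = 2L)
  nt <- 3.6 * 200
  data <- array(rnorm(nTrials * 8 * nt, sd = 1e-13), c(nTrials, 8L, nt))
  epochsData(sens, data, sfreq = 200, tmin = -1.8,
             headshape = makeHeadPoints(n = 30L, seed = 3L))
}

# synthetic per-trial spectrograms with fully controlled envelope values
flatSpectrograms <- function(value = 10, nTrials = 3L, sfreq = 100,
                             freqs = seq(30, 90, by = 0.5)) {
  nt <- 3.6 * sfreq
  times <- -1.8 + (seq_len(nt) - 1) / sfreq
  vals <- array(value, c(nTrials, length(freqs), nt))
  new("TrialSpectrograms", values = vals, freqs = freqs, times = times,
      edgeOK = times >= -1.6 & times <= 1.6)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}

# Independent evaluation of the spherical-conductor closed form, written
# directly from the textbook expression with scalar arithmetic and no
# shared helpers, used as a dual-implementation oracle.
sarvasOracle <- function(loc, q, pos, ori, center) {
  out <- numeric(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, ] - center
    r0 <- loc - center
    a <- r - r0
    na <- sqrt(sum(a * a)); nr <- sqrt(sum(r * r))
    F <- na * (nr * na + nr * nr - sum(r0 * r))
    gradF <- (na * na / nr + sum(a * r) / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + sum(a * r) / na) * r0
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
              q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    B <- 1e-7 / F^2 * (F * qxr0 - sum(qxr0 * r) * gradF)
    out[k] <- sum(B * ori[k, ])
  }
  out
}
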