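## Synthetic MEG cohort generator.
##
## Emulates the statistical structure of a visual-gamma MEG study: an
## occipital dipolar source producing (a) a transient broadband (30-80 Hz)
## burst shortly after stimulus onset and (b) a sustained narrow-band
## oscillation at a subject-specific frequency drawn from N(52.5, 8.5) Hz,
## on top of pink-noise background dipoles and white sensor noise, recorded
## by a radial-gradiometer helmet.  Group effects (high-risk group reduced)
## are planted as standardized mean differences of specific source-component
## amplitudes: the 30-40 Hz part of the burst (spike effect) and
## band-limited sustained components in the configured bands.  All per-trial
## phases are random, so responses are induced, not phase-locked.

#' Canonical head sphere used by the simulator
#'
#' @return a single-sphere [HeadModel-class] centred at (0, 0, 0.04) m with
#'   radius 0.09 m.
#' @export
defaultHeadSphere <- function() {
  new("HeadModel", mode = "single_sphere",
      center = matrix(c(0, 0, 0.04), 1), radius = 0.09)
}

#' Quasi-uniform radial gradiometer helmet
#'
#' Places `nChannels` sensors on the upper hemisphere of a helmet sphere
#' concentric with the head sphere, 10 mm outside the scalp (helmet radius
#' 0.10 m for the 0.09 m head), using a Fibonacci lattice with a small
#' seeded angular jitter; orientations are exactly radial (outward).
#'
#' @param nChannels number of channels (>= 8).
#' @param seed RNG seed for the jitter.
#' @return a [SensorArray-class].
#' @export
makeSensorArray <- function(nChannels, seed = 1L) {
  if (nChannels < 8L) stop("need at least 8 channels")
  set.seed(seed)
  helmetCenter <- c(0, 0, 0.04)
  R <- 0.10                                     # head radius + 10 mm standoff
  k <- seq_len(nChannels)
  z <- 0.05 + 0.95 * (k - 0.5) / nChannels      # cos(theta), upper hemisphere
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden + stats::rnorm(nChannels, 0, 0.005)
  theta <- acos(pmin(1, z + stats::rnorm(nChannels, 0, 0.002)))
  u <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  pos <- sweep(R * u, 2, helmetCenter, "+")
  sensorArray(sprintf("MEG%03d", k), pos, u)
}

#' Synthetic head-surface point cloud
#'
#' Points on the head sphere (upper portion, as a scalp digitisation
#' would cover) with isotropic measurement noise.
#'
#' @param head a single-sphere [HeadModel-class].
#' @param n number of points.
#' @param noise isotropic point noise sd, m.
#' @param seed RNG seed.
#' @return n x 3 matrix of points, m.
#' @export
makeHeadPoints <- function(head = defaultHeadSphere(), n = 150L,
                           noise = 5e-4, seed = 1L) {
  set.seed(seed)
  z <- stats::runif(n, -0.25, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  st <- sqrt(1 - z^2)
  u <- cbind(st * cos(phi), st * sin(phi), z)
  sweep(head@radius[1] * u, 2, head@center[1, ], "+") +
    matrix(stats::rnorm(3 * n, 0, noise), n, 3)
}

# truncated-normal draw by rejection
.rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lo & x < hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# gamma-family amplitude draw with an exact standardized group difference:
# both groups share the shape k = (mean/sd)^2; the high group's scale is
# reduced by the factor (1 - delta) solving
#   d = sqrt(k) * delta / sqrt((1 + (1-delta)^2) / 2),
# so the population Cohen's d (pooled SD) equals the configured d while the
# support stays positive (no truncation distortion).
.gammaScaleDelta <- function(d, shape) {
  if (d == 0) return(0)
  f <- function(delta)
    sqrt(shape) * delta / sqrt((1 + (1 - delta)^2) / 2) - d
  stats::uniroot(f, c(1e-12, 1 - 1e-9))$root
}

.rAmpEffect <- function(n, mean, sd, d, group) {
  shape <- (mean / sd)^2
  scl <- mean / shape
  if (group == "high") scl <- scl * (1 - .gammaScaleDelta(d, shape))
  stats::rgamma(n, shape = shape, scale = scl)
}

#' Draw the ground truth for one simulated subject
#'
#' Effect-carrying amplitudes (the 30-40 Hz burst component, via
#' `effectDSpike`, and each sustained band component, via
#' `effectDSustained`) are drawn from a gamma family with a common shape;
#' the high-risk group's scale is reduced so that the population Cohen's d
#' (pooled SD) equals the configured value exactly while the support stays
#' positive.  The main sustained oscillation frequency is a
#' truncated-normal draw and its amplitude carries no group effect.
#'
#' @param cohort a [CohortConfig-class].
#' @param group "low" or "high".
#' @param id subject identifier.
#' @param seed RNG seed.
#' @return a [SubjectTruth-class].
#' @export
makeSubjectTruth <- function(cohort, group = c("low", "high"),
                             id = "sub-01", seed = 1L) {
  group <- match.arg(group)
  set.seed(seed)
  f <- .rtnorm(1, cohort@freqMean, cohort@freqSd,
               cohort@freqClip[1], cohort@freqClip[2])
  lat <- .rtnorm(1, cohort@latencyMean, cohort@latencySd, 0.04, 0.25)
  spikeAmp <- .rAmpEffect(1, cohort@spikeAmpMean, cohort@spikeAmpSd,
                          cohort@effectDSpike, group)
  susAmp <- .rtnorm(1, cohort@sustainedAmpMean, cohort@sustainedAmpSd,
                    0.1, Inf)
  nb <- nrow(cohort@effectBands)
  bandAmps <- vapply(seq_len(nb), function(k)
    .rAmpEffect(1, cohort@bandAmpMean, cohort@bandAmpSd,
                cohort@effectDSustained[k], group),
    numeric(1))
  names(bandAmps) <- sprintf("%g-%g", cohort@effectBands[, 1],
                             cohort@effectBands[, 2])
  ctr <- defaultHeadSphere()@center[1, ]
  loc <- ctr + c(-0.055, 0, 0.011) + c(stats::rnorm(1, 0, 0.004),
                                     stats::rnorm(1, 0, 0.006),
                                     stats::rnorm(1, 0, 0.006))
  ur <- (loc - ctr) / sqrt(sum((loc - ctr)^2))
  v <- stats::rnorm(3)
  tang <- v - sum(v * ur) * ur
  tang <- tang / sqrt(sum(tang^2))
  new("SubjectTruth", subjectId = id, sourceLocation = loc,
      sourceOrientation = tang, gammaPeakFreq = f, spikeLatency = lat,
      spikeAmplitude = spikeAmp, spikeBroadAmplitude = cohort@spikeBroadAmp,
      spikeNarrowAmplitude = cohort@spikeNarrowAmp,
      sustainedAmplitude = susAmp, sustainedBandAmps = bandAmps,
      spikeWindow = c(0, 0.3), sustainedWindow = c(0.3, 1.5),
      snrSensor = susAmp / cohort@background1fLevel)
}

# unit-rms band-limited noise, one column per trial
.bandNoise <- function(nt, ntr, lo, hi, sfreq) {
  X <- zeroPhaseBandpass(matrix(stats::rnorm(nt * ntr), nt, ntr),
                         lo, hi, sfreq)
  sweep(X, 2, sqrt(colMeans(X^2)), "/")
}

# raised-cosine on/off envelope over [on, off] with ramp seconds of taper
.rampEnvelope <- function(times, on, off, ramp = 0.05) {
  env <- numeric(length(times))
  env[times >= on + ramp & times <= off - ramp] <- 1
  ru <- times >= on & times < on + ramp
  env[ru] <- 0.5 * (1 - cos(pi * (times[ru] - on) / ramp))
  rd <- times > off - ramp & times <= off
  env[rd] <- 0.5 * (1 - cos(pi * (off - times[rd]) / ramp))
  env
}

#' Source time courses for one subject
#'
#' Builds the trial x time dipole moment (nAm): a Gaussian-envelope
#' transient burst (30-40 Hz effect component, 40-80 Hz broadband
#' remainder, and a narrow-band component at the subject's own gamma
#' frequency so the transient peaks at the individual peak frequency;
#' FWHM ~50 ms at the subject's latency) and the sustained activity
#' (main narrow-band oscillation at the subject's peak frequency with
#' trial-random phase and ~10% slow amplitude jitter, plus the band-limited
#' effect components), gated to 0.3-1.5 s with 50 ms ramps.
#'
#' @param truth a [SubjectTruth-class].
#' @param cohort a [CohortConfig-class].
#' @param times sample times, s.
#' @param nTrials number of trials.
#' @return matrix nTrials x length(times), nAm.  Uses the current RNG
#'   state (callers seed).
#' @export
sourceTimecourses <- function(truth, cohort, times, nTrials) {
  nt <- length(times)
  sf <- cohort@sfreq
  sigma <- 0.05 / (2 * sqrt(2 * log(2)))          # 50 ms FWHM
  genv <- exp(-(times - truth@spikeLatency)^2 / (2 * sigma^2))
  spikePhase <- stats::runif(nTrials, 0, 2 * pi)
  narrow <- sin(outer(spikePhase, 2 * pi * truth@gammaPeakFreq * times, "+"))
  spike <- truth@spikeAmplitude * t(.bandNoise(nt, nTrials, 30, 40, sf)) +
    truth@spikeBroadAmplitude * t(.bandNoise(nt, nTrials, 40, 80, sf)) +
    truth@spikeNarrowAmplitude * narrow
  spike <- sweep(spike, 2, genv, "*")
  senv <- .rampEnvelope(times, truth@sustainedWindow[1],
                        truth@sustainedWindow[2])
  phase <- stats::runif(nTrials, 0, 2 * pi)
  jit <- 1 + 0.1 * t(.bandNoise(nt, nTrials, 0.5, 5, sf))
  carrier <- sin(outer(phase, 2 * pi * truth@gammaPeakFreq * times, "+"))
  sus <- truth@sustainedAmplitude * jit * carrier
  for (k in seq_along(truth@sustainedBandAmps))
    sus <- sus + truth@sustainedBandAmps[k] *
      t(.bandNoise(nt, nTrials, cohort@effectBands[k, 1],
                   cohort@effectBands[k, 2], sf))
  spike + sweep(sus, 2, senv, "*")
}

#' Simulate one subject's epochs
#'
#' Sensor data = leadfield(source) x source time course + pink-noise
#' background dipoles + white sensor noise, per trial.  With `truth = NULL`
#' a source-free (noise-only) subject is produced.  A synthetic head-surface
#' point cloud is attached for forward-model fitting downstream.
#'
#' @param truth a [SubjectTruth-class], or NULL for a noise-only subject.
#' @param cohort a [CohortConfig-class].
#' @param sensors a [SensorArray-class].
#' @param head a single-sphere [HeadModel-class] (simulation truth).
#' @param seed RNG seed.
#' @return list with `epochs` ([EpochsData-class]) and `truth`.
#' @export
simulateSubject <- function(truth, cohort, sensors, head = defaultHeadSphere(),
                            seed = 1L) {
  set.seed(seed)
  ntr <- cohort@nTrials
  nch <- nChannels(sensors)
  nt <- round(diff(cohort@epochWindow) * cohort@sfreq)
  times <- cohort@epochWindow[1] + (seq_len(nt) - 1) / cohort@sfreq
  D <- array(0, dim = c(ntr, nch, nt))
  if (!is.null(truth)) {
    tangNorm <- {
      ctr <- head@center[1, ]
      ur <- truth@sourceLocation - ctr
      ur <- ur / sqrt(sum(ur^2))
      sqrt(sum((truth@sourceOrientation - sum(truth@sourceOrientation * ur) * ur)^2))
    }
    if (tangNorm < 1e-12)
      stop("silent source in spherical model: orientation is purely radial")
    L <- leadfieldDipole(truth@sourceLocation, truth@sourceOrientation,
                         sensors, head)
    src <- sourceTimecourses(truth, cohort, times, ntr) * 1e-9   # nAm -> Am
    D <- D + aperm(outer(src, L), c(1, 3, 2))
  }
  ctr <- head@center[1, ]
  rad <- head@radius[1]
  nd <- cohort@nBackgroundDipoles
  if (nd > 0) {
    Lmat <- matrix(0, nd, nch)
    S <- matrix(0, ntr * nt, nd)
    for (b in seq_len(nd)) {
      repeat {
        loc <- ctr + stats::runif(3, -0.7, 0.7) * rad
        r <- sqrt(sum((loc - ctr)^2))
        if (r > 0.01 && r < 0.7 * rad) break
      }
      ur <- (loc - ctr) / sqrt(sum((loc - ctr)^2))
      v <- stats::rnorm(3)
      tang <- v - sum(v * ur) * ur
      tang <- tang / sqrt(sum(tang^2))
      Lmat[b, ] <- leadfieldDipole(loc, tang, sensors, head)
      pink <- .pinkNoise(nt, ntr, cohort@sfreq) *
        cohort@background1fLevel * 1e-9
      S[, b] <- as.vector(t(pink))            # trial-fastest (trial, time)
    }
    D <- D + aperm(array(S %*% Lmat, c(ntr, nt, nch)), c(1, 3, 2))
  }
  D <- D + array(stats::rnorm(length(D), 0, cohort@sensorNoiseLevel), dim(D))
  hs <- makeHeadPoints(head, seed = seed)
  list(epochs = epochsData(sensors, D, cohort@sfreq, times = times,
                           headshape = hs),
       truth = truth)
}

# unit-rms background noise, one column per trial: 1/f power between 1 and
# 25 Hz with a flat plateau above (MEG background spectra flatten through
# the gamma range, where sensor/system noise dominates)
.pinkNoise <- function(nt, ntr, sfreq) {
  f <- c(0, seq_len(nt - 1)) * sfreq / nt
  f <- pmin(f, sfreq - f)                    # two-sided frequency axis
  shape <- 1 / sqrt(pmax(pmin(f, 25), 1))
  X <- matrix(stats::rnorm(nt * ntr), nt, ntr)
  P <- Re(mvfft(mvfft(X) * shape, inverse = TRUE)) / nt
  sweep(P, 2, sqrt(colMeans(P^2)), "/")
}

#' Draw a cohort's ground truths
#'
#' Deterministically expands the master seed into per-subject seeds
#' (fixed counter scheme), so any subject can be re-simulated in isolation.
#'
#' @param cohort a [CohortConfig-class].
#' @param seed master seed (defaults to `cohort@seed`).
#' @return data.frame-like list with per-subject `id`, `group`, `seed`, and
#'   `truth` objects.
#' @export
drawCohortTruths <- function(cohort, seed = cohort@seed) {
  n <- cohort@nLow + cohort@nHigh
  groups <- rep(c("low", "high"), c(cohort@nLow, cohort@nHigh))
  ids <- sprintf("sub-%03d", seq_len(n))
  seeds <- vapply(seq_len(n), function(i) .subjectSeed(seed, i), integer(1))
  truths <- lapply(seq_len(n), function(i)
    makeSubjectTruth(cohort, groups[i], ids[i], seeds[i]))
  list(id = ids, group = groups, seed = seeds, truth = truths)
}

#' Simulate a full cohort
#'
#' Materialises every subject's epochs; for large cohorts prefer
#' [drawCohortTruths()] + [simulateSubject()] one subject at a time.
#'
#' @param cohort a [CohortConfig-class].
#' @param seed master seed (defaults to `cohort@seed`).
#' @return list of per-subject lists (`epochs`, `truth`, `group`, `id`).
#' @export
simulateCohort <- function(cohort, seed = cohort@seed) {
  plan <- drawCohortTruths(cohort, seed)
  sensors <- makeSensorArray(cohort@nChannels, seed)
  head <- defaultHeadSphere()
  lapply(seq_along(plan$id), function(i) {
    sim <- simulateSubject(plan$truth[[i]], cohort, sensors, head,
                           seed = plan$seed[i])
    list(epochs = sim$epochs, truth = plan$truth[[i]],
         group = plan$group[i], id = plan$id[i])
  })
}
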