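#' @import methods
NULL

.unitTol <- 1e-9

#' MEG sensor array geometry
#'
#' Positions and orientations of the gradiometer sensors in head coordinates
#' (CTF-style fiducial axes: x through the nasion, y through the left
#' pre-auricular point, z superior; origin midway between the pre-auricular
#' points; metres). Each channel is modelled as a point magnetometer reading
#' the field component along its (radial) gradiometer axis.
#'
#' @slot channelId character vector of unique channel labels.
#' @slot position n x 3 matrix of sensor positions (m).
#' @slot orientation n x 3 matrix of unit gradiometer axes.
#' @export
setClass("SensorArray",
  representation(channelId = "character",
                 position = "matrix",
                 orientation = "matrix"),
  validity = function(object) {
    n <- length(object@channelId)
    if (n < 8L) return("need at least 8 channels")
    if (anyDuplicated(object@channelId)) return("channel ids must be unique")
    if (!is.numeric(object@position) || !identical(dim(object@position), c(n, 3L)))
      return("position must be an n x 3 numeric matrix")
    if (!identical(dim(object@orientation), c(n, 3L)))
      return("orientation must be an n x 3 numeric matrix")
    if (!all(is.finite(object@position))) return("positions must be finite")
    if (!all(is.finite(object@orientation))) return("orientations must be finite")
    nrm <- sqrt(rowSums(object@orientation^2))
    if (any(abs(nrm - 1) > .unitTol))
      return("orientations must be unit-norm within 1e-9")
    TRUE
  })

#' Epoch-segmented MEG recording
#'
#' Trial x channel x time sensor data (tesla) on a uniform time grid, with
#' stimulus onset at time 0.  The epoch must contain both the baseline
#' (-1.5, 0) s and the active (0, 1.5) s analysis windows.  An optional
#' head-surface point cloud (used to fit the spherical forward model) may be
#' attached.
#'
#' @slot sensors a [SensorArray-class].
#' @slot sfreq sampling rate, Hz.
#' @slot times sample times, s, uniform grid with step 1/sfreq.
#' @slot data numeric array, trial x channel x time.
#' @slot stimulusOnset stimulus onset time, s (0 by convention).
#' @slot headshape m x 3 matrix of head-surface points (may have 0 rows).
#' @export
setClass("EpochsData",
  representation(sensors = "SensorArray",
                 sfreq = "numeric",
                 times = "numeric",
                 data = "array",
                 stimulusOnset = "numeric",
                 headshape = "matrix"),
  validity = function(object) {
    if (length(object@sfreq) != 1L || object@sfreq <= 0)
      return("sfreq must be a positive scalar")
    nt <- length(object@times)
    if (nt < 2L) return("need at least 2 samples")
    dt <- diff(object@times)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (any(abs(dt - 1 / object@sfreq) > 1e-6 / object@sfreq))
      return("times must advance in steps of 1/sfreq")
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a trial x channel x time array")
    if (d[1] < 1L) return("need at least 1 trial")
    if (d[2] != length(object@sensors@channelId))
      return("data channel dimension does not match the sensor array")
    if (d[3] != nt) return("data time dimension does not match times")
    if (!all(is.finite(object@data))) return("data must be finite (no NaN/Inf)")
    if (object@times[1] > -1.5 || object@times[nt] < 1.5)
      return("epoch must cover the baseline (-1.5,0) and active (0,1.5) windows")
    if (ncol(object@headshape) != 3L) return("headshape must have 3 columns")
    TRUE
  })

#' Analysis configuration
#'
#' Every numeric constant of the analysis chain in one validated object; see
#' [analysisConfig()] for defaults and meaning.
#'
#' @export
setClass("AnalysisConfig",
  representation(bandLo = "numeric", bandHi = "numeric",
                 tfBandwidth = "numeric", tfFilterOrder = "integer",
                 nFreqBins = "integer",
                 baselineWindow = "numeric", activeWindowImage = "numeric",
                 spikeWindow = "numeric", sustainedWindow = "numeric",
                 gridSpacing = "numeric", statsTimePoints = "integer",
                 fdrQ = "numeric", pThreshold = "numeric",
                 bootstrapB = "integer", qcHalfwidth = "numeric",
                 qcCoverage = "numeric", qcZmin = "numeric",
                 regularizationFraction = "numeric",
                 vsRegularizationFraction = "numeric", edgePad = "numeric",
                 seed = "integer"),
  validity = function(object) {
    w2 <- function(w) length(w) == 2L && w[1] < w[2]
    if (object@bandLo >= object@bandHi) return("bandLo must be < bandHi")
    if (object@bandLo <= 0) return("bandLo must be positive")
    if (object@nFreqBins < 2L) return("need at least 2 frequency bins")
    for (nm in c("baselineWindow", "activeWindowImage", "spikeWindow",
                 "sustainedWindow"))
      if (!w2(slot(object, nm))) return(sprintf("%s must be (lo, hi)", nm))
    if (object@gridSpacing <= 0) return("gridSpacing must be positive")
    if (object@fdrQ <= 0 || object@fdrQ >= 1) return("fdrQ must be in (0,1)")
    if (object@pThreshold <= 0 || object@pThreshold >= 1)
      return("pThreshold must be in (0,1)")
    if (object@bootstrapB < 1L) return("bootstrapB must be >= 1")
    if (object@qcCoverage <= 0 || object@qcCoverage > 1)
      return("qcCoverage must be in (0,1]")
    if (object@regularizationFraction < 0)
      return("regularizationFraction must be >= 0")
    if (object@edgePad < 0) return("edgePad must be >= 0")
    TRUE
  })

#' Spherical conductor head model
#'
#' Either a single sphere shared by all channels or one local sphere per
#' channel (multiple local-spheres model).
#'
#' @slot mode "single_sphere" or "local_spheres".
#' @slot center k x 3 matrix of sphere centres (k = 1 or n channels), m.
#' @slot radius sphere radii, m (length k).
#' @export
setClass("HeadModel",
  representation(mode = "character", center = "matrix", radius = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("single_sphere", "local_spheres"))
      return("mode must be single_sphere or local_spheres")
    if (nrow(object@center) != length(object@radius))
      return("one radius per sphere centre required")
    if (object@mode == "single_sphere" && nrow(object@center) != 1L)
      return("single_sphere mode requires exactly one sphere")
    if (any(object@radius <= 0)) return("radii must be positive")
    if (!all(is.finite(object@center))) return("centres must be finite")
    TRUE
  })

#' Volumetric source grid
#'
#' Axis-aligned lattice of candidate source locations clipped to the interior
#' of the head sphere, with a posterior ("occipital") search mask defined as
#' the posterior third along the anterior-posterior (x) axis.
#'
#' @slot spacing lattice spacing, m.
#' @slot origin reference sphere centre, m.
#' @slot voxels n x 3 matrix of voxel centres, m.
#' @slot posteriorMask logical per voxel.
#' @export
setClass("SourceGrid",
  representation(spacing = "numeric", origin = "numeric",
                 voxels = "matrix", posteriorMask = "logical"),
  validity = function(object) {
    if (object@spacing <= 0) return("spacing must be positive")
    if (nrow(object@voxels) < 1L) return("grid has no voxels")
    if (length(object@posteriorMask) != nrow(object@voxels))
      return("posteriorMask length must match voxel count")
    if (!any(object@posteriorMask)) return("posterior mask is empty")
    TRUE
  })

#' Dipole lead fields on a source grid
#'
#' Per retained voxel, the channel x 2 gain matrix for unit dipoles along the
#' two tangential basis vectors (a radial dipole is silent in a spherical
#' conductor, so only the tangential plane is parameterised).
#'
#' @slot grid the [SourceGrid-class] the fields were computed on.
#' @slot keep indices of grid voxels retained (others were within 1 mm of a
#'   sphere centre).
#' @slot gain array channel x 2 x nkeep, tesla per Am.
#' @slot basis array 3 x 2 x nkeep of tangential unit vectors.
#' @slot channelId channel labels the gains refer to.
#' @export
setClass("LeadField",
  representation(grid = "SourceGrid", keep = "integer", gain = "array",
                 basis = "array", channelId = "character"),
  validity = function(object) {
    d <- dim(object@gain)
    if (length(d) != 3L || d[2] != 2L) return("gain must be channel x 2 x nvox")
    if (d[3] != length(object@keep)) return("gain voxel count mismatch")
    if (d[1] != length(object@channelId)) return("gain channel count mismatch")
    if (!all(is.finite(object@gain))) return("gain must be finite")
    TRUE
  })

#' Band-limited sensor covariance
#'
#' Sample covariance of band-filtered epochs over a time window, with
#' diagonal loading.  `matrix` is the regularised covariance used for the
#' beamformer weights; `raw` is the unregularised estimate (its smallest
#' eigenvalue is the sensor-noise power used by the pseudo-t statistic).
#'
#' @export
setClass("CovarianceMatrix",
  representation(matrix = "matrix", raw = "matrix", window = "numeric",
                 band = "numeric", nSamples = "integer", lambda = "numeric"),
  validity = function(object) {
    if (nrow(object@matrix) != ncol(object@matrix)) return("must be square")
    if (max(abs(object@matrix - t(object@matrix))) > 1e-12 * max(abs(object@matrix), 1e-300))
      return("covariance must be symmetric")
    if (!all(is.finite(object@matrix))) return("covariance must be finite")
    TRUE
  })

#' Pseudo-t source image
#'
#' Voxelwise (active - baseline) source power contrast normalised by the
#' projected sensor-noise power, with the optimised source orientation and
#' the beamformer weights per voxel.
#'
#' @export
setClass("StatImage",
  representation(grid = "SourceGrid", keep = "integer", pseudoT = "numeric",
                 orientation = "matrix", weights = "matrix", sigma2 = "numeric"),
  validity = function(object) {
    n <- length(object@keep)
    if (length(object@pseudoT) != n) return("pseudoT length mismatch")
    if (!all(is.finite(object@pseudoT))) return("pseudoT must be finite")
    if (nrow(object@orientation) != n) return("orientation rows mismatch")
    TRUE
  })

#' Selected peak voxel
#'
#' The voxel with the largest positive pseudo-t inside the posterior mask,
#' with the beamformer weights used for virtual-sensor extraction.
#'
#' @export
setClass("PeakVoxel",
  representation(index = "integer", location = "numeric", pseudoT = "numeric",
                 weights = "numeric", orientation = "numeric"),
  validity = function(object) {
    if (length(object@location) != 3L) return("location must be a 3-vector")
    if (object@pseudoT <= 0) return("peak pseudo-t must be positive")
    TRUE
  })

#' Virtual sensor (source time series)
#'
#' Trial x time source amplitude at the selected voxel, in nAm (unit-gain
#' beamformer output scaled to nanoampere-metres).
#'
#' @export
setClass("VirtualSensor",
  representation(data = "matrix", sfreq = "numeric", times = "numeric"),
  validity = function(object) {
    if (ncol(object@data) != length(object@times))
      return("data columns must match times")
    if (!all(is.finite(object@data))) return("data must be finite")
    TRUE
  })

#' Per-trial Hilbert-envelope spectrograms
#'
#' Raw envelope (not baseline-normalised) per trial, frequency and time.
#' `edgeOK` flags samples far enough from the epoch edges that filter and
#' Hilbert transients are negligible.
#'
#' @export
setClass("TrialSpectrograms",
  representation(values = "array", freqs = "numeric", times = "numeric",
                 edgeOK = "logical"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("values must be trial x freq x time")
    if (d[2] != length(object@freqs)) return("frequency dimension mismatch")
    if (d[3] != length(object@times)) return("time dimension mismatch")
    if (length(object@edgeOK) != length(object@times))
      return("edgeOK length mismatch")
    TRUE
  })

#' Time-frequency map
#'
#' Frequency x time matrix; for kind "induced" the values are percent change
#' from the per-trial baseline mean, averaged over trials.
#'
#' @export
setClass("TFMap",
  representation(values = "matrix", freqs = "numeric", times = "numeric",
                 edgeOK = "logical", kind = "character"),
  validity = function(object) {
    if (nrow(object@values) != length(object@freqs))
      return("rows must match freqs")
    if (ncol(object@values) != length(object@times))
      return("columns must match times")
    if (is.unsorted(object@freqs, strictly = TRUE))
      return("freqs must be strictly increasing")
    TRUE
  })

#' Window-averaged spectrum
#'
#' Percent change from baseline of the window-averaged envelope, per
#' frequency bin, averaged over trials.
#'
#' @export
setClass("SpectrumSummary",
  representation(freqs = "numeric", pctChange = "numeric",
                 activeWindow = "numeric", baselineWindow = "numeric"),
  validity = function(object) {
    if (length(object@pctChange) != length(object@freqs))
      return("pctChange length must match freqs")
    if (!all(is.finite(object@pctChange))) return("pctChange must be finite")
    TRUE
  })

#' Gamma peak parameters
#'
#' Frequency, amplitude (percent change) and latency of the maximum of the
#' induced time-frequency map within an extraction window.
#'
#' @export
setClass("GammaPeak",
  representation(frequency = "numeric", amplitude = "numeric",
                 latency = "numeric", window = "numeric"))

#' Bootstrap distribution of gamma-peak estimates
#'
#' @slot peakFreqs peak frequency per bootstrap resample, Hz.
#' @slot peakAmps peak amplitude per resample, percent change.
#' @slot B number of resamples.
#' @slot seed RNG seed used.
#' @export
setClass("BootstrapDistribution",
  representation(peakFreqs = "numeric", peakAmps = "numeric",
                 B = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@peakFreqs) != object@B) return("peakFreqs length != B")
    if (length(object@peakAmps) != object@B) return("peakAmps length != B")
    TRUE
  })

#' Subject-level reliability verdict
#'
#' @slot modeFreq centre of the maximal-coverage 4 Hz window, Hz.
#' @slot coverage fraction of bootstrap peak frequencies within +/-2 Hz of it.
#' @slot ampZ mean/sd of the bootstrap peak amplitudes.
#' @slot passCoverage,passZ,pass criterion flags.
#' @export
setClass("QCResult",
  representation(modeFreq = "numeric", coverage = "numeric", ampZ = "numeric",
                 passCoverage = "logical", passZ = "logical", pass = "logical"),
  validity = function(object) {
    if (object@coverage < 0 || object@coverage > 1)
      return("coverage must be in [0,1]")
    if (!identical(object@pass, object@passCoverage && object@passZ))
      return("pass must equal passCoverage AND passZ")
    TRUE
  })

#' Group contrast result
#'
#' Rank-sum z and p maps (raw and BH-adjusted), significance mask, per-bin
#' Cohen's d (window contrasts) and maximal contiguous significant frequency
#' bands.  Positive z / positive d mean the first (low-risk) group exceeds
#' the second (high-risk) group.
#'
#' @export
setClass("GroupContrast",
  representation(freqs = "numeric", times = "numeric", z = "matrix",
                 pRaw = "matrix", pAdj = "matrix", sigMask = "matrix",
                 d = "numeric", bands = "matrix", window = "character",
                 nA = "integer", nB = "integer"),
  validity = function(object) {
    if (any(object@pRaw < 0 | object@pRaw > 1)) return("p values must be in [0,1]")
    if (any(object@pAdj < 0 | object@pAdj > 1)) return("adjusted p must be in [0,1]")
    if (!identical(dim(object@z), dim(object@pRaw))) return("z/p shape mismatch")
    if (ncol(object@bands) != 2L) return("bands must be k x 2")
    TRUE
  })

#' Ground truth for one simulated subject
#'
#' @slot sourceLocation dipole location, m (head coordinates).
#' @slot sourceOrientation unit tangential dipole orientation.
#' @slot gammaPeakFreq sustained narrow-band gamma frequency, Hz.
#' @slot spikeLatency centre of the transient burst envelope, s.
#' @slot spikeAmplitude 30-40 Hz burst component amplitude, nAm (carries the
#'   spike-window group effect).
#' @slot spikeBroadAmplitude 40-80 Hz burst remainder amplitude, nAm.
#' @slot spikeNarrowAmplitude amplitude of the burst's narrow-band component
#'   at the subject's gamma frequency, nAm.
#' @slot sustainedAmplitude main narrow-band oscillation amplitude, nAm.
#' @slot sustainedBandAmps named amplitudes (nAm) of the band-limited
#'   sustained components carrying the sustained group effects.
#' @slot spikeWindow,sustainedWindow response windows, s.
#' @slot snrSensor nominal sensor-level amplitude SNR (informative).
#' @export
setClass("SubjectTruth",
  representation(subjectId = "character", sourceLocation = "numeric",
                 sourceOrientation = "numeric", gammaPeakFreq = "numeric",
                 spikeLatency = "numeric", spikeAmplitude = "numeric",
                 spikeBroadAmplitude = "numeric",
                 spikeNarrowAmplitude = "numeric",
                 sustainedAmplitude = "numeric",
                 sustainedBandAmps = "numeric", spikeWindow = "numeric",
                 sustainedWindow = "numeric", snrSensor = "numeric"),
  validity = function(object) {
    if (length(object@sourceLocation) != 3L) return("location must be a 3-vector")
    if (abs(sqrt(sum(object@sourceOrientation^2)) - 1) > 1e-6)
      return("orientation must be unit-norm")
    if (object@gammaPeakFreq <= 30 || object@gammaPeakFreq >= 90)
      return("gamma peak frequency must be inside (30, 90) Hz")
    if (object@sustainedAmplitude <= 0 || object@spikeAmplitude <= 0)
      return("amplitudes must be positive")
    TRUE
  })

#' Cohort simulation configuration
#'
#' See [cohortConfig()] for defaults and the meaning of every field.
#'
#' @export
setClass("CohortConfig",
  representation(nLow = "integer", nHigh = "integer", nTrials = "integer",
                 nChannels = "integer", sfreq = "numeric",
                 epochWindow = "numeric", freqMean = "numeric",
                 freqSd = "numeric", freqClip = "numeric",
                 latencyMean = "numeric", latencySd = "numeric",
                 effectDSpike = "numeric", effectBands = "matrix",
                 effectDSustained = "numeric",
                 sustainedAmpMean = "numeric", sustainedAmpSd = "numeric",
                 spikeAmpMean = "numeric", spikeAmpSd = "numeric",
                 spikeBroadAmp = "numeric", spikeNarrowAmp = "numeric",
                 bandAmpMean = "numeric",
                 bandAmpSd = "numeric", background1fLevel = "numeric",
                 sensorNoiseLevel = "numeric", nBackgroundDipoles = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (object@nLow < 1L || object@nHigh < 1L) return("group sizes must be >= 1")
    if (object@nTrials < 1L) return("nTrials must be >= 1")
    if (object@effectDSpike < 0 || any(object@effectDSustained < 0))
      return("effect sizes must be >= 0")
    if (nrow(object@effectBands) != length(object@effectDSustained))
      return("one sustained effect size per band required")
    lo <- object@freqClip[1]; hi <- object@freqClip[2]
    if (lo <= 30 || hi >= 90) return("freqClip must lie inside (30, 90) Hz")
    TRUE
  })

#' Per-subject analysis result
#'
#' Bundles every subject-level output of the pipeline plus the exclusion
#' verdict.  Excluded subjects carry no downstream statistics beyond the
#' stage at which they were excluded.
#'
#' @export
setClass("SubjectResult",
  representation(subjectId = "character", groupLabel = "character",
                 peak = "ANY", tfInduced = "ANY", spikeSpectrum = "ANY",
                 sustainedSpectrum = "ANY", gammaPeak = "ANY", qc = "ANY",
                 excluded = "logical", exclusionReason = "character"))

#' Cohort-level results
#'
#' Per-subject results, the exclusion log, and the group contrasts computed
#' on the QC-passed subjects.
#'
#' @export
setClass("CohortResults",
  representation(subjects = "list", exclusions = "data.frame",
                 tfContrast = "ANY", spikeContrast = "ANY",
                 sustainedContrast = "ANY", peakComparison = "ANY",
                 config = "AnalysisConfig"))
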