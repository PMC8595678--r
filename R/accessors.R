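#' @describeIn nChannels channel count of a sensor array
#' @export
setMethod("nChannels", "SensorArray", function(x) length(x@channelId))

#' @describeIn nChannels channel count of an epochs object
#' @export
setMethod("nChannels", "EpochsData", function(x) nChannels(x@sensors))

#' @describeIn nChannels channel count of a lead field
#' @export
setMethod("nChannels", "LeadField", function(x) length(x@channelId))

#' @describeIn nTrials trial count of an epochs object
#' @export
setMethod("nTrials", "EpochsData", function(x) dim(x@data)[1])

#' @describeIn nTrials trial count of a virtual sensor
#' @export
setMethod("nTrials", "VirtualSensor", function(x) nrow(x@data))

#' @describeIn nTrials trial count of per-trial spectrograms
#' @export
setMethod("nTrials", "TrialSpectrograms", function(x) dim(x@values)[1])

#' @describeIn samplingRate sampling rate of an epochs object
#' @export
setMethod("samplingRate", "EpochsData", function(x) x@sfreq)

#' @describeIn samplingRate sampling rate of a virtual sensor
#' @export
setMethod("samplingRate", "VirtualSensor", function(x) x@sfreq)

#' @describeIn epochTimes times of an epochs object
#' @export
setMethod("epochTimes", "EpochsData", function(x) x@times)

#' @describeIn epochTimes times of a virtual sensor
#' @export
setMethod("epochTimes", "VirtualSensor", function(x) x@times)

#' @describeIn epochTimes times of a time-frequency map
#' @export
setMethod("epochTimes", "TFMap", function(x) x@times)

#' @describeIn epochTimes times of per-trial spectrograms
#' @export
setMethod("epochTimes", "TrialSpectrograms", function(x) x@times)

#' @describeIn channelIds labels of a sensor array
#' @export
setMethod("channelIds", "SensorArray", function(x) x@channelId)

#' @describeIn channelIds labels of an epochs object
#' @export
setMethod("channelIds", "EpochsData", function(x) x@sensors@channelId)

#' @describeIn nVoxels voxel count of a source grid
#' @export
setMethod("nVoxels", "SourceGrid", function(x) nrow(x@voxels))

#' @describeIn nVoxels retained voxel count of a lead field
#' @export
setMethod("nVoxels", "LeadField", function(x) length(x@keep))

#' @describeIn nVoxels retained voxel count of a stat image
#' @export
setMethod("nVoxels", "StatImage", function(x) length(x@keep))

#' @describeIn frequencies frequency grid of a TF map
#' @export
setMethod("frequencies", "TFMap", function(x) x@freqs)

#' @describeIn frequencies frequency grid of per-trial spectrograms
#' @export
setMethod("frequencies", "TrialSpectrograms", function(x) x@freqs)

#' @describeIn frequencies frequency grid of a spectrum summary
#' @export
setMethod("frequencies", "SpectrumSummary", function(x) x@freqs)

#' @describeIn frequencies frequency grid of a group contrast
#' @export
setMethod("frequencies", "GroupContrast", function(x) x@freqs)

#' @describeIn isExcluded exclusion flag of a subject result
#' @export
setMethod("isExcluded", "SubjectResult", function(x) x@excluded)

#' @describeIn isExcluded TRUE when the QC gate failed
#' @export
setMethod("isExcluded", "QCResult", function(x) !x@pass)

setMethod("show", "SensorArray", function(object) {
  cat(sprintf("SensorArray: %d channels\n", nChannels(object)))
  r <- range(object@position[, 3])
  cat(sprintf("  z range %.3f to %.3f m\n", r[1], r[2]))
})

setMethod("show", "EpochsData", function(object) {
  cat(sprintf("EpochsData: %d trials x %d channels x %d samples @ %g Hz\n",
              nTrials(object), nChannels(object), length(object@times),
              object@sfreq))
  cat(sprintf("  epoch %.3f to %.3f s (stimulus onset at %g s)\n",
              object@times[1], object@times[length(object@times)],
              object@stimulusOnset))
  if (nrow(object@headshape) > 0)
    cat(sprintf("  headshape: %d points\n", nrow(object@headshape)))
})

setMethod("show", "HeadModel", function(object) {
  cat(sprintf("HeadModel (%s): %d sphere(s), mean radius %.1f mm\n",
              object@mode, nrow(object@center), 1000 * mean(object@radius)))
})

setMethod("show", "SourceGrid", function(object) {
  cat(sprintf("SourceGrid: %d voxels, %.0f mm spacing, %d in posterior mask\n",
              nVoxels(object), 1000 * object@spacing, sum(object@posteriorMask)))
})

setMethod("show", "StatImage", function(object) {
  cat(sprintf("StatImage: %d voxels, pseudo-t range [%.2f, %.2f]\n",
              nVoxels(object), min(object@pseudoT), max(object@pseudoT)))
})

setMethod("show", "PeakVoxel", function(object) {
  cat(sprintf("PeakVoxel: t = %.2f at (%.1f, %.1f, %.1f) mm\n",
              object@pseudoT, 1000 * object@location[1],
              1000 * object@location[2], 1000 * object@location[3]))
})

setMethod("show", "TFMap", function(object) {
  cat(sprintf("TFMap (%s): %d freqs x %d times, range [%.1f, %.1f]\n",
              object@kind, length(object@freqs), length(object@times),
              min(object@values), max(object@values)))
})

setMethod("show", "GammaPeak", function(object) {
  cat(sprintf("GammaPeak: %.1f Hz, %.1f%% change, latency %.3f s\n",
              object@frequency, object@amplitude, object@latency))
})

setMethod("show", "QCResult", function(object) {
  cat(sprintf(
    "QCResult: %s (coverage %.2f at %.1f Hz, amplitude z %.2f)\n",
    if (object@pass) "PASS" else "FAIL", object@coverage, object@modeFreq,
    object@ampZ))
})

setMethod("show", "GroupContrast", function(object) {
  cat(sprintf("GroupContrast (%s): %d x %d points, %d significant, n = %d/%d\n",
              object@window, nrow(object@z), ncol(object@z),
              sum(object@sigMask), object@nA, object@nB))
  if (nrow(object@bands) > 0)
    cat(sprintf("  bands: %s\n",
                paste(sprintf("%.1f-%.1f Hz", object@bands[, 1],
                              object@bands[, 2]), collapse = ", ")))
})

setMethod("show", "SubjectResult", function(object) {
  cat(sprintf("SubjectResult %s [%s]: %s\n", object@subjectId,
              object@groupLabel,
              if (object@excluded)
                paste("EXCLUDED -", object@exclusionReason)
              else "analyzed"))
})

setMethod("show", "CohortResults", function(object) {
  n <- length(object@subjects)
  nex <- sum(vapply(object@subjects, isExcluded, logical(1)))
  cat(sprintf("CohortResults: %d subjects (%d excluded, %d analyzed)\n",
              n, nex, n - nex))
})
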