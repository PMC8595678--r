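#' Number of channels
#' @param x a SensorArray, EpochsData, or LeadField.
#' @return integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of trials
#' @param x an EpochsData, VirtualSensor, or TrialSpectrograms.
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Sampling rate in Hz
#' @param x an EpochsData or VirtualSensor.
#' @return sampling rate, Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Sample times in seconds
#' @param x an EpochsData, VirtualSensor, TFMap or TrialSpectrograms.
#' @return numeric vector of sample times, s.
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))

#' Channel labels
#' @param x a SensorArray or EpochsData.
#' @return character vector of channel ids.
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' Number of voxels
#' @param x a SourceGrid, LeadField or StatImage.
#' @return integer voxel count.
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Frequency grid of a time-frequency object
#' @param x a TFMap, TrialSpectrograms, SpectrumSummary or GroupContrast.
#' @return numeric vector of centre frequencies, Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Did the subject pass all gates?
#' @param x a SubjectResult or QCResult.
#' @return logical.
#' @export
setGeneric("isExcluded", function(x) standardGeneric("isExcluded"))
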