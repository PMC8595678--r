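## On-disk containers.
##
## Epochs container (HDF5):
##   /data                 float64, trial x channel x time (tesla)
##   /times                float64, s
##   /sensors/id           strings
##   /sensors/position     channel x 3, m
##   /sensors/orientation  channel x 3, unit vectors
##   /headshape            optional, m x 3 points
##   root attributes: sfreq (Hz), stimulus_onset (s)
## Subject results are a second HDF5 layout (induced map, window spectra,
## peak, QC); cohort-level tables are CSV, band intervals JSON, and the
## pseudo-t image exports to NIfTI with a JSON sidecar.

#' Write epochs to the HDF5 container
#'
#' @param epochs a valid [EpochsData-class].
#' @param path output file path.
#' @param overwrite overwrite an existing file (default FALSE: refuse).
#' @return `path`, invisibly.
#' @export
writeEpochs <- function(epochs, path, overwrite = FALSE) {
  validObject(epochs)
  if (file.exists(path)) {
    if (!overwrite) stop("file exists; use overwrite = TRUE to replace: ", path)
    unlink(path)
  }
  if (!dir.exists(dirname(path))) stop("unwritable path: ", dirname(path))
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs@data, path, "data")
  rhdf5::h5write(epochs@times, path, "times")
  rhdf5::h5createGroup(path, "sensors")
  rhdf5::h5write(epochs@sensors@channelId, path, "sensors/id")
  rhdf5::h5write(epochs@sensors@position, path, "sensors/position")
  rhdf5::h5write(epochs@sensors@orientation, path, "sensors/orientation")
  if (nrow(epochs@headshape) > 0)
    rhdf5::h5write(epochs@headshape, path, "headshape")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs@sfreq, fid, "sfreq")
  rhdf5::h5writeAttribute(epochs@stimulusOnset, fid, "stimulus_onset")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read epochs from the HDF5 container
#'
#' @param path container file path.
#' @return a validated [EpochsData-class].
#' @export
readEpochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path)
  ds <- file.path(sub("^/$", "", have$group), have$name)
  ds <- sub("^/", "", ds)
  for (need in c("data", "times", "sensors/id", "sensors/position",
                 "sensors/orientation"))
    if (!need %in% ds)
      stop("format error: dataset '", need, "' missing from ", path)
  at <- rhdf5::h5readAttributes(path, "/")
  for (need in c("sfreq", "stimulus_onset"))
    if (is.null(at[[need]]))
      stop("format error: attribute '", need, "' missing from ", path)
  hs <- if ("headshape" %in% ds) rhdf5::h5read(path, "headshape") else NULL
  sens <- sensorArray(as.character(rhdf5::h5read(path, "sensors/id")),
                      rhdf5::h5read(path, "sensors/position"),
                      rhdf5::h5read(path, "sensors/orientation"))
  epochsData(sens, rhdf5::h5read(path, "data"),
             sfreq = as.numeric(at$sfreq),
             times = as.numeric(rhdf5::h5read(path, "times")),
             stimulusOnset = as.numeric(at$stimulus_onset),
             headshape = hs)
}

#' Write a subject's results to HDF5
#'
#' Excluded subjects get whatever stages completed; the exclusion flag and
#' reason are always written.
#'
#' @param res a [SubjectResult-class].
#' @param path output file path.
#' @param overwrite overwrite an existing file.
#' @return `path`, invisibly.
#' @export
writeSubjectResult <- function(res, path, overwrite = FALSE) {
  if (file.exists(path)) {
    if (!overwrite) stop("file exists; use overwrite = TRUE to replace: ", path)
    unlink(path)
  }
  rhdf5::h5createFile(path)
  rhdf5::h5write(res@subjectId, path, "subject_id")
  rhdf5::h5write(res@groupLabel, path, "group")
  rhdf5::h5write(as.integer(res@excluded), path, "excluded")
  rhdf5::h5write(res@exclusionReason, path, "exclusion_reason")
  if (is(res@tfInduced, "TFMap")) {
    rhdf5::h5createGroup(path, "tf_induced")
    rhdf5::h5write(res@tfInduced@values, path, "tf_induced/values")
    rhdf5::h5write(res@tfInduced@freqs, path, "tf_induced/freqs")
    rhdf5::h5write(res@tfInduced@times, path, "tf_induced/times")
  }
  if (is(res@spikeSpectrum, "SpectrumSummary") ||
      is(res@sustainedSpectrum, "SpectrumSummary")) {
    rhdf5::h5createGroup(path, "spectra")
    for (nm in c("spike", "sustained")) {
      sp <- slot(res, paste0(nm, "Spectrum"))
      if (is(sp, "SpectrumSummary")) {
        rhdf5::h5createGroup(path, paste0("spectra/", nm))
        rhdf5::h5write(sp@freqs, path, paste0("spectra/", nm, "/freqs"))
        rhdf5::h5write(sp@pctChange, path,
                       paste0("spectra/", nm, "/pct_change"))
      }
    }
  }
  if (is(res@peak, "PeakVoxel")) {
    rhdf5::h5createGroup(path, "peak")
    rhdf5::h5write(res@peak@location, path, "peak/location")
    rhdf5::h5write(res@peak@pseudoT, path, "peak/pseudo_t")
    rhdf5::h5write(res@peak@weights, path, "peak/weights")
  }
  if (is(res@gammaPeak, "GammaPeak")) {
    rhdf5::h5createGroup(path, "gamma_peak")
    rhdf5::h5write(res@gammaPeak@frequency, path, "gamma_peak/frequency_hz")
    rhdf5::h5write(res@gammaPeak@amplitude, path, "gamma_peak/amplitude_pct")
    rhdf5::h5write(res@gammaPeak@latency, path, "gamma_peak/latency_s")
  }
  if (is(res@qc, "QCResult")) {
    rhdf5::h5createGroup(path, "qc")
    rhdf5::h5write(res@qc@coverage, path, "qc/coverage")
    rhdf5::h5write(res@qc@modeFreq, path, "qc/mode_freq_hz")
    rhdf5::h5write(res@qc@ampZ, path, "qc/amp_z")
    rhdf5::h5write(as.integer(res@qc@pass), path, "qc/pass")
  }
  invisible(path)
}

#' Cohort summary tables
#'
#' One row per subject: gamma-peak parameters, QC verdict, exclusion status.
#'
#' @param cohort a [CohortResults-class].
#' @return data.frame.
#' @export
cohortSummaryTable <- function(cohort) {
  rows <- lapply(cohort@subjects, function(s) {
    gp <- s@gammaPeak
    qc <- s@qc
    data.frame(
      subject_id = s@subjectId, group = s@groupLabel,
      peak_freq_hz = if (is(gp, "GammaPeak")) gp@frequency else NA_real_,
      peak_amp_pct = if (is(gp, "GammaPeak")) gp@amplitude else NA_real_,
      peak_latency_s = if (is(gp, "GammaPeak")) gp@latency else NA_real_,
      qc_coverage = if (is(qc, "QCResult")) qc@coverage else NA_real_,
      qc_amp_z = if (is(qc, "QCResult")) qc@ampZ else NA_real_,
      qc_pass = if (is(qc, "QCResult")) qc@pass else FALSE,
      excluded = s@excluded,
      reason = if (s@excluded) s@exclusionReason else "")
  })
  do.call(rbind, rows)
}

# contrast -> CSV-ready data.frame (window spectra contrasts)
.contrastTable <- function(ct) {
  data.frame(freq_hz = ct@freqs, d = ct@d, z = as.numeric(ct@z),
             p_raw = as.numeric(ct@pRaw), p_adj = as.numeric(ct@pAdj),
             significant = as.logical(ct@sigMask))
}

#' Write cohort outputs to a directory
#'
#' subjects.csv, exclusions.csv, per-window contrast CSVs
#' (freq_hz, d, z, p_raw, p_adj, significant), the significant band
#' intervals as JSON, and the peak-parameter comparison table.
#'
#' @param cohort a [CohortResults-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohortSummaryTable(cohort)
  utils::write.csv(tab, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(tab[tab$excluded, c("subject_id", "group", "qc_coverage",
                                       "qc_amp_z", "qc_pass", "reason")],
                   file.path(dir, "exclusions.csv"), row.names = FALSE)
  bands <- list()
  for (nm in c("spikeContrast", "sustainedContrast")) {
    ct <- slot(cohort, nm)
    if (is(ct, "GroupContrast")) {
      lbl <- sub("Contrast$", "", nm)
      utils::write.csv(.contrastTable(ct),
                       file.path(dir, sprintf("contrast_%s.csv", lbl)),
                       row.names = FALSE)
      bands[[lbl]] <- if (nrow(ct@bands) > 0)
        apply(ct@bands, 1, function(b) list(lo_hz = b[1], hi_hz = b[2]))
      else list()
    }
  }
  jsonlite::write_json(bands, file.path(dir, "significant_bands.json"),
                       auto_unbox = TRUE, digits = NA)
  if (is.data.frame(cohort@peakComparison))
    utils::write.csv(cohort@peakComparison,
                     file.path(dir, "peak_comparison.csv"), row.names = FALSE)
  invisible(dir)
}

#' Export a pseudo-t image to NIfTI
#'
#' Rasterises the pseudo-t values onto the full source lattice (dropped or
#' out-of-sphere voxels are 0) and writes a NIfTI volume with the grid
#' spacing as voxel size, plus a JSON sidecar recording the grid origin and
#' axis convention.
#'
#' @param image a [StatImage-class].
#' @param path output path (".nii" or ".nii.gz").
#' @return `path`, invisibly.
#' @export
statImageToNifti <- function(image, path) {
  vox <- image@grid@voxels
  sp <- image@grid@spacing
  ax <- lapply(1:3, function(j) sort(unique(round(vox[, j] / sp))))
  dims <- vapply(ax, length, integer(1))
  vol <- array(0, dims)
  idx <- vapply(1:3, function(j)
    match(round(vox[, j] / sp), ax[[j]]), integer(nrow(vox)))
  sel <- idx[image@keep, , drop = FALSE]
  vol[sel] <- image@pseudoT
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(sp * 1000, 3)                 # mm voxels
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(
    origin_m = as.numeric(c(ax[[1]][1], ax[[2]][1], ax[[3]][1]) * sp),
    spacing_m = sp,
    axes = "CTF-style head coordinates: +x anterior (nasion), +y left, +z superior",
    sigma2 = image@sigma2),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
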