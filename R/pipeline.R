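## Subject- and cohort-level orchestration.
##
## Per subject: fit the head model from the attached head-surface cloud,
## band-filter, covariances (weights from all epoched data; active and
## baseline windows enter only through projected powers), pseudo-t image,
## occipital peak, virtual sensor, Hilbert time-frequency analysis, gamma
## peak, window spectra, bootstrap QC.  Two exclusion gates mirror the
## study design: no positive occipital pseudo-t peak, and QC failure.
## Cohort level: rank-sum TF and spectrum contrasts with FDR on the
## QC-passed subjects, plus the gamma-peak parameter comparison.

#' Analyse one subject
#'
#' Runs the full subject-level chain and returns a [SubjectResult-class];
#' exclusion gates (no positive occipital peak; bootstrap QC failure) are
#' applied and logged rather than raised.
#'
#' @param epochs an [EpochsData-class] (with a headshape cloud attached
#'   unless `head` is given).
#' @param cfg an [AnalysisConfig-class].
#' @param subjectId label for logs and outputs.
#' @param groupLabel "low" or "high".
#' @param head optional [HeadModel-class]; fitted from the headshape cloud
#'   (local spheres) when missing.
#' @param leadfield optional precomputed [LeadField-class] (reused across
#'   subjects sharing a head model and grid).
#' @param qcWindow peak-extraction window used by the bootstrap gate; the
#'   default is the whole stimulation period, which pools the transient and
#'   sustained evidence for the subject's peak frequency.
#' @return a [SubjectResult-class].
#' @export
runSubject <- function(epochs, cfg = analysisConfig(), subjectId = "sub-01",
                       groupLabel = "low", head = NULL, leadfield = NULL,
                       qcWindow = cfg@activeWindowImage) {
  if (is.null(head)) {
    if (nrow(epochs@headshape) == 0)
      stop("no head model given and no headshape cloud attached")
    head <- fitHeadModel(epochs@headshape, epochs@sensors,
                         mode = "local_spheres")
  }
  filt <- bandFilter(epochs, c(cfg@bandLo, cfg@bandHi))
  allWin <- range(cfg@baselineWindow, cfg@activeWindowImage)
  covAll <- computeCovariance(filt, allWin, cfg@regularizationFraction,
                              band = c(cfg@bandLo, cfg@bandHi))
  covAct <- computeCovariance(filt, cfg@activeWindowImage, 0,
                              band = c(cfg@bandLo, cfg@bandHi))
  covBase <- computeCovariance(filt, cfg@baselineWindow, 0,
                               band = c(cfg@bandLo, cfg@bandHi))
  if (is.null(leadfield)) {
    grid <- buildGrid(head, cfg@gridSpacing)
    leadfield <- computeLeadfields(grid, epochs@sensors, head)
  }
  image <- pseudoTImage(leadfield, covAll, covAct, covBase)
  peak <- tryCatch(findPeakVoxel(image), vgammaNoPositivePeak = function(e) e)
  if (inherits(peak, "condition")) {
    message(subjectId, ": excluded (no positive occipital peak)")
    return(new("SubjectResult", subjectId = subjectId,
               groupLabel = groupLabel, peak = NULL, tfInduced = NULL,
               spikeSpectrum = NULL, sustainedSpectrum = NULL,
               gammaPeak = NULL, qc = NULL, excluded = TRUE,
               exclusionReason = "no positive occipital peak"))
  }
  peak <- .reweightPeak(peak, leadfield, covAll, cfg@vsRegularizationFraction)
  vs <- extractVirtualSensor(epochs, peak)
  tmaps <- trialSpectrograms(vs, cfg)
  induced <- inducedPercentChange(tmaps, cfg@baselineWindow)
  gpeak <- extractGammaPeak(induced, cfg@spikeWindow,
                            c(cfg@bandLo, cfg@bandHi))
  spike <- windowSpectrum(tmaps, cfg@spikeWindow, cfg@baselineWindow)
  sust <- windowSpectrum(tmaps, cfg@sustainedWindow, cfg@baselineWindow)
  boot <- bootstrapPeaks(tmaps, cfg, seed = cfg@seed, window = qcWindow)
  qc <- qcEvaluate(boot, cfg)
  if (!qc@pass)
    message(subjectId, sprintf(
      ": excluded by QC (coverage %.2f, amp z %.2f)", qc@coverage, qc@ampZ))
  new("SubjectResult", subjectId = subjectId, groupLabel = groupLabel,
      peak = peak, tfInduced = induced, spikeSpectrum = spike,
      sustainedSpectrum = sust, gammaPeak = gpeak, qc = qc,
      excluded = !qc@pass,
      exclusionReason = if (qc@pass) "" else "failed bootstrap QC")
}

#' Cohort-level statistics over subject results
#'
#' Applies the exclusion accounting, then computes the time-frequency
#' contrast, the spike- and sustained-window spectrum contrasts, and the
#' gamma-peak parameter comparison over the retained subjects.  If either
#' group is left with fewer than 2 subjects, an error of class
#' `vgammaEmptyGroup` is raised; the per-subject results remain available
#' in the condition's `subjects` field.
#'
#' @param results list of [SubjectResult-class].
#' @param cfg an [AnalysisConfig-class].
#' @return a [CohortResults-class].
#' @export
cohortStatistics <- function(results, cfg = analysisConfig()) {
  labels <- vapply(results, function(s) s@groupLabel, character(1))
  keep <- !vapply(results, isExcluded, logical(1))
  exTab <- do.call(rbind, lapply(results, function(s)
    data.frame(subject_id = s@subjectId, group = s@groupLabel,
               excluded = s@excluded,
               reason = if (s@excluded) s@exclusionReason else "")))
  nPer <- function(g) sum(keep & labels == g)
  if (nPer("low") < 2L || nPer("high") < 2L)
    stop(structure(class = c("vgammaEmptyGroup", "error", "condition"),
                   list(message = sprintf(
                     "a group was emptied by exclusions (low: %d, high: %d analyzable)",
                     nPer("low"), nPer("high")),
                     call = sys.call(), subjects = results)))
  sel <- function(g) results[keep & labels == g]
  A <- sel("low"); B <- sel("high")
  tf <- tfContrast(lapply(A, function(s) s@tfInduced),
                   lapply(B, function(s) s@tfInduced), cfg)
  spike <- spectrumContrast(lapply(A, function(s) s@spikeSpectrum),
                            lapply(B, function(s) s@spikeSpectrum),
                            cfg, window = "spike")
  sust <- spectrumContrast(lapply(A, function(s) s@sustainedSpectrum),
                           lapply(B, function(s) s@sustainedSpectrum),
                           cfg, window = "sustained")
  pk <- peakGroupComparison(lapply(A, function(s) s@gammaPeak),
                            lapply(B, function(s) s@gammaPeak))
  new("CohortResults", subjects = results, exclusions = exTab,
      tfContrast = tf, spikeContrast = spike, sustainedContrast = sust,
      peakComparison = pk, config = cfg)
}

#' Run the full pipeline over a cohort
#'
#' `subjects` may be a character vector of epochs container paths or a list
#' of [EpochsData-class] objects.  Each subject is analysed with
#' [runSubject()]; cohort statistics are computed on the survivors with
#' [cohortStatistics()].  With `outDir` set, per-subject HDF5 results and
#' the cohort CSV/JSON tables are written.
#'
#' @param subjects character paths or list of epochs.
#' @param groupLabels "low"/"high" per subject.
#' @param cfg an [AnalysisConfig-class].
#' @param subjectIds labels (default sub-001...).
#' @param head optional shared [HeadModel-class]; per-subject fits otherwise.
#' @param outDir optional output directory.
#' @return a [CohortResults-class].
#' @export
runCohort <- function(subjects, groupLabels, cfg = analysisConfig(),
                      subjectIds = sprintf("sub-%03d", seq_along(subjects)),
                      head = NULL, outDir = NULL) {
  stopifnot(length(groupLabels) == length(subjects))
  results <- vector("list", length(subjects))
  lf <- NULL
  for (i in seq_along(subjects)) {
    ep <- subjects[[i]]
    if (is.character(ep)) ep <- readEpochs(ep)
    if (!is.null(head) && is.null(lf)) {
      grid <- buildGrid(head, cfg@gridSpacing)
      lf <- computeLeadfields(grid, ep@sensors, head)
    }
    results[[i]] <- runSubject(ep, cfg, subjectIds[i], groupLabels[i],
                               head = head, leadfield = lf)
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      writeSubjectResult(results[[i]],
                         file.path(outDir, paste0(subjectIds[i], ".h5")),
                         overwrite = TRUE)
    }
  }
  cohort <- cohortStatistics(results, cfg)
  if (!is.null(outDir)) writeCohortTables(cohort, outDir)
  cohort
}
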