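## Generics, accessors and show methods

#' Number of cells in a cohort
#' @param object an [RGCCohort-class]
#' @return integer cell count
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "RGCCohort", function(object) nrow(object@cellData))

#' Per-cell metadata of a cohort
#' @param object an [RGCCohort-class]
#' @return a [S4Vectors::DataFrame] with one row per cell
#' @export
setGeneric("cellData", function(object) standardGeneric("cellData"))

#' @rdname cellData
#' @export
setMethod("cellData", "RGCCohort", function(object) object@cellData)

#' Raw traces for one stimulus
#' @param object an [RGCCohort-class]
#' @param stimulus one of the stimulus names in the cohort
#'   (e.g. "chirp", "bar", "noise")
#' @return numeric matrix, time samples x cells
#' @export
setGeneric("traces", function(object, stimulus) standardGeneric("traces"))

#' @rdname traces
#' @export
setMethod("traces", "RGCCohort", function(object, stimulus) {
  if (!stimulus %in% names(object@traces))
    stop("no traces recorded for stimulus '", stimulus, "'")
  object@traces[[stimulus]]
})

#' Trigger times for one stimulus
#' @inheritParams traces
#' @return numeric vector of trigger times in s
#' @export
setGeneric("triggerTimes",
           function(object, stimulus) standardGeneric("triggerTimes"))

#' @rdname triggerTimes
#' @export
setMethod("triggerTimes", "RGCCohort", function(object, stimulus) {
  if (!stimulus %in% names(object@triggers))
    stop("no trigger log for stimulus '", stimulus, "'")
  object@triggers[[stimulus]]
})

#' Stimulus objects presented to a cohort
#' @param object an [RGCCohort-class]
#' @return named list of stimulus objects
#' @export
setGeneric("stimuli", function(object) standardGeneric("stimuli"))

#' @rdname stimuli
#' @export
setMethod("stimuli", "RGCCohort", function(object) object@stimuli)

#' Type templates of a library
#' @param object a [TypeLibrary-class]
#' @return list of 32 template parameter lists
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname templates
#' @export
setMethod("templates", "TypeLibrary", function(object) object@templates)

## show methods ---------------------------------------------------------------

setMethod("show", "ChirpStimulus", function(object) {
  cat(sprintf("ChirpStimulus: %d reps x %.1f s at %g Hz (%d samples)\n",
              object@nReps,
              length(object@trace) / object@nReps / object@sampleRate,
              object@sampleRate, length(object@trace)))
})

setMethod("show", "MovingBarStimulus", function(object) {
  cat(sprintf(
    "MovingBarStimulus: %d reps x 8 directions, %.2g x %.2g mm bar at %g mm/s (sweep %.2f s, gap %.1f s)\n",
    object@nReps, object@barSize[1], object@barSize[2], object@speed,
    object@sweepDuration, object@gapDuration))
})

setMethod("show", "ShiftedDenseNoise", function(object) {
  cat(sprintf(
    "ShiftedDenseNoise: %d x %d checks of %g um, %g Hz x %g s (%d frames), shifts on a %g um grid\n",
    object@grid[1], object@grid[2], object@checkSize, object@frameRate,
    object@duration, dim(object@frames)[3], object@shiftGrid))
})

setMethod("show", "TypeLibrary", function(object) {
  sg <- vapply(object@templates, function(tp) tp$super_group, character(1))
  cat("TypeLibrary: 32 functional RGC type templates\n")
  print(table(factor(sg, levels = SUPER_GROUPS)))
})

setMethod("show", "DegenerationSchedule", function(object) {
  cat("DegenerationSchedule (responsiveness multipliers):\n")
  print(round(object@multipliers, 3))
})

setMethod("show", "RGCCohort", function(object) {
  cd <- object@cellData
  cat(sprintf("RGCCohort: %d cells in %d fields (%s, %s)\n",
              nrow(cd), length(unique(cd$field_id)),
              paste(unique(cd$genotype), collapse = "/"),
              paste(unique(cd$age), collapse = "/")))
  cat("stimuli:", paste(names(object@traces), collapse = ", "), "\n")
})

setMethod("show", "SplineBasis", function(object) {
  cat(sprintf("SplineBasis: grid (%s) <- knots (%s), %d features\n",
              paste(object@dims, collapse = ","),
              paste(object@knots, collapse = ","),
              prod(object@knots)))
})

setMethod("show", "RFModel", function(object) {
  cat(sprintf(
    "RFModel: QI_SVD %.2f, QI_sRF %.2f, main peak lag %s s, diameter %s um -> %s\n",
    object@qiSvd, object@qiSrf,
    ifelse(is.na(object@mainPeakLag), "NA",
           sprintf("%.3f", object@mainPeakLag)),
    ifelse(is.null(object@rfSize$diameter_um), "NA",
           sprintf("%.1f", object@rfSize$diameter_um)),
    ifelse(object@passesQuality, "passes quality", "fails quality")))
})
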