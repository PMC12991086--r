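#' @importClassesFrom Matrix Matrix
NULL

#' @rdname TrialTensor-class
#' @param object,x an object.
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname TrialTensor-class
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname TrialTensor-class
#' @export
setGeneric("taskLabel", function(x) standardGeneric("taskLabel"))
#' @rdname TrialTensor-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname TrialTensor-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname TrialTensor-class
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname SessionPair-class
#' @export
setGeneric("cellMap", function(x) standardGeneric("cellMap"))
#' @rdname SessionPair-class
#' @export
setGeneric("pairType", function(x) standardGeneric("pairType"))
#' @rdname SessionPair-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname SessionPair-class
#' @export
setGeneric("sessionA", function(x) standardGeneric("sessionA"))
#' @rdname SessionPair-class
#' @export
setGeneric("sessionB", function(x) standardGeneric("sessionB"))

#' @rdname TrajectorySet-class
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))
#' @rdname TrajectorySet-class
#' @export
setGeneric("loadings", function(x, ...) standardGeneric("loadings"))
#' @rdname TrajectorySet-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname TrajectorySet-class
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

## TrialTensor accessors -----------------------------------------------------

#' @rdname TrialTensor-class
#' @export
setMethod("values", "TrialTensor", function(x) x@values)
#' @rdname TrialTensor-class
#' @export
setMethod("timeAxis", "TrialTensor", function(x) x@timeAxis)
#' @rdname TrialTensor-class
#' @export
setMethod("taskLabel", "TrialTensor", function(x) x@taskLabel)
#' @rdname TrialTensor-class
#' @export
setMethod("frameRate", "TrialTensor", function(x) x@frameRate)
#' @rdname TrialTensor-class
#' @export
setMethod("nTrials", "TrialTensor", function(x) dim(x@values)[3])
#' @rdname TrialTensor-class
#' @export
setMethod("nNeurons", "TrialTensor", function(x) dim(x@values)[1])

#' @rdname TrialTensor-class
#' @export
setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "TrialTensor: %d neurons x %d frames x %d trials (%s, %.3g Hz, [%.2g, %.2g] s)\n",
    d[1], d[2], d[3], object@taskLabel, object@frameRate,
    min(object@timeAxis), max(object@timeAxis)))
})

## SessionPair accessors -----------------------------------------------------

#' @rdname SessionPair-class
#' @export
setMethod("cellMap", "SessionPair", function(x) x@cellMap)
#' @rdname SessionPair-class
#' @export
setMethod("pairType", "SessionPair", function(x) x@pairType)
#' @rdname SessionPair-class
#' @export
setMethod("groundTruth", "SessionPair", function(x) x@groundTruth)
#' @rdname SessionPair-class
#' @export
setMethod("sessionA", "SessionPair", function(x) x@a)
#' @rdname SessionPair-class
#' @export
setMethod("sessionB", "SessionPair", function(x) x@b)

#' @rdname SessionPair-class
#' @export
setMethod("show", "SessionPair", function(object) {
  cat(sprintf("SessionPair (%s): %s vs %s, %d tracked cells\n",
              object@pairType, object@a@taskLabel, object@b@taskLabel,
              nrow(object@cellMap)))
})

#' @rdname SessionPairSet-class
#' @param object a `SessionPairSet`.
#' @export
setMethod("show", "SessionPairSet", function(object) {
  cat("SessionPairSet\n  pop1: "); show(object@pop1)
  cat("  pop2: "); show(object@pop2)
  cat(sprintf("  licks: %d + %d trials (%s strategy)\n",
              length(object@lickA@events), length(object@lickB@events),
              object@config@lickStrategy))
})

#' @rdname SessionPairSet-class
#' @param x a `SessionPairSet`.
#' @param population 1 or 2.
#' @export
populationPair <- function(x, population = 1) {
  stopifnot(is(x, "SessionPairSet"), population %in% 1:2)
  if (population == 1) x@pop1 else x@pop2
}

#' @rdname SessionPairSet-class
#' @param session `"a"` or `"b"`.
#' @export
lickTrain <- function(x, session = c("a", "b")) {
  stopifnot(is(x, "SessionPairSet"))
  if (match.arg(session) == "a") x@lickA else x@lickB
}

## TrajectorySet accessors ---------------------------------------------------

#' @rdname TrajectorySet-class
#' @param x a `TrajectorySet`.
#' @param task optional task-block name (or index); default returns the list
#'   of per-task score blocks (a bare matrix when there is a single block).
#' @param ... unused.
#' @export
setMethod("scores", "TrajectorySet", function(x, task = NULL, ...) {
  if (is.null(task)) {
    if (length(x@scores) == 1L) x@scores[[1L]] else x@scores
  } else x@scores[[task]]
})
#' @rdname TrajectorySet-class
#' @export
setMethod("loadings", "TrajectorySet", function(x, ...) x@loadings)
#' @rdname TrajectorySet-class
#' @export
setMethod("eigenvalues", "TrajectorySet", function(x) x@eigenvalues)
#' @rdname TrajectorySet-class
#' @export
setMethod("varianceFraction", "TrajectorySet", function(x) x@varianceFraction)

#' @rdname TrajectorySet-class
#' @param object a `TrajectorySet`.
#' @export
setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf(
    "TrajectorySet (%s space): %d components, blocks [%s], top-2 variance %.1f%%\n",
    object@space, length(object@eigenvalues),
    paste(names(object@scores), collapse = ", "),
    100 * sum(object@varianceFraction[seq_len(min(2, length(object@varianceFraction)))])))
})

## Other show methods --------------------------------------------------------

#' @rdname SynthConfig-class
#' @param object a `SynthConfig`.
#' @export
setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    paste0("SynthConfig: pop sizes %d/%d, %d trials/task, rotation %g deg, ",
           "elongation %g, reliability target %g, seed %d\n"),
    object@nNeuronsPop1, object@nNeuronsPop2, object@nTrialsPerTask,
    object@crossContextRotation, object@elongationGain,
    object@reliabilityTarget, object@seed))
})

#' @rdname TaskGeometry-class
#' @param object a `TaskGeometry`.
#' @export
setMethod("show", "TaskGeometry", function(object) {
  cat(sprintf(
    "TaskGeometry: R^%d ambient, r=%g, targets %g/%g deg, sigma=%g (1/f^%g), n=%d\n",
    object@ambientDim, object@radius, object@targetRotations[1],
    object@targetRotations[2], object@noiseSd, object@pinkBeta,
    object@nSamples))
})

#' @rdname CircuitModel-class
#' @param object a `CircuitModel`.
#' @export
setMethod("show", "CircuitModel", function(object) {
  cat(sprintf("CircuitModel (%s): %d granule cells x %d mossy fibers, 4 inputs/cell\n",
              object@kind, nrow(object@Wexp), ncol(object@Wexp)))
})

#' @rdname TrainingTrace-class
#' @param object a `TrainingTrace`.
#' @export
setMethod("show", "TrainingTrace", function(object) {
  cat(sprintf(
    "TrainingTrace (%s, seed %d): phases [%s] x %d epochs, final loss %.4g\n",
    object@kind, object@seed, paste(object@phaseSchedule, collapse = ","),
    object@epochsPerPhase, utils::tail(object@epochLoss, 1)))
})

#' @rdname GramMatrix-class
#' @param object a `GramMatrix`.
#' @export
setMethod("show", "GramMatrix", function(object) {
  cat(sprintf("GramMatrix: %d timepoints, blocks [%s]\n", nrow(object@values),
              paste(levels(object@blockIndex), collapse = ", ")))
})
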