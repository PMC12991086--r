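#' @import methods
#' @importFrom stats cor sd rnorm runif rpois quantile median fft var coef predict
#' @importFrom Matrix sparseMatrix
#' @importFrom Rcpp sourceCpp
#' @useDynLib manifoldRemap, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Synthetic-session containers
## ---------------------------------------------------------------------------

#' Configuration for the synthetic two-context session generator
#'
#' Holds every tunable of [generateSessionPair()]. Population 1 emulates a
#' cortical (layer-5 pyramidal-tract-like) population whose low-rank latent
#' trajectories generalize across the two behavioral contexts; population 2
#' emulates a granule-cell-like population whose latents are rotated (and
#' optionally elongated out-of-plane) between contexts.
#'
#' @slot nNeuronsPop1,nNeuronsPop2 integer, population sizes.
#' @slot nTrialsPerTask integer, trials per session.
#' @slot frameRate numeric, imaging rate in Hz.
#' @slot window numeric length-2, start/end of the trial window in seconds
#'   relative to reward delivery (start < 0 < end).
#' @slot latentRank integer, number of latent time courses (even values give
#'   exactly variance-balanced neurons; see vignette).
#' @slot crossContextRotation numeric, planted angle (degrees, in \[0, 180\])
#'   applied to population 2's top-2 latent plane between contexts.
#' @slot elongationGain numeric >= 0, out-of-plane variance gain applied to
#'   population 2's third latent in the second context.
#' @slot noiseSd numeric, per-frame i.i.d. trial noise SD; `NA` (default)
#'   means "solve analytically from `reliabilityTarget`".
#' @slot reliabilityTarget numeric in (0, 1], expected split-half reliability.
#' @slot couplingRank integer, number of latents shared between the two
#'   populations (remaining pop-2 latents are private).
#' @slot lickStrategy `"reactive"` or `"predictive"`.
#' @slot seed integer RNG seed.
#' @export
setClass("SynthConfig", representation(
  nNeuronsPop1 = "integer", nNeuronsPop2 = "integer",
  nTrialsPerTask = "integer", frameRate = "numeric", window = "numeric",
  latentRank = "integer", crossContextRotation = "numeric",
  elongationGain = "numeric", noiseSd = "numeric",
  reliabilityTarget = "numeric", couplingRank = "integer",
  lickStrategy = "character", seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nNeuronsPop1 < 1L || object@nNeuronsPop2 < 1L ||
      object@nTrialsPerTask < 1L || object@latentRank < 1L)
    msg <- c(msg, "all counts must be >= 1")
  if (!(object@window[1] < 0 && 0 < object@window[2]))
    msg <- c(msg, "window must satisfy start < 0 < end")
  if (object@crossContextRotation < 0 || object@crossContextRotation > 180)
    msg <- c(msg, "crossContextRotation must lie in [0, 180] degrees")
  if (object@elongationGain < 0)
    msg <- c(msg, "elongationGain must be >= 0")
  if (!is.na(object@reliabilityTarget) &&
      (object@reliabilityTarget <= 0 || object@reliabilityTarget > 1))
    msg <- c(msg, "reliabilityTarget must lie in (0, 1]")
  if (object@couplingRank < 0L || object@couplingRank > object@latentRank)
    msg <- c(msg, "couplingRank must lie in [0, latentRank]")
  if (!object@lickStrategy %in% c("reactive", "predictive"))
    msg <- c(msg, "lickStrategy must be 'reactive' or 'predictive'")
  if (length(msg)) msg else TRUE
})

#' Trial-aligned population activity for one session
#'
#' A neuron x time x trial array of (synthetic) fluorescence traces with a
#' time axis in seconds relative to reward delivery.
#'
#' @slot values numeric array `[neuron, time, trial]`.
#' @slot timeAxis numeric, strictly increasing, containing 0 (reward).
#' @slot taskLabel `"Reach"` or `"VR"`.
#' @slot frameRate numeric, Hz.
#' @export
setClass("TrialTensor", representation(
  values = "array", timeAxis = "numeric", taskLabel = "character",
  frameRate = "numeric"))

setValidity("TrialTensor", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-d array")
  if (length(d) == 3L && d[2] != length(object@timeAxis))
    msg <- c(msg, "timeAxis length must match dim(values)[2]")
  if (any(diff(object@timeAxis) <= 0))
    msg <- c(msg, "timeAxis must be strictly increasing")
  if (min(object@timeAxis) > 0 || max(object@timeAxis) < 0)
    msg <- c(msg, "reward time 0 must lie inside the window")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' A matched pair of sessions with tracked cells
#'
#' Two [TrialTensor]s (one per session) with a cell-correspondence map and a
#' pair type: `"cross_task"` (e.g., Reach then VR) or `"same_task"` control.
#'
#' @slot a,b [TrialTensor] objects.
#' @slot cellMap integer matrix with columns `a`, `b`: row i says cell
#'   `cellMap[i, "a"]` in session a is cell `cellMap[i, "b"]` in session b.
#' @slot pairType `"cross_task"` or `"same_task"`.
#' @slot groundTruth list echoing planted generator parameters (possibly empty).
#' @export
setClass("SessionPair", representation(
  a = "TrialTensor", b = "TrialTensor", cellMap = "matrix",
  pairType = "character", groundTruth = "list"))

setValidity("SessionPair", function(object) {
  msg <- character()
  cm <- object@cellMap
  if (ncol(cm) != 2L) msg <- c(msg, "cellMap must have two columns")
  na <- dim(object@a@values)[1]; nb <- dim(object@b@values)[1]
  if (nrow(cm) > 0) {
    if (any(cm[, 1] < 1 | cm[, 1] > na) || any(cm[, 2] < 1 | cm[, 2] > nb))
      msg <- c(msg, "cellMap indices out of range")
    if (anyDuplicated(cm[, 1]) || anyDuplicated(cm[, 2]))
      msg <- c(msg, "cellMap must be injective on both sides")
  }
  if (!object@pairType %in% c("cross_task", "same_task"))
    msg <- c(msg, "pairType must be 'cross_task' or 'same_task'")
  if (length(msg)) msg else TRUE
})

#' Per-trial lick event times
#'
#' @slot events list of numeric vectors, one per trial, event times in
#'   seconds relative to reward.
#' @slot trialOutcomes character, `"rewarded"` or `"omitted"` per trial.
#' @slot stuck logical per trial: TRUE marks trials where the capacitive
#'   sensor was continuously high over some 1.5 s interval (excluded from
#'   lick scoring).
#' @slot window numeric length-2 session window (seconds relative to reward).
#' @export
setClass("LickTrain", representation(
  events = "list", trialOutcomes = "character", stuck = "logical",
  window = "numeric"))

setValidity("LickTrain", function(object) {
  msg <- character()
  n <- length(object@events)
  if (length(object@trialOutcomes) != n || length(object@stuck) != n)
    msg <- c(msg, "trialOutcomes and stuck must align with trial count")
  if (!all(object@trialOutcomes %in% c("rewarded", "omitted")))
    msg <- c(msg, "trialOutcomes must be 'rewarded' or 'omitted'")
  rng <- range(c(object@window, unlist(object@events, use.names = FALSE)))
  if (rng[1] < object@window[1] - 1e-9 || rng[2] > object@window[2] + 1e-9)
    msg <- c(msg, "events must lie within the session window")
  if (length(msg)) msg else TRUE
})

#' Bundle of both populations' session pairs plus lick trains
#'
#' The synthetic generator records two populations simultaneously; CCA and
#' the RSA comparison need them on a shared time base, so
#' [generateSessionPair()] returns both [SessionPair]s together with one
#' [LickTrain] per session.
#'
#' @slot pop1,pop2 [SessionPair] objects (same sessions, two populations).
#' @slot lickA,lickB [LickTrain] objects for sessions a and b.
#' @slot config the generating [SynthConfig].
#' @export
setClass("SessionPairSet", representation(
  pop1 = "SessionPair", pop2 = "SessionPair",
  lickA = "LickTrain", lickB = "LickTrain", config = "SynthConfig"))

## ---------------------------------------------------------------------------
## Dimensionality-reduction containers
## ---------------------------------------------------------------------------

#' Low-dimensional trajectories from (joint-)task PCA
#'
#' @slot scores named list of numeric `[time, component]` matrices, one per
#'   task block (a single block for task-space PCA).
#' @slot loadings numeric `[neuron, component]`, orthonormal columns.
#' @slot eigenvalues numeric, nonincreasing, >= 0 (variance units).
#' @slot varianceFraction numeric, per-component fraction of the total
#'   variance of the fitted matrix.
#' @slot taskVariance named numeric, total variance of each task block
#'   (sum of per-neuron variances within the block).
#' @slot space `"task"` or `"joint"`.
#' @export
setClass("TrajectorySet", representation(
  scores = "list", loadings = "matrix", eigenvalues = "numeric",
  varianceFraction = "numeric", taskVariance = "numeric", space = "character"))

setValidity("TrajectorySet", function(object) {
  msg <- character()
  if (any(diff(object@eigenvalues) > 1e-8))
    msg <- c(msg, "eigenvalues must be nonincreasing")
  if (any(object@eigenvalues < -1e-8))
    msg <- c(msg, "eigenvalues must be >= 0")
  if (sum(object@varianceFraction) > 1 + 1e-6)
    msg <- c(msg, "variance fractions must sum to <= 1")
  if (!object@space %in% c("task", "joint"))
    msg <- c(msg, "space must be 'task' or 'joint'")
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-6)
    msg <- c(msg, "loadings columns must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Time-by-time similarity (Gram) matrix for RSA
#'
#' Entry (i, j) is the dot product of the population activity vectors at
#' timepoints i and j (unnormalized covariance), preserving activation
#' magnitude.
#'
#' @slot values numeric symmetric `[time_total, time_total]` matrix.
#' @slot blockIndex factor of length `time_total` labeling each timepoint's
#'   task block; within-task blocks are same-label pairs, cross-task blocks
#'   different-label pairs.
#' @export
setClass("GramMatrix", representation(
  values = "matrix", blockIndex = "factor"))

setValidity("GramMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-6 * (1 + max(abs(v))))
    msg <- c(msg, "values must be symmetric")
  if (length(object@blockIndex) != nrow(v))
    msg <- c(msg, "blockIndex must label every timepoint")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Circuit-simulation containers
## ---------------------------------------------------------------------------

#' Two-task circular-manifold geometry for the circuit simulation
#'
#' Sheared unit circles of intrinsic dimension 2 embedded in a 100-dimensional
#' ambient space; the two tasks share the base circle, shear and embedding
#' plane and differ only by a translation orthogonal to that plane. Targets
#' are in-plane rotations of the base manifold (40 and 130 degrees).
#'
#' @slot ambientDim integer (100).
#' @slot radius numeric intrinsic radius (1).
#' @slot shear numeric 2x2 intrinsic shear (det 1).
#' @slot embedding numeric `[ambientDim, 2]` with orthonormal columns.
#' @slot tPerp numeric ambient translation with `t(embedding) %*% tPerp = 0`.
#' @slot targetRotations numeric length-2, degrees (task 1, task 2).
#' @slot noiseSd numeric, noise scale sigma.
#' @slot pinkBeta numeric, 1/f^beta exponent of the noise.
#' @slot nSamples integer, samples per task.
#' @slot seed integer.
#' @export
setClass("TaskGeometry", representation(
  ambientDim = "integer", radius = "numeric", shear = "matrix",
  embedding = "matrix", tPerp = "numeric", targetRotations = "numeric",
  noiseSd = "numeric", pinkBeta = "numeric", nSamples = "integer",
  seed = "integer"))

setValidity("TaskGeometry", function(object) {
  msg <- character()
  E <- object@embedding
  if (nrow(E) != object@ambientDim || ncol(E) != 2L)
    msg <- c(msg, "embedding must be ambientDim x 2")
  if (max(abs(crossprod(E) - diag(2))) > 1e-8)
    msg <- c(msg, "embedding columns must be orthonormal")
  if (max(abs(crossprod(E, object@tPerp))) > 1e-8)
    msg <- c(msg, "tPerp must be orthogonal to the embedding plane")
  if (abs(det(object@shear) - 1) > 1e-8)
    msg <- c(msg, "shear must have determinant 1")
  if (length(msg)) msg else TRUE
})

#' Paired input/target samples for one task
#'
#' @slot inputs,targets numeric `[n, ambientDim]` matrices.
#' @slot phases numeric, generating angular positions (radians, sorted).
#' @slot taskId integer, 1 or 2.
#' @export
setClass("TaskDataset", representation(
  inputs = "matrix", targets = "matrix", phases = "numeric",
  taskId = "integer"))

setValidity("TaskDataset", function(object) {
  msg <- character()
  if (!all(is.finite(object@inputs)) || !all(is.finite(object@targets)))
    msg <- c(msg, "inputs and targets must be finite")
  if (nrow(object@inputs) != length(object@phases) ||
      nrow(object@targets) != length(object@phases))
    msg <- c(msg, "inputs/targets rows must match phases")
  if (!object@taskId %in% 1:2) msg <- c(msg, "taskId must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' A granule-layer network (Relay, Expansion or Rotation)
#'
#' All three architectures share the same fixed sparse mossy-fiber projection
#' (exactly 4 nonzero inputs per granule cell) and a trainable linear readout;
#' they differ only in how granule activations are computed.
#'
#' @slot kind `"relay"`, `"expansion"` or `"rotation"`.
#' @slot Wexp sparse `[nGranule, ambientDim]` projection, fixed.
#' @slot bias numeric, granule bias (used by the expansion model; -0.07).
#' @slot transforms list of two 2x2 intrinsic-coordinate transforms (rotation
#'   model only; empty otherwise).
#' @slot embedding the task geometry's embedding plane (rotation model needs
#'   it to split in-plane from out-of-plane components).
#' @slot Wout numeric `[nGranule, ambientDim]` readout weights (trainable).
#' @slot bout numeric length-ambientDim readout bias (trainable).
#' @slot seed integer.
#' @export
setClass("CircuitModel", representation(
  kind = "character", Wexp = "Matrix", bias = "numeric",
  transforms = "list", embedding = "matrix", Wout = "matrix",
  bout = "numeric", seed = "integer"))

setValidity("CircuitModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("relay", "expansion", "rotation"))
    msg <- c(msg, "kind must be relay, expansion or rotation")
  nnzRow <- Matrix::rowSums(object@Wexp != 0)
  if (!all(nnzRow == 4L))
    msg <- c(msg, "every Wexp row must have exactly 4 nonzero entries")
  if (object@kind == "rotation" && length(object@transforms) != 2L)
    msg <- c(msg, "rotation model needs two task transforms")
  if (length(msg)) msg else TRUE
})

#' Record of one curriculum training run
#'
#' @slot trainLoss numeric, per-batch training MSE.
#' @slot epochLoss numeric, per-epoch mean training MSE.
#' @slot prevTaskLoss numeric, per-epoch MSE on the previous phase's task
#'   (NA during the first phase), evaluated without gradient updates.
#' @slot phaseSchedule integer task ids per phase.
#' @slot epochsPerPhase,batchSize integer.
#' @slot lr numeric learning rate.
#' @slot kind character, architecture trained.
#' @slot seed integer.
#' @export
setClass("TrainingTrace", representation(
  trainLoss = "numeric", epochLoss = "numeric", prevTaskLoss = "numeric",
  phaseSchedule = "integer", epochsPerPhase = "integer",
  batchSize = "integer", lr = "numeric", kind = "character",
  seed = "integer"))

setValidity("TrainingTrace", function(object) {
  nE <- length(object@phaseSchedule) * object@epochsPerPhase
  if (length(object@epochLoss) != nE)
    "epochLoss length must equal total epochs" else TRUE
})
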