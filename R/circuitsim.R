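## Cerebellar granule-layer circuit simulation: two-task circular-manifold
## geometry, Relay / Expansion / Rotation architectures, the alternating
## curriculum, and the comparison metrics (learning speed, previous-task
## interference, Jaccard overlap, PC variance, input shattering).

#' Construct the two-task circular-manifold geometry
#'
#' Sheared unit circles (intrinsic dimension 2) embedded in a 100-dimensional
#' ambient space through a random orthonormal plane; the two tasks share the
#' base circle, shear and plane and differ only by a translation orthogonal
#' to the plane. Targets are in-plane rotations of the base manifold by 40
#' (task 1) and 130 (task 2) degrees.
#'
#' @param seed integer RNG seed for the embedding and translation.
#' @param ambientDim ambient dimensionality (default 100).
#' @param radius intrinsic radius (default 1).
#' @param shear 2x2 intrinsic shear (default `[[1, 0.2], [0, 1]]`).
#' @param targetRotations degrees for tasks 1 and 2 (default 40, 130).
#' @param noiseSd noise scale sigma (default 0.15).
#' @param pinkBeta 1/f^beta exponent (default 1).
#' @param nSamples samples per task (default 1000).
#' @param tPerpNorm magnitude of the between-task translation; the default 1
#'   puts the separation on the manifold's own radial scale.
#' @return a [TaskGeometry].
#' @export
taskGeometry <- function(seed = 1, ambientDim = 100, radius = 1,
                         shear = matrix(c(1, 0, 0.2, 1), 2, 2),
                         targetRotations = c(40, 130), noiseSd = 0.15,
                         pinkBeta = 1, nSamples = 1000, tPerpNorm = 1) {
  set.seed(seed)
  E <- qr.Q(qr(matrix(rnorm(ambientDim * 2), ambientDim, 2)))
  t0 <- rnorm(ambientDim)
  t0 <- t0 - E %*% crossprod(E, t0)
  tPerp <- drop(t0 / sqrt(sum(t0^2)) * tPerpNorm)
  new("TaskGeometry", ambientDim = as.integer(ambientDim), radius = radius,
      shear = shear, embedding = E, tPerp = tPerp,
      targetRotations = targetRotations, noiseSd = noiseSd,
      pinkBeta = pinkBeta, nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

#' Pink (1/f^beta) noise matrix
#'
#' Spectrally shaped noise over the sample index, independently per
#' dimension: white Gaussian noise is Fourier-transformed, its amplitude at
#' frequency f scaled by `f^(-beta/2)` (DC removed), inverted, and each
#' column standardized to zero mean and unit variance. `beta = 0` recovers
#' white noise.
#'
#' @param nSamples,dim matrix dimensions.
#' @param beta spectral exponent (default 1).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return `[nSamples, dim]` matrix, unit variance per column.
#' @export
pinkNoise <- function(nSamples, dim, beta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(rnorm(nSamples * dim), nSamples, dim)
  if (beta != 0 && nSamples > 2) {
    j <- 0:(nSamples - 1)
    f <- pmin(j, nSamples - j)
    amp <- ifelse(f == 0, 0, f^(-beta / 2))
    w <- Re(stats::mvfft(stats::mvfft(w) * amp, inverse = TRUE)) / nSamples
  }
  ctr <- sweep(w, 2, colMeans(w))
  sds <- sqrt(colMeans(ctr^2))
  sds[sds == 0] <- 1
  sweep(ctr, 2, sds, "/")
}

.rotationRad <- function(th)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

#' Generate paired input/target samples for one task
#'
#' Phases are uniform on \[0, 2 pi) (returned sorted so the pink noise is
#' smooth along the manifold); the base point is `S [cos t, sin t]'`, inputs
#' embed it through the plane (plus the perpendicular translation for task
#' 2), and targets embed the base point rotated in-plane by the task's
#' target angle. Independent pink noise scaled by `noiseSd` is added to
#' inputs and targets.
#'
#' @param geom a [TaskGeometry].
#' @param taskId 1 or 2.
#' @param noise logical; `FALSE` yields the noiseless manifolds.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param noiseKind `"pink"` (1/f over the theta-sorted sample index, the
#'   default) or `"white"` (i.i.d. per sample).
#' @return a [TaskDataset].
#' @export
makeTaskDataset <- function(geom, taskId, noise = TRUE, seed = NULL,
                            noiseKind = c("pink", "white")) {
  stopifnot(is(geom, "TaskGeometry"), taskId %in% 1:2)
  validObject(geom)
  noiseKind <- match.arg(noiseKind)
  if (!is.null(seed)) set.seed(seed)
  n <- geom@nSamples
  theta <- sort(runif(n, 0, 2 * pi))
  base <- geom@shear %*% rbind(cos(theta), sin(theta)) * geom@radius  # 2 x n
  phi <- geom@targetRotations[taskId] * pi / 180
  inputs <- t(geom@embedding %*% base)
  targets <- t(geom@embedding %*% (.rotationRad(phi) %*% base))
  if (taskId == 2) {
    inputs <- sweep(inputs, 2, geom@tPerp, "+")
    targets <- sweep(targets, 2, geom@tPerp, "+")
  }
  if (noise && geom@noiseSd > 0) {
    beta <- if (noiseKind == "pink") geom@pinkBeta else 0
    inputs <- inputs + geom@noiseSd * pinkNoise(n, geom@ambientDim, beta)
    targets <- targets + geom@noiseSd * pinkNoise(n, geom@ambientDim, beta)
  }
  new("TaskDataset", inputs = inputs, targets = targets, phases = theta,
      taskId = as.integer(taskId))
}

#' Build a granule-layer circuit model
#'
#' All architectures share a fixed sparse mossy-fiber projection in which
#' every granule cell receives exactly 4 of the 100 inputs, with
#' Kaiming-normal weights (fan-in 100) masked after initialization, and a
#' trainable linear readout (Kaiming-normal, fan-in `nGranule`; zero bias).
#' The expansion model adds L2 input normalization and a fixed negative bias
#' (-0.07) enforcing ~1% population sparsity; the rotation model applies a
#' task-specific in-plane transform (shear for task 1, 90-degree rotation
#' times shear for task 2) before the shared projection.
#'
#' @param kind `"relay"`, `"expansion"` or `"rotation"`.
#' @param geom the [TaskGeometry] (the rotation model needs its embedding
#'   plane).
#' @param nGranule granule-layer size (default 10000).
#' @param seed integer RNG seed.
#' @param bias expansion-model granule bias (default -0.07).
#' @return a [CircuitModel].
#' @export
circuitModel <- function(kind = c("relay", "expansion", "rotation"), geom,
                         nGranule = 10000, seed = 1, bias = -0.07) {
  kind <- match.arg(kind)
  stopifnot(is(geom, "TaskGeometry"))
  set.seed(seed)
  d <- geom@ambientDim
  idx <- t(vapply(seq_len(nGranule), function(i) sample.int(d, 4),
                  integer(4)))
  Wexp <- Matrix::sparseMatrix(
    i = rep(seq_len(nGranule), each = 4), j = as.integer(t(idx)),
    x = rnorm(4L * nGranule, sd = sqrt(2 / d)), dims = c(nGranule, d))
  transforms <- list()
  if (kind == "rotation") {
    T1 <- matrix(c(1, 0, 0.5, 1), 2, 2)
    transforms <- list(T1, .rotationRad(pi / 2) %*% T1)
  }
  Wout <- matrix(rnorm(nGranule * d, sd = sqrt(2 / nGranule)), nGranule, d)
  new("CircuitModel", kind = kind, Wexp = Wexp,
      bias = if (kind == "expansion") bias else 0,
      transforms = transforms, embedding = geom@embedding, Wout = Wout,
      bout = numeric(d), seed = as.integer(seed))
}

#' Granule-layer forward pass
#'
#' Relay: `h = ReLU(Wexp x)`. Expansion: `h = ReLU(Wexp (x / ||x||) + b)`.
#' Rotation: the input is split into its in-plane (`E E' x`) and
#' out-of-plane components; the task transform acts on the in-plane part in
#' intrinsic 2-D coordinates, the out-of-plane part is preserved, and the
#' recombined vector passes through the shared sparse projection and ReLU.
#'
#' @param model a [CircuitModel].
#' @param x `[n, ambientDim]` input matrix (a vector is treated as one row).
#' @param taskId task identity (used by the rotation model only).
#' @return dense `[n, nGranule]` activation matrix.
#' @export
granuleForward <- function(model, x, taskId = 1) {
  stopifnot(is(model, "CircuitModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (model@kind == "expansion") {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) stop("zero-norm input: L2 normalization undefined")
    x <- x / nrm
  } else if (model@kind == "rotation") {
    Tc <- model@transforms[[taskId]]
    xp <- x %*% model@embedding                       # in-plane coordinates
    x <- x + (xp %*% t(Tc - diag(2))) %*% t(model@embedding)
  }
  pre <- as.matrix(x %*% Matrix::t(model@Wexp)) + model@bias
  pre[pre < 0] <- 0
  pre
}

#' Mean fraction of active granule cells
#'
#' @param model a [CircuitModel].
#' @param dataset a [TaskDataset].
#' @return mean over samples of the fraction of cells with `h > 0`.
#' @export
activeFraction <- function(model, dataset) {
  h <- granuleForward(model, dataset@inputs, dataset@taskId)
  mean(h > 0)
}

#' Train the readout through the alternating two-task curriculum
#'
#' Only the readout (`Wout`, `bout`) is trained, with Adam (learning rate
#' 1e-4) on the mean-squared-error loss over shuffled minibatches of 32,
#' through four sequential phases (task 1, 2, 1, 2) of 100 epochs each. An
#' epoch is one pass over the task's samples (the final partial batch is
#' kept). During phases after the first, the mean squared error on the
#' previous task is evaluated once per epoch, without gradient updates, on a
#' fixed random subsample.
#'
#' @param model a [CircuitModel].
#' @param data1,data2 [TaskDataset]s for tasks 1 and 2.
#' @param lr Adam learning rate (default 1e-4).
#' @param batchSize minibatch size (default 32).
#' @param phases integer task schedule (default `c(1, 2, 1, 2)`).
#' @param epochsPerPhase epochs per phase (default 100).
#' @param seed integer seed for batch shuffling and the evaluation subsample.
#' @param prevEvalSamples size of the previous-task evaluation subsample.
#' @return list with `trace` (a [TrainingTrace]) and `model` (the
#'   [CircuitModel] with trained readout).
#' @export
trainCurriculum <- function(model, data1, data2, lr = 1e-4, batchSize = 32,
                            phases = c(1L, 2L, 1L, 2L), epochsPerPhase = 100,
                            seed = 1, prevEvalSamples = 256) {
  stopifnot(is(model, "CircuitModel"), is(data1, "TaskDataset"),
            is(data2, "TaskDataset"), data1@taskId == 1L, data2@taskId == 2L)
  H1 <- granuleForward(model, data1@inputs, 1L)
  H2 <- granuleForward(model, data2@inputs, 2L)
  n1 <- nrow(H1); n2 <- nrow(H2)
  stopifnot(n1 == n2)  # the permutation schedule assumes equal task sizes
  set.seed(seed)
  totalEpochs <- length(phases) * epochsPerPhase
  perms <- vapply(seq_len(totalEpochs), function(e) sample.int(n1),
                  integer(n1))
  prevIdx1 <- sample.int(n1, min(prevEvalSamples, n1))
  prevIdx2 <- sample.int(n2, min(prevEvalSamples, n2))
  fit <- train_readout_cpp(t(H1), data1@targets, t(H2), data2@targets,
                           model@Wout, model@bout,
                           as.integer(phases), as.integer(epochsPerPhase),
                           perms, prevIdx1 - 1L, prevIdx2 - 1L,
                           lr, as.integer(batchSize), 0.9, 0.999, 1e-8)
  model@Wout <- fit$W
  model@bout <- drop(fit$b)
  trace <- new("TrainingTrace", trainLoss = fit$trainLoss,
               epochLoss = drop(fit$epochLoss),
               prevTaskLoss = drop(fit$prevLoss),
               phaseSchedule = as.integer(phases),
               epochsPerPhase = as.integer(epochsPerPhase),
               batchSize = as.integer(batchSize), lr = lr,
               kind = model@kind, seed = as.integer(seed))
  list(trace = trace, model = model)
}

#' Learning speed from an exponential fit to a phase's loss curve
#'
#' Fits `L(t) = A exp(-t / tau) + B` to the per-epoch training loss of one
#' phase by bounded nonlinear least squares (`A >= 0`, `tau > 0`) and
#' reports `speed = 1 / tau`. Initialization: `A = L(0) - L(end)`,
#' `B = L(end)`, `tau = phaseLength / 5`. A flat curve (A ~ 0) leaves tau
#' unidentified and is flagged.
#'
#' @param trace a [TrainingTrace] (or a bare numeric per-epoch loss vector).
#' @param phase which phase (default 1; speeds are comparable across
#'   architectures only for the first phase).
#' @return list with `A`, `tau`, `B`, `speed` and `flat` (logical).
#' @export
learningSpeed <- function(trace, phase = 1) {
  L <- if (is(trace, "TrainingTrace")) {
    e <- trace@epochsPerPhase
    trace@epochLoss[((phase - 1) * e + 1):(phase * e)]
  } else as.numeric(trace)
  if (length(L) < 10) stop("need at least 10 loss points in the phase")
  t <- seq_along(L) - 1
  A0 <- max(L[1] - L[length(L)], 1e-8)
  fit <- tryCatch(
    minpack.lm::nlsLM(L ~ A * exp(-t / tau) + B,
                      start = list(A = A0, tau = length(L) / 5,
                                   B = max(L[length(L)], 1e-12)),
                      lower = c(A = 0, tau = 1e-6, B = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = NA_real_, tau = NA_real_, B = NA_real_,
                speed = NA_real_, flat = NA))
  cf <- coef(fit)
  flat <- cf[["A"]] < 1e-6 * max(abs(L), 1e-12)
  list(A = cf[["A"]], tau = cf[["tau"]], B = cf[["B"]],
       speed = if (flat) NA_real_ else 1 / cf[["tau"]], flat = flat)
}

#' Jaccard overlap of active granule-cell sets between tasks
#'
#' For each sample index, the sets of active cells (`h > 0`) under the two
#' tasks are compared by the Jaccard index `|A n B| / |A u B|`, then
#' averaged over samples. Granule activations depend only on the fixed
#' expansion weights (and the task transform), never on the trained readout,
#' so any training checkpoint gives the same value.
#'
#' @param model a [CircuitModel].
#' @param data1,data2 [TaskDataset]s for tasks 1 and 2.
#' @return mean Jaccard index (samples with two empty sets are dropped).
#' @export
jaccardOverlap <- function(model, data1, data2) {
  a <- granuleForward(model, data1@inputs, 1L) > 0
  b <- granuleForward(model, data2@inputs, 2L) > 0
  inter <- rowSums(a & b)
  uni <- rowSums(a | b)
  mean(ifelse(uni == 0, NA_real_, inter / uni), na.rm = TRUE)
}

#' Variance captured by the leading PCs of granule activations
#'
#' PCA of the granule activation matrix pooled across both tasks; reports
#' the proportion of variance explained by the first `nPcs` components.
#'
#' @param model a [CircuitModel].
#' @param data1,data2 [TaskDataset]s.
#' @param nPcs leading components (default 20).
#' @return list with `fraction` (scalar) and `perComponent`.
#' @export
grcPcaVariance <- function(model, data1, data2, nPcs = 20) {
  H <- rbind(granuleForward(model, data1@inputs, 1L),
             granuleForward(model, data2@inputs, 2L))
  Hc <- sweep(H, 2, colMeans(H))
  lam <- pmax(eigen(tcrossprod(Hc), symmetric = TRUE,
                    only.values = TRUE)$values, 0)
  k <- min(nPcs, length(lam))
  list(fraction = sum(lam[seq_len(k)]) / sum(lam),
       perComponent = lam[seq_len(k)] / sum(lam))
}

#' Sinusoidally shatter an input manifold
#'
#' Adds `nFolds` sinusoidal displacements, each along a random ambient unit
#' direction with an integer frequency drawn uniformly from `{2, ..., max(2,
#' nFolds)}` and a random phase, as a function of each point's angular
#' position; every point is then rescaled to its original norm. `nFolds < 1`
#' (or zero amplitude) returns the input unchanged.
#'
#' @param x `[n, dim]` input matrix.
#' @param theta angular position of each point in the manifold's embedding
#'   plane (radians).
#' @param nFolds number of folds I.
#' @param amplitude displacement amplitude a (default 0.5).
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @return shattered matrix with per-point norms preserved.
#' @export
shatterInputs <- function(x, theta, nFolds, amplitude = 0.5, seed = NULL) {
  stopifnot(nrow(x) == length(theta))
  if (nFolds < 1 || amplitude == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  norms0 <- sqrt(rowSums(x^2))
  disp <- matrix(0, nrow(x), ncol(x))
  fmax <- max(2L, as.integer(nFolds))
  for (i in seq_len(nFolds)) {
    d <- rnorm(ncol(x)); d <- d / sqrt(sum(d^2))
    f <- sample(2:fmax, 1)
    phase <- runif(1, 0, 2 * pi)
    disp <- disp + outer(sin(f * theta + phase), d)
  }
  out <- x + amplitude * disp
  out * (norms0 / sqrt(rowSums(out^2)))
}

#' Compare the three granule-layer architectures across seeds
#'
#' For each architecture and seed: generates both tasks' datasets, trains the
#' readout through the full curriculum, and summarizes learning speed (phase
#' 1), previous-task interference (mean previous-task MSE over the later
#' phases), active-set Jaccard overlap between tasks, and the activation
#' variance captured by the first 20 PCs.
#'
#' @param geom a [TaskGeometry].
#' @param kinds architectures to run.
#' @param nSeeds seeds per architecture.
#' @param nGranule granule-layer size.
#' @param baseSeed offset added to the per-run seed.
#' @param ... passed to [trainCurriculum()].
#' @return data.frame with one row per (kind, seed).
#' @export
compareArchitectures <- function(geom,
                                 kinds = c("relay", "expansion", "rotation"),
                                 nSeeds = 5, nGranule = 10000, baseSeed = 0,
                                 ...) {
  rows <- list()
  for (kind in kinds) for (s in seq_len(nSeeds)) {
    seed <- baseSeed + s
    d1 <- makeTaskDataset(geom, 1, seed = seed)
    d2 <- makeTaskDataset(geom, 2, seed = seed + 10000L)
    model <- circuitModel(kind, geom, nGranule = nGranule, seed = seed)
    fit <- trainCurriculum(model, d1, d2, seed = seed, ...)
    sp <- learningSpeed(fit$trace, phase = 1)
    interference <- mean(fit$trace@prevTaskLoss, na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, seed = seed, speed = sp$speed, tau = sp$tau,
      interference = interference,
      jaccard = jaccardOverlap(model, d1, d2),
      pcVar20 = grcPcaVariance(model, d1, d2)$fraction,
      finalLoss = utils::tail(fit$trace@epochLoss, 1))
  }
  do.call(rbind, rows)
}

#' Input-geometry shattering sweep on the relay model
#'
#' Applies the sinusoidal shattering transform to the relay model's inputs
#' at increasing fold counts (mapped linearly to a shattering strength s in
#' \[0, 1\] across the tested range), retrains the readout, and records
#' learning speed and previous-task interference at each level.
#'
#' @param geom a [TaskGeometry].
#' @param levels fold counts I (default `c(1, 2, 4, 8, 16, 32)`).
#' @param nSeeds seeds per level.
#' @param nGranule granule-layer size.
#' @param amplitude displacement amplitude (default 0.5).
#' @param baseSeed offset added to the per-run seed.
#' @param ... passed to [trainCurriculum()].
#' @return data.frame with one row per (level, seed), including the
#'   normalized strength `s`.
#' @export
shatterSweep <- function(geom, levels = c(1, 2, 4, 8, 16, 32), nSeeds = 2,
                         nGranule = 10000, amplitude = 0.5, baseSeed = 0,
                         ...) {
  s01 <- if (length(levels) > 1)
    (levels - min(levels)) / (max(levels) - min(levels)) else 0
  rows <- list()
  for (li in seq_along(levels)) for (sd in seq_len(nSeeds)) {
    seed <- baseSeed + sd
    d1 <- makeTaskDataset(geom, 1, seed = seed)
    d2 <- makeTaskDataset(geom, 2, seed = seed + 10000L)
    d1@inputs <- shatterInputs(d1@inputs, d1@phases, levels[li], amplitude,
                               seed = seed + 20000L)
    d2@inputs <- shatterInputs(d2@inputs, d2@phases, levels[li], amplitude,
                               seed = seed + 30000L)
    model <- circuitModel("relay", geom, nGranule = nGranule, seed = seed)
    fit <- trainCurriculum(model, d1, d2, seed = seed, ...)
    sp <- learningSpeed(fit$trace, phase = 1)
    rows[[length(rows) + 1L]] <- data.frame(
      level = levels[li], s = s01[li], seed = seed, speed = sp$speed,
      interference = mean(fit$trace@prevTaskLoss, na.rm = TRUE))
  }
  do.call(rbind, rows)
}
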