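## Synthetic two-context session generator.
##
## The generator plants the structure the downstream analyses are designed to
## detect: both populations share a low-rank temporal scaffold; population 1
## reuses its latents across contexts, population 2's latents are rotated in
## the top-2 latent plane (and optionally elongated out-of-plane). Loadings
## are built from paired harmonic columns so that every neuron carries equal
## signal variance: per-neuron z-scoring then reduces to a uniform rescale and
## the joint-PCA -> Procrustes pipeline recovers the planted angle exactly in
## the noiseless limit.

#' Construct a synthetic-session configuration
#'
#' @param nNeuronsPop1,nNeuronsPop2 population sizes (default 60 and 120,
#'   echoing the coarse 1:2 cortex:granule ratio of a desk-scale session).
#' @param nTrialsPerTask trials per session (default 100).
#' @param frameRate imaging rate, Hz.
#' @param window trial window in seconds relative to reward.
#' @param latentRank number of latent time courses (even values recommended).
#' @param crossContextRotation planted rotation (degrees in \[0, 180\])
#'   applied to population 2's top-2 latent plane between contexts.
#' @param elongationGain out-of-plane variance gain for population 2 in the
#'   second context (0 disables).
#' @param noiseSd per-frame trial noise SD; `NA` solves it from
#'   `reliabilityTarget` analytically.
#' @param reliabilityTarget expected split-half reliability in (0, 1].
#' @param couplingRank latents shared between the populations.
#' @param lickStrategy `"reactive"` or `"predictive"`.
#' @param seed integer RNG seed.
#' @return a [SynthConfig] object.
#' @export
synthConfig <- function(nNeuronsPop1 = 60, nNeuronsPop2 = 120,
                        nTrialsPerTask = 100, frameRate = 30,
                        window = c(-2, 2), latentRank = 4,
                        crossContextRotation = 50, elongationGain = 0,
                        noiseSd = NA_real_, reliabilityTarget = 0.7,
                        couplingRank = latentRank,
                        lickStrategy = c("predictive", "reactive"),
                        seed = 1L) {
  new("SynthConfig",
      nNeuronsPop1 = as.integer(nNeuronsPop1),
      nNeuronsPop2 = as.integer(nNeuronsPop2),
      nTrialsPerTask = as.integer(nTrialsPerTask),
      frameRate = frameRate, window = window,
      latentRank = as.integer(latentRank),
      crossContextRotation = crossContextRotation,
      elongationGain = elongationGain, noiseSd = as.numeric(noiseSd),
      reliabilityTarget = as.numeric(reliabilityTarget),
      couplingRank = as.integer(couplingRank),
      lickStrategy = match.arg(lickStrategy), seed = as.integer(seed))
}

#' Construct a TrialTensor
#'
#' @param values numeric array `[neuron, time, trial]`.
#' @param timeAxis numeric time axis (seconds relative to reward).
#' @param taskLabel `"Reach"` or `"VR"`.
#' @param frameRate Hz.
#' @export
trialTensor <- function(values, timeAxis, taskLabel = "Reach", frameRate = 30) {
  new("TrialTensor", values = values, timeAxis = timeAxis,
      taskLabel = taskLabel, frameRate = frameRate)
}

#' Construct a SessionPair
#'
#' @param a,b [TrialTensor] objects.
#' @param cellMap two-column integer matrix of tracked-cell index pairs.
#' @param pairType `"cross_task"` or `"same_task"`.
#' @param groundTruth optional list of planted parameters.
#' @export
sessionPair <- function(a, b, cellMap, pairType = "cross_task",
                        groundTruth = list()) {
  cm <- as.matrix(cellMap)
  storage.mode(cm) <- "integer"
  colnames(cm) <- c("a", "b")
  new("SessionPair", a = a, b = b, cellMap = cm, pairType = pairType,
      groundTruth = groundTruth)
}

## Time axis containing frame 0 exactly at reward
.frameAxis <- function(window, frameRate) {
  frames <- seq(ceiling(window[1] * frameRate), floor(window[2] * frameRate))
  frames / frameRate
}

## Smooth latent scaffold: a ramp plus Gaussian bumps tiling the window,
## centered in time and QR-orthonormalized so the empirical latent covariance
## is exactly diagonal.
.latentScaffold <- function(timeAxis, rank) {
  tt <- length(timeAxis)
  stopifnot(rank < tt)
  width <- diff(range(timeAxis))
  centers <- seq(min(timeAxis) + 0.1 * width, max(timeAxis) - 0.1 * width,
                 length.out = max(rank - 1, 1))
  sdb <- width / (rank + 1)
  raw <- cbind(timeAxis,
               vapply(centers, function(m) exp(-(timeAxis - m)^2 / (2 * sdb^2)),
                      numeric(tt)))[, seq_len(rank), drop = FALSE]
  raw <- scale(raw, center = TRUE, scale = FALSE)
  qr.Q(qr(raw))  # T x rank, orthonormal columns, zero time-mean
}

## Paired decaying latent SD profile: members of each (2k-1, 2k) pair share a
## variance so the planted rotation plane (latents 1, 2) is isotropic.
.latentSdProfile <- function(rank, decay = 0.7) {
  pair <- (seq_len(rank) + 1L) %/% 2L
  sqrt(decay^(pair - 1L))
}

## Loadings with orthonormal columns and (for even rank) constant row norms:
## paired random-frequency harmonics with a random per-pair phase, random row
## sign flips and a random row permutation.
.harmonicLoadings <- function(n, rank) {
  nPairs <- ceiling(rank / 2)
  maxFreq <- (n - 1L) %/% 2L
  stopifnot(nPairs <= maxFreq)
  freqs <- sample.int(maxFreq, nPairs)
  idx <- seq_len(n) - 1L
  W <- matrix(0, n, rank)
  for (p in seq_len(nPairs)) {
    phase <- runif(1, 0, 2 * pi)
    arg <- 2 * pi * freqs[p] * idx / n + phase
    W[, 2L * p - 1L] <- sqrt(2 / n) * cos(arg)
    if (2L * p <= rank) W[, 2L * p] <- sqrt(2 / n) * sin(arg)
  }
  flip <- sample(c(-1, 1), n, replace = TRUE)
  (W * flip)[sample.int(n), , drop = FALSE]
}

.rotation2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

## Latents -> neuron x time x trial tensor with i.i.d. Gaussian trial noise.
## noiseSdPerNeuron may be a scalar or one value per neuron.
.latentsToTensor <- function(latents, load, sdProfile, nTrials,
                             noiseSdPerNeuron) {
  tt <- nrow(latents)
  meanTrace <- t(latents %*% diag(sdProfile * sqrt(tt), length(sdProfile)) %*%
                   t(load))  # neuron x time
  n <- nrow(meanTrace)
  arr <- array(rep(meanTrace, nTrials), dim = c(n, tt, nTrials))
  if (any(noiseSdPerNeuron > 0))
    arr <- arr + array(rnorm(n * tt * nTrials), dim = c(n, tt, nTrials)) *
      noiseSdPerNeuron
  arr
}

## Solve per-neuron noise SD from the split-half reliability target:
## r = v_sig / (v_sig + 2 sigma^2 / nTrials).
.noiseFromReliability <- function(meanTraceVar, target, nTrials) {
  if (target >= 1) return(rep(0, length(meanTraceVar)))
  sqrt(meanTraceVar * (1 / target - 1) * nTrials / 2)
}

#' Generate a matched pair of two-context sessions for two populations
#'
#' Simulates two simultaneously recorded populations across a matched session
#' pair sharing a temporal scaffold (action, 1-s delay, reward at t = 0).
#' Population 1's trial-averaged latents are identical across the two sessions
#' up to trial noise; for a `"cross_task"` pair, population 2's second-session
#' latents equal its first-session latents rotated by the planted angle in the
#' top-2 latent plane, with `elongationGain` injecting extra out-of-plane
#' variance. Single trials are the trial average plus i.i.d. Gaussian noise
#' scaled so the expected split-half reliability matches the target. Output is
#' bit-reproducible given `config@seed`.
#'
#' @param config a [SynthConfig].
#' @param pairType `"cross_task"` (Reach then VR; rotation/elongation applied)
#'   or `"same_task"` control (two Reach sessions, no planted change).
#' @return a [SessionPairSet] with one [SessionPair] per population and one
#'   [LickTrain] per session.
#' @examples
#' ps <- generateSessionPair(synthConfig(nNeuronsPop1 = 20, nNeuronsPop2 = 30,
#'                                       nTrialsPerTask = 20, seed = 7))
#' ps
#' @export
generateSessionPair <- function(config, pairType = c("cross_task", "same_task")) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  pairType <- match.arg(pairType)
  if (is.na(config@reliabilityTarget) && is.na(config@noiseSd))
    stop("either reliabilityTarget or noiseSd must be set")
  set.seed(config@seed)

  L <- config@latentRank
  nPrivate <- L - config@couplingRank
  timeAxis <- .frameAxis(config@window, config@frameRate)
  Z0 <- .latentScaffold(timeAxis, L + nPrivate)
  sdProf <- .latentSdProfile(L)

  Z1 <- Z0[, seq_len(L), drop = FALSE]
  pop2Cols <- c(seq_len(config@couplingRank), L + seq_len(nPrivate))
  Z2a <- Z0[, pop2Cols, drop = FALSE]

  ## cross-context transformation of population 2's latents
  Z2b <- Z2a
  phi <- 0
  if (pairType == "cross_task") {
    phi <- config@crossContextRotation
    if (L >= 2)
      Z2b[, 1:2] <- Z2a[, 1:2] %*% t(.rotation2(phi))
    if (L >= 3 && config@elongationGain > 0)
      Z2b[, 3] <- Z2a[, 3] * (1 + config@elongationGain)
  }

  W1 <- .harmonicLoadings(config@nNeuronsPop1, L)
  W2 <- .harmonicLoadings(config@nNeuronsPop2, L)

  tt <- length(timeAxis)
  sigVar <- function(load) {
    m <- t(Z1 %*% diag(sdProf * sqrt(tt), L) %*% t(load))
    apply(m, 1, var)
  }
  noiseFor <- function(load, nNeurons) {
    if (!is.na(config@noiseSd)) rep(config@noiseSd, nNeurons)
    else .noiseFromReliability(sigVar(load), config@reliabilityTarget,
                               config@nTrialsPerTask)
  }
  sd1 <- noiseFor(W1, config@nNeuronsPop1)
  sd2 <- noiseFor(W2, config@nNeuronsPop2)

  nTr <- config@nTrialsPerTask
  labels <- if (pairType == "cross_task") c("Reach", "VR") else c("Reach", "Reach")
  mk <- function(latents, load, sdn, label)
    trialTensor(.latentsToTensor(latents, load, sdProf, nTr, sdn),
                timeAxis, label, config@frameRate)

  t1a <- mk(Z1, W1, sd1, labels[1]); t1b <- mk(Z1, W1, sd1, labels[2])
  t2a <- mk(Z2a, W2, sd2, labels[1]); t2b <- mk(Z2b, W2, sd2, labels[2])

  gt <- list(rotation = phi, elongationGain = config@elongationGain,
             pairType = pairType, latentRank = L,
             couplingRank = config@couplingRank,
             noiseSdPop1 = sd1, noiseSdPop2 = sd2)
  idMap <- function(n) cbind(a = seq_len(n), b = seq_len(n))
  p1 <- sessionPair(t1a, t1b, idMap(config@nNeuronsPop1), pairType, gt)
  p2 <- sessionPair(t2a, t2b, idMap(config@nNeuronsPop2), pairType, gt)

  lickA <- generateLickTrain(config@lickStrategy, nTr, window = config@window)
  lickB <- generateLickTrain(config@lickStrategy, nTr, window = config@window)
  new("SessionPairSet", pop1 = p1, pop2 = p2, lickA = lickA, lickB = lickB,
      config = config)
}

#' Generate a per-trial lick event train
#'
#' A reactive strategy concentrates licking after reward delivery (and only on
#' rewarded trials); a predictive strategy elevates licking in the half second
#' before the expected reward on all trials, including reward omissions. Event
#' counts are Poisson given per-window rates; times are uniform within each
#' window.
#'
#' @param strategy `"reactive"` or `"predictive"`.
#' @param nTrials number of trials.
#' @param omissionFraction fraction of reward-omission trials in \[0, 1).
#' @param seed optional integer; `NULL` continues the current RNG stream.
#' @param ratePre lick rate (Hz) in the anticipatory window \[-0.5, 0) s;
#'   default 0.5 (reactive) or 5 (predictive).
#' @param ratePost consumption lick rate (Hz) in \[0, 1.5) s on rewarded
#'   trials; default 6 (reactive) or 2 (predictive).
#' @param baselineRate rate (Hz) elsewhere in the window.
#' @param window session window, seconds relative to reward.
#' @return a [LickTrain].
#' @export
generateLickTrain <- function(strategy = c("predictive", "reactive"),
                              nTrials = 100, omissionFraction = 0.2,
                              seed = NULL, ratePre = NULL, ratePost = NULL,
                              baselineRate = 0, window = c(-2, 2)) {
  strategy <- match.arg(strategy)
  stopifnot(omissionFraction >= 0, omissionFraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ratePre)) ratePre <- if (strategy == "predictive") 5 else 0.5
  if (is.null(ratePost)) ratePost <- if (strategy == "predictive") 2 else 6
  omitted <- runif(nTrials) < omissionFraction

  segTimes <- function(rate, lo, hi) {
    k <- rpois(1, rate * (hi - lo))
    if (k == 0) numeric() else sort(runif(k, lo, hi))
  }
  events <- lapply(seq_len(nTrials), function(i) {
    ev <- c(segTimes(baselineRate, window[1], -0.5),
            segTimes(ratePre, -0.5, 0),
            if (!omitted[i]) segTimes(ratePost, 0, min(1.5, window[2])),
            if (window[2] > 1.5) segTimes(baselineRate, 1.5, window[2]))
    sort(ev)
  })
  new("LickTrain", events = events,
      trialOutcomes = ifelse(omitted, "omitted", "rewarded"),
      stuck = rep(FALSE, nTrials), window = window)
}

## ---------------------------------------------------------------------------
## Plain-text serialization (CSV tensors + JSON sidecar)
## ---------------------------------------------------------------------------

#' Write/read a SessionPairSet as plain-text files
#'
#' Tensors are stored as one CSV per session and population (rows = neurons,
#' columns = flattened time-by-trial frames) next to a JSON sidecar holding
#' the configuration, ground truth, time axis, cell maps and lick events.
#'
#' @param x a [SessionPairSet].
#' @param dir output directory (created if needed).
#' @return `writeSessionPairSet` returns `dir` invisibly;
#'   `readSessionPairSet` returns the restored [SessionPairSet].
#' @export
writeSessionPairSet <- function(x, dir) {
  stopifnot(is(x, "SessionPairSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- x@config
  meta <- list(
    config = list(nNeuronsPop1 = cfg@nNeuronsPop1,
                  nNeuronsPop2 = cfg@nNeuronsPop2,
                  nTrialsPerTask = cfg@nTrialsPerTask,
                  frameRate = cfg@frameRate, window = cfg@window,
                  latentRank = cfg@latentRank,
                  crossContextRotation = cfg@crossContextRotation,
                  elongationGain = cfg@elongationGain, noiseSd = cfg@noiseSd,
                  reliabilityTarget = cfg@reliabilityTarget,
                  couplingRank = cfg@couplingRank,
                  lickStrategy = cfg@lickStrategy, seed = cfg@seed),
    timeAxis = x@pop1@a@timeAxis,
    taskLabels = c(x@pop1@a@taskLabel, x@pop1@b@taskLabel),
    pairType = x@pop1@pairType,
    groundTruth = x@pop1@groundTruth,
    cellMapPop1 = x@pop1@cellMap, cellMapPop2 = x@pop2@cellMap,
    licks = lapply(list(a = x@lickA, b = x@lickB), function(l)
      list(events = l@events, trialOutcomes = l@trialOutcomes,
           stuck = l@stuck, window = l@window)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  tensors <- list(pop1_a = x@pop1@a, pop1_b = x@pop1@b,
                  pop2_a = x@pop2@a, pop2_b = x@pop2@b)
  for (nm in names(tensors)) {
    v <- tensors[[nm]]@values
    m <- matrix(v, nrow = dim(v)[1])
    utils::write.table(m, file.path(dir, paste0(nm, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeSessionPairSet
#' @export
readSessionPairSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cc <- meta$config
  if (is.null(cc$noiseSd)) cc$noiseSd <- NA_real_
  if (is.null(cc$reliabilityTarget)) cc$reliabilityTarget <- NA_real_
  cfg <- do.call(synthConfig, cc)
  timeAxis <- meta$timeAxis
  readTensor <- function(nm, label) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".csv")),
                                     sep = ",", header = FALSE))
    dimnames(m) <- NULL
    tt <- length(timeAxis)
    trialTensor(array(m, dim = c(nrow(m), tt, ncol(m) / tt)), timeAxis,
                label, meta$config$frameRate)
  }
  gt <- meta$groundTruth
  mkPair <- function(pop) {
    sessionPair(readTensor(paste0(pop, "_a"), meta$taskLabels[1]),
                readTensor(paste0(pop, "_b"), meta$taskLabels[2]),
                meta[[paste0("cellMap", sub("p", "P", pop))]],
                meta$pairType, as.list(gt))
  }
  mkLick <- function(l) {
    ev <- l$events
    if (is.null(ev)) ev <- list()
    if (is.matrix(ev)) ev <- split(ev, row(ev))
    new("LickTrain", events = lapply(ev, as.numeric),
        trialOutcomes = as.character(l$trialOutcomes),
        stuck = as.logical(l$stuck), window = as.numeric(l$window))
  }
  new("SessionPairSet", pop1 = mkPair("pop1"), pop2 = mkPair("pop2"),
      lickA = mkLick(meta$licks$a), lickB = mkLick(meta$licks$b),
      config = cfg)
}
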