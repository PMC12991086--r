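## End-to-end session-pair analysis: reliability filtering, joint PCA,
## manifold geometry and RSA, mirroring the full imaging workflow on
## synthetic sessions.

.subsetTensor <- function(tensor, cells) {
  trialTensor(tensor@values[cells, , , drop = FALSE], tensor@timeAxis,
              tensor@taskLabel, tensor@frameRate)
}

#' Recover the planted cross-context rotation from a synthetic pair
#'
#' Runs the full pipeline used on real session pairs — trial averaging with
#' per-neuron z-scoring, joint-task PCA, planar Procrustes on the top-2
#' shared-space score blocks — on population 2 of a generated pair, and
#' returns the estimated rotation angle.
#'
#' @param pairSet a [SessionPairSet] (or a [SynthConfig], which is generated
#'   first).
#' @param population population index (default 2, the remapping population).
#' @param reliabilityThreshold joint-reliability cutoff; `NA` skips
#'   filtering (useful in the noiseless limit where reliability is
#'   undefined-by-constancy of halves).
#' @param smoothingSigma passed to [trialAverage()].
#' @return list with `angle` (degrees), `procrustes`, `jointSet` and the
#'   cell map used.
#' @export
recoverPlantedRotation <- function(pairSet, population = 2,
                                   reliabilityThreshold = NA,
                                   smoothingSigma = 0) {
  if (is(pairSet, "SynthConfig")) pairSet <- generateSessionPair(pairSet)
  pair <- populationPair(pairSet, population)
  cm <- if (is.na(reliabilityThreshold)) pair@cellMap
        else jointReliableFilter(pair, reliabilityThreshold)
  if (nrow(cm) < 3) stop("fewer than 3 jointly reliable cells")
  avgA <- trialAverage(.subsetTensor(pair@a, cm[, 1]),
                       smoothingSigma = smoothingSigma)
  avgB <- trialAverage(.subsetTensor(pair@b, cm[, 2]),
                       smoothingSigma = smoothingSigma)
  joint <- pcaJoint(avgA, avgB,
                    taskLabels = c(pair@a@taskLabel, pair@b@taskLabel))
  pr <- procrustesRotation(joint@scores[[1]][, 1:2], joint@scores[[2]][, 1:2])
  list(angle = pr$angle, procrustes = pr, jointSet = joint, cellMap = cm)
}

#' Full geometric analysis of a two-population session pair
#'
#' For each population: joint-reliability filtering, per-task and joint-task
#' PCA, cross-task PC correlation, Procrustes shared-space rotation,
#' elongation, participation ratios, and per-cell cross-session correlations
#' (raw and attenuation-corrected). Across populations: RSA comparison of
#' the temporal Gram matrices within and across tasks, and pairwise
#' correlation preservation.
#'
#' @param pairSet a [SessionPairSet].
#' @param threshold joint-reliability cutoff (default 0.4); `NA` disables
#'   filtering.
#' @param smoothingSigma temporal smoothing (seconds) for trial averages.
#' @return nested list: `perPopulation` (one entry per population) and
#'   `rsa` (within/cross Spearman rho between the populations' Grams).
#' @export
analyzeSessionPair <- function(pairSet, threshold = 0.4,
                               smoothingSigma = 0) {
  stopifnot(is(pairSet, "SessionPairSet"))
  grams <- list()
  perPop <- lapply(1:2, function(popI) {
    pair <- populationPair(pairSet, popI)
    cm <- if (is.na(threshold)) pair@cellMap
          else jointReliableFilter(pair, threshold)
    if (nrow(cm) < 3)
      stop(sprintf("population %d: fewer than 3 jointly reliable cells", popI))
    ta <- .subsetTensor(pair@a, cm[, 1])
    tb <- .subsetTensor(pair@b, cm[, 2])
    avgA <- trialAverage(ta, smoothingSigma = smoothingSigma)
    avgB <- trialAverage(tb, smoothingSigma = smoothingSigma)
    labels <- c(pair@a@taskLabel, pair@b@taskLabel)
    if (labels[1] == labels[2]) labels <- paste0(labels, c(".a", ".b"))
    joint <- pcaJoint(avgA, avgB, taskLabels = labels)
    taskA <- pcaTask(avgA, labels[1]); taskB <- pcaTask(avgB, labels[2])
    proc <- procrustesRotation(joint@scores[[1]][, 1:2],
                               joint@scores[[2]][, 1:2])
    relA <- splitHalfReliability(pair@a, cm[, 1])
    relB <- splitHalfReliability(pair@b, cm[, 2])
    cellCor <- vapply(seq_len(nrow(cm)), function(i)
      cor(avgA[, i], avgB[, i]), numeric(1))
    cellCorTrue <- vapply(seq_len(nrow(cm)), function(i)
      suppressWarnings(attenuationCorrectedCorrelation(
        avgA[, i], avgB[, i], relA[i, ], relB[i, ])), numeric(1))
    grams[[popI]] <<- rsaGram(rbind(avgA, avgB),
                              factor(rep(labels, each = nrow(avgA))))
    list(cellMap = cm,
         jointSet = joint, taskSetA = taskA, taskSetB = taskB,
         crossTaskPcCor = crossTaskPcCorrelation(joint)$mean,
         procrustesAngle = proc$angle,
         elongation = pairElongation(taskA, taskB, joint)$summary,
         prA = participationRatio(taskA), prB = participationRatio(taskB),
         medianCellCor = median(cellCor),
         medianCellCorCorrected = median(cellCorTrue, na.rm = TRUE))
  })
  names(perPop) <- c("pop1", "pop2")
  list(perPopulation = perPop,
       rsa = list(within = rsaCompare(grams[[1]], grams[[2]], "within"),
                  cross = rsaCompare(grams[[1]], grams[[2]], "cross")),
       pairwiseCorrPreservation = vapply(1:2, function(popI) {
         pair <- populationPair(pairSet, popI)
         cm <- perPop[[popI]]$cellMap
         pairwiseCorrPreservation(.subsetTensor(pair@a, cm[, 1]),
                                  .subsetTensor(pair@b, cm[, 2]))
       }, numeric(1)))
}

#' Plot top-2 trajectories of a TrajectorySet
#'
#' @param x a [TrajectorySet].
#' @param y ignored.
#' @param ... passed to [graphics::matplot()]-style base plotting.
#' @export
setMethod("plot", signature(x = "TrajectorySet", y = "missing"),
          function(x, y, ...) {
  blocks <- x@scores
  xy <- do.call(rbind, lapply(blocks, function(m) m[, 1:2]))
  graphics::plot(xy[, 1], xy[, 2], type = "n", xlab = "PC1", ylab = "PC2",
                 main = sprintf("%s-space trajectories", x@space), ...)
  for (i in seq_along(blocks))
    graphics::lines(blocks[[i]][, 1], blocks[[i]][, 2], col = i, lwd = 2)
  graphics::legend("topright", legend = names(blocks),
                   col = seq_along(blocks), lwd = 2, bty = "n")
})
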