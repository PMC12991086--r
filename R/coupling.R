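## Cross-population and cross-session predictive analyses: CCA communicating
## subspaces, cross-population regression transfer, LDA state decoding.

#' Whole-session frame matrix from a trial tensor
#'
#' Concatenates all trials along time into a `[frames, neuron]` matrix, the
#' input expected by [ccaSubspace()] and [pairwiseCorrPreservation()]-style
#' single-trial analyses.
#'
#' @param tensor a [TrialTensor].
#' @param neurons optional neuron indices.
#' @export
sessionMatrix <- function(tensor, neurons = NULL) {
  v <- tensor@values
  if (!is.null(neurons)) v <- v[neurons, , , drop = FALSE]
  t(matrix(v, nrow = dim(v)[1]))
}

## Inverse square root of a regularized covariance block
.invSqrtCov <- function(C, ridge) {
  p <- ncol(C)
  Cr <- C + diag(ridge * sum(diag(C)) / p, p)
  eg <- eigen(Cr, symmetric = TRUE)
  eg$vectors %*% diag(1 / sqrt(pmax(eg$values, .Machine$double.eps)), p) %*%
    t(eg$vectors)
}

#' Canonical-correlation communicating subspace between two populations
#'
#' Fits CCA on the concatenation of both tasks' whole-session frame matrices
#' and evaluates each canonical variable's correlation separately within each
#' task's frames using the common weights. Covariance blocks are ridge
#' regularized (shrinkage relative to their trace) to handle whole-session
#' collinearity. CVs are retained when their correlation in the fitting data
#' exceeds `retainThreshold`.
#'
#' @param xA,yA `[frames, neuron]` matrices of populations X and Y in task A.
#' @param xB,yB the same populations in task B (frame-aligned within task).
#' @param ridge shrinkage relative to the covariance trace (default 1e-3).
#' @param retainThreshold retention cutoff on the fitted correlation
#'   (default 0.1).
#' @param nComponents number of CVs (default `min(ncol(x), ncol(y))`).
#' @return list with `correlations` (fitting data), `perTask` (matrix of
#'   within-task CV correlations, tasks in columns), `weightsX`, `weightsY`,
#'   and `retained` (logical).
#' @export
ccaSubspace <- function(xA, yA, xB, yB, ridge = 1e-3, retainThreshold = 0.1,
                        nComponents = NULL) {
  stopifnot(nrow(xA) == nrow(yA), nrow(xB) == nrow(yB))
  X <- rbind(xA, xB); Y <- rbind(yA, yB)
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  Cxx <- crossprod(Xc) / (n - 1)
  Cyy <- crossprod(Yc) / (n - 1)
  Cxy <- crossprod(Xc, Yc) / (n - 1)
  Wx <- .invSqrtCov(Cxx, ridge); Wy <- .invSqrtCov(Cyy, ridge)
  sv <- svd(Wx %*% Cxy %*% Wy)
  k <- if (is.null(nComponents)) min(ncol(X), ncol(Y))
       else min(nComponents, ncol(X), ncol(Y))
  wX <- Wx %*% sv$u[, seq_len(k), drop = FALSE]
  wY <- Wy %*% sv$v[, seq_len(k), drop = FALSE]
  corSafe <- function(a, b)
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  fitCor <- vapply(seq_len(k), function(i)
    corSafe(Xc %*% wX[, i], Yc %*% wY[, i]), numeric(1))
  taskCor <- function(x, y) {
    xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
    vapply(seq_len(k), function(i)
      corSafe(xc %*% wX[, i], yc %*% wY[, i]), numeric(1))
  }
  perTask <- cbind(A = taskCor(xA, yA), B = taskCor(xB, yB))
  list(correlations = pmin(pmax(fitCor, 0), 1), perTask = perTask,
       weightsX = wX, weightsY = wY,
       retained = fitCor > retainThreshold)
}

#' Cross-session transfer of a population-to-population linear map
#'
#' Fits an ordinary least-squares linear map from the top `nPredictorPcs`
#' predictor-population shared-space PC scores to the top `nTargetPcs`
#' target-population shared-space PC scores on a training session, then
#' evaluates it on a held-out session. Accuracy is the squared Pearson
#' correlation between predicted and actual target scores, averaged over
#' target components.
#'
#' @param trainX,trainY `[time, pcs]` predictor/target score matrices of the
#'   training session.
#' @param testX,testY the same for the test session.
#' @param nPredictorPcs,nTargetPcs requested component counts (default 20
#'   and 2); if fewer are available the available count is used with a
#'   warning.
#' @param condition label (`"same_task"` or `"cross_task"`) carried through.
#' @return list with `rSquared`, `perComponent`, `condition` and the fitted
#'   `coefficients`.
#' @export
transferRegression <- function(trainX, trainY, testX, testY,
                               nPredictorPcs = 20, nTargetPcs = 2,
                               condition = c("same_task", "cross_task")) {
  condition <- match.arg(condition)
  if (ncol(trainX) < nPredictorPcs || ncol(trainY) < nTargetPcs)
    warning(sprintf("only %d predictor / %d target PCs available; using those",
                    ncol(trainX), ncol(trainY)), call. = FALSE)
  p <- min(nPredictorPcs, ncol(trainX), ncol(testX))
  q <- min(nTargetPcs, ncol(trainY), ncol(testY))
  Xtr <- cbind(1, trainX[, seq_len(p), drop = FALSE])
  beta <- qr.solve(Xtr, trainY[, seq_len(q), drop = FALSE])
  pred <- cbind(1, testX[, seq_len(p), drop = FALSE]) %*% beta
  r2 <- vapply(seq_len(q), function(i) {
    a <- pred[, i]; b <- testY[, i]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)^2
  }, numeric(1))
  list(rSquared = mean(r2), perComponent = r2, condition = condition,
       coefficients = beta)
}

#' Per-trial epoch features in a shared PC space
#'
#' Projects every single trial of a tensor onto shared-space loadings (using
#' the z-scoring parameters of the session's trial average so single trials
#' land in the same space) and averages the projection over each epoch's
#' frames, yielding one feature vector per trial and epoch.
#'
#' @param tensor a [TrialTensor].
#' @param loadings `[neuron, component]` shared-space loadings.
#' @param center,scale per-neuron z-scoring parameters (defaults taken from
#'   the session's own [trialAverage()]).
#' @param epochs named list of `[start, end)` windows in seconds (default
#'   delay `[-1, 0)` and reward `[0, 1)`).
#' @param nPcs number of leading components (default 2).
#' @return list with `features` (`[trial*epoch, nPcs]`), `labels` (factor)
#'   and `trial` (index).
#' @export
epochFeatures <- function(tensor, loadings, center = NULL, scale = NULL,
                          epochs = list(delay = c(-1, 0), reward = c(0, 1)),
                          nPcs = 2) {
  avg <- trialAverage(tensor, smoothingSigma = 0)
  if (is.null(center)) center <- attr(avg, "center")
  if (is.null(scale)) scale <- attr(avg, "scale")
  L <- loadings[, seq_len(min(nPcs, ncol(loadings))), drop = FALSE]
  ta <- tensor@timeAxis
  nTr <- nTrials(tensor)
  feats <- vector("list", length(epochs) * nTr)
  labels <- character(length(feats)); trial <- integer(length(feats))
  k <- 0L
  for (r in seq_len(nTr)) {
    z <- sweep(sweep(t(tensor@values[, , r]), 2, center), 2, scale, "/")
    proj <- z %*% L
    for (e in seq_along(epochs)) {
      k <- k + 1L
      inWin <- ta >= epochs[[e]][1] & ta < epochs[[e]][2]
      feats[[k]] <- colMeans(proj[inWin, , drop = FALSE])
      labels[k] <- names(epochs)[e]; trial[k] <- r
    }
  }
  list(features = do.call(rbind, feats), labels = factor(labels),
       trial = trial)
}

#' Two-class linear discriminant state decoder
#'
#' Fits a Fisher linear discriminant (pooled within-class covariance, equal
#' priors, shrinkage-regularized when singular) on training-session epoch
#' features and classifies test-session features by thresholding the
#' projection at the midpoint of the projected class means. Accuracy is the
#' percentage of correctly classified trial epochs.
#'
#' @param trainFeatures,trainLabels training feature matrix and two-level
#'   factor.
#' @param testFeatures,testLabels test-session features and labels.
#' @param shrinkage ridge added to the pooled covariance relative to its
#'   trace (default 1e-6; raised automatically if singular).
#' @param condition label carried through.
#' @return list with `accuracy` (percent), `axis`, `threshold`, `projection`
#'   (test features on the axis) and `condition`.
#' @export
ldaStateDecoder <- function(trainFeatures, trainLabels, testFeatures,
                            testLabels, shrinkage = 1e-6,
                            condition = c("same_task", "cross_task")) {
  condition <- match.arg(condition)
  trainLabels <- factor(trainLabels); lev <- levels(trainLabels)
  stopifnot(length(lev) == 2)
  X <- as.matrix(trainFeatures)
  m0 <- colMeans(X[trainLabels == lev[1], , drop = FALSE])
  m1 <- colMeans(X[trainLabels == lev[2], , drop = FALSE])
  Sw <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xl <- X[trainLabels == l, , drop = FALSE]
    Xl <- sweep(Xl, 2, colMeans(Xl))
    Sw <- Sw + crossprod(Xl)
  }
  Sw <- Sw / (nrow(X) - 2)
  lam <- shrinkage * sum(diag(Sw)) / ncol(X)
  w <- tryCatch(solve(Sw + diag(lam, ncol(X)), m1 - m0),
                error = function(e)
                  solve(Sw + diag(max(lam, 1e-3 * sum(diag(Sw)) / ncol(X)) +
                                    1e-12, ncol(X)), m1 - m0))
  thr <- sum(w * (m0 + m1)) / 2              # midpoint of projected means
  proj <- as.matrix(testFeatures) %*% w
  predicted <- ifelse(drop(proj) > thr, lev[2], lev[1])
  acc <- 100 * mean(predicted == as.character(testLabels))
  list(accuracy = acc, axis = w, threshold = thr, projection = drop(proj),
       condition = condition)
}

#' Project continuous time courses onto a discriminant axis
#'
#' Convenience for the decoding time-course visualization: projects a
#' session's trial-averaged shared-space PC scores onto a fitted
#' discriminant axis.
#'
#' @param scoreMatrix `[time, pcs]` score block.
#' @param decoder result of [ldaStateDecoder()].
#' @export
decoderTimeCourse <- function(scoreMatrix, decoder) {
  drop(scoreMatrix[, seq_along(decoder$axis), drop = FALSE] %*% decoder$axis) -
    decoder$threshold
}
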