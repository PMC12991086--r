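## Per-task and joint-task PCA, participation-ratio dimensionality,
## saturation curves, PC coherence and cross-task PC correlations.

## PCA core on a time x neuron matrix: eigendecomposition of the time
## covariance (1/(T-1)), components sorted by variance, sign fixed so each
## loading vector's largest-magnitude entry is positive.
.pcaCore <- function(x) {
  if (any(!is.finite(x))) stop("non-finite values in input matrix")
  tt <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  C <- crossprod(xc) / (tt - 1)
  eg <- eigen(C, symmetric = TRUE)
  k <- min(tt - 1L, ncol(x))
  lam <- pmax(eg$values[seq_len(k)], 0)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  signs <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  signs[signs == 0] <- 1
  V <- sweep(V, 2, signs, "*")
  list(loadings = V, eigenvalues = lam, scores = xc %*% V,
       totalVariance = sum(diag(C)))
}

#' Task-space PCA of a trial-averaged activity matrix
#'
#' Eigendecomposition of the time covariance of a (typically z-scored)
#' `[time, neuron]` trial-averaged matrix, with components sorted by variance
#' and a deterministic sign convention (largest-magnitude loading entry
#' positive).
#'
#' @param avgMatrix numeric `[time, neuron]` matrix (>= 2 rows and columns),
#'   e.g. from [trialAverage()].
#' @param taskLabel name for the single score block.
#' @return a [TrajectorySet] with `space = "task"`.
#' @export
pcaTask <- function(avgMatrix, taskLabel = "task") {
  stopifnot(nrow(avgMatrix) >= 2, ncol(avgMatrix) >= 2)
  p <- .pcaCore(avgMatrix)
  sc <- list(p$scores); names(sc) <- taskLabel
  tv <- p$totalVariance; names(tv) <- taskLabel
  new("TrajectorySet", scores = sc, loadings = p$loadings,
      eigenvalues = p$eigenvalues,
      varianceFraction = p$eigenvalues / p$totalVariance,
      taskVariance = tv, space = "task")
}

#' Joint-task PCA on temporally concatenated matrices
#'
#' The two tasks' (independently z-scored) trial-averaged matrices are
#' concatenated along the temporal dimension and a single PCA is fitted,
#' yielding one common set of loadings; scores are split back into per-task
#' blocks.
#'
#' @param avgA,avgB numeric `[time, neuron]` matrices over the same tracked
#'   neurons, in cell-map order.
#' @param taskLabels names for the two blocks.
#' @return a [TrajectorySet] with `space = "joint"` and two score blocks.
#' @export
pcaJoint <- function(avgA, avgB, taskLabels = c("A", "B")) {
  if (ncol(avgA) != ncol(avgB))
    stop("the two matrices must have the same neurons (columns)")
  tA <- nrow(avgA)
  p <- .pcaCore(rbind(avgA, avgB))
  sc <- list(p$scores[seq_len(tA), , drop = FALSE],
             p$scores[-seq_len(tA), , drop = FALSE])
  names(sc) <- taskLabels
  tv <- c(sum(apply(avgA, 2, var)), sum(apply(avgB, 2, var)))
  names(tv) <- taskLabels
  new("TrajectorySet", scores = sc, loadings = p$loadings,
      eigenvalues = p$eigenvalues,
      varianceFraction = p$eigenvalues / p$totalVariance,
      taskVariance = tv, space = "joint")
}

#' Participation ratio
#'
#' Effective dimensionality of a covariance spectrum,
#' `PR = (sum lambda)^2 / sum lambda^2`; 1 for rank-1 spectra and N for an
#' isotropic N-dimensional spectrum.
#'
#' @param eigenvalues numeric nonnegative eigenvalues (or a [TrajectorySet]).
#' @export
participationRatio <- function(eigenvalues) {
  if (is(eigenvalues, "TrajectorySet")) eigenvalues <- eigenvalues@eigenvalues
  if (all(eigenvalues == 0)) stop("all-zero spectrum: PR undefined")
  sum(eigenvalues)^2 / sum(eigenvalues^2)
}

#' Participation-ratio saturation curve
#'
#' Recomputes the participation ratio on random neuron subsamples of
#' increasing size (without replacement), averaging over bootstrap draws, to
#' check that the dimensionality estimate saturates below the full population
#' size.
#'
#' @param tensor a [TrialTensor] (trial-averaged and z-scored internally) or
#'   a precomputed `[time, neuron]` matrix.
#' @param intervals number of cell-count levels from 1 to N (default 20).
#' @param bootstraps random subsamples per level (default 50).
#' @param seed integer RNG seed.
#' @param smoothingSigma passed to [trialAverage()] when `tensor` is a
#'   [TrialTensor].
#' @return list with `pr` (full population), `curve` (data.frame of
#'   `nCells`, `meanPr`) and `nBootstrap`.
#' @export
prSaturation <- function(tensor, intervals = 20, bootstraps = 50, seed = 1,
                         smoothingSigma = 0) {
  x <- if (is(tensor, "TrialTensor"))
    trialAverage(tensor, smoothingSigma = smoothingSigma) else tensor
  n <- ncol(x)
  set.seed(seed)
  counts <- unique(round(seq(1, n, length.out = min(intervals, n))))
  meanPr <- vapply(counts, function(k) {
    mean(vapply(seq_len(bootstraps), function(b) {
      idx <- sample.int(n, k)
      if (k == 1) return(1)
      participationRatio(.pcaCore(x[, idx, drop = FALSE])$eigenvalues)
    }, numeric(1)))
  }, numeric(1))
  list(pr = participationRatio(.pcaCore(x)$eigenvalues),
       curve = data.frame(nCells = counts, meanPr = meanPr),
       nBootstrap = bootstraps)
}

#' Coherence of joint-task PCs
#'
#' Ratio of the variance of a joint PC's task-block scores to the expected
#' variance of a random unit-vector projection of that task's matrix. The
#' expectation is computed analytically as the task's total variance divided
#' by the number of neurons (the mean of `u' C u` over random unit `u`);
#' a Monte-Carlo sampler over random projections is kept as a test oracle.
#'
#' @param jointSet a joint-space [TrajectorySet].
#' @param task block name or index.
#' @param components which PCs (default all).
#' @return numeric coherence per component.
#' @export
pcCoherence <- function(jointSet, task, components = NULL) {
  stopifnot(is(jointSet, "TrajectorySet"), jointSet@space == "joint")
  sc <- jointSet@scores[[task]]
  if (is.null(components)) components <- seq_len(ncol(sc))
  nNeurons <- nrow(jointSet@loadings)
  expectedVar <- jointSet@taskVariance[[task]] / nNeurons
  apply(sc[, components, drop = FALSE], 2, var) / expectedVar
}

#' Cross-task correlation of joint-PC activity profiles
#'
#' Pearson correlation between the two tasks' score blocks for each of the
#' top `topK` joint PCs, averaged.
#'
#' @param jointSet a joint-space [TrajectorySet] with two blocks.
#' @param topK number of leading PCs (default 2).
#' @return list with `perComponent` and `mean`.
#' @export
crossTaskPcCorrelation <- function(jointSet, topK = 2) {
  stopifnot(is(jointSet, "TrajectorySet"), length(jointSet@scores) == 2)
  a <- jointSet@scores[[1]]; b <- jointSet@scores[[2]]
  k <- min(topK, ncol(a))
  rs <- vapply(seq_len(k), function(i) cor(a[, i], b[, i]), numeric(1))
  list(perComponent = rs, mean = mean(rs))
}

#' Monte-Carlo variance of random unit-vector projections (test oracle for
#' [pcCoherence()]'s analytic expectation)
#'
#' @param x `[time, neuron]` matrix.
#' @param nDraws random directions.
#' @param seed RNG seed.
#' @keywords internal
#' @export
randomProjectionVariance <- function(x, nDraws = 2000, seed = 1) {
  set.seed(seed)
  n <- ncol(x)
  mean(vapply(seq_len(nDraws), function(i) {
    u <- rnorm(n); u <- u / sqrt(sum(u^2))
    var(x %*% u)
  }, numeric(1)))
}
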