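## Manifold-transformation metrics: Procrustes rotation, isoperimetric
## circularity, elongation, temporal-covariance RSA and pairwise-correlation
## preservation.

#' Planar Procrustes rotation between two trajectories
#'
#' Finds the similarity transform (translation + scale + rotation, no
#' reflection) best mapping trajectory A onto trajectory B in the least
#' squares sense and reports the magnitude of its angular component in
#' \[0, 180\] degrees. Reflections are excluded by forcing the rotation's
#' determinant to +1; an improper optimum is reported via the `reflection`
#' flag instead.
#'
#' @param trajA,trajB numeric `[time, 2]` trajectories (equal lengths),
#'   typically top-2 shared-space score blocks.
#' @return list with `angle` (degrees), `scale` (factor applied to A),
#'   `disparity` (residual sum of squares), `rotation` (2x2 matrix) and
#'   `reflection` (logical).
#' @export
procrustesRotation <- function(trajA, trajB) {
  stopifnot(ncol(trajA) == 2, ncol(trajB) == 2, nrow(trajA) == nrow(trajB))
  A <- scale(trajA, center = TRUE, scale = FALSE)
  B <- scale(trajB, center = TRUE, scale = FALSE)
  na <- sum(A^2); nb <- sum(B^2)
  if (na == 0 || nb == 0) {
    warning("degenerate (zero-variance) trajectory: rotation undefined",
            call. = FALSE)
    return(list(angle = NA_real_, scale = NA_real_, disparity = NA_real_,
                rotation = matrix(NA_real_, 2, 2), reflection = NA))
  }
  M <- crossprod(A, B)                       # maps A -> B
  sv <- svd(M)
  properSign <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, properSign))
  R <- sv$u %*% D %*% t(sv$v)                # rotation, det +1
  traceS <- sum(diag(D) * sv$d)
  s <- traceS / na
  disparity <- nb - traceS^2 / na
  angle <- abs(atan2(R[2, 1], R[1, 1])) * 180 / pi
  list(angle = angle, scale = s, disparity = max(disparity, 0), rotation = R,
       reflection = properSign < 0)
}

## Segment self-intersection test for a closed polygon (O(T^2) orientation
## checks); adjacent segments share endpoints and are skipped.
.selfIntersects <- function(x, y) {
  n <- length(x)
  if (n < 4) return(FALSE)
  xs <- c(x, x[1]); ys <- c(y, y[1])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    o1 <- orient(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[js], ys[js])
    o2 <- orient(xs[i], ys[i], xs[i + 1], ys[i + 1], xs[js + 1], ys[js + 1])
    o3 <- orient(xs[js], ys[js], xs[js + 1], ys[js + 1], xs[i], ys[i])
    o4 <- orient(xs[js], ys[js], xs[js + 1], ys[js + 1], xs[i + 1], ys[i + 1])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0))
      return(TRUE)
  }
  FALSE
}

#' Isoperimetric circularity of a closed 2-D trajectory
#'
#' `4 pi Area / Perimeter^2`, where the trajectory is closed by joining its
#' last point back to the first, the area is the absolute shoelace sum and
#' the perimeter includes the closing segment. 1.0 for a perfect circle,
#' approaching 0 for elongated or convoluted curves. For self-intersecting
#' trajectories even-odd regions may cancel in the shoelace sum; such curves
#' are flagged via the `selfIntersecting` attribute, not rejected.
#'
#' @param traj numeric `[time, 2]` trajectory with >= 3 points.
#' @param checkSelfIntersection logical; the O(T^2) test can be skipped.
#' @return circularity value with attribute `selfIntersecting`.
#' @export
circularity <- function(traj, checkSelfIntersection = TRUE) {
  stopifnot(ncol(traj) == 2, nrow(traj) >= 3)
  x <- traj[, 1]; y <- traj[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  if (perim == 0) {
    warning("zero perimeter: circularity undefined", call. = FALSE)
    return(NA_real_)
  }
  out <- 4 * pi * area / perim^2
  attr(out, "selfIntersecting") <-
    if (checkSelfIntersection) .selfIntersects(x, y) else NA
  out
}

#' Trajectory elongation (loss of circularity in shared space)
#'
#' `1 - circShared / circTask` per session: how much rounder the trajectory
#' is in its own task space than in the shared (joint-PCA) space, indexing
#' out-of-plane separation. Values may be negative (the shared-space curve
#' can be rounder); they are reported unclipped.
#'
#' @param circShared,circTask circularity values (vectorized).
#' @export
elongation <- function(circShared, circTask) {
  if (any(circTask == 0, na.rm = TRUE))
    stop("task-space circularity of 0: elongation undefined")
  1 - as.numeric(circShared) / as.numeric(circTask)
}

#' Session-pair elongation summary
#'
#' Computes, for each session of a pair, the circularity of the top-2
#' trajectory in its own task space and in the shared space, takes the
#' per-session elongation and summarizes the pair by the maximum across the
#' two sessions.
#'
#' @param taskSetA,taskSetB task-space [TrajectorySet]s of the two sessions.
#' @param jointSet the shared-space [TrajectorySet] with two blocks.
#' @return list with `perSession` (named length-2) and `summary` (max).
#' @export
pairElongation <- function(taskSetA, taskSetB, jointSet) {
  top2 <- function(m) m[, 1:2, drop = FALSE]
  circ <- function(m) as.numeric(circularity(top2(m),
                                             checkSelfIntersection = FALSE))
  e <- c(elongation(circ(jointSet@scores[[1]]), circ(scores(taskSetA))),
         elongation(circ(jointSet@scores[[2]]), circ(scores(taskSetB))))
  names(e) <- names(jointSet@scores)
  list(perSession = e, summary = max(e))
}

#' Temporal Gram matrix for representational similarity analysis
#'
#' Entry (i, j) is the dot product of the population activity vectors at
#' timepoints i and j — the unnormalized temporal covariance, preserving the
#' magnitude of population activation.
#'
#' @param avgMatrix numeric `[time, neuron]` matrix (typically the z-scored
#'   trial averages of both tasks concatenated along time).
#' @param blockIndex optional factor (length `nrow`) labeling each
#'   timepoint's task; defaults to a single block.
#' @return a [GramMatrix].
#' @export
rsaGram <- function(avgMatrix, blockIndex = NULL) {
  if (is.null(blockIndex))
    blockIndex <- factor(rep("all", nrow(avgMatrix)))
  new("GramMatrix", values = tcrossprod(avgMatrix),
      blockIndex = as.factor(blockIndex))
}

#' Compare two Gram matrices by Spearman rank correlation
#'
#' Vectorizes the upper-triangular entries of both matrices (optionally
#' restricted to within-task or cross-task blocks) and reports Spearman's
#' rho.
#'
#' @param g1,g2 [GramMatrix] objects on matching time axes.
#' @param blocks `"all"`, `"within"` (both timepoints in the same task) or
#'   `"cross"` (timepoints in different tasks).
#' @return Spearman's rho.
#' @export
rsaCompare <- function(g1, g2, blocks = c("all", "within", "cross")) {
  blocks <- match.arg(blocks)
  stopifnot(nrow(g1@values) == nrow(g2@values))
  n <- nrow(g1@values)
  up <- upper.tri(g1@values)
  if (blocks != "all") {
    same <- outer(g1@blockIndex, g1@blockIndex, "==")
    up <- up & (if (blocks == "within") same else !same)
  }
  v1 <- g1@values[up]; v2 <- g2@values[up]
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("constant Gram entries: Spearman rho undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(v1, v2, method = "spearman")
}

#' Cross-task preservation of pairwise neural correlations
#'
#' For each session, computes the neuron-by-neuron Pearson correlation matrix
#' over all single-trial frames (time and trials concatenated), then reports
#' the Pearson correlation between the two sessions' vectorized upper
#' triangles.
#'
#' @param tensorA,tensorB [TrialTensor]s over the same tracked cells (same
#'   neuron count and order).
#' @return Pearson correlation of the upper-triangular correlation entries.
#' @export
pairwiseCorrPreservation <- function(tensorA, tensorB) {
  stopifnot(nNeurons(tensorA) == nNeurons(tensorB))
  corMat <- function(tensor) {
    v <- tensor@values
    m <- matrix(v, nrow = dim(v)[1])        # neuron x (time*trial)
    cor(t(m))
  }
  up <- upper.tri(diag(nNeurons(tensorA)))
  cor(corMat(tensorA)[up], corMat(tensorB)[up])
}
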