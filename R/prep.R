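## Trial averaging, reliability statistics, single-neuron timing metrics and
## behavioral lick metrics.

## Gaussian smoothing with edge renormalization (kernel truncated at 4 sigma).
## sigmaSamples in units of samples; <= 0 returns the input unchanged.
.gaussSmooth <- function(x, sigmaSamples) {
  if (sigmaSamples <= 0) return(x)
  r <- max(1L, ceiling(4 * sigmaSamples))
  k <- stats::dnorm(seq(-r, r), sd = sigmaSamples)
  k <- k / sum(k)
  n <- length(x)
  num <- stats::convolve(c(numeric(r), x, numeric(r)), rev(k), type = "filter")
  den <- stats::convolve(c(numeric(r), rep(1, n), numeric(r)), rev(k),
                         type = "filter")
  num / den
}

#' Trial-averaged, smoothed, z-scored activity matrix
#'
#' Averages a [TrialTensor] over a trial subset, Gaussian-smooths each
#' neuron's average along time, and optionally z-scores each neuron's trace
#' (population SD, i.e. divisor `T`; constant traces map to zeros). Per-neuron
#' centering/scaling parameters are attached as attributes `center` and
#' `scale` so single trials can be projected into the same space.
#'
#' @param tensor a [TrialTensor].
#' @param trialSubset integer trial indices (default all).
#' @param smoothingSigma Gaussian kernel SD in seconds (default 0.015);
#'   a value below the frame interval makes smoothing near-identity and is
#'   flagged with a warning.
#' @param zscore logical, z-score each neuron's average.
#' @return numeric `[time, neuron]` matrix.
#' @export
trialAverage <- function(tensor, trialSubset = NULL, smoothingSigma = 0.015,
                         zscore = TRUE) {
  stopifnot(is(tensor, "TrialTensor"))
  if (is.null(trialSubset)) trialSubset <- seq_len(nTrials(tensor))
  if (length(trialSubset) == 0) stop("trial subset must be nonempty")
  frameInterval <- 1 / tensor@frameRate
  if (smoothingSigma > 0 && smoothingSigma < frameInterval)
    warning("smoothing sigma below the frame interval; smoothing is near-identity",
            call. = FALSE)
  avg <- apply(tensor@values[, , trialSubset, drop = FALSE], c(1, 2), mean)
  sigmaSamples <- smoothingSigma * tensor@frameRate
  if (sigmaSamples > 0)
    avg <- t(apply(avg, 1, .gaussSmooth, sigmaSamples = sigmaSamples))
  out <- t(avg)                              # time x neuron
  ctr <- colMeans(out)
  scl <- rep(1, ncol(out))
  if (zscore) {
    tt <- nrow(out)
    sds <- sqrt(colMeans(out^2) - ctr^2)     # population SD (divisor T)
    scl <- ifelse(sds > 0, sds, Inf)         # constant trace -> zeros
    out <- sweep(sweep(out, 2, ctr), 2, scl, "/")
    scl[!is.finite(scl)] <- 1
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "timeAxis") <- tensor@timeAxis
  out
}

.clip1 <- function(x) pmin(1, pmax(-1, x))

#' Split-half reliability with Spearman-Brown correction and prophecy
#' standardization
#'
#' For each neuron, `r` is the Pearson correlation between the trial-averaged
#' traces of odd- versus even-numbered trials (1-based numbering: trial 1 is
#' odd). The full-session reliability is the Spearman-Brown correction
#' `R_raw = 2 r / (1 + r)`, and `R_adj` standardizes it to a fixed reference
#' trial count via the prophecy formula
#' `R_adj = K R_raw / (1 + (K - 1) R_raw)` with `K = kRef / nTrials`.
#' All values are clipped to \[-1, 1\]. A half with zero variance yields
#' reliability 0 with a warning.
#'
#' @param tensor a [TrialTensor].
#' @param neurons integer indices (default all).
#' @param kRef reference trial count (default 100).
#' @return a data.frame with columns `neuron`, `rOddEven`, `Rraw`, `Radj`,
#'   `nTrials`, `kRef`.
#' @export
splitHalfReliability <- function(tensor, neurons = NULL, kRef = 100) {
  stopifnot(is(tensor, "TrialTensor"))
  nTr <- nTrials(tensor)
  if (nTr < 4) stop("need at least 4 trials for a split-half estimate")
  if (is.null(neurons)) neurons <- seq_len(nNeurons(tensor))
  odd <- seq(1, nTr, by = 2)
  even <- seq(2, nTr, by = 2)
  degenerate <- FALSE
  r <- vapply(neurons, function(i) {
    a <- rowMeans(tensor@values[i, , odd, drop = TRUE])
    b <- rowMeans(tensor@values[i, , even, drop = TRUE])
    if (sd(a) == 0 || sd(b) == 0) { degenerate <<- TRUE; return(0) }
    cor(a, b)
  }, numeric(1))
  if (degenerate)
    warning("zero-variance half for some neuron(s); reliability set to 0",
            call. = FALSE)
  r <- .clip1(r)
  Rraw <- .clip1(2 * r / (1 + r))
  K <- kRef / nTr
  Radj <- .clip1(K * Rraw / (1 + (K - 1) * Rraw))
  data.frame(neuron = neurons, rOddEven = r, Rraw = Rraw, Radj = Radj,
             nTrials = nTr, kRef = kRef)
}

#' Spearman-Brown prophecy formula
#'
#' Predicted reliability when the trial count is multiplied by `K`.
#'
#' @param Rraw full-length reliability in \[-1, 1\].
#' @param K length multiplier (> 0).
#' @export
prophecy <- function(Rraw, K) .clip1(K * Rraw / (1 + (K - 1) * Rraw))

#' Restrict a cell map to jointly reliable neurons
#'
#' Keeps exactly the tracked cells whose prophecy-standardized reliability
#' `R_adj` strictly exceeds `threshold` in *both* sessions of the pair,
#' preserving order. The result may be empty; downstream operations must
#' reject empty maps themselves.
#'
#' @param pair a [SessionPair].
#' @param threshold reliability cutoff (default 0.4).
#' @param kRef reference trial count for the prophecy standardization.
#' @return the filtered two-column cell map, with per-session `Radj` values
#'   attached as attributes `RadjA` and `RadjB`.
#' @export
jointReliableFilter <- function(pair, threshold = 0.4, kRef = 100) {
  stopifnot(is(pair, "SessionPair"))
  cm <- pair@cellMap
  relA <- splitHalfReliability(pair@a, cm[, 1], kRef = kRef)$Radj
  relB <- splitHalfReliability(pair@b, cm[, 2], kRef = kRef)$Radj
  keep <- relA > threshold & relB > threshold
  out <- cm[keep, , drop = FALSE]
  attr(out, "RadjA") <- relA[keep]
  attr(out, "RadjB") <- relB[keep]
  out
}

#' Attenuation-corrected cross-session correlation
#'
#' Disattenuates the raw Pearson correlation between two trial-averaged
#' traces by the sessions' internal reliabilities:
#' `r_true = r_raw / sqrt(r_xx * r_yy)`, clipped to \[-1, 1\] (clipping is
#' flagged with a warning). Reliabilities may be given as numbers or as rows
#' of [splitHalfReliability()] output (the `Rraw` full-session reliability is
#' used).
#'
#' @param avgA,avgB numeric trial-averaged traces (equal length).
#' @param relA,relB reliabilities: numerics, or single-row data.frames with
#'   an `Rraw` column.
#' @return the corrected correlation, or `NA` (with a warning) when either
#'   reliability is non-positive.
#' @export
attenuationCorrectedCorrelation <- function(avgA, avgB, relA, relB) {
  getRel <- function(r) if (is.data.frame(r)) r$Rraw[1] else as.numeric(r)[1]
  rxx <- getRel(relA); ryy <- getRel(relB)
  if (!is.finite(rxx) || !is.finite(ryy) || rxx <= 0 || ryy <= 0) {
    warning("non-positive reliability: corrected correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  raw <- cor(avgA, avgB)
  rtrue <- raw / sqrt(rxx * ryy)
  if (abs(rtrue) > 1)
    warning("corrected correlation exceeded 1 in magnitude; clipped",
            call. = FALSE)
  .clip1(rtrue)
}

#' Peak time and full width at half maximum of a trial-averaged trace
#'
#' The peak is the maximum of the trace within the window. The baseline is
#' the trace minimum (z-scored traces have no natural zero), the half-maximum
#' level is `min + (max - min)/2`, and the FWHM is the time between the first
#' and last crossings of that level, located by linear interpolation between
#' frames. If the trace sits above the half-maximum at either window edge the
#' width is censored and `NA` is returned; a flat trace yields `NA` for both.
#'
#' @param avgTrace numeric trace.
#' @param timeAxis numeric time axis (same length).
#' @return list with `peakTime` and `fwhm` (seconds).
#' @export
peakAndFwhm <- function(avgTrace, timeAxis) {
  stopifnot(length(avgTrace) == length(timeAxis))
  if (max(avgTrace) == min(avgTrace))
    return(list(peakTime = NA_real_, fwhm = NA_real_))
  peakIdx <- which.max(avgTrace)
  half <- min(avgTrace) + (max(avgTrace) - min(avgTrace)) / 2
  y <- avgTrace - half
  if (y[1] >= 0 || y[length(y)] >= 0)   # censored at a window edge
    return(list(peakTime = timeAxis[peakIdx], fwhm = NA_real_))
  s <- which(y[-1] * y[-length(y)] <= 0 & y[-length(y)] != 0)
  crossT <- timeAxis[s] - y[s] * (timeAxis[s + 1] - timeAxis[s]) /
    (y[s + 1] - y[s])
  exact <- timeAxis[y == 0]
  crossT <- sort(c(crossT, exact))
  list(peakTime = timeAxis[peakIdx],
       fwhm = max(crossT) - min(crossT))
}

#' Predictive licking score
#'
#' Per-trial lick rates are computed in the anticipatory window \[-0.5, 0) s
#' and the consumption window \[1.0, 1.5) s relative to reward; the score is
#' `pre / (pre + post)` of the across-trial median rates, so 1 means purely
#' anticipatory and 0 purely reactive licking. Trials flagged as having a
#' stuck sensor are excluded.
#'
#' @param lick a [LickTrain].
#' @return list with `lickPre`, `lickPost` (Hz) and `score`; the score is
#'   `NA` (with a warning) when both median rates are zero.
#' @export
predictiveLickingScore <- function(lick) {
  stopifnot(is(lick, "LickTrain"))
  valid <- which(!lick@stuck)
  if (length(valid) == 0) stop("no valid trials after stuck-sensor exclusion")
  rateIn <- function(ev, lo, hi) sum(ev >= lo & ev < hi) / (hi - lo)
  pre <- vapply(lick@events[valid], rateIn, numeric(1), lo = -0.5, hi = 0)
  post <- vapply(lick@events[valid], rateIn, numeric(1), lo = 1.0, hi = 1.5)
  lickPre <- median(pre); lickPost <- median(post)
  if (lickPre + lickPost == 0) {
    warning("zero median lick rate in both windows: score undefined",
            call. = FALSE)
    score <- NA_real_
  } else score <- lickPre / (lickPre + lickPost)
  list(lickPre = lickPre, lickPost = lickPost, score = score)
}

#' Dual-task licking score
#'
#' The minimum of the two tasks' predictive licking scores: high only when
#' the animal licks predictively in both contexts.
#'
#' @param scoreTaskA,scoreTaskB scores (numbers or [predictiveLickingScore()]
#'   results).
#' @export
dualTaskScore <- function(scoreTaskA, scoreTaskB) {
  g <- function(s) if (is.list(s)) s$score else s
  min(g(scoreTaskA), g(scoreTaskB))
}

#' Smoothed lick-rate traces
#'
#' Bins lick events at 1 kHz over the session window, smooths with a Gaussian
#' kernel, and optionally normalizes the trial-averaged rate to its peak.
#'
#' @param lick a [LickTrain].
#' @param sigma Gaussian kernel SD in seconds (default 0.033).
#' @param normalize logical: divide the trial-averaged rate by its peak.
#' @return list with `time` (bin centers, s), `rate` (`[trial, time]` Hz)
#'   and `meanRate` (trial average; peak-normalized if requested).
#' @export
smoothLickRate <- function(lick, sigma = 0.033, normalize = FALSE) {
  stopifnot(is(lick, "LickTrain"))
  dt <- 0.001
  edges <- seq(lick@window[1], lick@window[2], by = dt)
  centers <- edges[-length(edges)] + dt / 2
  rate <- t(vapply(lick@events, function(ev) {
    counts <- tabulate(findInterval(ev, edges, rightmost.closed = TRUE),
                       nbins = length(centers))
    .gaussSmooth(counts / dt, sigma / dt)
  }, numeric(length(centers))))
  meanRate <- colMeans(rate)
  if (normalize && max(meanRate) > 0) meanRate <- meanRate / max(meanRate)
  list(time = centers, rate = rate, meanRate = meanRate)
}
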