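test_that("trial averaging is the identity for a single raw trial", {
  arr <- array(rnorm(5 * 40 * 1), dim = c(5, 40, 1))
  tens <- tensorFromArray(arr)
  avg <- trialAverage(tens, smoothingSigma = 0, zscore = FALSE)
  expect_equal(unname(avg), t(arr[, , 1]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("averaging two mirrored trials cancels and constants z-score to zero", {
  v <- array(0, dim = c(3, 30, 2))
  v[, , 1] <- rnorm(90); v[, , 2] <- -v[, , 1]
  expect_true(all(abs(trialAverage(tensorFromArray(v), smoothingSigma = 0,
                                   zscore = FALSE)) < 1e-12))
  const <- array(7, dim = c(2, 30, 3))
  z <- trialAverage(tensorFromArray(const), smoothingSigma = 0, zscore = TRUE)
  expect_true(all(z == 0))
})

test_that("sub-frame-interval smoothing is flagged; empty subsets are rejected", {
  arr <- array(rnorm(2 * 30 * 2), dim = c(2, 30, 2))
  tens <- tensorFromArray(arr, frameRate = 10)   # frame interval 0.1 s
  expect_warning(trialAverage(tens, smoothingSigma = 0.015), "near-identity")
  expect_error(trialAverage(tens, trialSubset = integer(0)), "nonempty")
})

test_that("Gaussian smoothing preserves a constant and the trace mass", {
  x <- c(numeric(50), 10, numeric(50))
  y <- manifoldRemap:::.gaussSmooth(x, 3)
  expect_equal(sum(y), sum(x), tolerance = 1e-6)
  expect_equal(manifoldRemap:::.gaussSmooth(rep(2, 40), 5), rep(2, 40),
               tolerance = 1e-12)
})

test_that("split-half reliability follows the Spearman-Brown algebra", {
  set.seed(1)
  arr <- array(rep(sin(seq(0, 3 * pi, length.out = 50)), 8 * 20),
               dim = c(1, 50, 20))  # replicate one neuron trace
  arr <- arr[, , 1:20, drop = FALSE] + array(rnorm(50 * 20, sd = 0.5),
                                             dim = c(1, 50, 20))
  rel <- splitHalfReliability(tensorFromArray(arr), kRef = 100)
  r <- rel$rOddEven
  expect_equal(rel$Rraw, 2 * r / (1 + r), tolerance = 1e-12)
  K <- 100 / 20
  expect_equal(rel$Radj, K * rel$Rraw / (1 + (K - 1) * rel$Rraw),
               tolerance = 1e-12)
  # at the reference trial count the prophecy is the identity
  arr100 <- array(rnorm(30 * 100), dim = c(1, 30, 100))
  rel100 <- splitHalfReliability(tensorFromArray(arr100), kRef = 100)
  expect_equal(rel100$Radj, rel100$Rraw, tolerance = 1e-12)
  # perfectly repeated trials: r = 1 is a fixed point for any K
  noiseless <- array(rep(cos(seq_len(30)), 8), dim = c(1, 30, 8))
  relP <- splitHalfReliability(tensorFromArray(noiseless), kRef = 100)
  expect_equal(relP$rOddEven, 1)
  expect_equal(relP$Radj, 1)
})

test_that("reliability of a zero-variance half is 0 with a warning", {
  arr <- array(0, dim = c(1, 20, 6))
  expect_warning(rel <- splitHalfReliability(tensorFromArray(arr)),
                 "zero-variance")
  expect_equal(rel$Radj, 0)
  expect_error(splitHalfReliability(tensorFromArray(arr[, , 1:3, drop = FALSE])),
               "at least 4")
})

test_that("the prophecy formula is strictly increasing in K", {
  for (Rraw in c(0.1, 0.5, 0.9)) {
    Ks <- c(0.5, 1, 2, 5, 10)
    expect_true(all(diff(prophecy(Rraw, Ks)) > 0))
  }
  expect_equal(prophecy(0.5, 1), 0.5)
})

test_that("the joint-reliability filter keeps exactly the cells above threshold in both sessions", {
  set.seed(33)
  nT <- 40; tt <- 50
  sig <- sin(seq(0, 4 * pi, length.out = tt))
  mkTensor <- function(noiseSds) {
    arr <- array(0, dim = c(length(noiseSds), tt, nT))
    for (i in seq_along(noiseSds))
      arr[i, , ] <- sig + rnorm(tt * nT, sd = noiseSds[i])
    tensorFromArray(arr)
  }
  # neurons 1-3 reliable in both; 4 only in a; 5 only in b; 6 in neither
  ta <- mkTensor(c(0.1, 0.1, 0.1, 0.1, 30, 30))
  tb <- mkTensor(c(0.1, 0.1, 0.1, 30, 0.1, 30))
  pair <- sessionPair(ta, tb, cbind(1:6, 1:6))
  cm <- jointReliableFilter(pair, threshold = 0.4)
  expect_equal(unname(cm[, 1]), 1:3)
  # agrees with a manual recomputation of the rule
  ra <- splitHalfReliability(ta)$Radj
  rb <- splitHalfReliability(tb)$Radj
  expect_equal(unname(cm[, 1]), which(ra > 0.4 & rb > 0.4))
  expect_equal(unname(attr(cm, "RadjA")), ra[cm[, 1]])
})

test_that("attenuation correction rescales, clips and rejects as specified", {
  set.seed(2)
  a <- rnorm(60); b <- a + rnorm(60, sd = 1)
  raw <- cor(a, b)   # ~0.7 with this seed
  expect_equal(attenuationCorrectedCorrelation(a, b, 1, 1), raw)
  expect_equal(attenuationCorrectedCorrelation(a, b, 0.81, 0.81), raw / 0.81)
  # clipping contract: quotient above 1 clips with a warning
  expect_warning(r1 <- attenuationCorrectedCorrelation(a, b, 0.5, 0.5),
                 "clipped")
  expect_equal(r1, 1)
  expect_warning(rna <- attenuationCorrectedCorrelation(a, b, 0, 1),
                 "non-positive")
  expect_true(is.na(rna))
})

test_that("peak time and FWHM match closed forms", {
  t <- seq(-2, 2, by = 0.004)
  gauss <- exp(-(t - 0.5)^2 / (2 * 0.2^2))
  res <- peakAndFwhm(gauss, t)
  expect_equal(res$peakTime, 0.5, tolerance = 0.005)
  expect_equal(res$fwhm, 2 * sqrt(2 * log(2)) * 0.2, tolerance = 1e-3)
  # symmetric triangle of half-width w has FWHM exactly w
  w <- 0.8
  tri <- pmax(0, 1 - abs(t) / w)
  expect_equal(peakAndFwhm(tri, t)$fwhm, w, tolerance = 1e-6)
  # monotone ramp peaks at the window edge; width right-censored
  ramp <- peakAndFwhm(t, t)
  expect_equal(ramp$peakTime, 2)
  expect_true(is.na(ramp$fwhm))
  flat <- peakAndFwhm(rep(1, length(t)), t)
  expect_true(is.na(flat$peakTime) && is.na(flat$fwhm))
})

test_that("lick scores follow the pre/post ratio, the min rule and exclusions", {
  # one lick at -0.25 s (2 Hz pre) and one at 1.25 s (2 Hz post) per trial
  mk <- function(n, stuck = rep(FALSE, n))
    new("LickTrain", events = rep(list(c(-0.25, 1.25)), n),
        trialOutcomes = rep("rewarded", n), stuck = stuck, window = c(-2, 2))
  sc <- predictiveLickingScore(mk(10))
  expect_equal(sc$lickPre, 2); expect_equal(sc$lickPost, 2)
  expect_equal(sc$score, 0.5)
  expect_equal(dualTaskScore(0.8, 0.3), 0.3)
  expect_equal(dualTaskScore(sc, list(score = 0.9)), 0.5)
  expect_error(predictiveLickingScore(mk(5, stuck = rep(TRUE, 5))),
               "no valid trials")
  # licks outside both windows: undefined score
  empty <- new("LickTrain", events = rep(list(1.9), 4),
               trialOutcomes = rep("rewarded", 4), stuck = rep(FALSE, 4),
               window = c(-2, 2))
  expect_warning(s0 <- predictiveLickingScore(empty), "undefined")
  expect_true(is.na(s0$score))
})

test_that("smoothed lick rates integrate to the event count", {
  l <- new("LickTrain", events = list(0.2, numeric(0)),
           trialOutcomes = c("rewarded", "rewarded"), stuck = c(FALSE, FALSE),
           window = c(-2, 2))
  sm <- smoothLickRate(l, sigma = 0.033)
  expect_equal(sum(sm$rate[1, ]) * 0.001, 1, tolerance = 1e-6)
  expect_true(all(sm$rate[2, ] == 0))
  smn <- smoothLickRate(l, normalize = TRUE)
  expect_equal(max(smn$meanRate), 1)
})
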