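test_that("Procrustes recovers constructed rotations, scales and identities", {
  set.seed(10)
  A <- cbind(cos(seq(0, 2 * pi, length.out = 50)) * c(1.3),
             sin(seq(0, 2 * pi, length.out = 50)))
  rot <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  }
  B <- A %*% t(rot(30))
  res <- procrustesRotation(A, B)
  expect_equal(res$angle, 30, tolerance = 1e-8)
  expect_lt(res$disparity, 1e-12)
  expect_false(res$reflection)
  # identity
  resI <- procrustesRotation(A, A)
  expect_equal(resI$angle, 0, tolerance = 1e-8)
  expect_equal(resI$scale, 1, tolerance = 1e-10)
  # similarity invariance: scale + offset recovered, zero angle
  res2 <- procrustesRotation(A, 2 * A + 5)
  expect_equal(res2$angle, 0, tolerance = 1e-8)
  expect_equal(res2$scale, 2, tolerance = 1e-10)
  expect_lt(res2$disparity, 1e-10)
})

test_that("Procrustes angle is invariant to common similarity transforms and pairing order", {
  set.seed(11)
  A <- matrix(rnorm(40 * 2), 40, 2)
  B <- matrix(rnorm(40 * 2), 40, 2)
  base <- procrustesRotation(A, B)$angle
  expect_equal(procrustesRotation(3 * A + 2, 3 * B + 2)$angle, base,
               tolerance = 1e-8)
  expect_equal(procrustesRotation(B, A)$angle, base, tolerance = 1e-8)
  expect_warning(bad <- procrustesRotation(matrix(1, 40, 2), B), "degenerate")
  expect_true(is.na(bad$angle))
})

test_that("circularity matches closed forms for circle, square and degenerate curves", {
  expect_equal(as.numeric(circularity(circleTraj(1000))), 1, tolerance = 1e-4)
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(as.numeric(circularity(square)), pi / 4, tolerance = 1e-12)
  collinear <- cbind(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10))
  expect_equal(as.numeric(circularity(collinear)), 0)
  expect_warning(circularity(matrix(1, 5, 2)), "zero perimeter")
  # isoperimetric bound for simple closed curves
  set.seed(12)
  blob <- circleTraj(100) * (1 + 0.2 * sin(3 * (1:100)))
  expect_lte(as.numeric(circularity(blob)), 1)
})

test_that("self-intersecting trajectories are flagged but still scored", {
  # figure eight, phase-offset so the crossing is not a shared vertex
  th <- seq(0, 2 * pi, length.out = 201)[-201] + 0.0137
  eight <- cbind(sin(2 * th), sin(th))
  c8 <- circularity(eight)
  expect_true(attr(c8, "selfIntersecting"))
  expect_false(attr(circularity(circleTraj(50)), "selfIntersecting"))
})

test_that("elongation follows the shared/task circularity ratio and the max rule", {
  expect_equal(elongation(0.08, 0.8), 0.9)
  expect_equal(elongation(0.5, 0.5), 0)
  expect_error(elongation(0.1, 0), "undefined")
  expect_equal(max(c(0.2, 0.9)), 0.9)  # pair summary is the max across sessions
  # planted out-of-plane gain produces positive pair elongation
  ps <- generateSessionPair(noiselessConfig(crossContextRotation = 0,
                                            elongationGain = 3,
                                            nNeuronsPop2 = 40))
  pair <- populationPair(ps, 2)
  avgA <- trialAverage(sessionA(pair), smoothingSigma = 0)
  avgB <- trialAverage(sessionB(pair), smoothingSigma = 0)
  j <- pcaJoint(avgA, avgB)
  pe <- pairElongation(pcaTask(avgA), pcaTask(avgB), j)
  expect_gt(pe$summary, 0.1)
  expect_equal(pe$summary, max(pe$perSession))
})

test_that("the temporal Gram is invariant to orthonormal neuron rotations and Spearman to monotone maps", {
  set.seed(13)
  x <- matrix(rnorm(30 * 15), 30, 15)
  g1 <- rsaGram(x)
  expect_equal(rsaCompare(g1, g1), 1)
  Q <- qr.Q(qr(matrix(rnorm(225), 15, 15)))
  g2 <- rsaGram(x %*% Q)
  expect_equal(g2@values, g1@values, tolerance = 1e-10)
  expect_equal(rsaCompare(g1, g2), 1, tolerance = 1e-10)
  # monotone (cubic) distortion leaves ranks unchanged
  g3 <- new("GramMatrix", values = (g1@values)^3, blockIndex = g1@blockIndex)
  expect_equal(rsaCompare(g1, g3), 1)
})

test_that("within- and cross-task block selection picks the right Gram entries", {
  blocks <- factor(c("R", "R", "V", "V"))
  m <- matrix(0, 4, 4); m[upper.tri(m)] <- 1:6; m <- m + t(m)
  g <- new("GramMatrix", values = m, blockIndex = blocks)
  gRef <- new("GramMatrix", values = m^2, blockIndex = blocks)  # monotone on positives
  # manual masks: within pairs (1,2) and (3,4); cross pairs the other four
  same <- outer(blocks, blocks, "==")
  up <- upper.tri(m)
  expect_equal(rsaCompare(g, gRef, "within"),
               cor(m[up & same], (m^2)[up & same], method = "spearman"))
  expect_equal(rsaCompare(g, gRef, "cross"),
               cor(m[up & !same], (m^2)[up & !same], method = "spearman"))
})

test_that("RSA cross-task similarity degrades with planted rotation while within-task holds", {
  rhoW <- c(); rhoC <- c()
  for (phi in c(0, 90)) {
    ps <- generateSessionPair(noiselessConfig(crossContextRotation = phi,
                                              nNeuronsPop1 = 30,
                                              nNeuronsPop2 = 40))
    grams <- lapply(1:2, function(p) {
      pair <- populationPair(ps, p)
      avgA <- trialAverage(sessionA(pair), smoothingSigma = 0)
      avgB <- trialAverage(sessionB(pair), smoothingSigma = 0)
      rsaGram(rbind(avgA, avgB), factor(rep(c("A", "B"), each = nrow(avgA))))
    })
    rhoW <- c(rhoW, rsaCompare(grams[[1]], grams[[2]], "within"))
    rhoC <- c(rhoC, rsaCompare(grams[[1]], grams[[2]], "cross"))
  }
  expect_true(all(rhoW > 0.95))        # within-task geometry preserved
  expect_gt(rhoC[1], 0.95)             # no rotation: cross-task preserved too
  expect_lt(rhoC[2], rhoC[1] - 0.3)    # rotation breaks cross-task geometry
})

test_that("pairwise correlation preservation detects identity, null and sign structure", {
  set.seed(14)
  arr <- array(rnorm(100 * 20 * 4), dim = c(100, 20, 4))
  tens <- tensorFromArray(arr)
  expect_equal(pairwiseCorrPreservation(tens, tens), 1)
  indep <- tensorFromArray(array(rnorm(100 * 20 * 4), dim = c(100, 20, 4)))
  expect_lt(abs(pairwiseCorrPreservation(tens, indep)), 0.1)
  # flipping cluster structure between sessions yields a negative value
  z <- rnorm(80)
  mk <- function(signs) {
    a <- array(0, dim = c(4, 20, 4))
    for (i in 1:4) a[i, , ] <- signs[i] * z + rnorm(80, sd = 0.05)
    tensorFromArray(a)
  }
  expect_lt(pairwiseCorrPreservation(mk(c(1, 1, -1, -1)), mk(c(1, -1, 1, -1))),
            -0.2)
})
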