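test_that("task geometry embeds the sheared circle as specified", {
  g <- taskGeometry(seed = 3)
  # invariants of the construction
  expect_equal(crossprod(g@embedding), diag(2), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(g@embedding, g@tPerp))), 1e-10)
  expect_equal(det(g@shear), 1)
  expect_equal(drop(g@shear %*% c(0, 1)), c(0.2, 1))  # theta = pi/2 base point
  d1 <- makeTaskDataset(g, 1, noise = FALSE, seed = 5)
  # projecting inputs back into the plane recovers the sheared circle
  back <- d1@inputs %*% g@embedding
  expected <- t(g@shear %*% rbind(cos(d1@phases), sin(d1@phases)))
  expect_equal(back, expected, tolerance = 1e-10)
  # targets are the base manifold rotated in-plane by 40 degrees
  backT <- d1@targets %*% g@embedding
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(backT, t(R %*% t(expected)), tolerance = 1e-10)
})

test_that("tasks differ by the constant out-of-plane translation", {
  g <- taskGeometry(seed = 4)
  d1 <- makeTaskDataset(g, 1, noise = FALSE, seed = 9)
  d2 <- makeTaskDataset(g, 2, noise = FALSE, seed = 9)  # same phases
  diffs <- d2@inputs - d1@inputs
  expect_equal(diffs, matrix(g@tPerp, nrow(diffs), ncol(diffs), byrow = TRUE),
               tolerance = 1e-10)
  expect_lt(max(abs(diffs %*% g@embedding)), 1e-10)  # orthogonal to the plane
  # noiseless input covariance has rank exactly 2
  ev <- eigen(stats::cov(d1@inputs), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 1e-10 * ev[1]), 2)
})

test_that("pink noise has the requested spectral slope and is reproducible", {
  pnA <- pinkNoise(512, 5, beta = 1, seed = 7)
  pnB <- pinkNoise(512, 5, beta = 1, seed = 7)
  expect_identical(pnA, pnB)
  expect_equal(colMeans(pnA), numeric(5), tolerance = 1e-12)
  expect_equal(sqrt(colMeans(pnA^2)), rep(1, 5), tolerance = 1e-12)
  slope <- function(x) {
    p <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
    mid <- p$freq > 0.01 & p$freq < 0.3
    unname(coef(lm(log(p$spec[mid]) ~ log(p$freq[mid])))[2])
  }
  expect_lt(abs(mean(apply(pnA, 2, slope)) + 1), 0.2)
  white <- pinkNoise(512, 5, beta = 0, seed = 8)
  expect_lt(abs(mean(apply(white, 2, slope))), 0.2)
})

test_that("every granule cell receives exactly 4 inputs and W_exp survives training untouched", {
  g <- taskGeometry(seed = 1)
  m <- circuitModel("relay", g, nGranule = 400, seed = 2)
  expect_true(all(Matrix::rowSums(m@Wexp != 0) == 4))
  d1 <- makeTaskDataset(g, 1, seed = 3)
  d2 <- makeTaskDataset(g, 2, seed = 4)
  fit <- trainCurriculum(m, d1, d2, phases = c(1L, 2L), epochsPerPhase = 3,
                         seed = 5)
  expect_identical(fit$model@Wexp, m@Wexp)
  expect_false(identical(fit$model@Wout, m@Wout))
})

test_that("forward passes implement the three architectures", {
  g <- taskGeometry(seed = 6)
  relay <- circuitModel("relay", g, nGranule = 300, seed = 7)
  rot <- circuitModel("rotation", g, nGranule = 300, seed = 7)  # same Wexp
  expect_true(all(granuleForward(relay, numeric(100)) == 0))
  # rotation model == relay model applied to the in-plane-transformed input
  x <- matrix(rnorm(5 * 100), 5, 100)
  E <- g@embedding
  for (task in 1:2) {
    Tc <- rot@transforms[[task]]
    xFull <- t(E %*% Tc %*% t(x %*% E)) + (x - (x %*% E) %*% t(E))
    expect_equal(granuleForward(rot, x, task), granuleForward(relay, xFull),
                 tolerance = 1e-10)
    # out-of-plane component is untouched by the task transform
    expect_equal(xFull - (xFull %*% E) %*% t(E), x - (x %*% E) %*% t(E),
                 tolerance = 1e-10)
  }
  exp5 <- circuitModel("expansion", g, nGranule = 300, seed = 7)
  expect_error(granuleForward(exp5, rbind(numeric(100))), "zero-norm")
  # expansion normalizes: scaling the input does not change activations
  expect_equal(granuleForward(exp5, x), granuleForward(exp5, 10 * x),
               tolerance = 1e-10)
})

test_that("expansion-model activity is sparse on the task input distribution", {
  fr <- vapply(1:3, function(s) {
    g <- taskGeometry(seed = s)
    activeFraction(circuitModel("expansion", g, nGranule = 2000, seed = s),
                   makeTaskDataset(g, 1, seed = s + 50))
  }, numeric(1))
  expect_true(all(fr > 0.003 & fr < 0.025))
})

test_that("training descends, is seed-reproducible, and freezes at zero learning rate", {
  g <- taskGeometry(seed = 8)
  d1 <- makeTaskDataset(g, 1, seed = 11)
  d2 <- makeTaskDataset(g, 2, seed = 12)
  m <- circuitModel("relay", g, nGranule = 300, seed = 13)
  frozen <- trainCurriculum(m, d1, d2, lr = 0, phases = c(1L),
                            epochsPerPhase = 6, seed = 14)
  # weights exactly frozen; epoch losses constant up to batch-composition
  # jitter (the final partial batch reweights the mean across shuffles)
  expect_equal(frozen$model@Wout, m@Wout)
  expect_identical(frozen$model@bout, m@bout)
  expect_lt(diff(range(frozen$trace@epochLoss)), 0.05)
  fitA <- trainCurriculum(m, d1, d2, phases = c(1L), epochsPerPhase = 30,
                          seed = 14)
  fitB <- trainCurriculum(m, d1, d2, phases = c(1L), epochsPerPhase = 30,
                          seed = 14)
  expect_identical(fitA$trace@epochLoss, fitB$trace@epochLoss)
  expect_lt(utils::tail(fitA$trace@epochLoss, 1), fitA$trace@epochLoss[1])
  # previous-task loss exists only after the first phase
  two <- trainCurriculum(m, d1, d2, phases = c(1L, 2L), epochsPerPhase = 5,
                         seed = 15)
  expect_true(all(is.na(two$trace@prevTaskLoss[1:5])))
  expect_true(all(is.finite(two$trace@prevTaskLoss[6:10])))
})

test_that("learning-speed fits recover known exponentials and flag flat curves", {
  t <- 0:99
  clean <- 2 * exp(-t / 20) + 0.1
  fit <- learningSpeed(clean)
  expect_equal(fit$tau, 20, tolerance = 0.01)
  expect_equal(fit$speed, 0.05, tolerance = 0.01)
  set.seed(30)
  recovered <- vapply(1:5, function(i)
    learningSpeed(clean + rnorm(100, sd = 0.02))$tau, numeric(1))
  expect_true(all(abs(recovered - 20) / 20 < 0.1))
  flat <- learningSpeed(rep(0.5, 50))
  expect_true(isTRUE(flat$flat) || is.na(flat$speed))
  expect_error(learningSpeed(1:5), "at least 10")
})

test_that("Jaccard overlap matches a brute-force per-sample computation", {
  g <- taskGeometry(seed = 16)
  m <- circuitModel("rotation", g, nGranule = 150, seed = 17)
  d1 <- makeTaskDataset(g, 1, seed = 18)
  d2 <- makeTaskDataset(g, 2, seed = 19)
  jac <- jaccardOverlap(m, d1, d2)
  h1 <- granuleForward(m, d1@inputs, 1); h2 <- granuleForward(m, d2@inputs, 2)
  brute <- mean(vapply(seq_len(nrow(h1)), function(i) {
    A <- which(h1[i, ] > 0); B <- which(h2[i, ] > 0)
    length(intersect(A, B)) / length(union(A, B))
  }, numeric(1)), na.rm = TRUE)
  expect_equal(jac, brute, tolerance = 1e-12)
  # identical activation sets give exactly 1 (relay model, same data)
  relay <- circuitModel("relay", g, nGranule = 150, seed = 17)
  expect_equal(jaccardOverlap(relay, d1, d1), 1)
})

test_that("granule PCA variance is concentrated for the relay on noiseless low-rank input", {
  g <- taskGeometry(seed = 20)
  relay <- circuitModel("relay", g, nGranule = 400, seed = 21)
  d1 <- makeTaskDataset(g, 1, noise = FALSE, seed = 22)
  d2 <- makeTaskDataset(g, 2, noise = FALSE, seed = 22)
  pv <- grcPcaVariance(relay, d1, d2, nPcs = 20)
  expect_gt(pv$fraction, 0.99)
  expect_equal(pv$perComponent,
               grcPcaVariance(relay, d1, d2, nPcs = 20)$perComponent)
})

test_that("shattering preserves norms, respects the amplitude-zero identity, and crumples geometry", {
  g <- taskGeometry(seed = 23)
  d <- makeTaskDataset(g, 1, seed = 24)
  x <- d@inputs
  expect_identical(shatterInputs(x, d@phases, nFolds = 8, amplitude = 0), x)
  expect_identical(shatterInputs(x, d@phases, nFolds = 0), x)
  sh <- shatterInputs(x, d@phases, nFolds = 16, amplitude = 0.5, seed = 25)
  expect_equal(sqrt(rowSums(sh^2)), sqrt(rowSums(x^2)), tolerance = 1e-10)
  expect_gt(mean(abs(sh - x)), 0.01)
  shB <- shatterInputs(x, d@phases, nFolds = 16, amplitude = 0.5, seed = 25)
  expect_identical(sh, shB)
})

test_that("expansion spreads activation variance across more PCs than relay", {
  # the ordering needs a large granule layer: the sparse code's effective
  # dimensionality grows with population size, so a fixed 20-PC window
  # captures less of it only once the layer is big enough (CI scale 2000)
  g <- taskGeometry(seed = 26)
  d1 <- makeTaskDataset(g, 1, seed = 27)
  d2 <- makeTaskDataset(g, 2, seed = 28)
  relay <- circuitModel("relay", g, nGranule = 2000, seed = 29)
  expansion <- circuitModel("expansion", g, nGranule = 2000, seed = 29)
  expect_gt(grcPcaVariance(relay, d1, d2)$fraction,
            grcPcaVariance(expansion, d1, d2)$fraction)
})
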