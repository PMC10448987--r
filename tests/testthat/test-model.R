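test_that("head probabilities obey closed forms and sum to one", {
  # zero weights: uniform over classes by symmetry
  z <- rnorm(5)
  expect_equal(unname(batchHeadProbs(z, matrix(0, 5, 3))), rep(1 / 3, 3))
  # logistic at 0 and at log 3
  expect_equal(unname(batchHeadProbs(c(1, 1), c(0, 0))), c(0.5, 0.5))
  psi <- c(log(3), 0)
  expect_equal(unname(batchHeadProbs(c(1, 0), psi))[2], 0.75)
  # bio head shares the contract; disabled head errors
  expect_equal(unname(bioHeadProbs(z, matrix(0, 5, 4))), rep(0.25, 4))
  expect_error(bioHeadProbs(z, NULL), "disabled")
  expect_error(batchHeadProbs(c(1, NaN), c(1, 1)), "finite")
})

test_that("logistic and two-class softmax parameterizations agree", {
  set.seed(3)
  z <- matrix(rnorm(20 * 4), 20, 4)
  psi <- rnorm(4)
  pLogistic <- batchHeadProbs(z, psi)
  pSoftmax <- batchHeadProbs(z, cbind(0, psi))
  expect_equal(unname(pLogistic), unname(pSoftmax), tolerance = 1e-12)
})

test_that("softmax head matches an independent recomputation", {
  set.seed(4)
  for (i in 1:100) {
    d <- sample(2:6, 1)
    M <- sample(2:5, 1)
    z <- rnorm(d)
    om <- matrix(rnorm(d * M), d, M)
    got <- if (M == 2) bioHeadProbs(z, om[, 2] - om[, 1])
           else bioHeadProbs(z, om)
    e <- exp(drop(z %*% om))
    expect_equal(unname(got), unname(e / sum(e)), tolerance = 1e-10)
  }
})

test_that("joint loss decomposes exactly into its four weighted terms", {
  set.seed(5)
  p <- beene:::cpp_init_params(c(8L, 6L, 3L), c(3L, 6L, 8L), 2L, 3L, 1L)
  X <- matrix(rnorm(40), 5, 8)
  blab <- c(0L, 1L, 0L, 1L, 1L)
  ylab <- c(0L, 1L, 2L, 0L, 2L)
  spec <- list(lambdas = c(0.7, 2.5, 1.3), l2Coeff = 1e-4)
  lp <- jointLoss(X, blab, ylab, p, spec)
  expect_equal(lp$total,
               0.7 * lp$reconstruction + 2.5 * lp$batchCE + 1.3 * lp$bioCE +
                 1e-4 * lp$l2,
               tolerance = 1e-8)
  expect_error(jointLoss(X, c(0L, 1L, 0L, 1L, 2L), ylab, p, spec),
               "out of")
})

test_that("uniform batch head on one cell gives the log-2 cross entropy", {
  p <- beene:::cpp_init_params(c(4L, 3L, 2L), c(2L, 3L, 4L), 2L, 0L, 1L)
  p$psi[] <- 0
  p$psi_b[] <- 0
  spec <- list(lambdas = c(0, 2, 0), l2Coeff = 0)
  lp <- jointLoss(matrix(rnorm(4), 1, 4), 0L, NULL, p, spec)
  expect_equal(lp$total, 2 * log(2), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(6)
  p <- beene:::cpp_init_params(c(8L, 6L, 3L), c(3L, 6L, 8L), 2L, 3L, 2L)
  X <- matrix(rnorm(40), 5, 8)
  blab <- c(0L, 1L, 0L, 1L, 1L)
  ylab <- c(0L, 1L, 2L, 0L, 2L)
  lam <- c(1, 2, 1); l2c <- 1e-4
  g <- beene:::cpp_grad(X, blab, ylab, p, lam[1], lam[2], lam[3], l2c)
  gFlat <- flattenParams(g)
  pFlat <- flattenParams(p)
  lossAt <- function(v) beene:::cpp_loss(X, blab, ylab,
                                         unflattenParams(v, p),
                                         lam[1], lam[2], lam[3], l2c)$total
  eps <- 1e-5
  idx <- seq_along(pFlat)   # every parameter, ~150 of them
  fd <- vapply(idx, function(i) {
    up <- pFlat; up[i] <- up[i] + eps
    dn <- pFlat; dn[i] <- dn[i] - eps
    (lossAt(up) - lossAt(dn)) / (2 * eps)
  }, numeric(1))
  relErr <- abs(fd - gFlat[idx]) / pmax(1e-6, abs(fd) + abs(gFlat[idx]))
  expect_lt(max(relErr), 1e-4)
})

test_that("training reduces the loss and is seed-deterministic", {
  be <- makeSeparableData()
  sp <- standardizeGenes(splitCells(be, seed = 2))
  cfg <- trainConfig(maxEpochs = 40, patience = 40, seed = 5,
                     batchSize = 16)
  m1 <- trainBeene(sp, spec = tinySpec(40L), config = cfg)
  lg <- m1@trainLog
  expect_lt(lg$train_total[lg$epoch == m1@bestEpoch],
            lg$train_total[lg$epoch == 0])
  m2 <- trainBeene(sp, spec = tinySpec(40L), config = cfg)
  expect_identical(m1@params$W, m2@params$W)
  expect_identical(m1@params$psi, m2@params$psi)
  m3 <- trainBeene(sp, spec = tinySpec(40L),
                   config = trainConfig(maxEpochs = 40, patience = 40,
                                        seed = 6, batchSize = 16))
  expect_false(identical(m1@params$W, m3@params$W))
})

test_that("batch head reaches high held-out accuracy on separable data", {
  be <- makeSeparableData(n = 200L, D = 40L)
  sp <- standardizeGenes(splitCells(be, seed = 3))
  m <- trainBeene(sp, spec = tinySpec(40L),
                  config = trainConfig(maxEpochs = 60, patience = 60,
                                       seed = 1, batchSize = 16))
  test <- partition(sp, "test")
  z <- encodeCells(m, cellMatrix(test), applyNormStats = FALSE)
  probs <- beene:::cpp_head_probs(z, m@params, "batch")
  acc <- mean((probs[, 2] > 0.5) == (batchCodes(test) == 1L))
  expect_gt(acc, 0.95)
})

test_that("encoding is deterministic, shape-correct and functional", {
  be <- makeSeparableData()
  sp <- standardizeGenes(splitCells(be, seed = 2))
  m <- trainBeene(sp, spec = tinySpec(40L),
                  config = trainConfig(maxEpochs = 10, seed = 1))
  xTest <- cellMatrix(partition(sp, "test"))
  z1 <- encodeCells(m, xTest, applyNormStats = FALSE)
  expect_equal(dim(z1), c(nrow(xTest), 10L))
  expect_identical(z1, encodeCells(m, xTest, applyNormStats = FALSE))
  # identical cells embed identically
  dup <- xTest[c(1, 1), , drop = FALSE]
  zd <- encodeCells(m, dup, applyNormStats = FALSE)
  expect_identical(zd[1, ], zd[2, ])
  expect_error(encodeCells(m, xTest[, 1:10]), "features")
})

test_that("named variants carry the published hyperparameter regimes", {
  expect_equal(beeneVariantSpec("default", 2500)$lambdas, c(1, 2, 1))
  nb <- beeneVariantSpec("no_bio", 2500)
  expect_equal(nb$lambdas[3], 0)
  hd <- beeneVariantSpec("high_dim", 11000)
  expect_equal(hd$inputDropout, 0.70)
  expect_equal(hd$lambdas[1:2], c(0.001, 5.0))
  pc <- beeneVariantSpec("pc_input", 100)
  expect_equal(pc$encoderHidden, 50L)
  expect_equal(pc$latentDim, 20L)
  expect_equal(beeneVariantSpec("default", 2500)$encoderHidden,
               c(200L, 100L))
  expect_equal(beeneVariantSpec("default", 2500)$latentDim, 50L)
  expect_error(beeneModelSpec(100, lambdas = c(1, 0, 1)), "lambda2")
  expect_error(beeneModelSpec(10, latentDim = 10), "smaller")
})

test_that("a bio head cannot be requested without biological labels", {
  be <- makeSeparableData(n = 80L, D = 60L)
  SummarizedExperiment::colData(be)$bio <- NULL
  sp <- standardizeGenes(splitCells(be, seed = 2))
  expect_error(trainBeene(sp, spec = tinySpec(60L),
                          config = trainConfig(maxEpochs = 2)),
               "bio")
  # variant default silently falls back to no_bio (latent 50 fits D = 60)
  m <- trainBeene(sp, variant = "default",
                  config = trainConfig(maxEpochs = 2))
  expect_null(m@params$omega)
})

test_that("the unguided autoencoder lower-bounds the guided reconstruction", {
  be <- makeSeparableData(n = 120L, D = 30L)
  sp <- standardizeGenes(splitCells(be, seed = 4))
  tr <- partition(sp, "train"); vl <- partition(sp, "val")
  sizes <- list(enc = c(30L, 16L, 6L), dec = c(6L, 16L, 30L))
  run <- function(l2w) {
    p0 <- beene:::cpp_init_params(sizes$enc, sizes$dec, 2L, 0L, 9L)
    fit <- beene:::cpp_train(cellMatrix(tr), batchCodes(tr), integer(0),
                             cellMatrix(vl), batchCodes(vl), integer(0),
                             p0, 1, l2w, 0, 1e-4, 0.0, 0.0,
                             16L, 60L, 60L, 1e-3, "adam", 9L, "double")
    beene:::cpp_loss(cellMatrix(vl), batchCodes(vl), integer(0),
                     fit$params, 1, 0, 0, 0)$reconstruction
  }
  recPlain <- run(0)        # plain autoencoder (batch head unweighted)
  recGuided <- run(5)       # strong batch guidance
  expect_lte(recPlain, recGuided * 1.05)
})
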