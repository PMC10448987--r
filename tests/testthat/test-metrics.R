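test_that("PCA embedding matches prcomp on a random matrix", {
  set.seed(10)
  x <- matrix(rnorm(30 * 10), 30, 10)
  sc <- pcaEmbed(x, nPcs = 10)
  ref <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:10) {
    a <- sc[, j]; b <- ref$x[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
  expect_equal(unname(attr(sc, "sdev")), unname(ref$sdev), tolerance = 1e-8)
  # wide-matrix route (n <= D) agrees with prcomp too
  xw <- matrix(rnorm(20 * 50), 20, 50)
  scw <- pcaEmbed(xw, nPcs = 5)
  refw <- stats::prcomp(xw)$x[, 1:5]
  for (j in 1:5)
    expect_lt(min(max(abs(scw[, j] - refw[, j])),
                  max(abs(scw[, j] + refw[, j]))), 1e-8)
})

test_that("PCA aligns with the variance axis and is sign-deterministic", {
  set.seed(11)
  x <- cbind(rnorm(50, sd = 5), rnorm(50, sd = 1e-4))
  sc <- pcaEmbed(x, nPcs = 2)
  expect_gt(stats::cor(abs(sc[, 1]), abs(x[, 1] - mean(x[, 1]))), 0.999)
  expect_lt(max(abs(sc[, 2])), 1e-2)
  expect_identical(sc, pcaEmbed(x, nPcs = 2))
  expect_error(pcaEmbed(x, nPcs = 3), "exceeds")
})

test_that("exact kNN matches brute force and breaks ties toward lower index", {
  # collinear: the middle point's neighbor is the nearer endpoint
  z <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(knnIndices(z, 1)[2, ], 1L)
  # identical points: ties resolved to the two lowest other indices
  zAll <- matrix(1, 5, 2)
  expect_equal(knnIndices(zAll, 2)[1, ], c(2L, 3L))
  expect_equal(knnIndices(zAll, 2)[4, ], c(1L, 2L))
  # brute-force oracle on 200 random points
  set.seed(12)
  z <- matrix(rnorm(200 * 3), 200, 3)
  got <- knnIndices(z, 7)
  for (i in c(1, 50, 137, 200)) {
    d <- sqrt(colSums((t(z) - z[i, ])^2))
    d[i] <- Inf
    expect_equal(got[i, ], order(d)[1:7])
  }
  expect_error(knnIndices(z, 200), "smaller")
})

test_that("chi-squared rejection decisions match closed-form survival functions", {
  set.seed(13)
  for (rep in 1:50) {
    K <- sample(2:3, 1)
    k0 <- 40L
    f <- as.numeric(stats::rmultinom(1, 100, rep(1, K))) / 100
    if (any(f == 0)) next
    counts <- as.numeric(stats::rmultinom(1, k0, f))
    stat <- sum((counts - k0 * f)^2 / (k0 * f))
    p <- stats::pchisq(stat, df = K - 1, lower.tail = FALSE)
    # independent survival functions: erfc for df 1, exp for df 2
    pRef <- if (K == 2) 2 * stats::pnorm(sqrt(stat), lower.tail = FALSE)
            else exp(-stat / 2)
    expect_lt(abs(p - pRef), 1e-10)
  }
})

test_that("kBET is near zero for perfectly mixed and near one for separated batches", {
  # alternating parity on a 1-D lattice: every even-sized neighborhood is
  # exactly half-and-half
  n <- 200
  z <- matrix(seq_len(n), n, 1)
  batch <- rep(c(0, 1), n / 2)
  mixed <- kbetRejection(z, batch, kbetConfig(k0 = 20L, seed = 1))
  expect_lt(mixed@meanRate, 0.1)
  # two distant blobs, one per batch
  set.seed(14)
  z2 <- rbind(matrix(rnorm(100 * 2), 100, 2),
              matrix(rnorm(100 * 2) + 50, 100, 2))
  sep <- kbetRejection(z2, rep(c(0, 1), each = 100),
                       kbetConfig(k0 = 20L, seed = 1))
  expect_gt(sep@meanRate, 0.95)
  expect_true(all(sep@rates >= 0 & sep@rates <= 1))
})

test_that("kBET is invariant to rigid motion and respects the null level", {
  set.seed(15)
  z <- matrix(rnorm(150 * 5), 150, 5)
  batch <- sample(rep(0:1, 75))
  cfg <- kbetConfig(seed = 8)
  r1 <- kbetRejection(z, batch, cfg)
  # rotation + translation preserves all distances, hence all decisions
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  r2 <- kbetRejection(sweep(z %*% q, 2, c(3, -1, 2, 0, 7), `+`), batch, cfg)
  expect_equal(r1@rates, r2@rates)
  # under label shuffling the mean rate stays near alpha
  nTested <- ceiling(0.1 * round(0.5 * 150)) * 100
  se <- sqrt(0.05 * 0.95 / nTested)
  expect_lte(r1@meanRate, 0.05 + 3 * se + 0.02)
})

test_that("iLISI hits its theoretical bounds and relabeling invariance", {
  # widely separated single-batch clusters: no mixing, iLISI = 1
  set.seed(16)
  z <- rbind(matrix(rnorm(60 * 2, sd = 0.1), 60, 2),
             matrix(rnorm(60 * 2, sd = 0.1) + 1000, 60, 2))
  batch <- rep(c("a", "b"), each = 60)
  r <- ilisi(z, batch, lisiConfig(perplexity = 10, nNeighbors = 30))
  expect_equal(r@perCell, rep(1, 120), tolerance = 1e-6)
  # degenerate geometry forces uniform weights; majority-batch cells then
  # see exactly 20 of each batch among their 40 neighbors, giving K = 2
  zSame <- matrix(0, 41, 2)
  labs <- c(rep("a", 21), rep("b", 20))
  expect_warning(
    r2 <- ilisi(zSame, labs, lisiConfig(perplexity = 5, nNeighbors = 40)),
    "uniform")
  expect_equal(r2@perCell[labs == "a"], rep(2, 21), tolerance = 1e-12)
  expect_true(all(r2@perCell >= 1 & r2@perCell <= 2))
  # relabeling batches does not change the score
  set.seed(17)
  z3 <- matrix(rnorm(100 * 3), 100, 3)
  b3 <- sample(rep(0:2, length.out = 100))
  ra <- ilisi(z3, b3, lisiConfig(perplexity = 10))
  rb <- ilisi(z3, c("z", "y", "x")[b3 + 1], lisiConfig(perplexity = 10))
  expect_equal(ra@perCell, rb@perCell, tolerance = 1e-12)
  expect_true(all(ra@perCell >= 1 & ra@perCell <= 3))
})

test_that("iLISI matches a dense independent recomputation", {
  set.seed(18)
  n <- 100
  z <- matrix(rnorm(n * 4), n, 4)
  batch <- sample(rep(0:1, n / 2))
  got <- ilisi(z, batch, lisiConfig(perplexity = 15, nNeighbors = n - 1))
  # independent implementation: dense distances, own bisection in nats
  d2 <- as.matrix(stats::dist(z))^2
  ref <- vapply(seq_len(n), function(i) {
    di <- d2[i, -i]
    bi <- batch[-i]
    target <- log(15)
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:100) {
      w <- exp(-beta * (di - min(di)))
      w <- w / sum(w)
      h <- -sum(w[w > 0] * log(w[w > 0]))
      if (abs(h - target) < 1e-10) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (beta + lo) / 2 }
    }
    pb <- c(sum(w[bi == 0]), sum(w[bi == 1]))
    1 / sum(pb^2)
  }, numeric(1))
  expect_equal(got@perCell, ref, tolerance = 1e-6)
})

test_that("null-shuffled labels score as perfectly mixed within 5 percent", {
  set.seed(19)
  z <- matrix(rnorm(200 * 5), 200, 5)
  shuffled <- sample(rep(0:1, 100))
  r <- ilisi(z, shuffled, lisiConfig(perplexity = 20))
  # same embedding with a deliberately mixed lattice-like labeling
  ordered <- rep(0:1, 100)
  rRef <- ilisi(z, ordered, lisiConfig(perplexity = 20))
  expect_lt(abs(r@meanIlisi - rRef@meanIlisi) / rRef@meanIlisi, 0.05)
  expect_gt(r@meanIlisi, 1.8)
})

test_that("the score wrapper equals its two components and serializes", {
  set.seed(20)
  z <- matrix(rnorm(80 * 3), 80, 3)
  batch <- rep(c("a", "b"), 40)
  kc <- kbetConfig(nSubsamples = 15, seed = 4)
  lc <- lisiConfig(perplexity = 8)
  sc <- scoreEmbedding(z, batch, kc, lc)
  expect_equal(sc$kbet@rates, kbetRejection(z, batch, kc)@rates)
  expect_equal(sc$ilisi@perCell, ilisi(z, batch, lc)@perCell)
  ser <- metricsAsList(sc, "test", 80L, 2L)
  js <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA)
  expect_true(jsonlite::validate(js))
  expect_equal(jsonlite::fromJSON(js)$kbet$mean, sc$kbet@meanRate)
})

test_that("both metrics order a weak and a strong batch effect consistently", {
  be0 <- tinyCondition("batchfree_2type", seed = 30L)
  be1 <- tinyCondition("linear_2type", b = 0.8, seed = 30L)
  kc <- kbetConfig(seed = 2)
  lc <- lisiConfig(perplexity = 15)
  s0 <- scoreEmbedding(pcaEmbed(be0, nPcs = 30), batchLabels(be0), kc, lc)
  s1 <- scoreEmbedding(pcaEmbed(be1, nPcs = 30), batchLabels(be1), kc, lc)
  expect_gte(s1$kbet@meanRate, s0$kbet@meanRate)
  expect_lte(s1$ilisi@meanIlisi, s0$ilisi@meanIlisi)
})
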