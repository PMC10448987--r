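# Shared fixtures, built in code and cached so expensive objects (trained
# models, full-size simulations) are constructed once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache, inherits = FALSE))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache, inherits = FALSE)
}

# A small labeled dataset with a strong, linearly separable batch signal:
# batch 2 cells are shifted by +2 on the first half of the genes.
makeSeparableData <- function(n = 120L, D = 40L, seed = 7L) {
  set.seed(seed)
  x <- matrix(rnorm(n * D), n, D)
  batch <- rep(c("a", "b"), length.out = n)
  x[batch == "b", seq_len(D / 2)] <- x[batch == "b", seq_len(D / 2)] + 2
  BeeneExperiment(x, orientation = "cells_x_genes",
                  batch = batch,
                  bio = rep(c("t1", "t2"), each = n / 2))
}

# Tiny simulated condition for pipeline-level tests.
tinyCondition <- function(condition = "nonlinear_2type", b = 0.4, seed = 11L) {
  simulateCondition(condition, b = b, seed = seed,
                    nGenes = 120L, nCellsPerType = 90L)
}

tinySpec <- function(D = 120L) {
  beeneModelSpec(D, encoderHidden = c(40L, 20L), latentDim = 10L)
}

# ---------------------------------------------------------------------------
# Full-size study-condition runs, shared by the acceptance-level tests.
# Each (condition, b, p, seed) is trained once and cached; quantities that
# the study reports as seed averages use three fixed seeds.

accSeeds <- c(101L, 211L, 499L)

# batch-free conditions are the nonlinear conditions at amplitude zero
# (the injection is a no-op when b = 0), so they share one cache entry
accSimulate <- function(condition, b, p, seedIdx) {
  condition <- sub("^batchfree", "nonlinear", condition)
  if (b == 0) p <- 1
  build <- function() simulateCondition(condition, b = b, p = p,
                                        seed = accSeeds[seedIdx])
  # the default-amplitude first-seed simulations are reused by other test
  # files; everything else is built fresh to bound memory
  if (seedIdx == 1L && b == 0.4 && p == 1)
    cachedFixture(sprintf("sim_%s_b%s_p%s", condition, b, p), build)
  else build()
}

accRun <- function(condition, b, p = 1, seedIdx = 1L, pca = TRUE) {
  condition <- sub("^batchfree", "nonlinear", condition)
  if (b == 0) p <- 1
  key <- sprintf("accrun_%s_b%s_p%s_s%d", condition, b, p, seedIdx)
  cachedFixture(key, function() {
    be <- accSimulate(condition, b, p, seedIdx)
    r <- runEstimation(be, seed = accSeeds[seedIdx], pcaBaselines = pca)
    r$model <- NULL   # drop the fitted network; only metrics are reused
    r
  })
}

# three-seed mean of one report field, e.g. accMean(..., "beene", "kbet")
accMean <- function(condition, b, embedding, metric, p = 1,
                    pca = TRUE, nSeeds = 3L) {
  mean(vapply(seq_len(nSeeds), function(i) {
    r <- accRun(condition, b, p, seedIdx = i, pca = pca)
    r[[embedding]][[metric]]$mean
  }, numeric(1)))
}

# Flatten a parameter list (as produced by the C++ core) to one numeric
# vector, and write a flat vector back; used by the finite-difference
# gradient oracle.
flattenParams <- function(p) {
  unlist(list(p$W, p$b, list(p$psi), list(p$psi_b),
              if (!is.null(p$omega)) list(p$omega),
              if (!is.null(p$omega)) list(p$omega_b)),
         use.names = FALSE)
}

unflattenParams <- function(flat, template) {
  out <- template
  pos <- 0L
  take <- function(obj) {
    k <- length(obj)
    v <- flat[pos + seq_len(k)]
    pos <<- pos + k
    array(v, dim = dim(obj) %||% length(obj))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  for (i in seq_along(out$W)) out$W[[i]] <- take(out$W[[i]])
  for (i in seq_along(out$b)) out$b[[i]] <- take(out$b[[i]])
  out$psi <- take(out$psi)
  out$psi_b <- take(out$psi_b)
  if (!is.null(out$omega)) {
    out$omega <- take(out$omega)
    out$omega_b <- take(out$omega_b)
  }
  out
}
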