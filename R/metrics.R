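#' PCA baseline embedding
#'
#' Mean-centered principal component scores, components ordered by
#' decreasing explained variance. The eigendecomposition runs on the
#' smaller of the two Gram matrices, so wide matrices (genes >> cells) stay
#' cheap. Component signs are fixed by convention: the largest-magnitude
#' loading of every component is positive, making the scores deterministic.
#'
#' @param x cells x genes matrix or a \linkS4class{BeeneExperiment}.
#' @param nPcs number of components (default 50, capped at min(n, D)).
#' @param assayName assay to use for BeeneExperiment input.
#' @return n x nPcs score matrix with attribute \code{source = "pca"} and
#'   attribute \code{sdev} (component standard deviations).
#' @export
pcaEmbed <- function(x, nPcs = 50L, assayName = 1L) {
  m <- if (methods::is(x, "BeeneExperiment")) cellMatrix(x, assayName)
       else as.matrix(x)
  n <- nrow(m); D <- ncol(m)
  nPcs <- as.integer(nPcs)
  if (nPcs > min(n, D))
    stop("nPcs = ", nPcs, " exceeds min(n, D) = ", min(n, D))
  mc <- sweep(m, 2L, colMeans(m))
  if (n <= D) {
    g <- tcrossprod(mc)              # n x n
    e <- eigen(g, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(nPcs)], 0)
    scores <- e$vectors[, seq_len(nPcs), drop = FALSE] %*%
      diag(sqrt(ev), nPcs)
    # loadings for sign convention: V = X'c U / sqrt(ev)
    rot <- crossprod(mc, e$vectors[, seq_len(nPcs), drop = FALSE])
    rot <- sweep(rot, 2L, sqrt(pmax(ev, .Machine$double.eps)), `/`)
  } else {
    g <- crossprod(mc)               # D x D
    e <- eigen(g, symmetric = TRUE)
    rot <- e$vectors[, seq_len(nPcs), drop = FALSE]
    ev <- pmax(e$values[seq_len(nPcs)], 0)
    scores <- mc %*% rot
  }
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(nPcs))
  attr(scores, "sdev") <- sqrt(ev / max(1L, n - 1L))
  attr(scores, "source") <- "pca"
  scores
}

#' Exact k-nearest-neighbor indices
#'
#' Exhaustive Euclidean search; the query point itself is excluded and
#' distance ties are broken toward the lower index.
#'
#' @param z n x d embedding matrix.
#' @param k neighbors per point (k < n).
#' @return n x k integer matrix of neighbor row indices.
#' @export
knnIndices <- function(z, k) {
  z <- as.matrix(z)
  n <- nrow(z)
  k <- as.integer(k)
  if (k >= n) stop("k must be smaller than the number of points")
  d2 <- .squaredDistances(z)
  diag(d2) <- Inf
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) out[i, ] <- order(d2[i, ])[seq_len(k)]
  out
}

# Pairwise squared Euclidean distances, clipped at 0 against roundoff.
.squaredDistances <- function(z) {
  sq <- rowSums(z * z)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(z)
  d2[d2 < 0] <- 0
  d2
}

#' kBET configuration
#'
#' @param k0 neighborhood size; default \code{max(10, floor(0.10 n))} of
#'   the scored subsample, resolved at run time when NULL.
#' @param alpha significance level of the chi-squared test (default 0.05).
#' @param testFraction fraction of subsampled points tested (default 0.10).
#' @param nSubsamples number of subsample repetitions (default 100).
#' @param subsampleFraction fraction of cells drawn per repetition
#'   (default 0.5).
#' @param seed integer seed.
#' @return a list of class \code{"kbetConfig"}.
#' @export
kbetConfig <- function(k0 = NULL, alpha = 0.05, testFraction = 0.10,
                       nSubsamples = 100L, subsampleFraction = 0.5,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, testFraction > 0, testFraction <= 1,
            nSubsamples >= 1, subsampleFraction > 0, subsampleFraction <= 1)
  structure(list(k0 = if (is.null(k0)) NULL else as.integer(k0),
                 alpha = alpha, testFraction = testFraction,
                 nSubsamples = as.integer(nSubsamples),
                 subsampleFraction = subsampleFraction,
                 seed = as.integer(seed)),
            class = "kbetConfig")
}

#' kBET: chi-squared rejection-rate test of batch mixing
#'
#' For each of \code{nSubsamples} repetitions, a random subsample of cells
#' is drawn and a random \code{testFraction} of it is tested: the batch
#' composition of each test point's k0 nearest neighborhood is compared to
#' the subsample's global batch frequencies with a Pearson chi-squared test
#' (dof K - 1); the repetition's rejection rate is the fraction of tested
#' points with p < alpha. Rates near 0 indicate well-mixed batches, rates
#' near 1 a strong batch effect. The statistic for a test point is
#' \deqn{\sum_k (n_k - k_0 f_k)^2 / (k_0 f_k)}
#' with \eqn{n_k} the neighborhood batch counts and \eqn{f_k} the global
#' frequencies.
#'
#' @param z n x d embedding matrix.
#' @param batch per-cell batch labels (factor or integer).
#' @param config a \code{\link{kbetConfig}}.
#' @return a \linkS4class{KbetResult}.
#' @export
kbetRejection <- function(z, batch, config = kbetConfig()) {
  z <- as.matrix(z)
  n <- nrow(z)
  batch <- firstAppearanceFactor(batch)
  if (length(batch) != n) stop("batch labels must match rows of z")
  K <- nlevels(batch)
  if (K < 2L) stop("kBET needs >= 2 batches")
  if (any(table(batch) < 2L)) stop("every batch needs >= 2 cells")
  k0 <- if (is.null(config$k0)) max(10L, as.integer(floor(0.10 * n)))
        else config$k0
  if (k0 < K) stop("k0 must be at least the number of batches")
  nSub <- max(2L, as.integer(round(config$subsampleFraction * n)))
  if (k0 >= nSub)
    stop("k0 = ", k0, " >= subsample size ", nSub,
         "; lower k0 or raise subsampleFraction")
  rates <- withSeed(config$seed, {
    vapply(seq_len(config$nSubsamples), function(rep) {
      sub <- sample.int(n, nSub)
      bsub <- batch[sub]
      f <- as.numeric(table(bsub)) / nSub
      if (any(f == 0))
        stop("batch absent from subsample (expected count zero); ",
             "raise subsampleFraction")
      zsub <- z[sub, , drop = FALSE]
      nTest <- ceiling(config$testFraction * nSub)
      testIdx <- sample.int(nSub, nTest)
      # distances only between test points and the subsample
      sqSub <- rowSums(zsub * zsub)
      zt <- zsub[testIdx, , drop = FALSE]
      d2t <- outer(rowSums(zt * zt), sqSub, `+`) - 2 * tcrossprod(zt, zsub)
      expected <- k0 * f
      rejected <- 0L
      for (j in seq_along(testIdx)) {
        dd <- d2t[j, ]
        dd[testIdx[j]] <- Inf
        nb <- order(dd)[seq_len(k0)]
        counts <- tabulate(as.integer(bsub[nb]), nbins = K)
        stat <- sum((counts - expected)^2 / expected)
        p <- stats::pchisq(stat, df = K - 1, lower.tail = FALSE)
        if (p < config$alpha) rejected <- rejected + 1L
      }
      rejected / nTest
    }, numeric(1L))
  })
  methods::new("KbetResult", rates = rates, meanRate = mean(rates),
               medianRate = stats::median(rates), k0 = as.integer(k0),
               alpha = config$alpha)
}

#' iLISI configuration
#'
#' @param perplexity target perplexity of the Gaussian neighborhood
#'   (default 30; must exceed 1).
#' @param nNeighbors neighbors per cell (default 3 x perplexity).
#' @param seed integer seed (kept for interface symmetry; the computation
#'   is deterministic).
#' @return a list of class \code{"lisiConfig"}.
#' @export
lisiConfig <- function(perplexity = 30, nNeighbors = NULL, seed = 1L) {
  stopifnot(perplexity > 1)
  if (is.null(nNeighbors)) nNeighbors <- as.integer(3 * perplexity)
  structure(list(perplexity = perplexity,
                 nNeighbors = as.integer(nNeighbors),
                 seed = as.integer(seed)),
            class = "lisiConfig")
}

#' iLISI: local inverse Simpson's index of batch mixing
#'
#' For every cell, a Gaussian kernel over its nearest neighbors is
#' calibrated by binary search on the bandwidth until the Shannon entropy
#' of the normalized weights equals \eqn{\log_2} perplexity (tolerance
#' 1e-5, at most 64 iterations). The batch probabilities
#' \eqn{p_b = \sum_{j \in b} w_j} then give the inverse Simpson index
#' \eqn{1 / \sum_b p_b^2}: the effective number of batches in the
#' neighborhood, from 1 (no mixing) to K (perfect mixing). If all neighbor
#' distances are zero the weights fall back to uniform with a warning.
#'
#' @param z n x d embedding matrix.
#' @param batch per-cell batch labels.
#' @param config a \code{\link{lisiConfig}}.
#' @return a \linkS4class{LisiResult}.
#' @export
ilisi <- function(z, batch, config = lisiConfig()) {
  z <- as.matrix(z)
  n <- nrow(z)
  batch <- firstAppearanceFactor(batch)
  if (length(batch) != n) stop("batch labels must match rows of z")
  K <- nlevels(batch)
  nn <- config$nNeighbors
  if (nn >= n) stop("nNeighbors must be smaller than the number of cells")
  d2full <- .squaredDistances(z)
  diag(d2full) <- Inf
  target <- log2(config$perplexity)
  bcode <- as.integer(batch)
  perCell <- numeric(n)
  degenerate <- FALSE
  for (i in seq_len(n)) {
    ordn <- order(d2full[i, ])[seq_len(nn)]
    d2 <- d2full[i, ordn]
    w <- .perplexityWeights(d2, target)
    if (is.null(w)) {
      degenerate <- TRUE
      w <- rep(1 / nn, nn)
    }
    pb <- vapply(seq_len(K), function(b) sum(w[bcode[ordn] == b]),
                 numeric(1L))
    perCell[i] <- 1 / sum(pb^2)
  }
  if (degenerate)
    warning("bandwidth calibration failed for some cells ",
            "(all neighbor distances zero); used uniform weights")
  methods::new("LisiResult", perCell = perCell, meanIlisi = mean(perCell),
               medianIlisi = stats::median(perCell),
               perplexity = config$perplexity)
}

# Binary search on the Gaussian precision beta so the entropy (bits) of the
# normalized weights of squared distances d2 hits `target`; NULL when the
# distances are degenerate (all zero).
.perplexityWeights <- function(d2, target, tol = 1e-5, maxIter = 64L) {
  if (all(d2 <= 0)) return(NULL)
  d2 <- d2 - min(d2)   # numerical stabilization; weights are shift-invariant
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (iter in seq_len(maxIter)) {
    w <- exp(-beta * d2)
    sw <- sum(w)
    w <- w / sw
    h <- -sum(ifelse(w > 0, w * log2(w), 0))
    diff <- h - target
    if (abs(diff) < tol) break
    if (diff > 0) {        # entropy too high -> sharpen
      lo <- beta
      beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
    } else {
      hi <- beta
      beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
    }
  }
  w
}

#' Score an embedding with both batch-mixing metrics
#'
#' Convenience wrapper equal to calling \code{\link{kbetRejection}} and
#' \code{\link{ilisi}} with the same inputs.
#'
#' @param z n x d embedding matrix.
#' @param batch per-cell batch labels.
#' @param kbet a \code{\link{kbetConfig}}.
#' @param lisi a \code{\link{lisiConfig}}.
#' @return list with elements \code{kbet} (\linkS4class{KbetResult}) and
#'   \code{ilisi} (\linkS4class{LisiResult}).
#' @export
scoreEmbedding <- function(z, batch, kbet = kbetConfig(),
                           lisi = lisiConfig()) {
  list(kbet = kbetRejection(z, batch, kbet),
       ilisi = ilisi(z, batch, lisi))
}

#' Serialize metric results to a report list
#'
#' @param scores output of \code{\link{scoreEmbedding}}.
#' @param source embedding source label (e.g. "beene", "pca").
#' @param n number of cells scored.
#' @param K number of batches.
#' @return a JSON-ready list.
#' @export
metricsAsList <- function(scores, source, n, K) {
  list(embedding_source = source, n = n, K = K,
       kbet = list(rates = scores$kbet@rates,
                   mean = scores$kbet@meanRate,
                   median = scores$kbet@medianRate,
                   k0 = scores$kbet@k0,
                   alpha = scores$kbet@alpha),
       ilisi = list(mean = scores$ilisi@meanIlisi,
                    median = scores$ilisi@medianIlisi,
                    perplexity = scores$ilisi@perplexity))
}
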