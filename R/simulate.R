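#' Simulation specification for gamma-Poisson single-cell counts
#'
#' The generative hierarchy follows the standard single-cell count model:
#' per-gene base means from a Gamma distribution, per-cell library sizes
#' from a log-normal, multiplicative differential-expression (DE) factors
#' distinguishing cell types, biological overdispersion as a gamma mixing
#' of the Poisson rate (controlled by the biological coefficient of
#' variation, BCV), and Poisson sampling. Defaults give ~60k counts per
#' cell over 2500 genes with 10\% DE genes between two types.
#'
#' @param nCellsPerType cells per cell type (default 1000 for the two-type
#'   design; use 1500 with \code{nTypes = 1} for the one-type design).
#' @param nTypes number of cell types (1 or 2).
#' @param nGenes number of genes D (default 2500).
#' @param nBatches number of batches K (default 2); cells divide evenly
#'   across batches within each type.
#' @param deProb fraction of genes carrying a DE factor between types
#'   (default 0.1).
#' @param deFacLoc,deFacScale log-normal location/scale of DE factors
#'   (default 0.1, 0.4); factors are inverted (down-regulated) with
#'   probability 0.5.
#' @param libLoc,libScale log-normal location/scale of library sizes
#'   (default 11, 0.2).
#' @param geneMeanShape,geneMeanRate Gamma shape/rate of gene base means
#'   (default 0.6, 0.3).
#' @param bcv biological coefficient of variation (default 0.1); 0 gives
#'   pure Poisson sampling.
#' @param seed integer seed.
#' @return a list of class \code{"simSpec"}.
#' @export
simSpec <- function(nCellsPerType = 1000L, nTypes = 2L, nGenes = 2500L,
                    nBatches = 2L, deProb = 0.1, deFacLoc = 0.1,
                    deFacScale = 0.4, libLoc = 11, libScale = 0.2,
                    geneMeanShape = 0.6, geneMeanRate = 0.3, bcv = 0.1,
                    seed = 1L) {
  stopifnot(nCellsPerType >= 1, nTypes %in% 1:2, nGenes >= 2,
            nBatches >= 2, deProb >= 0, deProb <= 1,
            deFacScale >= 0, libScale >= 0, geneMeanShape > 0,
            geneMeanRate > 0, bcv >= 0)
  if (nCellsPerType %% nBatches != 0)
    stop("cells must divide evenly across batches within each cell type")
  structure(list(nCellsPerType = as.integer(nCellsPerType),
                 nTypes = as.integer(nTypes), nGenes = as.integer(nGenes),
                 nBatches = as.integer(nBatches), deProb = deProb,
                 deFacLoc = deFacLoc, deFacScale = deFacScale,
                 libLoc = libLoc, libScale = libScale,
                 geneMeanShape = geneMeanShape, geneMeanRate = geneMeanRate,
                 bcv = bcv, seed = as.integer(seed)),
            class = "simSpec")
}

#' Simulate single-cell RNA-seq counts
#'
#' Draws an integer count matrix from the gamma-Poisson hierarchy of
#' \code{\link{simSpec}}. Cell types (when \code{nTypes = 2}) receive
#' type-specific multiplicative DE factors on a random \code{deProb}
#' fraction of genes. Cells are assigned round-robin to batches within
#' each type, so batch labels are orthogonal to type labels and carry no
#' expression signal until \code{\link{injectBatchEffect}} adds one.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return a \linkS4class{BeeneExperiment} with assay \code{"counts"},
#'   batch labels set, and bio labels set when \code{nTypes = 2}.
#' @export
simulateCounts <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  n <- spec$nCellsPerType * spec$nTypes
  D <- spec$nGenes
  withSeed(spec$seed, {
    baseMean <- stats::rgamma(D, shape = spec$geneMeanShape,
                              rate = spec$geneMeanRate)
    baseMean[baseMean < 1e-8] <- 1e-8
    typeMeans <- matrix(baseMean, nrow = D, ncol = spec$nTypes)
    if (spec$nTypes == 2L && spec$deProb > 0) {
      nDe <- round(spec$deProb * D)
      deGenes <- sample.int(D, nDe)
      fac <- exp(stats::rnorm(nDe, spec$deFacLoc, spec$deFacScale))
      flip <- stats::runif(nDe) < 0.5
      fac[flip] <- 1 / fac[flip]
      typeMeans[deGenes, 2L] <- typeMeans[deGenes, 2L] * fac
    }
    libSize <- stats::rlnorm(n, spec$libLoc, spec$libScale)
    type <- rep(seq_len(spec$nTypes), each = spec$nCellsPerType)
    batch <- unlist(lapply(seq_len(spec$nTypes), function(t)
      rep_len(seq_len(spec$nBatches), spec$nCellsPerType)))
    counts <- matrix(0L, nrow = D, ncol = n)
    for (t in seq_len(spec$nTypes)) {
      idx <- which(type == t)
      prop <- typeMeans[, t] / sum(typeMeans[, t])
      lam <- prop %o% libSize[idx]          # D x n_t expected counts
      if (spec$bcv > 0) {
        shape <- 1 / spec$bcv^2
        lam <- lam * matrix(stats::rgamma(length(lam), shape = shape,
                                          rate = shape),
                            nrow = D)
      }
      counts[, idx] <- stats::rpois(length(lam), lam)
    }
    be <- BeeneExperiment(counts, orientation = "genes_x_cells",
                          assayName = "counts")
    be <- setLabels(be, batch = paste0("batch", batch),
                    bio = if (spec$nTypes >= 2L) paste0("type", type)
                          else NULL)
    S4Vectors::metadata(be)$simSpec <- spec
    be
  })
}

#' Batch-effect specification
#'
#' Describes an additive batch effect: per-batch, per-gene effect
#' magnitudes confined to the amplitude range [0, b], applied to a
#' proportion p of genes, in either a linear (expression-independent) or a
#' nonlinear (expression-dependent) form. Batch 1 is the reference and
#' receives a zero vector, so the amplitude is interpretable as the
#' displacement between batches.
#'
#' @param form \code{"linear"}, \code{"nonlinear"} or \code{"none"}.
#' @param b amplitude bound; every effect component lies in [0, b]
#'   (\code{form = "none"} forces b = 0).
#' @param p proportion of genes affected, in (0, 1] (default 1).
#' @param omegaRange range of the per-gene frequencies of the nonlinear
#'   response (default \code{c(0.5, 2)}; see
#'   \code{\link{injectBatchEffect}}).
#' @param seed integer seed for drawing effect vectors.
#' @return a list of class \code{"batchEffectSpec"}.
#' @export
batchEffectSpec <- function(form = c("nonlinear", "linear", "none"),
                            b = 0.4, p = 1, omegaRange = c(0.5, 2),
                            seed = 1L) {
  form <- match.arg(form)
  if (form == "none") b <- 0
  stopifnot(b >= 0, p > 0, p <= 1, length(omegaRange) == 2L)
  structure(list(form = form, b = b, p = p,
                 omegaRange = as.numeric(omegaRange),
                 seed = as.integer(seed)),
            class = "batchEffectSpec")
}

#' Draw per-batch effect vectors
#'
#' Raw uniform per-gene magnitudes are rescaled so the maximum component of
#' each affected batch vector equals b exactly; the (1 - p) unaffected
#' genes (one common random subset) are exactly zero; batch 1 is the
#' reference and gets the zero vector.
#'
#' @param spec a \code{\link{batchEffectSpec}}.
#' @param D number of genes.
#' @param K number of batches.
#' @return D x K matrix of effect components in [0, b]; column 1 all zero.
#' @export
makeBatchVectors <- function(spec, D, K) {
  stopifnot(inherits(spec, "batchEffectSpec"), D >= 1, K >= 2)
  B <- matrix(0, nrow = D, ncol = K)
  if (spec$form == "none" || spec$b == 0) return(B)
  nAffected <- round(spec$p * D)
  if (nAffected < 1)
    stop("p * D < 1: no genes would carry the effect")
  withSeed(spec$seed, {
    affected <- sample.int(D, nAffected)
    for (k in 2:K) {
      raw <- stats::runif(nAffected)
      B[affected, k] <- raw / max(raw) * spec$b
    }
  })
  B
}

#' Inject an additive batch effect into normalized expression
#'
#' Linear form: cells of batch i >= 2 get the expression-independent shift
#' \eqn{x'_j = x_j + B^{(i)}_j} relative to the zero-vector reference
#' batch 1. Nonlinear form: every batch i (including the first) receives
#' \eqn{x'_j = x_j + B^{(i)}_j \sin^2(\omega_j x_j + \varphi^{(i)}_j)}
#' with a shared per-gene frequency \eqn{\omega_j}, batch-specific
#' magnitude vectors \eqn{B^{(i)}} (each component in [0, b]) and
#' batch-specific per-gene phases \eqn{\varphi^{(i)}_j}. The additive term
#' depends nonlinearly on the gene's own expression and stays within
#' [0, b]; because each batch carries its own bounded vector, the
#' between-batch difference is dominated by the expression-dependent
#' modulation rather than by a location shift, so linear projections see
#' the effect only weakly while a nonlinear encoder can learn it.
#' Unaffected genes are unchanged in both forms, and the effect never
#' subtracts expression.
#'
#' @param x a \linkS4class{BeeneExperiment} with batch labels and a
#'   normalized (log-scale) expression assay.
#' @param spec a \code{\link{batchEffectSpec}}.
#' @param assayName assay to modify (default first assay).
#' @return the modified object; the effect vectors are stored in
#'   \code{metadata(x)$batchVectors}.
#' @export
injectBatchEffect <- function(x, spec, assayName = 1L) {
  stopifnot(inherits(spec, "batchEffectSpec"))
  b <- batchCodes(x)
  if (is.null(b)) stop("batch labels must be set before injecting effects")
  if (spec$form == "none") return(x)
  m <- as.matrix(SummarizedExperiment::assay(x, assayName))  # genes x cells
  D <- nrow(m); K <- nBatches(x)
  if (spec$form == "linear") {
    B <- makeBatchVectors(spec, D, K)
    for (k in 2:K) {
      idx <- which(b == k - 1L)
      m[, idx] <- m[, idx] + B[, k]
    }
  } else {
    nAffected <- round(spec$p * D)
    if (nAffected < 1) stop("p * D < 1: no genes would carry the effect")
    B <- matrix(0, nrow = D, ncol = K)
    withSeed(childSeed(spec$seed, 7L), {
      affected <- sample.int(D, nAffected)
      omega <- stats::runif(D, spec$omegaRange[1], spec$omegaRange[2])
      for (k in seq_len(K)) {
        raw <- stats::runif(nAffected)
        B[affected, k] <- raw / max(raw) * spec$b
        phase <- stats::runif(D, 0, 2 * pi)
        idx <- which(b == k - 1L)
        g <- sin(omega * m[, idx] + phase)^2
        m[, idx] <- m[, idx] + B[, k] * g
      }
    })
  }
  SummarizedExperiment::assay(x, assayName, withDimnames = FALSE) <- m
  S4Vectors::metadata(x)$batchVectors <- B
  S4Vectors::metadata(x)$batchEffectSpec <- spec
  x
}

#' Benchmark simulation conditions
#'
#' One call builds each controlled study condition: counts from the
#' gamma-Poisson model, library-size log-normalization, per-gene
#' standardization, then an additive batch effect on the standardized
#' expression. Injecting after standardization is what makes the amplitude
#' bound b interpretable: every effect component is confined to [0, b] in
#' units of that gene's own expression standard deviation, so b = 0.1 is a
#' sub-noise perturbation and b = 0.5 a substantial one regardless of a
#' gene's expression level. The two-type design has 1000
#' cells per type (500 per batch within each type); the one-type design
#' has 1500 cells (750 per batch); both use 2500 genes and 2 batches.
#' \code{batchfree_*} conditions keep the pseudo-batch labels but inject
#' nothing.
#'
#' @param condition one of \code{"linear_2type"}, \code{"linear_1type"},
#'   \code{"nonlinear_2type"}, \code{"nonlinear_1type"},
#'   \code{"batchfree_2type"}, \code{"batchfree_1type"}.
#' @param b amplitude bound (default 0.4; ignored for batch-free).
#' @param p affected-gene proportion (default 1).
#' @param seed integer seed (drives both counts and effect vectors).
#' @param nGenes number of genes (default 2500).
#' @param keepCounts keep the raw count assay alongside \code{"expr"}
#'   (default FALSE to halve memory).
#' @param standardize z-score each gene across all cells before injection
#'   (default TRUE; see Details).
#' @param ... overrides forwarded to \code{\link{simSpec}}.
#' @return a \linkS4class{BeeneExperiment} with assay \code{"expr"}
#'   (standardized log1p counts-per-10k plus any injected effect).
#' @export
simulateCondition <- function(condition = c("nonlinear_2type",
                                            "nonlinear_1type",
                                            "linear_2type", "linear_1type",
                                            "batchfree_2type",
                                            "batchfree_1type"),
                              b = 0.4, p = 1, seed = 1L, nGenes = 2500L,
                              keepCounts = FALSE, standardize = TRUE, ...) {
  condition <- match.arg(condition)
  twoType <- grepl("2type$", condition)
  form <- sub("_[12]type$", "", condition)
  if (form == "batchfree") form <- "none"
  args <- list(nCellsPerType = if (twoType) 1000L else 1500L,
               nTypes = if (twoType) 2L else 1L,
               nGenes = nGenes, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  sspec <- do.call(simSpec, args)
  be <- simulateCounts(sspec)
  be <- normalizeExpression(be, "log1p_cpm")
  if (standardize) {
    m <- as.matrix(SummarizedExperiment::assay(be, "expr"))
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    SummarizedExperiment::assay(be, "expr", withDimnames = FALSE) <-
      (m - mu) / sdv
  }
  espec <- batchEffectSpec(form = form, b = b, p = p,
                           seed = childSeed(seed, 3L))
  be <- injectBatchEffect(be, espec, assayName = "expr")
  S4Vectors::metadata(be)$batchEffectSpec <- espec
  if (!keepCounts)
    SummarizedExperiment::assays(be) <-
      SummarizedExperiment::assays(be)["expr"]
  S4Vectors::metadata(be)$condition <- condition
  be
}
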