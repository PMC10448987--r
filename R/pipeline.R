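#' End-to-end batch-effect estimation
#'
#' Runs the full workflow on a labeled expression object: split (60:20:20
#' by default, stratified by batch and, when present, biological class),
#' per-gene standardization fitted on the training cells, guided
#' autoencoder training with early stopping on validation loss, then kBET
#' and iLISI scoring of (i) the latent embedding of the held-out test
#' cells, (ii) the PCA embedding of the test cells, and (iii) the PCA
#' embedding of the full dataset. Reports all three so the embedding and
#' the evaluation scope are never conflated.
#'
#' @param x a labeled \linkS4class{BeeneExperiment} whose first assay is
#'   normalized expression (see \code{\link{normalizeExpression}}).
#' @param variant model regime (see \code{\link{beeneVariantSpec}});
#'   \code{"default"} falls back to \code{"no_bio"} when no biological
#'   labels exist.
#' @param spec optional explicit \code{"beeneModelSpec"} overriding
#'   \code{variant}.
#' @param fractions split fractions (default \code{c(0.6, 0.2, 0.2)}).
#' @param seed master seed; the split, training, and metric subsampling
#'   derive their seeds from it.
#' @param train a \code{\link{trainConfig}} (its seed is overridden by
#'   \code{seed}).
#' @param kbet a \code{\link{kbetConfig}} (seed overridden).
#' @param lisi a \code{\link{lisiConfig}}.
#' @param nPcs PCA dimensionality (default 50).
#' @param scope \code{"test_only"} scores only the test-split embeddings;
#'   \code{"full"} additionally scores the latent embedding of every cell.
#' @param pcaBaselines also score PCA embeddings of the test split and the
#'   full data (default TRUE; disable to skip the baselines when only the
#'   latent-space metrics are needed).
#' @return a list of class \code{"beeneReport"} with per-embedding metric
#'   summaries, the trained \linkS4class{BeeneModel}, and a config echo.
#' @export
runEstimation <- function(x, variant = "default", spec = NULL,
                          fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          train = trainConfig(), kbet = kbetConfig(),
                          lisi = lisiConfig(), nPcs = 50L,
                          scope = c("test_only", "full"),
                          pcaBaselines = TRUE) {
  scope <- match.arg(scope)
  if (is.null(batchLabels(x)))
    stop("stage split: batch labels are not set")
  split <- splitCells(x, fractions = fractions, seed = childSeed(seed, 1L))
  split <- standardizeGenes(split)
  train$seed <- childSeed(seed, 2L)
  model <- tryCatch(
    trainBeene(split, spec = spec, variant = variant, config = train),
    error = function(e) stop("stage train: ", conditionMessage(e)))
  test <- partition(split, "test")
  bTest <- batchLabels(test)
  kbet$seed <- childSeed(seed, 3L)
  zBeene <- encodeCells(model, cellMatrix(test, 1L), applyNormStats = FALSE)
  scBeene <- scoreEmbedding(zBeene, bTest, kbet, lisi)
  out <- list(
    beene = metricsAsList(scBeene, "beene", ncol(test), nBatches(test)),
    model = model,
    config = list(variant = variant, fractions = fractions, seed = seed,
                  train = unclass(train), kbet = unclass(kbet),
                  lisi = unclass(lisi), nPcs = nPcs, scope = scope),
    version = as.character(utils::packageVersion("beene")))
  if (pcaBaselines) {
    zPcaTest <- pcaEmbed(cellMatrix(test, 1L),
                         nPcs = min(nPcs, ncol(test) - 1L))
    out$pca_test <- metricsAsList(
      scoreEmbedding(zPcaTest, bTest, kbet, lisi), "pca_test",
      ncol(test), nBatches(test))
    zPcaFull <- pcaEmbed(x, nPcs = nPcs)
    out$pca_full <- metricsAsList(
      scoreEmbedding(zPcaFull, batchLabels(x), kbet, lisi), "pca_full",
      ncol(x), nBatches(x))
  }
  if (scope == "full") {
    zAll <- encodeCells(model, x)
    out$beene_full <- metricsAsList(
      scoreEmbedding(zAll, batchLabels(x), kbet, lisi),
      "beene_full", ncol(x), nBatches(x))
  }
  class(out) <- "beeneReport"
  out
}

#' @export
print.beeneReport <- function(x, ...) {
  cat("Batch-effect estimation report\n")
  for (nm in intersect(c("beene", "beene_full", "pca_test", "pca_full"),
                       names(x))) {
    s <- x[[nm]]
    cat(sprintf("  %-10s n=%-5d kBET mean rejection %.3f | iLISI mean %.3f\n",
                nm, s$n, s$kbet$mean, s$ilisi$mean))
  }
  invisible(x)
}

#' Write a report (JSON + training log CSV)
#'
#' @param report a \code{"beeneReport"}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser <- report[setdiff(names(report), "model")]
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$model@trainLog,
                   file.path(dir, "training_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' Sweep batch-effect amplitude or affected-gene proportion
#'
#' Regenerates the nonlinear two-cell-type condition at each sweep value,
#' runs the full estimation pipeline, and tabulates the four headline
#' metrics: iLISI and kBET rejection in PCA space (full data) and on the
#' latent embedding of the test split.
#'
#' @param mode \code{"amplitude"} (vary b at p = 1) or
#'   \code{"proportion"} (vary p at the default amplitude).
#' @param values sweep values; defaults are
#'   \code{c(0, 0.1, 0.2, 0.3, 0.4, 0.5)} for amplitude and
#'   \code{c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0)} for proportion.
#' @param condition simulation condition family (default
#'   \code{"nonlinear_2type"}).
#' @param b amplitude used in proportion mode (default 0.4).
#' @param nReps independent repetitions per value (default 3).
#' @param seed master seed; rep r of value v uses a derived seed.
#' @param train,kbet,lisi configs forwarded to \code{\link{runEstimation}}.
#' @param nGenes genes per simulated dataset (default 2500).
#' @param verbose print one line per run.
#' @param ... further arguments to \code{\link{simulateCondition}} (e.g.
#'   \code{nCellsPerType} for scaled-down runs).
#' @return data.frame with one row per (value, rep) holding
#'   \code{pca_ilisi}, \code{beene_ilisi}, \code{pca_kbet},
#'   \code{beene_kbet}, plus attribute \code{"summary"}: the rep-averaged
#'   table.
#' @export
runSweep <- function(mode = c("amplitude", "proportion"), values = NULL,
                     condition = "nonlinear_2type", b = 0.4, nReps = 3L,
                     seed = 1L, train = trainConfig(), kbet = kbetConfig(),
                     lisi = lisiConfig(), nGenes = 2500L, verbose = FALSE,
                     ...) {
  mode <- match.arg(mode)
  if (is.null(values))
    values <- if (mode == "amplitude") c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
              else c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0)
  rows <- list()
  for (v in values) {
    for (r in seq_len(nReps)) {
      runSeed <- childSeed(seed, 1000L * match(v, values) + r)
      res <- tryCatch({
        be <- if (mode == "amplitude")
          simulateCondition(condition, b = v, p = 1, seed = runSeed,
                            nGenes = nGenes, ...)
        else
          simulateCondition(condition, b = b, p = v, seed = runSeed,
                            nGenes = nGenes, ...)
        rep_ <- runEstimation(be, seed = runSeed, train = train,
                              kbet = kbet, lisi = lisi)
        data.frame(mode = mode, value = v, rep = r,
                   pca_ilisi = rep_$pca_full$ilisi$mean,
                   beene_ilisi = rep_$beene$ilisi$mean,
                   pca_kbet = rep_$pca_full$kbet$mean,
                   beene_kbet = rep_$beene$kbet$mean,
                   error = NA_character_)
      }, error = function(e)
        data.frame(mode = mode, value = v, rep = r,
                   pca_ilisi = NA_real_, beene_ilisi = NA_real_,
                   pca_kbet = NA_real_, beene_kbet = NA_real_,
                   error = conditionMessage(e)))
      if (verbose)
        message(sprintf("%s = %-4g rep %d: BEENE kBET %.3f, iLISI %.3f",
                        mode, v, r, res$beene_kbet, res$beene_ilisi))
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(
    out[, c("pca_ilisi", "beene_ilisi", "pca_kbet", "beene_kbet")],
    by = list(value = out$value), FUN = mean, na.rm = TRUE)
  attr(out, "summary") <- agg
  out
}

#' Cross-validated batch-effect scores
#'
#' Splits the cells into batch-stratified folds (batch x bio when
#' biological labels exist); each fold in turn is held out for scoring
#' while the remaining cells are split 75:25 into training and validation
#' for early stopping. Reports per-fold kBET/iLISI on both the latent and
#' the PCA embedding of the held-out fold, plus mean and sd.
#'
#' @param x a labeled, normalized \linkS4class{BeeneExperiment}.
#' @param nFolds number of folds (default 5, >= 2).
#' @param variant model regime.
#' @param seed master seed.
#' @param train,kbet,lisi configs.
#' @param nPcs PCA dimensionality for the fold baseline.
#' @return list with \code{perFold} (data.frame), \code{mean}, \code{sd}.
#' @export
crossValidatedScores <- function(x, nFolds = 5L, variant = "default",
                                 seed = 1L, train = trainConfig(),
                                 kbet = kbetConfig(), lisi = lisiConfig(),
                                 nPcs = 50L) {
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  bAll <- batchLabels(x)
  if (is.null(bAll)) stop("batch labels must be set")
  y <- bioLabels(x)
  strata <- if (is.null(y)) bAll else interaction(bAll, y, drop = TRUE)
  fold <- integer(ncol(x))
  withSeed(childSeed(seed, 11L), {
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  rows <- list()
  for (f in seq_len(nFolds)) {
    heldOut <- which(fold == f)
    rest <- which(fold != f)
    restBe <- x[, rest]
    sp <- splitCells(restBe, fractions = c(0.75, 0.25, 0),
                     seed = childSeed(seed, 100L + f), minStratum = 2L)
    sp@test <- x[, heldOut]
    sp <- standardizeGenes(sp)
    train$seed <- childSeed(seed, 200L + f)
    model <- trainBeene(sp, variant = variant, config = train)
    test <- partition(sp, "test")
    kbet$seed <- childSeed(seed, 300L + f)
    kb <- kbet
    n <- ncol(test)
    z <- encodeCells(model, cellMatrix(test, 1L), applyNormStats = FALSE)
    scB <- scoreEmbedding(z, batchLabels(test), kb, lisi)
    zp <- pcaEmbed(cellMatrix(test, 1L), nPcs = min(nPcs, n - 1L))
    scP <- scoreEmbedding(zp, batchLabels(test), kb, lisi)
    rows[[f]] <- data.frame(fold = f, n = n,
                            beene_kbet = scB$kbet@meanRate,
                            beene_ilisi = scB$ilisi@meanIlisi,
                            pca_kbet = scP$kbet@meanRate,
                            pca_ilisi = scP$ilisi@meanIlisi)
  }
  perFold <- do.call(rbind, rows)
  metrics <- c("beene_kbet", "beene_ilisi", "pca_kbet", "pca_ilisi")
  list(perFold = perFold,
       mean = colMeans(perFold[, metrics]),
       sd = apply(perFold[, metrics], 2L, stats::sd))
}
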