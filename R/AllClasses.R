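#' @import methods
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' BeeneExperiment: expression matrix with batch and biological labels
#'
#' A thin extension of \linkS4class{SingleCellExperiment} holding a genes
#' \eqn{\times} cells expression matrix together with the per-cell batch
#' label (required for any batch-effect analysis) and an optional biological
#' label such as cell type. Labels are stored as factors in \code{colData};
#' their integer codings (0-based, first-appearance order) are what the
#' model and the metrics consume.
#'
#' @slot ... see \linkS4class{SingleCellExperiment}
#' @export
setClass("BeeneExperiment", contains = "SingleCellExperiment")

.validBeeneExperiment <- function(object) {
  msg <- NULL
  if (length(SummarizedExperiment::assayNames(object)) < 1L)
    msg <- c(msg, "at least one assay is required")
  else {
    a <- SummarizedExperiment::assay(object, 1L)
    if (anyNA(a))
      msg <- c(msg, "expression matrix contains missing values")
  }
  cd <- SummarizedExperiment::colData(object)
  for (lab in c("batch", "bio")) {
    if (lab %in% colnames(cd)) {
      f <- cd[[lab]]
      if (!is.factor(f))
        msg <- c(msg, sprintf("'%s' must be a factor", lab))
      else if (anyNA(f))
        msg <- c(msg, sprintf("'%s' contains missing labels", lab))
      else if (any(table(f) == 0L))
        msg <- c(msg, sprintf("every '%s' level must be observed", lab))
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("BeeneExperiment", .validBeeneExperiment)

#' Construct a BeeneExperiment
#'
#' @param expr numeric matrix, either genes x cells or cells x genes
#'   (declare via \code{orientation}; never guessed from shape).
#' @param orientation orientation of \code{expr} on input.
#' @param batch,bio optional per-cell label vectors (character, factor or
#'   integer); coded by first appearance.
#' @param geneIds,cellIds identifiers; synthesized (\code{"g0001"},
#'   \code{"c0001"}, ...) when absent.
#' @param assayName name of the stored assay (default \code{"expr"}).
#' @return A \linkS4class{BeeneExperiment}, genes x cells internally.
#' @export
BeeneExperiment <- function(expr,
                            orientation = c("cells_x_genes", "genes_x_cells"),
                            batch = NULL, bio = NULL,
                            geneIds = NULL, cellIds = NULL,
                            assayName = "expr") {
  orientation <- match.arg(orientation)
  expr <- as.matrix(expr)
  if (orientation == "cells_x_genes") expr <- t(expr)
  if (is.null(geneIds)) {
    geneIds <- rownames(expr)
    if (is.null(geneIds))
      geneIds <- sprintf("g%04d", seq_len(nrow(expr)))
  }
  if (is.null(cellIds)) {
    cellIds <- colnames(expr)
    if (is.null(cellIds))
      cellIds <- sprintf("c%04d", seq_len(ncol(expr)))
  }
  dimnames(expr) <- list(geneIds, cellIds)
  assays <- list(expr)
  names(assays) <- assayName
  cd <- S4Vectors::DataFrame(row.names = cellIds)
  obj <- methods::new("BeeneExperiment",
                      SingleCellExperiment::SingleCellExperiment(
                        assays = assays, colData = cd))
  if (!is.null(batch) || !is.null(bio))
    obj <- setLabels(obj, batch = batch, bio = bio)
  obj
}

#' BeeneSplit: train/validation/test partition of a BeeneExperiment
#'
#' @slot train,val,test \linkS4class{BeeneExperiment} views.
#' @slot fractions numeric(3) summing to 1.
#' @slot seed integer seed that produced the partition.
#' @slot normStats list; per-gene centering/scaling statistics computed on
#'   the training partition (empty until \code{\link{standardizeGenes}}).
#' @export
setClass("BeeneSplit",
         representation(train = "BeeneExperiment",
                        val = "BeeneExperiment",
                        test = "BeeneExperiment",
                        fractions = "numeric",
                        seed = "integer",
                        normStats = "list"))

setValidity("BeeneSplit", function(object) {
  msg <- NULL
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-8)
    msg <- c(msg, "fractions must be three values summing to 1")
  ids <- c(colnames(object@train), colnames(object@val), colnames(object@test))
  if (anyDuplicated(ids))
    msg <- c(msg, "partitions overlap: duplicated cell ids")
  if (is.null(msg)) TRUE else msg
})

#' BeeneModel: a trained guided-autoencoder model
#'
#' Holds the network specification, the fitted parameter blocks (encoder
#' \eqn{\phi}, decoder \eqn{\theta}, batch head \eqn{\psi}, optional bio
#' head \eqn{\omega}), the per-epoch training log and the gene
#' standardization statistics the model was trained under.
#'
#' @slot spec list created by \code{\link{beeneModelSpec}}.
#' @slot params list of parameter matrices (native layout of the C++ core).
#' @slot trainLog data.frame of per-epoch loss components.
#' @slot normStats list of per-gene center/scale used at training time.
#' @slot bestEpoch integer; epoch whose parameters are stored.
#' @export
setClass("BeeneModel",
         representation(spec = "list", params = "list",
                        trainLog = "data.frame", normStats = "list",
                        bestEpoch = "integer"))

#' KbetResult: kBET rejection-rate distribution
#'
#' @slot rates numeric vector of per-subsample rejection rates.
#' @slot meanRate,medianRate summaries over subsamples.
#' @slot k0 neighborhood size used.
#' @slot alpha significance level.
#' @export
setClass("KbetResult",
         representation(rates = "numeric", meanRate = "numeric",
                        medianRate = "numeric", k0 = "integer",
                        alpha = "numeric"))

setValidity("KbetResult", function(object) {
  if (any(object@rates < 0 | object@rates > 1))
    "rejection rates must lie in [0, 1]" else TRUE
})

#' LisiResult: per-cell iLISI scores
#'
#' @slot perCell numeric vector, one iLISI per cell, each in [1, K].
#' @slot meanIlisi,medianIlisi summaries over cells.
#' @slot perplexity perplexity used for the kernel calibration.
#' @export
setClass("LisiResult",
         representation(perCell = "numeric", meanIlisi = "numeric",
                        medianIlisi = "numeric", perplexity = "numeric"))

setMethod("show", "BeeneExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  if ("batch" %in% colnames(cd)) {
    tb <- table(cd$batch)
    cat(sprintf("batches (%d): %s\n", length(tb),
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  } else cat("batches: <unset>\n")
  if ("bio" %in% colnames(cd)) {
    tb <- table(cd$bio)
    cat(sprintf("bio classes (%d): %s\n", length(tb),
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
})

setMethod("show", "BeeneSplit", function(object) {
  cat(sprintf("BeeneSplit: %d train / %d val / %d test cells (seed %d)\n",
              ncol(object@train), ncol(object@val), ncol(object@test),
              object@seed))
  if (length(object@normStats))
    cat("gene standardization: fitted on training partition\n")
})

setMethod("show", "BeeneModel", function(object) {
  s <- object@spec
  cat(sprintf("BeeneModel: %d -> [%s] -> %d latent, lambdas = (%g, %g, %g)\n",
              s$inputDim, paste(s$encoderHidden, collapse = ", "),
              s$latentDim, s$lambdas[1], s$lambdas[2], s$lambdas[3]))
  cat(sprintf("trained %d epochs, best validation epoch %d\n",
              max(object@trainLog$epoch), object@bestEpoch))
})

setMethod("show", "KbetResult", function(object) {
  cat(sprintf(
    "kBET over %d subsamples (k0 = %d, alpha = %g): mean rejection %.3f, median %.3f\n",
    length(object@rates), object@k0, object@alpha,
    object@meanRate, object@medianRate))
})

setMethod("show", "LisiResult", function(object) {
  cat(sprintf(
    "iLISI over %d cells (perplexity %g): mean %.3f, median %.3f\n",
    length(object@perCell), object@perplexity,
    object@meanIlisi, object@medianIlisi))
})
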