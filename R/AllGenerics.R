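#' Per-cell batch labels
#'
#' @param x a \linkS4class{BeeneExperiment}.
#' @return \code{batchLabels}: factor of batch labels (or \code{NULL} when
#'   unset); \code{batchCodes}: 0-based integer coding in first-appearance
#'   order; \code{nBatches}: number of batch levels K.
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))

#' @rdname batchLabels
#' @export
setGeneric("bioLabels", function(x) standardGeneric("bioLabels"))

#' @rdname batchLabels
#' @export
setGeneric("batchCodes", function(x) standardGeneric("batchCodes"))

#' @rdname batchLabels
#' @export
setGeneric("bioCodes", function(x) standardGeneric("bioCodes"))

#' @rdname batchLabels
#' @export
setGeneric("nBatches", function(x) standardGeneric("nBatches"))

#' @rdname batchLabels
#' @export
setGeneric("nBioClasses", function(x) standardGeneric("nBioClasses"))

#' Expression matrix in cells x genes orientation
#'
#' The network and metrics operate on cells-as-rows matrices; internally a
#' \linkS4class{BeeneExperiment} stores genes x cells.
#'
#' @param x a \linkS4class{BeeneExperiment}.
#' @param assayName which assay to extract.
#' @return numeric matrix, cells x genes.
#' @export
setGeneric("cellMatrix", function(x, assayName = 1L) standardGeneric("cellMatrix"))

#' @describeIn batchLabels factor of batch labels
setMethod("batchLabels", "BeeneExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("batch" %in% colnames(cd)) cd$batch else NULL
})

#' @describeIn batchLabels factor of biological labels
setMethod("bioLabels", "BeeneExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("bio" %in% colnames(cd)) cd$bio else NULL
})

#' @describeIn batchLabels 0-based integer batch coding
setMethod("batchCodes", "BeeneExperiment", function(x) {
  f <- batchLabels(x)
  if (is.null(f)) NULL else as.integer(f) - 1L
})

#' @describeIn batchLabels 0-based integer bio coding
setMethod("bioCodes", "BeeneExperiment", function(x) {
  f <- bioLabels(x)
  if (is.null(f)) NULL else as.integer(f) - 1L
})

#' @describeIn batchLabels number of batches K
setMethod("nBatches", "BeeneExperiment", function(x) {
  f <- batchLabels(x)
  if (is.null(f)) 0L else nlevels(f)
})

#' @describeIn batchLabels number of biological classes M (0 when unset)
setMethod("nBioClasses", "BeeneExperiment", function(x) {
  f <- bioLabels(x)
  if (is.null(f)) 0L else nlevels(f)
})

#' @describeIn cellMatrix cells x genes matrix from the named assay
setMethod("cellMatrix", "BeeneExperiment", function(x, assayName = 1L) {
  t(as.matrix(SummarizedExperiment::assay(x, assayName)))
})

#' Partition accessors for BeeneSplit
#'
#' @param x a \linkS4class{BeeneSplit}.
#' @param which one of "train", "val", "test".
#' @return the requested \linkS4class{BeeneExperiment} partition.
#' @export
setGeneric("partition", function(x, which) standardGeneric("partition"))

#' @describeIn partition extract one partition
setMethod("partition", "BeeneSplit", function(x, which) {
  switch(match.arg(which, c("train", "val", "test")),
         train = x@train, val = x@val, test = x@test)
})
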