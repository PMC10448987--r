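#' Load an expression matrix from disk
#'
#' Reads a dense CSV/TSV table (header row required) or a MatrixMarket
#' \code{.mtx} triplet file with optional sidecar identifier files. The
#' on-disk orientation must be declared; it is never guessed from the shape,
#' because silently transposed matrices are the classic failure mode of
#' expression loaders.
#'
#' For MTX input, gene and cell identifiers are looked up in
#' \code{<stem>.genes.txt} / \code{features.tsv} and \code{<stem>.cells.txt}
#' / \code{barcodes.tsv} next to the matrix file; when absent they are
#' synthesized as \code{"g0001"...} and \code{"c0001"...}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"csv"}, \code{"tsv"} or
#'   \code{"mtx"}. The \code{"h5"} single-cell container format is not
#'   supported by this build and raises an informative error.
#' @param orientation orientation of the on-disk matrix.
#' @param countMode if \code{TRUE}, validate that entries are nonnegative
#'   (raw counts); NaN or negative entries raise a validation error.
#' @return a \linkS4class{BeeneExperiment} with labels unset.
#' @export
loadExpression <- function(path,
                           format = c("auto", "csv", "tsv", "mtx", "h5"),
                           orientation = c("cells_x_genes", "genes_x_cells"),
                           countMode = FALSE) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     h5 = "h5", hdf5 = "h5",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly"))
  }
  if (format == "h5")
    stop("HDF5 single-cell containers are not supported by this build; ",
         "export the matrix as MTX or CSV")
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("malformed MatrixMarket file '",
                                           path, "': ", conditionMessage(e)))
    m <- as.matrix(m)
    geneIds <- cellIds <- NULL
    stem <- sub("\\.mtx$", "", path)
    dirn <- dirname(path)
    readIds <- function(cands) {
      for (f in cands)
        if (file.exists(f)) {
          tab <- utils::read.table(f, sep = "\t", header = FALSE,
                                   stringsAsFactors = FALSE)
          return(as.character(tab[[1L]]))
        }
      NULL
    }
    rowIds <- readIds(c(paste0(stem, ".rows.txt")))
    colIds <- readIds(c(paste0(stem, ".cols.txt")))
    gcands <- c(paste0(stem, ".genes.txt"),
                file.path(dirn, "features.tsv"), file.path(dirn, "genes.tsv"))
    ccands <- c(paste0(stem, ".cells.txt"), file.path(dirn, "barcodes.tsv"))
    if (orientation == "cells_x_genes") {
      cellIds <- if (is.null(rowIds)) readIds(ccands) else rowIds
      geneIds <- if (is.null(colIds)) readIds(gcands) else colIds
    } else {
      geneIds <- if (is.null(rowIds)) readIds(gcands) else rowIds
      cellIds <- if (is.null(colIds)) readIds(ccands) else colIds
    }
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(utils::read.table(path, sep = sep, header = TRUE,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE),
                   error = function(e) stop("malformed ", format, " file '",
                                            path, "': ", conditionMessage(e)))
    rowIds <- NULL
    if (ncol(df) >= 2L && is.character(df[[1L]])) {
      rowIds <- df[[1L]]
      df <- df[, -1L, drop = FALSE]
    }
    bad <- which(!vapply(df, is.numeric, logical(1L)))
    if (length(bad))
      stop("non-numeric entries in column(s) ",
           paste(colnames(df)[bad], collapse = ", "), " of '", path, "'")
    m <- as.matrix(df)
    rownames(m) <- rowIds
    if (orientation == "cells_x_genes") {
      cellIds <- rowIds; geneIds <- colnames(df)
    } else {
      geneIds <- rowIds; cellIds <- colnames(df)
    }
  }
  if (anyNA(m))
    stop("expression matrix '", path, "' contains ", sum(is.na(m)),
         " missing/NaN entries")
  if (countMode && any(m < 0))
    stop("negative entries found in count-mode matrix '", path, "'")
  BeeneExperiment(m, orientation = orientation,
                  geneIds = geneIds, cellIds = cellIds)
}

#' Write an expression matrix (and labels) to disk
#'
#' Inverse of \code{\link{loadExpression}}: \code{"csv"}/\code{"tsv"} writes
#' a dense cells x genes table with a header row and a leading cell-id
#' column; \code{"mtx"} writes a MatrixMarket file plus
#' \code{<stem>.genes.txt} and \code{<stem>.cells.txt} sidecars. Batch/bio
#' labels, when present, are written as two-column TSVs next to the matrix.
#'
#' @param x a \linkS4class{BeeneExperiment}.
#' @param path output file path.
#' @param format \code{"csv"}, \code{"tsv"} or \code{"mtx"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  m <- cellMatrix(x)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(t(m), sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(SummarizedExperiment::assay(x, 1L)),
               paste0(stem, ".genes.txt"))
    writeLines(colnames(x), paste0(stem, ".cells.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  stem <- sub("\\.[a-z]+$", "", path)
  if (!is.null(batchLabels(x)))
    utils::write.table(
      data.frame(cell_id = colnames(x), label = as.character(batchLabels(x))),
      paste0(stem, ".batches.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bioLabels(x)))
    utils::write.table(
      data.frame(cell_id = colnames(x), label = as.character(bioLabels(x))),
      paste0(stem, ".bio.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Set batch / biological labels on a BeeneExperiment
#'
#' Labels are coded by first appearance: the first label seen becomes level
#' 0, the next new one level 1, and so on. This keeps codings reproducible
#' without any sorting assumption.
#'
#' @param x a \linkS4class{BeeneExperiment}.
#' @param batch,bio per-cell label vectors (length = number of cells), or
#'   \code{NULL} to leave unchanged.
#' @return the updated object.
#' @export
setLabels <- function(x, batch = NULL, bio = NULL) {
  n <- ncol(x)
  cd <- SummarizedExperiment::colData(x)
  if (!is.null(batch)) {
    if (length(batch) != n)
      stop("batch labels have length ", length(batch), " but there are ",
           n, " cells")
    f <- firstAppearanceFactor(batch)
    if (nlevels(f) < 2L)
      stop("at least 2 batches are required for batch-effect analysis")
    if (any(table(f) < 2L))
      stop("every batch needs >= 2 cells (chi-squared test undefined ",
           "otherwise); offending: ",
           paste(names(which(table(f) < 2L)), collapse = ", "))
    cd$batch <- f
  }
  if (!is.null(bio)) {
    if (length(bio) != n)
      stop("bio labels have length ", length(bio), " but there are ",
           n, " cells")
    cd$bio <- firstAppearanceFactor(bio)
  }
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
}

#' Attach labels from files
#'
#' Label files are single-column (one label per line, aligned by cell
#' order) or two-column TSV \code{(cell_id, label)}; with
#' \code{matchBy = "cell_id"} the rows may appear in any order.
#'
#' @param x a \linkS4class{BeeneExperiment}.
#' @param batchFile path to the batch label file (required).
#' @param bioFile optional path to the biological label file.
#' @param matchBy \code{"order"} or \code{"cell_id"}.
#' @return the labeled object.
#' @export
attachLabels <- function(x, batchFile, bioFile = NULL,
                         matchBy = c("order", "cell_id")) {
  matchBy <- match.arg(matchBy)
  readLab <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) == 1L) {
      if (matchBy == "cell_id")
        stop("label file '", path, "' has no cell_id column but ",
             "matchBy = 'cell_id' was requested")
      if (nrow(tab) != ncol(x))
        stop("label file '", path, "' has ", nrow(tab),
             " entries for ", ncol(x), " cells")
      as.character(tab[[1L]])
    } else {
      ids <- as.character(tab[[1L]])
      # tolerate a header line
      if (identical(tolower(ids[1L]), "cell_id")) {
        tab <- tab[-1L, , drop = FALSE]
        ids <- as.character(tab[[1L]])
      }
      if (nrow(tab) != ncol(x))
        stop("label file '", path, "' has ", nrow(tab),
             " entries for ", ncol(x), " cells")
      lab <- as.character(tab[[2L]])
      if (matchBy == "cell_id") {
        idx <- match(colnames(x), ids)
        if (anyNA(idx))
          stop("label file '", path, "' is missing cell id(s): ",
               paste(utils::head(colnames(x)[is.na(idx)], 5L),
                     collapse = ", "))
        lab <- lab[idx]
      }
      lab
    }
  }
  bio <- if (is.null(bioFile)) NULL else readLab(bioFile)
  setLabels(x, batch = readLab(batchFile), bio = bio)
}

#' Library-size normalization
#'
#' \code{"log1p_cpm"} scales every cell to a common library size
#' (\code{targetLibSize}, default counts-per-10k) and applies
#' \code{log(1 + .)}. Per-gene standardization is a separate, split-aware
#' step (\code{\link{standardizeGenes}}) because its statistics must come
#' from the training partition only.
#'
#' @param x a \linkS4class{BeeneExperiment} holding nonnegative counts.
#' @param scheme \code{"log1p_cpm"} or \code{"none"}.
#' @param targetLibSize common library size (default 1e4).
#' @param assayName output assay name (default \code{"expr"}).
#' @return the object with the normalized assay as first assay.
#' @export
normalizeExpression <- function(x, scheme = c("log1p_cpm", "none"),
                                targetLibSize = 1e4, assayName = "expr") {
  scheme <- match.arg(scheme)
  if (scheme == "none") return(x)
  m <- as.matrix(SummarizedExperiment::assay(x, 1L))  # genes x cells
  if (any(m < 0))
    stop("library-size normalization needs nonnegative counts")
  libs <- colSums(m)
  if (any(libs == 0))
    stop("cell(s) with zero library size: ",
         paste(utils::head(colnames(x)[libs == 0], 10L), collapse = ", "))
  norm <- log1p(sweep(m, 2L, targetLibSize / libs, `*`))
  SummarizedExperiment::assay(x, assayName, withDimnames = FALSE) <- norm
  # make the normalized assay the first one
  an <- SummarizedExperiment::assayNames(x)
  SummarizedExperiment::assays(x) <-
    SummarizedExperiment::assays(x)[c(assayName, setdiff(an, assayName))]
  x
}

#' Stratified train/validation/test split
#'
#' Randomly partitions cells with the requested fractions, stratified by
#' batch (and additionally by biological class when present), so that every
#' batch and every class is represented in every nonempty partition.
#' Within each stratum, counts are \code{floor(fraction * n)} with the
#' remainder assigned by largest fractional part — for round numbers (e.g.
#' 50 cells at 60:20:20) the partition is exact.
#'
#' @param x a labeled \linkS4class{BeeneExperiment}.
#' @param fractions numeric(3) train/val/test fractions summing to 1
#'   (default \code{c(0.6, 0.2, 0.2)}).
#' @param seed integer seed; the same seed always yields the same partition.
#' @param stratifyBy \code{"auto"} (batch x bio when bio labels exist, else
#'   batch), \code{"batch"}, or \code{"batch_and_bio"}.
#' @param minStratum minimum stratum size (default 5).
#' @return a \linkS4class{BeeneSplit}.
#' @export
splitCells <- function(x, fractions = c(0.6, 0.2, 0.2), seed = 1L,
                       stratifyBy = c("auto", "batch", "batch_and_bio"),
                       minStratum = 5L) {
  stratifyBy <- match.arg(stratifyBy)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three nonnegative values summing to 1")
  b <- batchLabels(x)
  if (is.null(b)) stop("batch labels must be set before splitting")
  y <- bioLabels(x)
  useBio <- switch(stratifyBy,
                   auto = !is.null(y),
                   batch = FALSE,
                   batch_and_bio = {
                     if (is.null(y)) stop("no bio labels to stratify by")
                     TRUE
                   })
  strata <- if (useBio) interaction(b, y, drop = TRUE) else b
  sizes <- table(strata)
  if (any(sizes < minStratum))
    stop("stratum/strata too small (< ", minStratum, " cells): ",
         paste(names(which(sizes < minStratum)), collapse = ", "),
         "; merge batches or adjust fractions")
  part <- integer(ncol(x))
  withSeed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      n <- length(idx)
      counts <- floor(fractions * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        frac <- fractions * n - counts
        extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      if (any(counts == 0L & fractions > 0))
        stop("stratum '", s, "' (", n, " cells) cannot fill every nonempty ",
             "partition at fractions ", paste(fractions, collapse = ":"))
      shuffled <- sample(idx)
      part[shuffled] <- rep.int(1:3, counts)
    }
  })
  methods::new("BeeneSplit",
               train = x[, part == 1L],
               val = x[, part == 2L],
               test = x[, part == 3L],
               fractions = as.numeric(fractions),
               seed = as.integer(seed),
               normStats = list())
}

#' Per-gene standardization fitted on the training partition
#'
#' Centers and scales every gene to mean 0 / sd 1 using statistics computed
#' on the training cells only; validation and test cells are transformed
#' with the training statistics. Genes constant in the training partition
#' are centered but left unscaled.
#'
#' @param split a \linkS4class{BeeneSplit}.
#' @param assayName assay to standardize (default first assay).
#' @return the split with standardized assays and \code{normStats} recorded.
#' @export
standardizeGenes <- function(split, assayName = 1L) {
  mTrain <- as.matrix(SummarizedExperiment::assay(split@train, assayName))
  center <- rowMeans(mTrain)
  scale <- apply(mTrain, 1L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  applyStd <- function(be) {
    if (ncol(be) == 0L) return(be)
    m <- as.matrix(SummarizedExperiment::assay(be, assayName))
    SummarizedExperiment::assay(be, assayName, withDimnames = FALSE) <-
      (m - center) / scale
    be
  }
  split@train <- applyStd(split@train)
  split@val <- applyStd(split@val)
  split@test <- applyStd(split@test)
  split@normStats <- list(center = center, scale = scale)
  split
}
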