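test_that("CSV read-back preserves shape, values and identifiers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("geneA,geneB", "1,2", "3,4", "5,6"), f)
  be <- loadExpression(f, orientation = "cells_x_genes")
  m <- cellMatrix(be)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(colnames(m), c("geneA", "geneB"))
  expect_equal(unname(m), matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
  expect_equal(rownames(m), c("c0001", "c0002", "c0003"))
})

test_that("MTX with zero stored entries yields an all-zero dense matrix", {
  f <- withr::local_tempfile(fileext = ".mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "4 3 0"), f)
  be <- loadExpression(f, orientation = "genes_x_cells")
  m <- cellMatrix(be)
  expect_equal(dim(m), c(3L, 4L))
  expect_true(all(m == 0))
})

test_that("write/load round-trips a random matrix in every dense format", {
  set.seed(42)
  x <- matrix(round(rexp(50 * 20) * 10, 6), 50, 20)
  be <- BeeneExperiment(x, orientation = "cells_x_genes",
                        batch = rep(c("p", "q"), 25))
  for (fmt in c("csv", "tsv", "mtx")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    writeExpression(be, f, format = fmt)
    back <- loadExpression(f, orientation = if (fmt == "mtx")
      "genes_x_cells" else "cells_x_genes")
    expect_lt(max(abs(cellMatrix(back) - cellMatrix(be))), 1e-12)
    # labels round-trip through the sidecar file
    lab <- paste0(sub("\\.[a-z]+$", "", f), ".batches.tsv")
    back <- attachLabels(back, lab, matchBy = "cell_id")
    expect_equal(as.character(batchLabels(back)),
                 as.character(batchLabels(be)))
  }
})

test_that("malformed and invalid matrices are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,x", "2,3"), f)
  expect_error(loadExpression(f), "non-numeric")
  writeLines(c("a,b", "1,NA", "2,3"), f)
  expect_error(loadExpression(f), "missing")
  writeLines(c("a,b", "1,-2", "2,3"), f)
  expect_error(loadExpression(f, countMode = TRUE), "egative")
  expect_error(loadExpression(f, format = "h5"), "not supported")
})

test_that("labels are coded by first appearance", {
  be <- BeeneExperiment(matrix(1, 4, 4), orientation = "cells_x_genes")
  be <- setLabels(be, batch = c("b", "a", "b", "a"))
  expect_equal(batchCodes(be), c(0L, 1L, 0L, 1L))
  expect_equal(levels(batchLabels(be)), c("b", "a"))
  expect_equal(nBatches(be), 2L)
  expect_equal(nBioClasses(be), 0L)
  expect_null(bioLabels(be))
})

test_that("id-aligned label files give the same coding as ordered files", {
  set.seed(1)
  be <- BeeneExperiment(matrix(rnorm(40), 10, 4),
                        orientation = "cells_x_genes")
  lab <- rep(c("x", "y"), 5)
  ordered <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lab, ordered)
  shuffled <- withr::local_tempfile(fileext = ".tsv")
  perm <- sample(10)
  utils::write.table(data.frame(id = colnames(be)[perm], lab = lab[perm]),
                     shuffled, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  a <- attachLabels(be, ordered, matchBy = "order")
  b <- attachLabels(be, shuffled, matchBy = "cell_id")
  expect_equal(batchCodes(a), batchCodes(b))
})

test_that("label validation rejects mismatch and singleton batches", {
  be <- BeeneExperiment(matrix(1, 3, 4), orientation = "cells_x_genes")
  expect_error(setLabels(be, batch = c("a", "b")), "length")
  expect_error(setLabels(be, batch = c("a", "a", "b")), ">= 2 cells")
  expect_error(setLabels(be, batch = c("a", "a", "a")), "2 batches")
})

test_that("library-size normalization matches the closed form", {
  be <- BeeneExperiment(matrix(c(9, 0), 1, 2), orientation = "cells_x_genes")
  norm <- normalizeExpression(be, "log1p_cpm", targetLibSize = 10)
  expect_equal(unname(cellMatrix(norm)[1, ]), c(log(11), 0))
  # scheme none is the identity
  expect_identical(cellMatrix(normalizeExpression(be, "none")),
                   cellMatrix(be))
  # zero-library cells are named in the error
  bad <- BeeneExperiment(rbind(c(1, 2), c(0, 0)),
                         orientation = "cells_x_genes")
  expect_error(normalizeExpression(bad), "zero library")
})

test_that("standardization statistics come from the training split only", {
  be <- tinyCondition(seed = 21L)
  sp <- standardizeGenes(splitCells(be, seed = 5))
  mTrain <- as.matrix(SummarizedExperiment::assay(partition(sp, "train"), 1L))
  expect_lt(max(abs(rowMeans(mTrain))), 1e-6)
  expect_lt(max(abs(apply(mTrain, 1, sd) - 1)), 1e-6)
  # val/test transformed with train statistics, not their own
  mVal <- as.matrix(SummarizedExperiment::assay(partition(sp, "val"), 1L))
  expect_gt(max(abs(rowMeans(mVal))), 1e-8)
  # recompute: train stats applied to raw val equal the stored val assay
  rawVal <- as.matrix(SummarizedExperiment::assay(
    partition(splitCells(be, seed = 5), "val"), 1L))
  expect_equal(mVal, (rawVal - sp@normStats$center) / sp@normStats$scale,
               tolerance = 1e-12)
})

test_that("stratified splitting is exact, deterministic and a partition", {
  be <- BeeneExperiment(matrix(rnorm(400), 100, 4),
                        orientation = "cells_x_genes",
                        batch = rep(c("a", "b"), each = 50))
  sp <- splitCells(be, seed = 9)
  expect_equal(ncol(partition(sp, "train")), 60L)
  expect_equal(ncol(partition(sp, "val")), 20L)
  expect_equal(ncol(partition(sp, "test")), 20L)
  for (w in c("train", "val", "test"))
    expect_equal(as.vector(table(batchLabels(partition(sp, w)))),
                 rep(ncol(partition(sp, w)) / 2, 2))
  sp2 <- splitCells(be, seed = 9)
  expect_identical(colnames(partition(sp, "train")),
                   colnames(partition(sp2, "train")))
  sp3 <- splitCells(be, seed = 10)
  expect_false(identical(colnames(partition(sp, "train")),
                         colnames(partition(sp3, "train"))))
  # union is the full cell set
  ids <- c(colnames(partition(sp, "train")), colnames(partition(sp, "val")),
           colnames(partition(sp, "test")))
  expect_setequal(ids, colnames(be))
  # degenerate fractions put everything in train
  spAll <- splitCells(be, fractions = c(1, 0, 0), seed = 1)
  expect_equal(ncol(partition(spAll, "train")), 100L)
  expect_equal(ncol(partition(spAll, "test")), 0L)
  # too-small strata are refused
  tiny <- BeeneExperiment(matrix(1, 6, 4), orientation = "cells_x_genes",
                          batch = c("a", "a", "a", "a", "b", "b"))
  expect_error(splitCells(tiny, seed = 1), "too small")
})
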