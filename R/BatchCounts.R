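#' Construct a BatchCounts object
#'
#' @param counts genes-by-cells matrix (dense or sparse) of raw non-negative
#'   integer counts.
#' @param batch per-cell batch labels (any atomic type); levels are taken in
#'   first-appearance order and recoded to 1..B internally.
#' @return A \linkS4class{BatchCounts} object.
#' @examples
#' y <- matrix(rpois(12, 3), nrow = 3)
#' bc <- BatchCounts(y, batch = c("a", "a", "b", "b"))
#' nBatches(bc)
#' @export
BatchCounts <- function(counts, batch) {
  counts <- as.matrix(counts)
  if (length(batch) != ncol(counts))
    stop("length(batch) must equal ncol(counts)")
  if (anyNA(counts) || anyNA(batch))
    stop("counts and batch must not contain missing values")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  b <- factor(as.character(batch), levels = unique(as.character(batch)))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = DataFrame(batch = b))
  new("BatchCounts", se)
}

#' @describeIn BatchCounts batch labels as a factor (first-appearance order)
#' @param x a BatchCounts object
#' @export
batchLabels <- function(x) colData(x)$batch

#' @describeIn BatchCounts integer batch index per cell (1..B)
#' @export
batchIds <- function(x) as.integer(batchLabels(x))

#' @describeIn BatchCounts number of batches
#' @export
nBatches <- function(x) nlevels(batchLabels(x))

#' @describeIn BatchCounts per-batch cell counts
#' @export
batchSizes <- function(x) as.integer(table(batchLabels(x)))

setMethod("show", "BatchCounts", function(object) {
  cat("BatchCounts:", nrow(object), "genes x", ncol(object), "cells in",
      nBatches(object), "batches (",
      paste(batchSizes(object), collapse = ", "), ")\n")
  y <- assay(object, "counts")
  cat(sprintf("  overall zero rate: %.3f\n", mean(y == 0)))
})

# internal: pull the dense integer matrix
.countsOf <- function(x) {
  if (is(x, "BatchCounts")) as.matrix(assay(x, "counts")) else as.matrix(x)
}
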