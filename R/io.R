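# Readers and writers for the standard on-disk formats: MatrixMarket or
# delimited counts, delimited cell metadata, simulation bundles and run
# manifests.

#' Read multi-batch counts from disk
#'
#' Counts may be MatrixMarket (\code{.mtx}, genes x cells) or a delimited
#' table with a header of cell identifiers and optional first column of
#' gene identifiers. Metadata is a delimited table with one row per cell
#' (same order as the count columns) containing a batch column. Batch
#' labels are recoded to 1..B in first-appearance order. Malformed input
#' (negative, fractional or missing counts; missing batch labels;
#' mismatched dimensions) is rejected, never coerced.
#'
#' @param countsPath path to the counts file.
#' @param metadataPath path to the cell metadata table.
#' @param batchCol name of the batch column in the metadata.
#' @return A \linkS4class{BatchCounts}.
#' @export
readBatchCounts <- function(countsPath, metadataPath, batchCol = "batch") {
  if (!file.exists(countsPath)) stop("counts file not found: ", countsPath)
  if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
  if (grepl("\\.mtx$", countsPath, ignore.case = TRUE)) {
    y <- as.matrix(Matrix::readMM(countsPath))
    rownames(y) <- paste0("gene", seq_len(nrow(y)))
    colnames(y) <- paste0("cell", seq_len(ncol(y)))
  } else {
    tab <- data.table::fread(countsPath, header = TRUE, data.table = FALSE)
    if (!ncol(tab)) stop("empty counts table: ", countsPath)
    if (!is.numeric(tab[[1]])) {
      rn <- as.character(tab[[1]])
      tab <- tab[, -1, drop = FALSE]
      y <- as.matrix(tab)
      rownames(y) <- rn
    } else {
      y <- as.matrix(tab)
      rownames(y) <- paste0("gene", seq_len(nrow(y)))
    }
  }
  if (anyNA(y))
    stop("counts contain missing values (row/col: ",
         paste(which(is.na(y), arr.ind = TRUE)[1, ], collapse = "/"), ")")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8)) {
    bad <- which(y < 0 | abs(y - round(y)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("counts must be non-negative integers (first offending row/col: ",
         paste(bad, collapse = "/"), ")")
  }
  meta <- data.table::fread(metadataPath, header = TRUE, data.table = FALSE)
  if (!batchCol %in% colnames(meta))
    stop("metadata lacks the batch column '", batchCol, "'")
  if (nrow(meta) != ncol(y))
    stop("metadata rows (", nrow(meta), ") do not match count columns (",
         ncol(y), ")")
  if (anyNA(meta[[batchCol]])) stop("missing batch labels in metadata")
  BatchCounts(y, batch = meta[[batchCol]])
}

#' Write multi-batch counts to disk
#'
#' Writes the counts as MatrixMarket (\code{counts.mtx}) and the cell
#' metadata as a tab-separated table (\code{cells.tsv}) into \code{dir}.
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param dir output directory (created if needed).
#' @param extra optional data.frame of extra per-cell columns (e.g. true
#'   types for simulations).
#' @return invisibly, the paths written.
#' @export
writeBatchCounts <- function(data, dir, extra = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  y <- .countsOf(data)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(Matrix::Matrix(y, sparse = TRUE), mtx)
  meta <- data.frame(cell = colnames(y), batch = as.character(batchLabels(data)))
  if (!is.null(extra)) meta <- cbind(meta, extra)
  tsv <- file.path(dir, "cells.tsv")
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = mtx, cells = tsv))
}

#' Write a simulation bundle
#'
#' Counts as MatrixMarket, cell metadata (with true types) as TSV, and the
#' ground-truth parameters as a JSON key-value container.
#'
#' @param sim the list returned by \code{\link{simulateData}}.
#' @param dir output directory.
#' @export
writeSimulation <- function(sim, dir) {
  truth <- sim$truth
  paths <- writeBatchCounts(sim$data, dir,
                            extra = data.frame(trueType = truth@latent$W))
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(params = truth@params, deGenes = truth@deGenes,
         presence = truth@design@presence * 1,
         nPerBatch = truth@design@nPerBatch, kind = truth@design@kind),
    tj, digits = NA, matrix = "columnmajor")
  invisible(c(paths, truth = tj))
}

#' Write a run manifest
#'
#' Every command of the CLI records its seed, configuration and package
#' version so the run can be reproduced exactly.
#' @param dir output directory.
#' @param command command name.
#' @param config the configuration list used.
#' @keywords internal
writeManifest <- function(dir, command, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(command = command, config = config,
         package = as.character(utils::packageVersion("scBatchMix")),
         rversion = R.version.string,
         time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(file.path(dir, "manifest.json"))
}
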