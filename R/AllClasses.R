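#' Multi-batch count data container
#'
#' A \linkS4class{SummarizedExperiment} holding a genes-by-cells matrix of
#' raw non-negative integer counts in the \code{"counts"} assay and a
#' \code{batch} factor in \code{colData}. Batch levels are ordered by first
#' appearance and every batch must be non-empty.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("BatchCounts", contains = "SummarizedExperiment")

setValidity("BatchCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    y <- assay(object, "counts")
    if (any(y < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(y - round(y)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (!"batch" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'batch' is required")
  else {
    b <- colData(object)$batch
    if (!is.factor(b)) msg <- c(msg, "batch must be a factor")
    else if (any(table(b) == 0)) msg <- c(msg, "every batch must be non-empty")
  }
  if (is.null(msg)) TRUE else msg
})

#' Experimental design: batch-by-type presence and compositions
#'
#' Describes which of the K cell types are present in each of the B batches
#' (the sets C_b), the cell-type composition of each batch, and the per-batch
#' sample sizes. Valid designs have every type present in at least one batch
#' and composition rows summing to one with support exactly on the present
#' types.
#'
#' @slot kind character; one of "complete", "reference_panel", "chain_type",
#'   "custom".
#' @slot presence B x K logical matrix.
#' @slot pi B x K composition matrix; zero exactly where presence is FALSE.
#' @slot nPerBatch integer vector of per-batch cell counts.
#' @export
setClass("BatchDesign",
  representation(kind = "character", presence = "matrix", pi = "matrix",
                 nPerBatch = "integer"))

setValidity("BatchDesign", function(object) {
  msg <- NULL
  pr <- object@presence; pp <- object@pi
  if (!is.logical(pr)) msg <- c(msg, "presence must be logical")
  if (!all(dim(pr) == dim(pp))) msg <- c(msg, "presence/pi dimension mismatch")
  if (nrow(pr) != length(object@nPerBatch))
    msg <- c(msg, "nPerBatch length must equal the number of batches")
  if (any(colSums(pr) == 0))
    msg <- c(msg, "every cell type must be present in at least one batch")
  if (any(rowSums(pr) == 0)) msg <- c(msg, "every batch must contain a type")
  if (any(abs(rowSums(pp) - 1) > 1e-8)) msg <- c(msg, "pi rows must sum to 1")
  if (any((pp > 0) != pr)) msg <- c(msg, "pi must be positive exactly on present types")
  if (any(object@nPerBatch < 1L)) msg <- c(msg, "batch sizes must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Batch graph of a design
#'
#' Nodes are batches; an undirected edge joins two batches that share at
#' least two cell types. A connected graph certifies identifiability of the
#' design (given the standing regularity conditions on the dropout slope and
#' the cell-type effects).
#'
#' @slot nBatches integer.
#' @slot edges two-column integer matrix of unordered batch pairs.
#' @slot shared integer vector, number of shared types per edge.
#' @slot connected logical.
#' @export
setClass("BatchGraph",
  representation(nBatches = "integer", edges = "matrix",
                 shared = "integer", connected = "logical"))

#' Ground truth of a simulated dataset
#'
#' @slot params list of generative parameters (alpha, beta, nu, delta, phi,
#'   gamma0, gamma1, pi).
#' @slot latent list with true X, Z, W (empty until data are simulated).
#' @slot deGenes integer indices of genes with a nonzero cell-type effect.
#' @slot design the \linkS4class{BatchDesign} used.
#' @export
setClass("SimTruth",
  representation(params = "list", latent = "list", deGenes = "integer",
                 design = "BatchDesign"))

#' Retained MCMC draws
#'
#' Post-burn-in draws of all parameter blocks for one or more independent
#' chains, together with acceptance-rate summaries, the sampler settings and
#' the data the chains were run on.
#'
#' @slot chains list (one element per chain) of draw arrays as returned by
#'   the compiled sampler.
#' @slot counts the observed count matrix the chains were fit to.
#' @slot batch integer batch index per cell (1..B).
#' @slot K integer, number of mixture components.
#' @slot nIter,burnin,thin integer sampler settings.
#' @slot seed integer master seed.
#' @slot variant "full" (zero-inflated) or "nzf" (no zero inflation).
#' @slot hyper list of hyperparameters used.
#' @export
setClass("MixChains",
  representation(chains = "list", counts = "matrix", batch = "integer",
                 K = "integer", nIter = "integer", burnin = "integer",
                 thin = "integer", seed = "integer", variant = "character",
                 hyper = "list"))

#' Posterior summary of a fit
#'
#' @slot thetaHat list of posterior means (alpha, beta, nu, delta, phi,
#'   gamma0, gamma1, pi).
#' @slot wHat integer posterior-mode cell type per cell (1..K).
#' @slot xHat imputed underlying counts; equals the observed count except at
#'   zero entries called as dropouts.
#' @slot pDrop posterior probability of a dropout event per entry.
#' @slot xi G x (K-1) posterior probabilities Pr(L_gk = 0 | y), k = 2..K.
#' @slot kappa0 threshold selected by the Bayesian FDR search (NA if none).
#' @slot intrinsic integer indices of intrinsic genes.
#' @slot calls logical G x (K-1) matrix of per-(gene,type) DE calls.
#' @slot bic,logLik numeric (NA until \code{computeBIC} is run).
#' @slot K integer; @slot batch integer per-cell batch index.
#' @export
setClass("MixFit",
  representation(thetaHat = "list", wHat = "integer", xHat = "matrix",
                 pDrop = "matrix", xi = "matrix", kappa0 = "numeric",
                 intrinsic = "integer", calls = "matrix",
                 bic = "numeric", logLik = "numeric",
                 K = "integer", batch = "integer"))

#' Batch-effects-corrected counts
#'
#' @slot xTilde G x N matrix of corrected non-negative integer counts.
#' @slot u G x N matrix of matching quantiles in (0, 1).
#' @slot seed integer seed used for the inverse-sampling draw.
#' @export
setClass("CorrectedCounts",
  representation(xTilde = "matrix", u = "matrix", seed = "integer"))
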