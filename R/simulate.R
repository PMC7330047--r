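# Generative simulator for the hierarchical model under valid designs.

#' Simulation configuration
#'
#' Effect-size settings for \code{\link{simulateTruth}}. Defaults emulate
#' the regime typical of multi-batch scRNA-seq experiments: baseline
#' log-expression around 2, cell-type effects on a symmetric two-tier log
#' grid, batch effects at or above the scale of the cell-type effects,
#' moderate cell-size variation, and logistic missing-not-at-random dropout
#' yielding overall zero rates around 40-60 percent of which roughly a
#' quarter to a half are dropouts.
#'
#' @param nGenes number of genes G.
#' @param nDE number of differentially expressed (intrinsic) genes.
#' @param betaMag magnitudes of the expression-level grid: each intrinsic
#'   gene draws, for every cell type independently, a log-scale level from
#'   the symmetric grid \code{c(-rev(betaMag), betaMag)} (high, medium
#'   high, ..., medium low, low), and the cell-type effect is the level
#'   difference against type 1; a draw with all levels equal is rejected.
#' @param alphaMean,alphaSD baseline log-expression distribution.
#' @param nuSD sd of location batch effects (batches 2..B).
#' @param deltaSD sd of cell-specific size factors.
#' @param phiRange uniform range for overdispersions.
#' @param gamma0Range,gamma1Range uniform ranges for the per-batch dropout
#'   intercept and (strictly negative) slope.
#' @export
simConfig <- function(nGenes = 500, nDE = round(nGenes / 6),
                      betaMag = c(2, 3),
                      alphaMean = 2, alphaSD = 1, nuSD = 2, deltaSD = 0.5,
                      phiRange = c(2, 6), gamma0Range = c(-0.6, 0.2),
                      gamma1Range = c(-0.25, -0.08)) {
  if (any(gamma1Range >= 0))
    stop("gamma1Range must be strictly negative (condition I)")
  if (nDE > nGenes) stop("nDE cannot exceed nGenes")
  list(nGenes = as.integer(nGenes), nDE = as.integer(nDE),
       betaMag = betaMag, alphaMean = alphaMean,
       alphaSD = alphaSD, nuSD = nuSD, deltaSD = deltaSD,
       phiRange = phiRange, gamma0Range = gamma0Range,
       gamma1Range = gamma1Range)
}

# condition (II): every pair of types differs in >= 2 genes
.conditionII <- function(beta) {
  K <- ncol(beta)
  for (k1 in seq_len(K - 1)) for (k2 in (k1 + 1):K)
    if (sum(abs(beta[, k1] - beta[, k2]) > 1e-12) < 2) return(FALSE)
  TRUE
}

# condition (III): distinct difference vectors across distinct type pairs
.conditionIII <- function(beta) {
  K <- ncol(beta)
  pairs <- utils::combn(K, 2)
  diffs <- apply(pairs, 2, function(p) beta[, p[1]] - beta[, p[2]])
  nrow(unique(t(cbind(diffs, -diffs)))) == 2 * ncol(pairs)
}

#' Generate ground-truth parameters for a design
#'
#' Draws a full parameter set satisfying the model's identifiability
#' constraints: the cell-type effect of type 1 and the batch effect of
#' batch 1 are zero, the size factor of each batch's first cell is zero,
#' all overdispersions are positive and all dropout slopes negative.
#' Exactly \code{config$nDE} genes receive a nonzero cell-type effect, and
#' the draw is repeated until every pair of types differs in at least two
#' genes (condition II) whenever \code{nDE > 0}.
#'
#' @param design a \linkS4class{BatchDesign}.
#' @param config a list from \code{\link{simConfig}}.
#' @param seed integer seed.
#' @param auditIII also check that effect-difference vectors are distinct
#'   across type pairs (condition III; holds almost surely, off by default).
#' @return A \linkS4class{SimTruth} with empty latent data.
#' @export
simulateTruth <- function(design, config = simConfig(), seed = 1L,
                          auditIII = FALSE) {
  stopifnot(is(design, "BatchDesign"))
  if (any(config$gamma1Range >= 0))
    stop("gamma1 must be negative (condition I)")
  B <- nrow(design@presence); K <- ncol(design@presence)
  G <- config$nGenes
  N <- sum(design@nPerBatch)
  set.seed(seed)

  alpha <- rnorm(G, config$alphaMean, config$alphaSD)
  de <- integer(0)
  beta <- matrix(0, G, K)
  if (config$nDE > 0) {
    grid <- sort(c(-config$betaMag, config$betaMag))
    for (try in seq_len(200)) {
      beta <- matrix(0, G, K)
      de <- sort(sample.int(G, config$nDE))
      for (g in de) {
        # one expression level per type on the symmetric grid; the type
        # effect is the level contrast against the baseline type
        repeat {
          lev <- sample(grid, K, replace = TRUE)
          if (length(unique(lev)) > 1) break
        }
        beta[g, ] <- lev - lev[1]
      }
      if (.conditionII(beta) && (!auditIII || .conditionIII(beta))) break
      if (try == 200)
        stop("could not satisfy condition (II); increase nDE")
    }
  }
  nu <- cbind(0, matrix(rnorm(G * (B - 1), 0, config$nuSD), G, B - 1))
  delta <- rnorm(N, 0, config$deltaSD)
  first <- cumsum(c(1, head(design@nPerBatch, -1)))
  batch <- rep(seq_len(B), design@nPerBatch)
  for (b in seq_len(B))  # anchor: first cell of each batch has delta = 0
    delta[batch == b] <- delta[batch == b] - delta[first[b]]
  phi <- matrix(runif(G * B, config$phiRange[1], config$phiRange[2]), G, B)
  gamma0 <- runif(B, config$gamma0Range[1], config$gamma0Range[2])
  gamma1 <- runif(B, config$gamma1Range[1], config$gamma1Range[2])

  params <- list(alpha = alpha, beta = beta, nu = nu, delta = delta,
                 phi = phi, gamma0 = gamma0, gamma1 = gamma1,
                 pi = design@pi)
  new("SimTruth", params = params, latent = list(),
      deGenes = de, design = design)
}

#' Simulate a multi-batch count dataset from ground truth
#'
#' Draws, for each cell, a type from its batch's composition; underlying
#' counts from the negative binomial with mean
#' \code{exp(alpha + beta + nu + delta)}; dropout indicators from the
#' logistic missing-not-at-random mechanism (only where the underlying
#' count is positive); and sets the observed count to zero at dropouts.
#' Bit-reproducible given the seed.
#'
#' @param truth a \linkS4class{SimTruth} from \code{\link{simulateTruth}}.
#' @param seed integer seed.
#' @return list with \code{data} (a \linkS4class{BatchCounts}) and
#'   \code{truth} (the input with latent X, Z, W filled in).
#' @export
simulateData <- function(truth, seed = 1L) {
  stopifnot(is(truth, "SimTruth"))
  p <- truth@params
  design <- truth@design
  B <- nrow(design@presence); K <- ncol(design@presence)
  G <- length(p$alpha)
  nb <- design@nPerBatch
  N <- sum(nb)
  batch <- rep(seq_len(B), nb)
  set.seed(seed)

  W <- integer(N)
  for (b in seq_len(B)) {
    idx <- which(batch == b)
    W[idx] <- sample.int(K, length(idx), replace = TRUE, prob = design@pi[b, ])
  }
  mu <- exp(p$alpha + p$beta[, W, drop = FALSE] + p$nu[, batch, drop = FALSE] +
              rep(p$delta, each = G))
  size <- p$phi[, batch, drop = FALSE]
  X <- matrix(rnbinom(G * N, size = size, mu = mu), G, N)
  storage.mode(X) <- "integer"
  pd <- plogis(rep(p$gamma0[batch], each = G) + rep(p$gamma1[batch], each = G) * X)
  Z <- matrix(0L, G, N)
  pos <- X > 0
  Z[pos] <- as.integer(runif(sum(pos)) < pd[pos])
  Y <- X * (1L - Z)

  data <- BatchCounts(Y, batch = paste0("batch", batch))
  truth@latent <- list(X = X, Z = Z, W = W)
  list(data = data, truth = truth)
}

#' Per-batch zero and dropout rates of a simulated dataset
#'
#' The zero rate is the fraction of observed zeros; the dropout rate is the
#' fraction of true dropout events among the observed zeros (NA for a batch
#' without zeros).
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param truth the matching \linkS4class{SimTruth} with latent data.
#' @return data.frame with one row per batch.
#' @export
datasetZeroStats <- function(data, truth) {
  y <- .countsOf(data)
  Z <- truth@latent$Z
  if (is.null(Z)) stop("truth has no latent data; run simulateData first")
  b <- batchIds(data)
  out <- lapply(seq_len(max(b)), function(bb) {
    yy <- y[, b == bb, drop = FALSE]
    zz <- Z[, b == bb, drop = FALSE]
    nz <- sum(yy == 0)
    data.frame(batch = bb, zeroRate = mean(yy == 0),
               dropoutRate = if (nz) sum(zz[yy == 0]) / nz else NA_real_)
  })
  do.call(rbind, out)
}

setMethod("show", "SimTruth", function(object) {
  d <- object@design
  cat("SimTruth:", length(object@params$alpha), "genes,",
      sum(d@nPerBatch), "cells,", nrow(d@presence), "batches,",
      ncol(d@presence), "types;", length(object@deGenes), "DE genes;",
      if (length(object@latent)) "latent data present" else "parameters only",
      "\n")
})
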