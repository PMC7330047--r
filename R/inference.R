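# Posterior summarization, label alignment, convergence diagnostics, model
# selection, intrinsic-gene detection, dropout reporting and clustering
# evaluation.

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (j in seq_len(n)) {
    block <- cbind(j, sub + (sub >= j))
    out <- rbind(out, block)
  }
  out
}

#' Align two labelings by optimal permutation
#'
#' Returns the permutation of candidate labels that maximizes agreement
#' with the reference, from the K x K co-occurrence matrix (exact
#' enumeration for K <= 8, greedy beyond). Differing label ranges are
#' handled by padding with zero-agreement dummy labels. Used to resolve
#' label switching across chains and against simulation truth.
#'
#' @param reference,candidate integer label vectors of equal length.
#' @param K size of the label space (defaults to the largest label seen);
#'   unused labels act as zero-agreement dummies.
#' @return integer vector \code{rho} with \code{rho[c]} the reference-space
#'   label assigned to candidate label \code{c}; apply as
#'   \code{rho[candidate]}.
#' @examples
#' alignLabels(c(1, 1, 2, 2), c(2, 2, 1, 1))  # swaps back: c(2, 1)
#' @export
alignLabels <- function(reference, candidate, K = max(reference, candidate)) {
  if (length(reference) != length(candidate))
    stop("label vectors must have equal length")
  K <- max(K, reference, candidate)
  C <- matrix(0, K, K)
  for (i in seq_along(reference))
    C[reference[i], candidate[i]] <- C[reference[i], candidate[i]] + 1
  if (K <= 8) {
    perms <- .permutations(as.integer(K))
    scores <- apply(perms, 1, function(s) sum(C[cbind(s, seq_len(K))]))
    rho <- perms[which.max(scores), ]
  } else {
    rho <- integer(K)
    used <- logical(K)
    ord <- order(-apply(C, 2, max))
    for (cc in ord) {
      pick <- order(-C[, cc])
      pick <- pick[!used[pick]][1]
      rho[cc] <- pick
      used[pick] <- TRUE
    }
  }
  as.integer(rho)
}

# Align every chain's draws to chain 1 through the posterior-mode labels,
# re-baselining (alpha, beta) through theta = alpha + beta so the aligned
# draws satisfy beta[, 1] = 0.
.alignChains <- function(chains) {
  ch <- chains@chains
  K <- chains@K
  modeOf <- function(draws) {
    apply(draws, 1, function(v) which.max(tabulate(v + 1L, K)))
  }
  ref <- modeOf(ch[[1]]$W)
  lapply(ch, function(cn) {
    T <- cn$nStored
    G <- dim(cn$beta)[1]; B <- dim(cn$nu)[2]
    # theta[, k, t] = alpha[, t] + beta[, k, t]
    theta <- cn$beta
    for (k in seq_len(K)) theta[, k, ] <- theta[, k, ] + cn$alpha
    rho <- alignLabels(ref, modeOf(cn$W), K = K)
    thetaA <- theta; piA <- cn$pi; LA <- cn$L
    WA <- matrix(rho[cn$W + 1L], nrow(cn$W), ncol(cn$W))
    for (k in seq_len(K)) {
      thetaA[, rho[k], ] <- theta[, k, ]
      piA[, rho[k], ] <- cn$pi[, k, ]
      LA[, rho[k], ] <- cn$L[, k, ]
    }
    alphaA <- thetaA[, 1, , drop = FALSE]
    dim(alphaA) <- c(G, T)
    betaA <- thetaA
    for (k in seq_len(K)) betaA[, k, ] <- betaA[, k, ] - alphaA
    list(theta = thetaA, alpha = alphaA, beta = betaA, nu = cn$nu,
         delta = cn$delta, phi = cn$phi, gamma0 = cn$gamma0,
         gamma1 = cn$gamma1, pi = piA, W = WA, L = LA, p = cn$p,
         tau0sq = cn$tau0sq, sumXZ1 = cn$sumXZ1, cntZ1 = cn$cntZ1,
         nStored = T)
  })
}

#' Summarize the posterior draws
#'
#' Continuous parameters are estimated by their posterior means (pooled
#' across chains after label alignment); the cell type of each cell by the
#' posterior mode of its label draws; the underlying count of each observed
#' zero by the rounded posterior mean of its imputed draws, at entries where
#' the posterior dropout probability exceeds one half. \code{xi} holds the
#' per-(gene, type) posterior probabilities of no differential expression,
#' from which intrinsic genes are called at the default 5 percent Bayesian
#' FDR (rerun \code{\link{intrinsicGenes}} for other levels).
#'
#' @param chains a \linkS4class{MixChains}.
#' @param fdrLevel Bayesian FDR level for the default intrinsic-gene call.
#' @return A \linkS4class{MixFit}.
#' @export
summarizePosterior <- function(chains, fdrLevel = 0.05) {
  stopifnot(is(chains, "MixChains"))
  al <- .alignChains(chains)
  if (al[[1]]$nStored < 1) stop("no retained draws")
  K <- chains@K
  G <- nrow(chains@counts); N <- ncol(chains@counts)
  Ttot <- sum(vapply(al, function(a) a$nStored, numeric(1)))

  meanOver <- function(name, dims) {
    acc <- 0
    for (a in al) {
      x <- a[[name]]
      nd <- length(dim(x))
      acc <- acc + apply(x, seq_len(nd - 1), sum)
    }
    acc / Ttot
  }
  thetaBar <- meanOver("theta")
  alpha <- thetaBar[, 1]
  beta <- thetaBar - alpha
  nu <- meanOver("nu")
  delta <- as.numeric(meanOver("delta"))
  phi <- meanOver("phi")
  gamma0 <- as.numeric(meanOver("gamma0"))
  gamma1 <- as.numeric(meanOver("gamma1"))
  pi <- meanOver("pi")

  Wall <- do.call(cbind, lapply(al, function(a) a$W))
  wHat <- apply(Wall, 1, function(v) which.max(tabulate(v, K)))

  Lbar <- meanOver("L")
  xi <- 1 - Lbar[, -1, drop = FALSE]
  if (K >= 2) colnames(xi) <- paste0("k", 2:K)

  sumXZ1 <- Reduce(`+`, lapply(al, function(a) a$sumXZ1))
  cntZ1 <- Reduce(`+`, lapply(al, function(a) a$cntZ1))
  pDrop <- cntZ1 / Ttot
  y <- chains@counts
  xHat <- y
  called <- y == 0 & pDrop > 0.5
  xHat[called] <- pmax(1, round(sumXZ1[called] / cntZ1[called]))
  storage.mode(xHat) <- "integer"

  det <- intrinsicGenes(xi, alpha = fdrLevel)
  new("MixFit",
      thetaHat = list(alpha = alpha, beta = beta, nu = nu, delta = delta,
                      phi = phi, gamma0 = gamma0, gamma1 = gamma1, pi = pi),
      wHat = as.integer(wHat), xHat = xHat, pDrop = pDrop, xi = xi,
      kappa0 = det$kappa0, intrinsic = det$genes, calls = det$calls,
      bic = NA_real_, logLik = NA_real_, K = chains@K,
      batch = chains@batch)
}

setMethod("show", "MixFit", function(object) {
  cat("MixFit: K =", object@K, ";", length(object@intrinsic),
      "intrinsic genes (kappa0 =",
      if (is.na(object@kappa0)) "none" else format(object@kappa0, digits = 3),
      ")\n")
  cat("  cluster sizes:", paste(tabulate(object@wHat, object@K),
                                collapse = ", "), "\n")
  if (!is.na(object@bic)) cat("  BIC:", format(object@bic), "\n")
})

#' Potential scale reduction convergence diagnostic
#'
#' Computes, per scalar, the classic potential scale reduction factor
#' \eqn{\hat R = \sqrt{(\frac{n-1}{n} W + \frac{B}{n}) / W}} from the
#' between- and within-chain variances of the retained draws, for the three
#' monitored groups: the log-scale type-specific expression levels
#' \eqn{\theta_{gk} = \alpha_g + \beta_{gk}} (computed after label
#' alignment), the batch effects \eqn{\nu_{bg}} (batches 2..B), and the
#' overdispersions \eqn{\phi_{bg}}. The chain is declared converged when
#' more than 80 percent of each group is below 1.3.
#'
#' @param chains a \linkS4class{MixChains} with at least two chains.
#' @param threshold,fracNeeded the rule's constants (1.3 and 0.8).
#' @return list with per-group EPSR vectors, fractions below the threshold,
#'   and a \code{converged} flag.
#' @export
computeEPSR <- function(chains, threshold = 1.3, fracNeeded = 0.8) {
  stopifnot(is(chains, "MixChains"))
  if (length(chains@chains) < 2)
    stop("the potential scale reduction diagnostic requires >= 2 chains")
  al <- .alignChains(chains)
  B <- max(chains@batch)
  flat <- function(name, keep = NULL) {
    lapply(al, function(a) {
      x <- a[[name]]
      d <- dim(x)
      T <- d[length(d)]
      m <- matrix(x, ncol = T)
      if (!is.null(keep)) m <- m[keep, , drop = FALSE]
      m
    })
  }
  groups <- list(theta = flat("theta"))
  if (B >= 2) {
    G <- nrow(chains@counts)
    keepNu <- as.vector(outer(seq_len(G), 2:B - 1, function(g, b) g + G * b))
    groups$nu <- flat("nu", keepNu)
  } else groups$nu <- NULL
  groups$phi <- flat("phi")
  groups <- groups[!vapply(groups, is.null, logical(1))]

  epsr <- lapply(groups, function(ms) .rhat(ms))
  frac <- vapply(epsr, function(r) mean(r < threshold, na.rm = TRUE), numeric(1))
  list(epsr = epsr, fracBelow = frac,
       converged = all(frac > fracNeeded))
}

# ms: list (chains) of scalar x T matrices
.rhat <- function(ms) {
  T <- ncol(ms[[1]])
  M <- length(ms)
  means <- vapply(ms, rowMeans, numeric(nrow(ms[[1]])))
  vars <- vapply(ms, function(m) apply(m, 1, var), numeric(nrow(ms[[1]])))
  means <- matrix(means, ncol = M); vars <- matrix(vars, ncol = M)
  W <- rowMeans(vars)
  Bv <- T * apply(means, 1, var)
  out <- sqrt(((T - 1) / T * W + Bv / T) / W)
  out[W == 0 & Bv == 0] <- 1
  out[W == 0 & Bv > 0] <- Inf
  out
}

#' Bayesian information criterion of a fit
#'
#' \code{-2 * observed log-likelihood at the posterior means} plus
#' \code{[K(B+G) + 2B + (2B-1)G + sum_b (n_b - 1)] * log(sum_b n_b G)}:
#' the bracketed term counts the free parameters (compositions and
#' type effects per K; dropout pairs; baselines, batch effects and
#' overdispersions per gene; anchored size factors).
#'
#' @param data the \linkS4class{BatchCounts} the fit was run on.
#' @param fit a \linkS4class{MixFit}.
#' @param variant likelihood variant, matching the fit.
#' @return the BIC value (also stored in the returned fit by
#'   \code{\link{selectK}}).
#' @export
computeBIC <- function(data, fit, variant = c("full", "nzf")) {
  variant <- match.arg(variant)
  stopifnot(is(fit, "MixFit"))
  y <- .countsOf(data)
  nb <- batchSizes(data)
  G <- nrow(y); B <- length(nb); K <- fit@K
  ll <- observedLogLik(data, fit, variant = variant)
  pen <- bicPenaltyCount(G, B, K, nb) * log(sum(nb) * G)
  -2 * ll + pen
}

#' Free-parameter count of the BIC penalty
#' @param G,B,K dimensions; @param nb per-batch sizes.
#' @export
bicPenaltyCount <- function(G, B, K, nb) {
  K * (B + G) + 2 * B + (2 * B - 1) * G + sum(nb - 1)
}

#' Select the number of cell types by BIC
#'
#' Fits the model for each candidate K and returns the K minimizing BIC
#' together with the full table. Fits that fail the convergence rule (when
#' run with >= 2 chains) are flagged in the table, not dropped.
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param Ks integer vector of candidate K values.
#' @param ...,hyper,nIter,burnin,thin,nChains,seed,variant passed to
#'   \code{\link{fitBatchMix}}.
#' @return list with \code{K} (the argmin), \code{table} (data.frame) and
#'   \code{fits} (the per-K \linkS4class{MixFit} objects).
#' @export
selectK <- function(data, Ks, hyper = mixHyper(), nIter = 2000,
                    burnin = 1000, thin = 1, nChains = 1, seed = 1,
                    variant = c("full", "nzf")) {
  variant <- match.arg(variant)
  if (!length(Ks)) stop("Ks must be non-empty")
  rows <- list(); fits <- list()
  for (j in seq_along(Ks)) {
    K <- Ks[j]
    ch <- fitBatchMix(data, K, hyper = hyper, nIter = nIter, burnin = burnin,
                      thin = thin, nChains = nChains, seed = seed,
                      variant = variant)
    fit <- summarizePosterior(ch)
    conv <- if (nChains >= 2) computeEPSR(ch)$converged else NA
    fit@logLik <- observedLogLik(data, fit, variant = variant)
    fit@bic <- -2 * fit@logLik +
      bicPenaltyCount(nrow(data), max(ch@batch), K, batchSizes(data)) *
      log(sum(batchSizes(data)) * nrow(data))
    rows[[j]] <- data.frame(K = K, logLik = fit@logLik, bic = fit@bic,
                            converged = conv)
    fits[[j]] <- fit
  }
  tab <- do.call(rbind, rows)
  list(K = Ks[which.min(tab$bic)], table = tab, fits = fits)
}

#' Detect intrinsic genes under Bayesian FDR control
#'
#' Searches for the largest threshold \code{kappa0 <= 0.5} such that the
#' estimated FDR — the mean of the posterior null probabilities among
#' entries at or below the threshold — is smaller than \code{alpha};
#' candidate thresholds are the observed \code{xi} values not exceeding
#' 0.5. A (gene, type) pair is called differentially expressed when
#' \code{xi <= kappa0}; intrinsic genes are genes with at least one call.
#'
#' @param xi G x (K-1) matrix of posterior null probabilities, or a
#'   \linkS4class{MixFit}.
#' @param alpha FDR control level in (0, 1).
#' @return list with \code{genes}, \code{kappa0} (NA if no threshold
#'   qualifies), \code{calls} (logical matrix) and \code{fdrHat} at kappa0.
#' @export
intrinsicGenes <- function(xi, alpha = 0.05) {
  if (is(xi, "MixFit")) xi <- xi@xi
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  if (any(xi < 0 | xi > 1)) stop("xi entries must lie in [0, 1]")
  xi <- as.matrix(xi)
  v <- sort(as.numeric(xi))
  cum <- cumsum(v) / seq_along(v)
  cand <- which(v <= 0.5)
  if (length(cand)) {
    # last occurrence of each distinct candidate value
    last <- cand[c(diff(v[cand]) > 0, TRUE)]
    ok <- last[cum[last] < alpha]
  } else ok <- integer(0)
  if (!length(ok)) {
    return(list(genes = integer(0), kappa0 = NA_real_,
                calls = matrix(FALSE, nrow(xi), ncol(xi)), fdrHat = NA_real_))
  }
  i0 <- max(ok)
  kappa0 <- v[i0]
  calls <- xi <= kappa0
  list(genes = which(rowSums(calls) > 0), kappa0 = kappa0, calls = calls,
       fdrHat = cum[i0])
}

#' Zero-rate, dropout-rate and posterior-predictive report
#'
#' Per batch: the observed zero rate; the inferred dropout rate, i.e. the
#' proportion of observed zeros whose imputed underlying count is positive
#' (NA where a batch has no zeros); and the posterior-predictive mean zero
#' rate, from replicate datasets simulated from retained parameter draws.
#'
#' @param data a \linkS4class{BatchCounts}.
#' @param fit the matching \linkS4class{MixFit}.
#' @param chains the \linkS4class{MixChains} behind the fit.
#' @param ppcDraws number of (evenly strided) retained draws to use for the
#'   replicate simulations.
#' @param seed seed for the replicate simulations.
#' @return data.frame with one row per batch.
#' @export
dropoutReport <- function(data, fit, chains, ppcDraws = 100, seed = 1) {
  y <- .countsOf(data)
  b <- batchIds(data)
  B <- max(b)
  G <- nrow(y)
  rho0 <- vapply(seq_len(B), function(bb) mean(y[, b == bb] == 0), numeric(1))
  rhod <- vapply(seq_len(B), function(bb) {
    yy <- y[, b == bb, drop = FALSE]
    xx <- fit@xHat[, b == bb, drop = FALSE]
    nz <- sum(yy == 0)
    if (nz == 0) return(NA_real_)
    sum(yy == 0 & xx > 0) / nz
  }, numeric(1))

  al <- .alignChains(chains)
  K <- chains@K
  picks <- do.call(rbind, lapply(seq_along(al), function(cc) {
    T <- al[[cc]]$nStored
    idx <- unique(round(seq(1, T, length.out = min(ppcDraws, T))))
    cbind(cc, idx)
  }))
  set.seed(seed)
  N <- ncol(y)
  zr <- matrix(0, nrow(picks), B)
  for (r in seq_len(nrow(picks))) {
    a <- al[[picks[r, 1]]]
    t <- picks[r, 2]
    piD <- matrix(a$pi[, , t], B, K)
    W <- integer(N)
    for (bb in seq_len(B)) {
      idx <- which(b == bb)
      W[idx] <- sample.int(K, length(idx), replace = TRUE, prob = piD[bb, ])
    }
    th <- matrix(a$theta[, , t], G, K)
    mu <- exp(th[, W] + a$nu[, b, t] + rep(a$delta[, t], each = G))
    size <- a$phi[, b, t]
    X <- matrix(rnbinom(G * N, size = size, mu = mu), G, N)
    if (chains@variant == "full") {
      pd <- plogis(rep(a$gamma0[b, t], each = G) +
                     rep(a$gamma1[b, t], each = G) * X)
      drop <- X > 0 & runif(G * N) < pd
      X[drop] <- 0L
    }
    zr[r, ] <- vapply(seq_len(B), function(bb) mean(X[, b == bb] == 0),
                      numeric(1))
  }
  data.frame(batch = seq_len(B), zeroRate = rho0, dropoutRate = rhod,
             ppcZeroRate = colMeans(zr))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions, from the contingency
#' table under the permutation model. Invariant to label renaming; the two
#' partitions may have different numbers of clusters.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sumnij <- sum(ch2(tab))
  ai <- sum(ch2(rowSums(tab)))
  bj <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- ai * bj / ch2(n)
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (sumnij - expected) / (maxidx - expected)
}
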