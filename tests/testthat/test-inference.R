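# Posterior summarization, diagnostics, model selection, intrinsic-gene
# detection, dropout reporting and clustering agreement.

test_that("label alignment recovers permutations and maximizes agreement", {
  expect_equal(alignLabels(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1:2)
  expect_equal(alignLabels(c(1, 1, 2, 2), c(2, 2, 1, 1)), c(2L, 1L))
  ref <- c(rep(1, 6), rep(2, 4), rep(3, 5))
  cand <- c(rep(1, 5), 3, rep(2, 4), 1, 1, rep(3, 3))
  # co-occurrence matrix [[5,0,1],[0,4,0],[2,0,3]]: identity wins with 12/15
  rho <- alignLabels(ref, cand)
  expect_equal(rho, 1:3)
  expect_equal(mean(ref == rho[cand]), 12 / 15)
  # all 6 permutations do no better
  perms <- scBatchMix:::.permutations(3L)
  scores <- apply(perms, 1, function(s) mean(ref == s[cand]))
  expect_equal(max(scores), 12 / 15)
  # differing label counts are padded
  rho2 <- alignLabels(c(1, 2, 3, 3), c(1, 1, 2, 2))
  expect_length(rho2, 3)
  expect_error(alignLabels(1:3, 1:4), "equal length")
})

test_that("posterior summaries reduce to the draw for a constant chain", {
  G <- 4; N <- 5; K <- 2; T <- 6
  y <- matrix(rpois(G * N, 3), G, N)
  alpha <- matrix(rnorm(G), G, T)
  beta <- array(0, c(G, K, T)); beta[, 2, ] <- 1.3
  W <- matrix(rep(c(0L, 1L, 0L, 1L, 0L), T), N, T)
  ch <- fakeChains(y, rep(1, N), K, list(list(alpha = alpha, beta = beta,
                                              W = W)))
  fit <- summarizePosterior(ch)
  expect_equal(fit@thetaHat$alpha, alpha[, 1])
  expect_equal(fit@thetaHat$beta[, 2], rep(1.3, G))
  expect_equal(fit@wHat, c(1L, 2L, 1L, 2L, 1L))
  expect_identical(unname(fit@xHat), unname(y))
})

test_that("xi and the cell-type mode follow their defining formulas", {
  G <- 2; N <- 3; K <- 2; T <- 4
  y <- matrix(1L, G, N)
  L <- array(0L, c(G, K, T))
  L[1, 2, ] <- c(1L, 0L, 1L, 1L)           # xi = 1 - 3/4 = 0.25
  W <- matrix(0L, N, T)
  W[2, ] <- c(1L, 1L, 2L, 1L) - 1L         # mode 1 -> label 1? draws (2,2,3,2)
  W[2, ] <- c(2L, 2L, 1L, 2L) - 1L         # draws (2,2,1,2): mode 2
  ch <- fakeChains(y, rep(1, N), K, list(list(alpha = matrix(0, G, T), L = L,
                                              W = W)))
  fit <- summarizePosterior(ch)
  expect_equal(as.numeric(fit@xi[1, 1]), 0.25)
  expect_equal(fit@wHat[2], 2L)
})

test_that("imputed counts change only at called dropout entries", {
  G <- 2; N <- 2; T <- 4
  y <- matrix(c(0L, 3L, 0L, 1L), G, N)
  sumXZ1 <- matrix(0, G, N); cntZ1 <- matrix(0L, G, N)
  sumXZ1[1, 1] <- 3 + 4 + 5; cntZ1[1, 1] <- 3L   # pDrop = 0.75 -> called
  sumXZ1[1, 2] <- 2; cntZ1[1, 2] <- 1L           # pDrop = 0.25 -> not called
  ch <- fakeChains(y, rep(1, N), 1, list(list(alpha = matrix(0, G, T),
                                              sumXZ1 = sumXZ1,
                                              cntZ1 = cntZ1)))
  fit <- summarizePosterior(ch)
  expect_equal(fit@xHat[1, 1], 4L)   # round(12 / 3)
  expect_equal(fit@xHat[1, 2], 0L)   # below the 0.5 posterior call
  expect_equal(fit@xHat[2, ], c(3L, 1L))
  expect_true(all(fit@xHat[y == 0 & fit@pDrop > 0.5] >= y[y == 0 & fit@pDrop > 0.5]))
})

test_that("the potential scale reduction factor matches hand computation", {
  # chains (1,2,3,4) and (5,6,7,8): W = 5/3, B = 32, Rhat = 2.355844
  ms <- list(matrix(1:4, 1, 4), matrix(5:8, 1, 4))
  expect_equal(scBatchMix:::.rhat(ms),
               sqrt((0.75 * 5 / 3 + 8) / (5 / 3)), tolerance = 1e-12)
  # identical chains: zero between-chain variance
  ms2 <- list(matrix(1:4, 1, 4), matrix(1:4, 1, 4))
  expect_equal(scBatchMix:::.rhat(ms2), sqrt(3 / 4), tolerance = 1e-12)
  # chains from the same distribution: Rhat close to 1
  set.seed(1)
  ms3 <- list(matrix(rnorm(5 * 2000), 5, 2000),
              matrix(rnorm(5 * 2000), 5, 2000))
  expect_true(all(abs(scBatchMix:::.rhat(ms3) - 1) < 0.05))
})

test_that("the convergence report applies the 80 percent rule", {
  G <- 6; N <- 4; K <- 2; T <- 50
  y <- matrix(rpois(G * N, 3), G, N)
  set.seed(2)
  mk <- function(shift = 0) list(alpha = matrix(rnorm(G * T) + shift, G, T),
                                 nu = array(rnorm(G * 2 * T), c(G, 2, T)),
                                 phi = array(abs(rnorm(G * 2 * T)) + 1,
                                             c(G, 2, T)))
  ch <- fakeChains(y, rep(1:2, each = 2), K, list(mk(), mk()))
  ep <- computeEPSR(ch)
  expect_true(all(names(ep$fracBelow) %in% c("theta", "nu", "phi")))
  expect_true(ep$converged)
  # a wildly shifted second chain breaks convergence
  ch2 <- fakeChains(y, rep(1:2, each = 2), K, list(mk(), mk(shift = 50)))
  expect_false(computeEPSR(ch2)$converged)
  expect_error(computeEPSR(fakeChains(y, rep(1:2, each = 2), K, list(mk()))),
               "2 chains")
})

test_that("summaries are invariant to a global relabeling of all chains", {
  sim <- quickSim(G = 40, nDE = 10, nPerBatch = c(25, 25))
  ch <- fitBatchMix(sim$data, K = 3, nIter = 120, burnin = 60, seed = 4)
  fit1 <- summarizePosterior(ch)
  # relabel every draw of the single chain by a fixed permutation
  perm <- c(3L, 1L, 2L)      # old label k becomes perm[k]
  cn <- ch@chains[[1]]
  inv <- order(perm)
  cn$beta <- cn$beta[, inv, , drop = FALSE]
  cn$pi <- cn$pi[, inv, , drop = FALSE]
  cn$L <- cn$L[, inv, , drop = FALSE]
  cn$W <- matrix(perm[cn$W + 1L] - 1L, nrow(cn$W), ncol(cn$W))
  # re-baseline so beta[, 1] = 0 in the relabeled chain
  th <- cn$beta
  for (k in 1:3) th[, k, ] <- th[, k, ] + cn$alpha
  cn$alpha <- matrix(th[, 1, ], dim(th)[1])
  for (k in 1:3) cn$beta[, k, ] <- th[, k, ] - cn$alpha
  ch2 <- ch; ch2@chains <- list(cn)
  fit2 <- summarizePosterior(ch2)
  expect_equal(adjustedRandIndex(fit1@wHat, fit2@wHat), 1)
  th1 <- fit1@thetaHat$alpha + fit1@thetaHat$beta
  th2 <- fit2@thetaHat$alpha + fit2@thetaHat$beta
  rho <- alignLabels(fit1@wHat, fit2@wHat)
  expect_equal(th1, th2[, order(rho)], tolerance = 1e-10)
})

test_that("the BIC penalty counts free parameters as specified", {
  expect_equal(bicPenaltyCount(3000, 4, 5, c(300, 300, 200, 200)), 37024)
  expect_equal(log(sum(c(300, 300, 200, 200)) * 3000), log(3e6))
  # equal log likelihoods differ by exactly the per-K penalty step
  G <- 120; B <- 3; nb <- c(20, 20, 20)
  d1 <- bicPenaltyCount(G, B, 4, nb) - bicPenaltyCount(G, B, 2, nb)
  expect_equal(d1, (4 - 2) * (B + G))
})

test_that("BIC combines the observed likelihood and the penalty", {
  sim <- quickSim(G = 25, nDE = 6, nPerBatch = c(15, 15))
  ch <- fitBatchMix(sim$data, K = 2, nIter = 80, burnin = 40, seed = 2)
  fit <- summarizePosterior(ch)
  bic <- computeBIC(sim$data, fit)
  ll <- observedLogLik(sim$data, fit)
  expect_equal(bic, -2 * ll + bicPenaltyCount(25, 2, 2, c(15, 15)) *
                 log(30 * 25), tolerance = 1e-8)
})

test_that("selectK returns a full table and the argmin", {
  sim <- quickSim(G = 30, nDE = 10, nPerBatch = c(20, 20), K = 2)
  res <- selectK(sim$data, Ks = c(2, 3), nIter = 100, burnin = 50, seed = 3)
  expect_equal(nrow(res$table), 2)
  expect_true(res$K %in% c(2, 3))
  expect_equal(res$table$K[which.min(res$table$bic)], res$K)
  res1 <- selectK(sim$data, Ks = 2, nIter = 100, burnin = 50, seed = 3)
  expect_equal(res1$K, 2)
  expect_error(selectK(sim$data, Ks = integer(0)))
})

test_that("the kappa0 search controls the estimated Bayesian FDR", {
  # candidates {0.01, 0.2, 0.4}: FDR(0.2) = 0.105 > 0.05, so kappa0 = 0.01
  res <- intrinsicGenes(matrix(c(0.01, 0.2, 0.4, 0.6), 4, 1), alpha = 0.05)
  expect_equal(res$kappa0, 0.01)
  expect_equal(res$genes, 1L)
  expect_equal(res$fdrHat, 0.01)
  # all xi = 0: everything called at zero estimated FDR
  res2 <- intrinsicGenes(matrix(0, 5, 2), alpha = 0.05)
  expect_equal(res2$genes, 1:5)
  expect_equal(res2$fdrHat, 0)
  # all xi above 0.5: the cap leaves nothing to call
  res3 <- intrinsicGenes(matrix(0.8, 5, 2), alpha = 0.2)
  expect_length(res3$genes, 0)
  expect_true(is.na(res3$kappa0))
  expect_error(intrinsicGenes(matrix(0.1, 2, 2), alpha = 1.2))
})

test_that("the kappa0 rule controls realized FDR on calibrated posteriors", {
  # xi drawn so that Pr(null | xi) = xi exactly; the realized false
  # discovery proportion at level 0.05 should then average below ~0.05
  set.seed(42)
  fdps <- replicate(40, {
    xi <- rbeta(800, 0.3, 1)
    isNull <- runif(800) < xi
    res <- intrinsicGenes(matrix(xi, ncol = 1), alpha = 0.05)
    called <- res$calls[, 1]
    if (any(called)) sum(isNull & called) / sum(called) else 0
  })
  expect_lt(mean(fdps), 0.05 + 2 * sd(fdps) / sqrt(40))
})

test_that("dropout reporting counts zeros, dropout calls and PPC zeros", {
  # 3 genes x 2 cells with zeros at 4 entries and dropout calls at 2
  y <- matrix(c(0L, 1L, 0L, 2L, 0L, 0L), 3, 2)
  T <- 60
  sumXZ1 <- matrix(0, 3, 2); cntZ1 <- matrix(0L, 3, 2)
  sumXZ1[1, 1] <- 5 * T; cntZ1[1, 1] <- T       # called dropout
  sumXZ1[3, 2] <- 2 * T; cntZ1[3, 2] <- T       # called dropout
  alpha <- matrix(1, 3, T)
  ch <- fakeChains(y, rep(1, 2), 1, list(list(alpha = alpha, sumXZ1 = sumXZ1,
                                              cntZ1 = cntZ1)))
  fit <- summarizePosterior(ch)
  rep <- dropoutReport(y2bc(y), fit, ch, ppcDraws = 60, seed = 9)
  expect_equal(rep$zeroRate, 4 / 6)
  expect_equal(rep$dropoutRate, 0.5)
  # constant draws: the PPC zero rate concentrates near its analytic value
  mu <- exp(1); phi <- 4; g0 <- 0; g1 <- -0.1
  pz <- exp(zeroObsLogProb(mu, phi, g0, g1))
  expect_lt(abs(rep$ppcZeroRate - pz), 0.06)
})

test_that("dropout-free fits report near-zero dropout rates", {
  d <- buildDesign("complete", B = 2, K = 2, nPerBatch = c(25, 25))
  tr <- simulateTruth(d, simConfig(nGenes = 40, nDE = 10,
                                   gamma0Range = c(-1e6, -1e6)), seed = 3)
  sim <- simulateData(tr, seed = 4)
  ch <- fitBatchMix(sim$data, K = 2, nIter = 150, burnin = 75, seed = 1)
  fit <- summarizePosterior(ch)
  rep <- dropoutReport(sim$data, fit, ch, ppcDraws = 10, seed = 1)
  expect_true(all(rep$dropoutRate < 0.1, na.rm = TRUE))
})

test_that("the adjusted Rand index follows the contingency-table formula", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # index = 1, expected = 1, max = 2.5 -> ARI = 0
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)
  a <- sample(1:3, 30, replace = TRUE)
  expect_equal(adjustedRandIndex(a, c(3, 1, 2)[a]), 1)  # relabel invariance
  # differing cluster counts are allowed
  expect_true(is.finite(adjustedRandIndex(rep(1:2, 10), rep(1:4, 5))))
  expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
  # independent cross-check against an established implementation
  set.seed(7)
  for (r in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
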