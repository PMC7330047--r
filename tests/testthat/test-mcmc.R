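# The Metropolis-within-Gibbs sampler: initialization, exactness of the
# full-conditional evaluators, conjugate updates, state consistency,
# determinism and stationarity.

test_that("initialization honors the identifiability constraints and seed", {
  sim <- quickSim(G = 60, nDE = 15)
  set.seed(11)
  init <- initializeChain(sim$data, 3)
  expect_equal(init$beta[, 1], rep(0, 60))
  expect_equal(init$nu[, 1], rep(0, 60))
  b <- batchIds(sim$data)
  first <- vapply(1:2, function(bb) which(b == bb)[1], integer(1))
  expect_equal(unname(init$delta[first]), rep(0, 2))
  expect_true(all(init$phi >= 0.1))
  expect_true(all(init$gamma1 < 0))
  expect_true(all(abs(rowSums(init$pi) - 1) < 1e-12))
  # Z=1 only at observed zeros, with X shifted positive
  y <- assay(sim$data, "counts")
  expect_true(all(y[init$Z == 1] == 0))
  expect_true(all(init$X[init$Z == 1] >= 1))
  expect_true(all(init$X[init$Z == 0] == y[init$Z == 0]))
  set.seed(11)
  init2 <- initializeChain(sim$data, 3)
  expect_identical(init, init2)
  # informative start on well-separated data
  expect_gt(adjustedRandIndex(init$W, sim$truth@latent$W), 0)
})

test_that("degenerate k-means initialization signals an error", {
  y <- matrix(rpois(12, 5), 3, 4)
  bc <- BatchCounts(y, batch = rep(1, 4))
  set.seed(1)
  expect_error(initializeChain(bc, 10), "k-means|cluster")
})

test_that("full-conditional evaluators match brute-force density ratios", {
  st <- makeTinyState(G = 3, N = 4, B = 2, K = 2, seed = 5)
  st$L[2, 2] <- 1L
  p <- st$pars
  hyper <- mixHyper()
  tau0sq <- 0.02
  cl <- function(block, i1, i2, value)
    scBatchMix:::cpp_block_logcond(block, i1, i2, value, st$X, st$Z,
                                   st$batch - 1L, st$W - 1L, p$alpha, p$beta,
                                   p$nu, p$delta, p$phi, p$gamma0, p$gamma1,
                                   st$L, 0.3, tau0sq, hyper)
  # alpha_g: likelihood over all cells + normal prior
  g <- 2
  likA <- function(a) sum(vapply(1:4, function(i) {
    mu <- exp(a + p$beta[g, st$W[i]] + p$nu[g, st$batch[i]] + p$delta[i])
    dnbinom(st$X[g, i], size = p$phi[g, st$batch[i]], mu = mu, log = TRUE)
  }, numeric(1)))
  a1 <- p$alpha[g]; a2 <- a1 + 0.37
  rCpp <- cl("alpha", g, 0, a2) - cl("alpha", g, 0, a1)
  rR <- (likA(a2) + dnorm(a2, hyper$m_a, sqrt(hyper$sigma_a_sq), log = TRUE)) -
        (likA(a1) + dnorm(a1, hyper$m_a, sqrt(hyper$sigma_a_sq), log = TRUE))
  expect_equal(rCpp, rR, tolerance = 1e-10)

  # beta_gk under spike (L=0) and slab (L=1) priors
  for (gk in list(c(1, 2, 0), c(2, 2, 1))) {
    g <- gk[1]; k <- gk[2]
    tau2 <- if (gk[3] == 1) hyper$tau_beta1_sq else tau0sq
    likB <- function(bb) sum(vapply(which(st$W == k), function(i) {
      mu <- exp(p$alpha[g] + bb + p$nu[g, st$batch[i]] + p$delta[i])
      dnbinom(st$X[g, i], size = p$phi[g, st$batch[i]], mu = mu, log = TRUE)
    }, numeric(1)))
    b1 <- p$beta[g, k]; b2 <- b1 - 0.52
    rCpp <- cl("beta", g, k, b2) - cl("beta", g, k, b1)
    rR <- (likB(b2) + dnorm(b2, 0, sqrt(tau2), log = TRUE)) -
          (likB(b1) + dnorm(b1, 0, sqrt(tau2), log = TRUE))
    expect_equal(rCpp, rR, tolerance = 1e-10)
  }

  # nu_bg
  g <- 3; bb <- 2
  likN <- function(nn) sum(vapply(which(st$batch == bb), function(i) {
    mu <- exp(p$alpha[g] + p$beta[g, st$W[i]] + nn + p$delta[i])
    dnbinom(st$X[g, i], size = p$phi[g, bb], mu = mu, log = TRUE)
  }, numeric(1)))
  n1 <- p$nu[g, bb]; n2 <- n1 + 0.41
  rCpp <- cl("nu", bb, g, n2) - cl("nu", bb, g, n1)
  rR <- (likN(n2) + dnorm(n2, hyper$m_c, sqrt(hyper$sigma_c_sq), log = TRUE)) -
        (likN(n1) + dnorm(n1, hyper$m_c, sqrt(hyper$sigma_c_sq), log = TRUE))
  expect_equal(rCpp, rR, tolerance = 1e-10)

  # delta_bi
  i <- 4
  likD <- function(dd) sum(dnbinom(st$X[, i], size = p$phi[, st$batch[i]],
    mu = exp(p$alpha + p$beta[, st$W[i]] + p$nu[, st$batch[i]] + dd),
    log = TRUE))
  d1 <- p$delta[i]; d2 <- d1 - 0.3
  rCpp <- cl("delta", i, 0, d2) - cl("delta", i, 0, d1)
  rR <- (likD(d2) + dnorm(d2, hyper$m_d, sqrt(hyper$sigma_d_sq), log = TRUE)) -
        (likD(d1) + dnorm(d1, hyper$m_d, sqrt(hyper$sigma_d_sq), log = TRUE))
  expect_equal(rCpp, rR, tolerance = 1e-10)

  # phi_bg with gamma prior
  g <- 1; bb <- 1
  likP <- function(ph) sum(vapply(which(st$batch == bb), function(i) {
    mu <- exp(p$alpha[g] + p$beta[g, st$W[i]] + p$nu[g, bb] + p$delta[i])
    dnbinom(st$X[g, i], size = ph, mu = mu, log = TRUE)
  }, numeric(1)))
  p1 <- p$phi[g, bb]; p2 <- p1 * 1.4
  rCpp <- cl("phi", bb, g, p2) - cl("phi", bb, g, p1)
  rR <- (likP(p2) + dgamma(p2, hyper$kappa_phi, rate = hyper$tau_phi, log = TRUE)) -
        (likP(p1) + dgamma(p1, hyper$kappa_phi, rate = hyper$tau_phi, log = TRUE))
  expect_equal(rCpp, rR, tolerance = 1e-10)

  # gamma_b: logistic regression of Z on X restricted to X > 0
  bb <- 2
  likG <- function(g0, g1) {
    s <- 0
    for (i in which(st$batch == bb)) for (g in 1:st$G) {
      x <- st$X[g, i]
      if (x > 0) {
        t <- g0 + g1 * x
        s <- s + ifelse(st$Z[g, i] == 1, plogis(t, log.p = TRUE),
                        plogis(-t, log.p = TRUE))
      }
    }
    s
  }
  v1 <- c(p$gamma0[bb], p$gamma1[bb]); v2 <- v1 + c(0.2, -0.05)
  rCpp <- cl("gamma", bb, 0, v2) - cl("gamma", bb, 0, v1)
  priorG <- function(v) dnorm(v[1], 0, sqrt(hyper$sigma_z0_sq), log = TRUE) +
    dgamma(-v[2], hyper$a_gamma, rate = hyper$b_gamma, log = TRUE)
  rR <- (likG(v2[1], v2[2]) + priorG(v2)) - (likG(v1[1], v1[2]) + priorG(v1))
  expect_equal(rCpp, rR, tolerance = 1e-10)
  expect_equal(cl("gamma", bb, 0, c(0, 0.1)), -Inf)
})

test_that("the joint (L, beta) flip acceptance matches its closed form", {
  st <- makeTinyState(G = 3, N = 6, B = 2, K = 2, seed = 8)
  p <- st$pars
  pSlab <- 0.3
  for (Lcur in 0:1) {
    st$L[1, 2] <- Lcur
    bNew <- 0.9
    got <- scBatchMix:::cpp_flip_logaccept(1L, 2L, bNew, st$X, st$batch - 1L,
                                           st$W - 1L, p$alpha, p$beta, p$nu,
                                           p$delta, p$phi, st$L, pSlab)
    lik <- function(bb) sum(vapply(which(st$W == 2), function(i) {
      mu <- exp(p$alpha[1] + bb + p$nu[1, st$batch[i]] + p$delta[i])
      dnbinom(st$X[1, i], size = p$phi[1, st$batch[i]], mu = mu, log = TRUE)
    }, numeric(1)))
    lodds <- log(pSlab) - log(1 - pSlab)
    want <- lik(bNew) - lik(p$beta[1, 2]) + ifelse(Lcur == 0, lodds, -lodds)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("the composition update is the conjugate Dirichlet", {
  # one batch, W frozen at counts (3, 1), xi = 1: pi ~ Dirichlet(4, 2),
  # mean (2/3, 1/3), var p1 = 8 / (36 * 7)
  y <- matrix(rpois(20, 4), 5, 4)
  bc <- BatchCounts(y, batch = rep(1, 4))
  set.seed(2)
  init <- initializeChain(bc, 2)
  init$W <- c(1L, 1L, 1L, 2L)
  nIt <- 4000L
  set.seed(3)
  res <- scBatchMix:::cpp_run_chain(scBatchMix:::.countsOf(bc), rep(0L, 4),
                                    2L, mixHyper(),
                                    scBatchMix:::.initForCpp(init),
                                    nIt, 0L, 1L, FALSE, nIt)
  p1 <- res$pi[1, 1, ]
  expect_lt(abs(mean(p1) - 2 / 3), 4 * sqrt(8 / (36 * 7) / nIt) + 0.005)
  expect_lt(abs(var(p1) - 8 / (36 * 7)), 0.004)
})

test_that("data without zeros leave the dropout state untouched", {
  set.seed(4)
  y <- matrix(rpois(80, 30) + 1L, 8, 10)  # strictly positive counts
  bc <- BatchCounts(y, batch = rep(1:2, each = 5))
  ch <- fitBatchMix(bc, K = 2, nIter = 60, burnin = 30, seed = 1)
  res <- ch@chains[[1]]
  expect_true(all(res$finalZ == 0))
  expect_identical(unname(res$finalX), unname(y))
  expect_true(all(res$cntZ1 == 0))
})

test_that("the observation rule Y = X(1 - Z) holds after every run", {
  sim <- quickSim(G = 40, nDE = 10, nPerBatch = c(25, 25))
  y <- assay(sim$data, "counts")
  for (variant in c("full", "nzf")) {
    ch <- fitBatchMix(sim$data, K = 3, nIter = 50, burnin = 20, seed = 2,
                      variant = variant)
    X <- ch@chains[[1]]$finalX; Z <- ch@chains[[1]]$finalZ
    expect_true(all(y[Z == 0] == X[Z == 0]))
    expect_true(all(y[Z == 1] == 0))
    expect_true(all(X[Z == 1] >= 1))
    if (variant == "nzf") expect_true(all(Z == 0))
  }
})

test_that("runs are bit-reproducible given the seed", {
  sim <- quickSim(G = 30, nDE = 8, nPerBatch = c(20, 20))
  ch1 <- fitBatchMix(sim$data, K = 3, nIter = 40, burnin = 20, seed = 7)
  ch2 <- fitBatchMix(sim$data, K = 3, nIter = 40, burnin = 20, seed = 7)
  expect_identical(ch1@chains[[1]]$alpha, ch2@chains[[1]]$alpha)
  expect_identical(ch1@chains[[1]]$W, ch2@chains[[1]]$W)
  expect_identical(ch1@chains[[1]]$pi, ch2@chains[[1]]$pi)
  ch3 <- fitBatchMix(sim$data, K = 3, nIter = 40, burnin = 20, seed = 8)
  expect_false(identical(ch1@chains[[1]]$alpha, ch3@chains[[1]]$alpha))
})

test_that("iteration-count preconditions are enforced", {
  sim <- quickSim(G = 20, nDE = 5, nPerBatch = c(10, 10))
  expect_error(fitBatchMix(sim$data, K = 2, nIter = 50, burnin = 50))
  expect_error(fitBatchMix(sim$data, K = 2, nIter = 50, burnin = 20, thin = 0))
})

test_that("a chain started at the truth stays in a stable likelihood band", {
  d <- buildDesign("complete", B = 2, K = 2, nPerBatch = c(30, 30))
  tr <- simulateTruth(d, simConfig(nGenes = 40, nDE = 10), seed = 31)
  sim <- simulateData(tr, seed = 32)
  tt <- sim$truth
  set.seed(33)
  init <- initializeChain(sim$data, 2)
  init$alpha <- tt@params$alpha; init$beta <- tt@params$beta
  init$nu <- tt@params$nu; init$delta <- tt@params$delta
  init$phi <- tt@params$phi; init$gamma0 <- tt@params$gamma0
  init$gamma1 <- tt@params$gamma1; init$pi <- tt@params$pi
  init$W <- tt@latent$W; init$X <- tt@latent$X; init$Z <- tt@latent$Z
  init$L <- matrix(as.integer(abs(tt@params$beta) > 0), 40, 2)
  res <- scBatchMix:::cpp_run_chain(scBatchMix:::.countsOf(sim$data),
                                    batchIds(sim$data) - 1L, 2L, mixHyper(),
                                    scBatchMix:::.initForCpp(init),
                                    500L, 0L, 1L, FALSE, 0L)
  idx <- round(seq(1, 500, length.out = 26))
  ll <- vapply(idx, function(t) {
    pars <- list(alpha = res$alpha[, t],
                 beta = matrix(res$beta[, , t], 40, 2),
                 nu = matrix(res$nu[, , t], 40, 2),
                 delta = res$delta[, t],
                 phi = matrix(res$phi[, , t], 40, 2),
                 gamma0 = res$gamma0[, t], gamma1 = res$gamma1[, t],
                 pi = matrix(res$pi[, , t], 2, 2))
    observedLogLik(sim$data, pars)
  }, numeric(1))
  half1 <- ll[1:13]; half2 <- ll[14:26]
  pooledSD <- sd(ll)
  expect_lt(abs(mean(half1) - mean(half2)), 2.5 * pooledSD)
  # and the clustering stays essentially at the truth
  Wmode <- apply(res$W, 1, function(v) which.max(tabulate(v + 1L, 2)))
  expect_gt(adjustedRandIndex(Wmode, tt@latent$W), 0.95)
})

test_that("adapted Metropolis blocks reach workable acceptance rates", {
  sim <- quickSim(G = 50, nDE = 12, nPerBatch = c(40, 40))
  ch <- fitBatchMix(sim$data, K = 3, nIter = 400, burnin = 200, seed = 5)
  acc <- acceptanceRates(ch)[1, c("alpha", "beta", "nu", "delta", "phi",
                                  "gamma")]
  expect_true(all(acc > 0.05 & acc < 0.95))
})

test_that("the nzf variant drops the dropout machinery but keeps the rest", {
  sim <- quickSim(G = 40, nDE = 10, nPerBatch = c(30, 30))
  ch <- fitBatchMix(sim$data, K = 3, nIter = 200, burnin = 100, seed = 3,
                    variant = "nzf")
  res <- ch@chains[[1]]
  expect_true(all(res$finalZ == 0))
  y <- assay(sim$data, "counts")
  expect_identical(unname(res$finalX), unname(as.matrix(y)))
  # gamma never updated from its initialization
  expect_true(all(res$gamma0 == res$gamma0[1, 1]))
  expect_true(is.na(res$acceptance$gamma))
  fit <- summarizePosterior(ch)
  expect_true(is.finite(observedLogLik(sim$data, fit, variant = "nzf")))
})
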