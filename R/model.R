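# Core density and likelihood computations of the hierarchy.

#' Negative binomial log probability mass
#'
#' The mean/overdispersion parameterization used throughout the model:
#' \deqn{f(x; \mu, \phi) = {\phi+x-1 \choose x}
#'   \left(\frac{\mu}{\mu+\phi}\right)^x
#'   \left(\frac{\phi}{\mu+\phi}\right)^\phi,}
#' so that the variance is \eqn{\mu + \mu^2/\phi}. Computed through
#' \code{stats::dnbinom(size = phi, mu = mu)}, which works in log-gamma
#' space and is stable for large arguments.
#'
#' @param x non-negative integer counts (vectorized).
#' @param mu positive mean.
#' @param phi positive overdispersion (NB size).
#' @return log probability mass, same length as the recycled arguments.
#' @export
nbLogPMF <- function(x, mu, phi) {
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8))
    stop("x must be a non-negative integer")
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be positive")
  dnbinom(round(x), size = phi, mu = mu, log = TRUE)
}

#' Dropout probability
#'
#' Probability that a true count \code{x} is observed as zero through a
#' dropout event: \code{plogis(gamma0 + gamma1 * x)}. The slope must be
#' negative (larger counts are less likely to drop out), which is also the
#' first regularity condition for identifiability.
#'
#' @param x non-negative counts.
#' @param gamma0 intercept.
#' @param gamma1 negative slope.
#' @export
dropoutProb <- function(x, gamma0, gamma1) {
  if (any(gamma1 >= 0))
    stop("gamma1 must be negative (condition I)")
  plogis(gamma0 + gamma1 * x)
}

#' Cell-level negative binomial mean
#'
#' \code{exp(alpha + beta + nu + delta)}: baseline expression, cell-type
#' effect, location batch effect and cell-specific size factor combine
#' multiplicatively on the count scale.
#'
#' @param alpha,beta,nu,delta log-scale effects (vectorized).
#' @export
cellMean <- function(alpha, beta = 0, nu = 0, delta = 0) {
  exp(alpha + beta + nu + delta)
}

#' Log probability of observing a zero
#'
#' The zero branch of the observed-data likelihood: a biological zero plus
#' the dropout series \eqn{\sum_{x \ge 1} \mathrm{logistic}(\gamma_0 +
#' \gamma_1 x) f_{NB}(x; \mu, \phi)}. The series is truncated at the
#' smallest count whose NB upper-tail mass falls below 1e-14, so the
#' truncation error is certified below that level (the logistic factor is
#' bounded by one).
#'
#' @param mu,phi NB mean and overdispersion (vectorized over mu/phi pairs).
#' @param gamma0,gamma1 dropout intercept and (negative) slope.
#' @return log of the zero-observation probability.
#' @export
zeroObsLogProb <- function(mu, phi, gamma0, gamma1) {
  if (any(mu <= 0) || any(phi <= 0)) stop("mu and phi must be positive")
  if (any(gamma1 >= 0)) stop("gamma1 must be negative (condition I)")
  n <- max(length(mu), length(phi), length(gamma0), length(gamma1))
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  gamma0 <- rep_len(gamma0, n); gamma1 <- rep_len(gamma1, n)
  vapply(seq_len(n), function(j)
    cpp_zero_obs_logprob(mu[j], phi[j], gamma0[j], gamma1[j]), numeric(1))
}

#' Observed-data log likelihood
#'
#' Sums, over cells, the log of the mixture over cell types of the product
#' over genes of per-entry observation probabilities. The per-cell inner
#' sums are computed in log space with a log-sum-exp over types. Under
#' \code{variant = "full"} a zero observation is a biological zero or a
#' dropout; under \code{variant = "nzf"} (no zero inflation) the plain NB
#' likelihood is used for all entries.
#'
#' @param data a \linkS4class{BatchCounts} object (or integer matrix with a
#'   \code{batch} argument supplied through \code{params$batch}).
#' @param params a named list with alpha (G), beta (G x K), nu (G x B),
#'   delta (N), phi (G x B), gamma0 (B), gamma1 (B), pi (B x K) — or a
#'   \linkS4class{MixFit}, whose posterior means are used.
#' @param variant "full" or "nzf".
#' @export
observedLogLik <- function(data, params, variant = c("full", "nzf")) {
  variant <- match.arg(variant)
  y <- .countsOf(data)
  b <- if (is(data, "BatchCounts")) batchIds(data) else params$batch
  if (is(params, "MixFit")) params <- params@thetaHat
  G <- nrow(y); N <- ncol(y); B <- max(b)
  K <- ncol(params$beta)
  stopifnot(length(params$alpha) == G, nrow(params$beta) == G,
            nrow(params$nu) == G, ncol(params$nu) == B,
            length(params$delta) == N, nrow(params$phi) == G,
            ncol(params$phi) == B, length(params$gamma0) == B,
            nrow(params$pi) == B, ncol(params$pi) == K)
  if (variant == "full" && any(params$gamma1 >= 0))
    stop("gamma1 must be negative (condition I)")
  cpp_observed_loglik(y, as.integer(b) - 1L, as.numeric(params$alpha),
                      as.matrix(params$beta), as.matrix(params$nu),
                      as.numeric(params$delta), as.matrix(params$phi),
                      as.numeric(params$gamma0), as.numeric(params$gamma1),
                      as.matrix(params$pi), variant == "nzf")
}
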