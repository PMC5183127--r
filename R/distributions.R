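#' Zero-truncated species-abundance distributions
#'
#' Probability mass, log-probability, cumulative probability, and random
#' sampling for the four candidate SAD models, all defined on abundances
#' n = 1, 2, 3, ... :
#'
#' \describe{
#'   \item{logseries}{Fisher's log-series, \eqn{P(n) = -p^n / (n \log(1-p))},
#'     `params = list(p = ...)`, 0 < p < 1. Natively supported on n >= 1.}
#'   \item{poisson_lognormal}{Poisson mixture with lognormal rate,
#'     `params = list(mu = ..., sigma = ...)`, sigma > 0, truncated at zero
#'     by conditioning on n >= 1.}
#'   \item{neg_binom}{negative binomial (Gamma-mixed Poisson),
#'     `params = list(k = ..., q = ...)` with dispersion k > 0 and success
#'     probability 0 < q < 1 (untruncated mean k(1-q)/q), truncated at zero.}
#'   \item{zipf}{discrete power law \eqn{P(n) = n^{-s} / \zeta(s)},
#'     `params = list(s = ...)`, s > 1. Natively supported on n >= 1.}
#' }
#'
#' Zero truncation for the Poisson lognormal and negative binomial divides
#' the untruncated mass by \eqn{1 - P(0)}; it reflects that a species with
#' zero individuals is never observed in a sample.
#'
#' @param family one of `sad_families()`.
#' @param params named list or vector of parameters (see above).
#' @param n vector of abundances (positive integers).
#' @param n_species number of i.i.d. draws for `sad_sample()`.
#' @param seed optional integer; when given, sampling is reproducible.
#'
#' @return `sad_pmf()` and `sad_cdf()` return probabilities in \[0, 1\];
#'   `sad_logpmf()` the natural-log probability (computed in log space, no
#'   exp-then-log round trips); `sad_sample()` an integer-valued vector of
#'   length `n_species` with all entries >= 1.
#'
#' @examples
#' sad_pmf("zipf", list(s = 2), 1)          # 6 / pi^2
#' sad_pmf("neg_binom", list(k = 1, q = 0.5), 2)  # geometric: 0.25
#' sad_sample("logseries", list(p = 0.9), 10, seed = 1)
#' @export
sad_logpmf <- function(family, params, n) {
  family <- match_family(family)
  params <- check_params(family, params)
  n <- check_abundance(n)
  switch(family,
    logseries = {
      p <- params[["p"]]
      n * log(p) - log(n) - log(-log1p(-p))
    },
    zipf = {
      s <- min(params[["s"]], 50)
      -s * log(n) - log(riemann_zeta(s))
    },
    neg_binom = {
      k <- params[["k"]]; q <- params[["q"]]
      stats::dnbinom(n, size = k, prob = q, log = TRUE) - log1mexp(-k * log(q))
    },
    poisson_lognormal = ztpoilog_logpmf(n, params[["mu"]], params[["sigma"]])
  )
}

#' @rdname sad_logpmf
#' @export
sad_pmf <- function(family, params, n) {
  exp(sad_logpmf(family, params, n))
}

#' @rdname sad_logpmf
#' @export
sad_cdf <- function(family, params, n) {
  family <- match_family(family)
  params <- check_params(family, params)
  n <- check_abundance(n)
  switch(family,
    zipf = {
      s <- min(params[["s"]], 50)
      pmin(1 - zeta_tail(s, n + 1) / riemann_zeta(s), 1)
    },
    neg_binom = {
      k <- params[["k"]]; q <- params[["q"]]
      p0 <- stats::pnbinom(0, size = k, prob = q)
      pmin((stats::pnbinom(n, size = k, prob = q) - p0) / (1 - p0), 1)
    },
    logseries = cdf_by_cumsum(family, params, n),
    poisson_lognormal = cdf_by_cumsum(family, params, n)
  )
}

# CDF by accumulating the pmf up to max(n); the summation stops early once
# the remaining mass is below fp resolution, so very large n is cheap.
cdf_by_cumsum <- function(family, params, n) {
  cap <- 200000
  top <- min(max(n), cap)
  grid <- seq_len(top)
  cs <- cumsum(exp(sad_logpmf(family, params, grid)))
  out <- cs[pmin(n, top)]
  # beyond the cap the residual mass is negligible for any parameters this
  # package fits; clamp into [0, 1]
  pmin(out, 1)
}

#' @rdname sad_logpmf
#' @export
sad_sample <- function(family, params, n_species, seed = NULL) {
  family <- match_family(family)
  params <- check_params(family, params)
  stopifnot(length(n_species) == 1, n_species >= 1, n_species == floor(n_species))
  if (!is.null(seed)) set.seed(seed)
  switch(family,
    logseries = sample_logseries(n_species, params[["p"]]),
    zipf = sample_zipf(n_species, min(params[["s"]], 50)),
    neg_binom = {
      k <- params[["k"]]; q <- params[["q"]]
      # exact inverse-CDF through the untruncated quantile function:
      # u uniform on (P(0), 1) maps to the zero-truncated law
      p0 <- stats::pnbinom(0, size = k, prob = q)
      stats::qnbinom(stats::runif(n_species, min = p0, max = 1), size = k, prob = q)
    },
    poisson_lognormal = sample_ztpoilog(n_species, params[["mu"]], params[["sigma"]])
  )
}

# Devroye's exact generator for the logarithmic (log-series) distribution
sample_logseries <- function(m, p) {
  u <- stats::runif(m)
  v <- stats::runif(m)
  q <- -expm1(u * log1p(-p))   # 1 - (1-p)^u
  k <- ifelse(q >= 1, Inf, floor(1 + log(v) / log(q)))
  k[!is.finite(k) | k < 1] <- 1
  pmin(k, 2^31 - 1)
}

# inverse CDF by vectorized bracketing on the Euler-Maclaurin tail sums.
# For small exponents the tail is so heavy that rare draws exceed exact
# double-integer range (2^53); beyond it the bracket is closed on relative
# width instead, returning the nearest representable integer value.
sample_zipf <- function(m, s) {
  u <- stats::runif(m)
  z <- riemann_zeta(s)
  cdf <- function(n) ifelse(n < 1, 0, 1 - zeta_tail(s, n + 1) / z)
  lo <- rep(0, m)
  hi <- rep(1, m)
  while (any(todo <- cdf(hi) < u)) hi[todo] <- hi[todo] * 2
  while (any(open <- (hi - lo > 1) & (hi / pmax(lo, 1) > 1 + 1e-14))) {
    mid <- floor((lo + hi) / 2)
    below <- cdf(mid) < u
    upd_lo <- open & below
    upd_hi <- open & !below
    lo[upd_lo] <- mid[upd_lo]
    hi[upd_hi] <- mid[upd_hi]
  }
  hi
}

# lambda ~ lognormal, n ~ Poisson(lambda), rejecting n = 0; this is the
# exact conditional law of the zero-truncated mixture
sample_ztpoilog <- function(m, mu, sigma) {
  out <- numeric(0)
  while (length(out) < m) {
    need <- m - length(out)
    lam <- stats::rlnorm(max(need, 8), meanlog = mu, sdlog = sigma)
    x <- ifelse(lam > 1e8,
                round(stats::rnorm(length(lam), mean = lam, sd = sqrt(lam))),
                stats::rpois(length(lam), pmin(lam, 1e8)))
    out <- c(out, x[x >= 1])
  }
  out[seq_len(m)]
}
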