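# Poisson lognormal probability mass by mode-centred Gauss-Hermite
# quadrature, all accumulation in log space.
#
# P(n) = Integral_0^Inf Poisson(n; lambda) Lognormal(lambda; mu, sigma) dlambda
#      = Integral exp(f(z)) dz,   lambda = exp(mu + sigma z), z ~ N(0,1)
#   f(z) = -lambda + n (mu + sigma z) - lgamma(n+1) - z^2/2 - log(2 pi)/2
#
# A fixed rule centred at z = 0 misses the integrand's peak when n is far
# from exp(mu), so for each n we locate the mode of f by Newton iteration
# (f is strictly concave: f'' = -sigma^2 lambda - 1 < 0) and place the
# 128-node Hermite rule at the mode, scaled by the local curvature.

.gh_cache <- new.env(parent = emptyenv())

# Golub-Welsch: nodes/weights of the m-point (physicists') Hermite rule
gauss_hermite <- function(m = 128L) {
  key <- as.character(m)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  i <- seq_len(m - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = e$values[ord], logw = log(pi) / 2 + 2 * log(abs(e$vectors[1, ord])))
  .gh_cache[[key]] <- res
  res
}

# log P(n) for the *untruncated* Poisson lognormal, n >= 0 integer vector
poilog_logpmf <- function(n, mu, sigma, nodes = 128L) {
  stopifnot(sigma > 0, all(n >= 0), all(n == floor(n)))
  gh <- gauss_hermite(nodes)
  # Newton for the mode z0 of f(z), vectorized over n
  z0 <- pmax(pmin(ifelse(n > 0, (log(pmax(n, 1)) - mu) / sigma, 0), 50), -50)
  for (it in 1:100) {
    lam <- exp(pmin(mu + sigma * z0, 700))
    g <- sigma * (n - lam) - z0           # f'(z0)
    h <- -sigma^2 * lam - 1               # f''(z0) < 0
    step <- pmax(pmin(g / h, 10), -10)
    z0 <- z0 - step
    if (max(abs(step)) < 1e-12) break
  }
  lam0 <- exp(pmin(mu + sigma * z0, 700))
  sdv <- 1 / sqrt(sigma^2 * lam0 + 1)     # local Gaussian scale at the mode
  # node grid: z[i, j] = z0_i + sqrt(2) sd_i x_j
  zz <- outer(z0, rep(1, length(gh$x))) + sqrt(2) * outer(sdv, gh$x)
  eta <- mu + sigma * zz
  f <- -exp(pmin(eta, 700)) + n * eta - lgamma(n + 1) - zz^2 / 2 - 0.5 * log(2 * pi)
  # log of sum_j w_j e^{x_j^2} exp(f) * sqrt(2) sd
  lt <- f + rep(gh$logw + gh$x^2, each = length(n))
  m <- apply(lt, 1, max)
  m + log(rowSums(exp(lt - m))) + 0.5 * log(2) + log(sdv)
}

# log P(n | n >= 1): zero-truncated form
ztpoilog_logpmf <- function(n, mu, sigma) {
  lp0 <- poilog_logpmf(0L, mu, sigma)
  poilog_logpmf(n, mu, sigma) - log1mexp(-lp0)
}
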