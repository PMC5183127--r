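# Frozen oracle values and shared test utilities.
#
# The Poisson-lognormal reference values below were computed once with
# mpmath (25 significant digits, adaptive quadrature of the mixture
# integral over a bracketed infinite range); the log-series MLE reference
# by arbitrary-precision root-finding on the mean equation; the Zipf MLE
# reference by exhaustive grid search (step 1e-3) on the exact profile
# likelihood. They are independent of the package's quadrature and
# optimizer code paths.

# untruncated PLN pmf: columns n, mu, sigma, pmf
PLN_ORACLE <- rbind(
  c(1,     0, 1.0, 0.258856122780777),
  c(5,     0, 1.0, 0.028195150145518),
  c(1,     2, 1.0, 0.0655609178861606),
  c(10,    2, 1.0, 0.0368423165181871),
  c(100,   2, 1.0, 0.000139738920523449),
  c(3,     1, 0.5, 0.169612781097847),
  c(1,    -1, 2.0, 0.165441856750252),
  c(50,   -1, 2.0, 0.000200406961661997),
  c(10000, 2, 1.0, 2.0554377407598e-16)
)
# zero-truncated log-pmf for the same rows
PLN_ZT_ORACLE <- c(-0.870610052959972, -3.08773246730915, -2.68477462326117,
                   -3.26110728781728, -8.83573382852358, -1.67109749682316,
                   -0.927833088730808, -7.64385807463393, -36.080871748866)

# log-series MLE for abundances c(1,1,1,2,5): root of the mean equation
LS_MEAN2_PHAT <- 0.715331862959162
LS_MEAN2_LOGLIK <- -6.79404873317921

# Zipf MLE for abundances c(1,2,4,8) by exhaustive grid search, step 1e-3
ZIPF_GRID_SHAT <- 1.661
ZIPF_GRID_LOGLIK <- -9.9436595826

# log-series pmf at p = 0.5, n = 1: -p / log(1 - p)
LS_HALF_P1 <- 0.721347520444482

# parameter grids used by the normalization suite (>= 20 points per family)
norm_grid <- function(family) {
  switch(family,
    logseries = lapply(seq(0.05, 0.999, length.out = 21), function(p) list(p = p)),
    zipf = lapply(seq(1.2, 6, length.out = 21), function(s) list(s = s)),
    neg_binom = {
      g <- expand.grid(k = c(0.2, 0.5, 1, 2, 10), q = c(0.05, 0.2, 0.5, 0.8, 0.95))
      lapply(seq_len(nrow(g)), function(i) list(k = g$k[i], q = g$q[i]))
    },
    poisson_lognormal = {
      g <- expand.grid(mu = c(-1, 0, 1, 2), sigma = c(0.3, 0.6, 1, 1.5, 2))
      lapply(seq_len(nrow(g)), function(i) list(mu = g$mu[i], sigma = g$sigma[i]))
    })
}

# sum of the zero-truncated pmf over 1..N plus an analytic tail bound;
# each bound is independent of the package's own cdf code
normalization_check <- function(family, params) {
  if (family == "logseries") {
    p <- params$p
    N <- max(2000, ceiling(-30 / log(p)))
    s <- sum(sad_pmf(family, params, 1:N))
    tail <- p^(N + 1) / ((N + 1) * (1 - p) * abs(log1p(-p)))
  } else if (family == "zipf") {
    s_par <- params$s
    N <- 20000
    s <- sum(sad_pmf(family, params, 1:N))
    # independent zeta estimate: direct partial sum + integral-bracket tail
    zeta_direct <- sum((1:N)^(-s_par)) + tail_integral_zipf(s_par, N)
    tail <- tail_integral_zipf(s_par, N) / zeta_direct
  } else if (family == "neg_binom") {
    k <- params$k; q <- params$q
    p0 <- pnbinom(0, size = k, prob = q)
    N <- max(2000, ceiling(qnbinom(1 - 1e-10, size = k, prob = q) * 2))
    s <- sum(sad_pmf(family, params, 1:N))
    tail <- pnbinom(N, size = k, prob = q, lower.tail = FALSE) / (1 - p0)
  } else {
    mu <- params$mu; sigma <- params$sigma
    N <- max(2000, ceiling(2 * qlnorm(1 - 4e-7, mu, sigma)))
    s <- 0
    for (lo in seq(1, N, by = 20000)) {       # chunked to bound memory
      hi <- min(lo + 19999, N)
      s <- s + sum(sad_pmf(family, params, lo:hi))
    }
    p0 <- exp(poilog_logpmf_test(0, mu, sigma))
    # P(X > N) <= P(lambda > N/2) + Chernoff bound at lambda = N/2
    tail <- (plnorm(N / 2, mu, sigma, lower.tail = FALSE) +
               exp(-N * (log(2) - 0.5))) / (1 - p0)
  }
  s + tail
}

# Euler-Maclaurin-free integral bracket for the zipf tail:
# sum_{m>N} m^-s lies between the integral from N+1 and from N; the
# midpoint of the bracket is accurate to half the bracket width
tail_integral_zipf <- function(s, N) {
  (N^(1 - s) + (N + 1)^(1 - s)) / (2 * (s - 1))
}

# access the untruncated PLN kernel for P(0) without exporting it
poilog_logpmf_test <- function(n, mu, sigma) {
  getFromNamespace("poilog_logpmf", "sadcompare")(n, mu, sigma)
}

# deterministic random small community, heavy-tailed like field data
random_small_community <- function(seed, S_max = 30) {
  set.seed(seed)
  S <- sample(5:S_max, 1)
  ab <- 1 + rnbinom(S, size = 0.7, mu = sample(c(2, 5, 20), 1))
  community(ab, site_id = paste0("rc", seed))
}

# write a 3-site fixture communities CSV; returns the path
write_fixture_csv <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    site_id = rep(c("s1", "s2", "s3"), times = c(6, 8, 5)),
    species_id = c(paste0("sp", 1:6), paste0("sp", 1:8), paste0("sp", 1:5)),
    abundance = c(30, 10, 4, 2, 1, 1,
                  55, 21, 13, 8, 5, 3, 1, 1,
                  9, 7, 3, 1, 1),
    dataset_id = rep(c("dsA", "dsA", "dsB"), times = c(6, 8, 5))
  )
  write.csv(df, path, row.names = FALSE)
  path
}

make_fit <- function(family, loglik, S) {
  getFromNamespace("new_fit", "sadcompare")(
    family, params = list(), loglik = loglik, S = S)
}
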