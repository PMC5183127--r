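# Maximum-likelihood fitting: frozen oracles, grid-search equivalence,
# parameter recovery, degenerate inputs, and the NB/log-series nesting.

test_that("log-series MLE solves the mean equation", {
  f <- fit_logseries(community(c(1, 1, 1, 2, 5)))
  expect_equal(f$params$p, LS_MEAN2_PHAT, tolerance = 1e-8)
  expect_equal(f$loglik, LS_MEAN2_LOGLIK, tolerance = 1e-8)
  expect_true(f$converged)
  expect_false(f$at_boundary)
  # all singletons: sample mean 1 forces the lower boundary
  fb <- fit_logseries(community(c(1, 1, 1)))
  expect_true(fb$at_boundary)
  expect_equal(fb$params$p, 1e-10)
})

test_that("Zipf MLE matches the exhaustive grid search", {
  f <- fit_zipf(community(c(1, 2, 4, 8)))
  expect_equal(f$params$s, ZIPF_GRID_SHAT, tolerance = 1e-3)
  expect_gte(f$loglik, ZIPF_GRID_LOGLIK - 1e-6)
  # all-singleton degeneracy: likelihood increases in s without bound
  fb <- fit_zipf(community(c(1, 1, 1)))
  expect_true(fb$at_boundary)
  expect_equal(fb$params$s, 50)
})

test_that("parameters are recovered from large simulated communities", {
  x <- sad_sample("logseries", list(p = 0.95), 2000, seed = 11)
  expect_lt(abs(fit_logseries(community(x))$params$p - 0.95), 0.01)

  x <- sad_sample("zipf", list(s = 1.5), 2000, seed = 12)
  expect_lt(abs(fit_zipf(community(x))$params$s - 1.5), 0.05)

  x <- sad_sample("neg_binom", list(k = 2, q = 0.3), 2000, seed = 13)
  fn <- fit_neg_binom(community(x))
  expect_lt(abs(fn$params$k / 2 - 1), 0.1)
  expect_lt(abs(fn$params$q / 0.3 - 1), 0.1)
  expect_true(fn$converged)

  x <- sad_sample("poisson_lognormal", list(mu = 1, sigma = 1), 2000, seed = 14)
  fp <- fit_poisson_lognormal(community(x))
  expect_lt(abs(fp$params$mu - 1), 0.1)
  expect_lt(abs(fp$params$sigma - 1), 0.1)
  expect_true(fp$converged)
})

test_that("2-parameter optimizers beat their starting values", {
  set.seed(21)
  for (rep in 1:5) {
    x <- sad_sample("neg_binom", list(k = 1.5, q = 0.2), 300)
    co <- community(x)
    m <- mean(x); v <- var(x)
    k0 <- min(max(if (v > m) m^2 / (v - m) else 10, 1e-3), 1e3)
    q0 <- min(max(k0 / (k0 + m), 1e-6), 1 - 1e-6)
    ll_start <- sum(sad_logpmf("neg_binom", list(k = k0, q = q0), x))
    expect_gte(fit_neg_binom(co)$loglik, ll_start)

    lx <- log(x)
    ll_start_p <- sum(sad_logpmf("poisson_lognormal",
                                 list(mu = mean(lx), sigma = max(sd(lx), 0.1)), x))
    expect_gte(fit_poisson_lognormal(co)$loglik, ll_start_p)
  }
})

test_that("degenerate communities yield flagged fits, never errors", {
  fn <- fit_neg_binom(community(c(1, 1, 1, 1)))
  expect_true(fn$at_boundary || !fn$converged)
  expect_true(is.finite(fn$loglik))

  fp <- fit_poisson_lognormal(community(c(3, 3, 3)))
  expect_true(fp$at_boundary)
  expect_equal(fp$params$sigma, 1e-3, tolerance = 1e-6)
  expect_true(is.finite(fp$loglik))

  f1 <- fit_all(community(5))
  expect_length(f1, 4)
  for (f in f1) expect_s3_class(f, "sad_fit")
})

test_that("fit_all returns four finite fits in canonical order", {
  fits <- fit_all(community(c(1, 1, 2, 4, 8, 16)))
  expect_identical(names(fits), sad_families())
  expect_identical(vapply(fits, `[[`, "", "family"),
                   setNames(sad_families(), sad_families()))
  expect_true(all(is.finite(vapply(fits, `[[`, 0, "loglik"))))
})

test_that("MLEs match exhaustive grid search on random small communities", {
  # spot-check here on 6 communities; the full 20-community sweep is the
  # acceptance criterion (test-acceptance.R)
  p_grid <- seq(1e-5, 1 - 1e-5, by = 1e-5)
  s_grid <- seq(1.001, 50, by = 1e-3)
  lz_grid <- log(vapply(s_grid, function(s) sum((1:2000)^(-s)) +
                          tail_integral_zipf(s, 2000), 0))
  kq <- expand.grid(k = exp(seq(log(0.05), log(50), length.out = 100)),
                    q = seq(0.005, 0.995, length.out = 100))
  ms <- expand.grid(mu = seq(-3, 4, length.out = 100),
                    sigma = seq(0.05, 4, length.out = 100))
  for (seed in c(2, 5, 8, 11, 14, 17)) {
    co <- random_small_community(seed)
    n <- co$abundances
    uv <- as.numeric(names(tw <- table(n))); w <- as.numeric(tw)

    # log-series: closed-form profile likelihood over the p grid
    ll_p <- sum(n) * log(p_grid) - sum(log(n)) -
      length(n) * log(-log1p(-p_grid))
    expect_lt(max(ll_p) - fit_logseries(co)$loglik, 1e-4)

    # zipf: profile over s
    ll_s <- -s_grid * sum(w * log(uv)) - sum(w) * lz_grid
    expect_lt(max(ll_s) - fit_zipf(co)$loglik, 1e-4)

    # 2-parameter families: beat-or-match a 100 x 100 grid
    ll_nb <- vapply(seq_len(nrow(kq)), function(i) {
      sum(w * sad_logpmf("neg_binom", list(k = kq$k[i], q = kq$q[i]), uv))
    }, 0)
    expect_lt(max(ll_nb) - fit_neg_binom(co)$loglik, 1e-3)

    ll_pl <- vapply(seq_len(nrow(ms)), function(i) {
      sum(w * sad_logpmf("poisson_lognormal",
                         list(mu = ms$mu[i], sigma = ms$sigma[i]), uv))
    }, 0)
    expect_lt(max(ll_pl) - fit_poisson_lognormal(co)$loglik, 1e-3)
  }
})

test_that("ZTNB nests the log-series: NB loglik >= log-series loglik", {
  # on arbitrary small communities
  for (seed in 1:20) {
    co <- random_small_community(seed)
    expect_gte(fit_neg_binom(co)$loglik, fit_logseries(co)$loglik - 1e-3,
               label = sprintf("seed %d", seed))
  }
  # and on data generated from the log-series itself (k -> 0 boundary)
  x <- sad_sample("logseries", list(p = 0.9), 500, seed = 31)
  co <- community(x)
  expect_gte(fit_neg_binom(co)$loglik, fit_logseries(co)$loglik - 1e-3)
})

test_that("fits are invariant to permutation of the abundance vector", {
  co <- random_small_community(77)
  set.seed(1)
  cop <- community(sample(co$abundances), site_id = co$site_id)
  for (fitter in list(fit_logseries, fit_zipf, fit_neg_binom,
                      fit_poisson_lognormal)) {
    f1 <- fitter(co); f2 <- fitter(cop)
    expect_identical(unlist(f1$params), unlist(f2$params))
    expect_identical(f1$loglik, f2$loglik)
  }
})

test_that("estimator error shrinks with richness", {
  sizes <- c(50, 500, 5000)
  med_err <- function(family, params, n_rep, est_name) {
    sapply(seq_along(sizes), function(j) {
      errs <- vapply(seq_len(n_rep), function(r) {
        x <- sad_sample(family, params, sizes[j], seed = 1000 * j + r)
        f <- switch(family, logseries = fit_logseries(community(x)),
                    zipf = fit_zipf(community(x)),
                    neg_binom = fit_neg_binom(community(x)),
                    poisson_lognormal = fit_poisson_lognormal(community(x)))
        abs(f$params[[est_name]] - params[[est_name]])
      }, 0)
      median(errs)
    })
  }
  # 1-parameter families: 100 replicates; 2-parameter: 40 (runtime)
  e <- med_err("logseries", list(p = 0.95), 100, "p")
  expect_true(all(diff(e) < 0), label = paste("logseries", toString(e)))
  e <- med_err("zipf", list(s = 1.5), 100, "s")
  expect_true(all(diff(e) < 0), label = paste("zipf", toString(e)))
  e <- med_err("neg_binom", list(k = 2, q = 0.3), 40, "k")
  expect_true(all(diff(e) < 0), label = paste("neg_binom", toString(e)))
  e <- med_err("poisson_lognormal", list(mu = 1, sigma = 1), 40, "mu")
  expect_true(all(diff(e) < 0), label = paste("poisson_lognormal", toString(e)))
})
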