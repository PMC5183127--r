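# Maximum-likelihood fits of the four candidate models to one community.
#
# All likelihoods are sums of log-pmf terms computed over the *unique*
# abundance values with multiplicity weights, which makes fitting cheap on
# large sites where most counts repeat. Boundary handling: parameters are
# clipped to the bounds below and any fit that lands on a clip is flagged
# `at_boundary` rather than silently returned.

.bounds <- list(
  p = c(1e-10, 1 - 1e-10),
  s = c(1 + 1e-6, 50),
  sigma_min = 1e-3,
  k = c(1e-8, 1e6)
)

new_fit <- function(family, params, loglik, converged = TRUE,
                    at_boundary = FALSE, S = NA_integer_, message = NA_character_) {
  structure(
    list(family = family,
         params = as.list(params),
         loglik = loglik,
         K = sad_param_count(family),
         converged = converged,
         at_boundary = at_boundary,
         S = S,
         message = message),
    class = "sad_fit"
  )
}

#' @export
print.sad_fit <- function(x, ...) {
  pv <- paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("<sad_fit> %s: %s | loglik = %.4f (K = %d)%s%s\n",
              x$family, pv, x$loglik, x$K,
              if (!isTRUE(x$converged)) " [not converged]" else "",
              if (isTRUE(x$at_boundary)) " [boundary]" else ""))
  invisible(x)
}

# weighted zero-truncated log-likelihood over unique values
wt_loglik <- function(family, params, uvals, wts) {
  sum(wts * sad_logpmf(family, params, uvals))
}

#' Fit SAD models to a community by maximum likelihood
#'
#' `fit_logseries()`, `fit_zipf()`, `fit_neg_binom()` and
#' `fit_poisson_lognormal()` estimate one family each;
#' `fit_all()` returns all four in the canonical family order.
#'
#' The log-series MLE is found by solving the mean equation
#' \eqn{-p / ((1-p)\log(1-p)) = \bar{n}} (the score equation in p); the
#' Zipf exponent by Brent search of the concave profile likelihood on
#' (1, 50]; the two-parameter families by Nelder-Mead followed by a BFGS
#' polish on transformed scales (log k, logit q; mu, log sigma), started
#' from method-of-moments values with additional fixed fallback starts.
#' Degenerate inputs (S = 1, all-equal abundances) yield flagged fits,
#' never errors.
#'
#' @param x an `sad_community`, or a bare vector of positive integer
#'   abundances.
#' @return An `sad_fit` (for `fit_all()`, a list of four `sad_fit`s named
#'   by family) with elements `family`, `params`, `loglik`, `K`,
#'   `converged`, `at_boundary`.
#' @examples
#' co <- community(c(20, 10, 4, 4, 2, 1, 1, 1))
#' fit_logseries(co)
#' fit_all(co)
#' @export
fit_logseries <- function(x) {
  co <- as_community(x)
  n <- co$abundances
  uv <- as.numeric(names(tw <- table(n))); wts <- as.numeric(tw)
  xbar <- mean(n)
  b <- .bounds$p
  ls_mean <- function(p) -p / ((1 - p) * log1p(-p))
  at_boundary <- FALSE
  if (xbar <= ls_mean(b[1])) {
    p_hat <- b[1]; at_boundary <- TRUE
  } else if (xbar >= ls_mean(b[2])) {
    p_hat <- b[2]; at_boundary <- TRUE
  } else {
    p_hat <- stats::uniroot(function(p) ls_mean(p) - xbar, interval = b,
                            tol = 1e-14)$root
  }
  new_fit("logseries", c(p = p_hat),
          wt_loglik("logseries", c(p = p_hat), uv, wts),
          converged = TRUE, at_boundary = at_boundary, S = co$S)
}

#' @rdname fit_logseries
#' @export
fit_zipf <- function(x) {
  co <- as_community(x)
  n <- co$abundances
  uv <- as.numeric(names(tw <- table(n))); wts <- as.numeric(tw)
  b <- .bounds$s
  if (all(n == 1)) {
    # all singletons: likelihood increases without bound in s
    s_hat <- b[2]
    return(new_fit("zipf", c(s = s_hat),
                   wt_loglik("zipf", c(s = s_hat), uv, wts),
                   converged = TRUE, at_boundary = TRUE, S = co$S))
  }
  nll <- function(s) -wt_loglik("zipf", c(s = s), uv, wts)
  opt <- stats::optimize(nll, interval = b, tol = 1e-10)
  s_hat <- opt$minimum
  at_boundary <- s_hat > b[2] - 1e-4 || s_hat < b[1] + 1e-6
  if (at_boundary && nll(b[2]) < opt$objective) {
    s_hat <- b[2]; opt$objective <- nll(b[2])
  }
  new_fit("zipf", c(s = s_hat), -opt$objective,
          converged = TRUE, at_boundary = at_boundary, S = co$S)
}

# shared machinery for the two-parameter families: multi-start
# Nelder-Mead + BFGS polish on unconstrained transformed parameters
fit_2par <- function(family, co, starts, to_params, nll_tr) {
  best <- NULL
  for (st in starts) {
    res <- tryCatch({
      r1 <- stats::optim(st, nll_tr, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      r2 <- tryCatch(
        stats::optim(r1$par, nll_tr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) r1)
      if (r2$value <= r1$value) r2 else r1
    }, error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) &&
        (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(new_fit(family, to_params(starts[[1]])$params, NA_real_,
                   converged = FALSE, at_boundary = FALSE, S = co$S,
                   message = "all starts failed"))
  }
  pb <- to_params(best$par)
  new_fit(family, pb$params, -best$value,
          converged = best$convergence == 0, at_boundary = pb$at_boundary,
          S = co$S)
}

#' @rdname fit_logseries
#' @export
fit_neg_binom <- function(x) {
  co <- as_community(x)
  n <- co$abundances
  uv <- as.numeric(names(tw <- table(n))); wts <- as.numeric(tw)
  kb <- .bounds$k
  to_params <- function(par) {
    k <- min(max(exp(par[1]), kb[1]), kb[2])
    q <- min(max(stats::plogis(par[2]), 1e-10), 1 - 1e-10)
    list(params = c(k = k, q = q, mean = unname(k * (1 - q) / q)),
         at_boundary = k <= kb[1] * 1.01 || k >= kb[2] * 0.99 ||
           q <= 2e-10 || q >= 1 - 2e-10)
  }
  nll_tr <- function(par) {
    pp <- to_params(par)$params
    v <- -wt_loglik("neg_binom", pp[c("k", "q")], uv, wts)
    if (!is.finite(v)) 1e12 else v
  }
  m <- mean(n); v <- stats::var(n)
  if (co$S < 2 || !is.finite(v) || v == 0) {
    # degenerate: no dispersion information
    k0 <- 1; q0 <- k0 / (k0 + m)
    ft <- fit_2par("neg_binom", co, list(c(log(k0), stats::qlogis(q0))),
                   to_params, nll_tr)
    ft$at_boundary <- TRUE
    ft$converged <- FALSE
    ft$message <- "degenerate input (S < 2 or zero variance)"
    return(ft)
  }
  k_mom <- if (v > m) m^2 / (v - m) else 10
  k_mom <- min(max(k_mom, 1e-3), 1e3)
  q_mom <- min(max(k_mom / (k_mom + m), 1e-6), 1 - 1e-6)
  # the k -> 0 ridge is the log-series limit (p = 1 - q); starting there
  # lets the optimizer reach the boundary when the data ask for it
  p_ls <- fit_logseries(co)$params$p
  starts <- list(
    c(log(k_mom), stats::qlogis(q_mom)),
    c(log(1), stats::qlogis(min(max(1 / (1 + m), 1e-6), 1 - 1e-6))),
    c(log(1e-4), stats::qlogis(min(max(1 - p_ls, 1e-9), 1 - 1e-9)))
  )
  fit_2par("neg_binom", co, starts, to_params, nll_tr)
}

#' @rdname fit_logseries
#' @export
fit_poisson_lognormal <- function(x) {
  co <- as_community(x)
  n <- co$abundances
  uv <- as.numeric(names(tw <- table(n))); wts <- as.numeric(tw)
  smin <- .bounds$sigma_min
  to_params <- function(par) {
    sigma <- smin + exp(par[2])
    list(params = c(mu = unname(par[1]), sigma = unname(sigma)),
         at_boundary = sigma <= smin * 1.01)
  }
  nll_tr <- function(par) {
    pp <- to_params(par)$params
    v <- -wt_loglik("poisson_lognormal", pp, uv, wts)
    if (!is.finite(v)) 1e12 else v
  }
  lx <- log(n)
  mu0 <- mean(lx); s0 <- stats::sd(lx)
  if (co$S < 2 || !is.finite(s0) || s0 == 0) {
    # all-equal abundances push sigma to its floor
    opt <- stats::optimize(function(mu) nll_tr(c(mu, -Inf + 0)),
                           interval = mu0 + c(-5, 5))
    opt1 <- stats::optim(c(opt$minimum, log(1e-8)), nll_tr,
                         method = "Nelder-Mead",
                         control = list(maxit = 1000, reltol = 1e-12))
    pb <- to_params(opt1$par)
    return(new_fit("poisson_lognormal", pb$params, -opt1$value,
                   converged = FALSE, at_boundary = TRUE, S = co$S,
                   message = "degenerate input (S < 2 or zero variance)"))
  }
  s0 <- max(s0, 0.1)
  starts <- list(
    c(mu0, log(s0)),
    c(mu0 - 0.5, log(s0 * 2)),
    c(mu0 + 0.5, log(max(s0 / 2, 2 * smin)))
  )
  fit_2par("poisson_lognormal", co, starts, to_params, nll_tr)
}

#' @rdname fit_logseries
#' @param families subset of `sad_families()` to fit (default all four).
#' @export
fit_all <- function(x, families = sad_families()) {
  co <- as_community(x)
  families <- match.arg(families, sad_families(), several.ok = TRUE)
  fitters <- list(logseries = fit_logseries,
                  poisson_lognormal = fit_poisson_lognormal,
                  neg_binom = fit_neg_binom,
                  zipf = fit_zipf)
  out <- lapply(sad_families()[sad_families() %in% families], function(fam) {
    tryCatch(fitters[[fam]](co), error = function(e) {
      new_fit(fam, stats::setNames(list(), character(0)), NA_real_,
              converged = FALSE, at_boundary = FALSE, S = co$S,
              message = conditionMessage(e))
    })
  })
  names(out) <- sad_families()[sad_families() %in% families]
  out
}
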