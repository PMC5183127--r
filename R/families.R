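#' Model families for species-abundance distributions
#'
#' The four candidate models compared by this package, in the canonical
#' order used everywhere downstream (fitting, model selection, output
#' tables, tie-breaking).
#'
#' @return Character vector of family names:
#'   `"logseries"`, `"poisson_lognormal"`, `"neg_binom"`, `"zipf"`.
#' @export
sad_families <- function() {
  c("logseries", "poisson_lognormal", "neg_binom", "zipf")
}

#' Number of fitted parameters per family
#'
#' Log-series and Zipf have one free parameter; the Poisson lognormal and
#' the negative binomial have two. This count is the K used in AICc.
#'
#' @param family character vector of family names.
#' @return Integer vector of parameter counts.
#' @export
sad_param_count <- function(family) {
  k <- c(logseries = 1L, poisson_lognormal = 2L, neg_binom = 2L, zipf = 1L)
  family <- match.arg(family, sad_families(), several.ok = TRUE)
  unname(k[family])
}

match_family <- function(family) {
  match.arg(family, sad_families())
}

# Validate a parameter list against the family's domain; returns the
# parameters as a named numeric vector. Domain violations are errors.
check_params <- function(family, params) {
  family <- match_family(family)
  params <- unlist(params)
  need <- switch(family,
    logseries = "p",
    poisson_lognormal = c("mu", "sigma"),
    neg_binom = c("k", "q"),
    zipf = "s"
  )
  if (is.null(names(params)) && length(params) == length(need)) {
    names(params) <- need
  }
  if (!all(need %in% names(params))) {
    stop(sprintf("family '%s' requires parameters: %s", family,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  params <- params[need]
  if (any(!is.finite(params))) {
    stop(sprintf("non-finite parameter for family '%s'", family), call. = FALSE)
  }
  ok <- switch(family,
    logseries = params[["p"]] > 0 && params[["p"]] < 1,
    poisson_lognormal = params[["sigma"]] > 0,
    neg_binom = params[["k"]] > 0 && params[["q"]] > 0 && params[["q"]] < 1,
    zipf = params[["s"]] > 1
  )
  if (!ok) {
    dom <- switch(family,
      logseries = "0 < p < 1",
      poisson_lognormal = "sigma > 0",
      neg_binom = "k > 0, 0 < q < 1",
      zipf = "s > 1"
    )
    stop(sprintf("parameters out of domain for family '%s' (need %s)",
                 family, dom), call. = FALSE)
  }
  params
}

check_abundance <- function(n) {
  if (length(n) == 0) stop("empty abundance vector", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop("abundances must be positive integers (n >= 1)", call. = FALSE)
  }
  as.numeric(n)
}

# log(1 - exp(-u)) for u > 0, stable for both small and large u
log1mexp <- function(u) {
  ifelse(u <= log(2), log(-expm1(-u)), log1p(-exp(-u)))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
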