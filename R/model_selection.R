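# AICc-based model selection among the four fitted families.
#
# Sample size for the small-sample correction is the number of species S
# (the number of data points entering the likelihood). Sites too
# species-poor to support the correction for the 2-parameter models
# (S < 4 gives n - K - 1 <= 0) are excluded upstream and counted.

#' Corrected Akaike Information Criterion
#'
#' \eqn{AICc = -2 \ell + 2K + 2K(K+1)/(n - K - 1)}, where \eqn{\ell} is the
#' maximized log-likelihood, K the number of fitted parameters, and n the
#' sample size (here: species richness S).
#'
#' @param loglik maximized log-likelihood (nats).
#' @param K number of fitted parameters.
#' @param n sample size; must satisfy `n - K - 1 >= 1`.
#' @return AICc value(s); vectorized over its arguments.
#' @examples
#' aicc(-100, 2, 10)  # 204 + 12/7
#' @export
aicc <- function(loglik, K, n) {
  if (any(n - K - 1 < 1)) {
    stop("AICc undefined: need n - K - 1 >= 1 (small-sample domain)",
         call. = FALSE)
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from AICc values
#'
#' Weights are computed from AICc differences,
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i = AICc_i - \min AICc}, which is numerically stable for
#' arbitrarily large spreads. A weight is interpretable as the probability
#' that the model is the best of the candidate set. Non-finite entries are
#' excluded and the remaining weights renormalized; the excluded positions
#' return `NA`.
#'
#' @param aiccs numeric vector of AICc values (one per candidate model).
#' @return Numeric vector of weights summing to 1 over the finite entries.
#' @examples
#' akaike_weights(c(10, 12))  # 0.731..., 0.268...
#' @export
akaike_weights <- function(aiccs) {
  out <- rep(NA_real_, length(aiccs))
  ok <- is.finite(aiccs)
  if (!any(ok)) return(out)
  d <- aiccs[ok] - min(aiccs[ok])
  w <- exp(-d / 2)
  out[ok] <- w / sum(w)
  out
}

#' Compare the four fits for one site
#'
#' Assembles per-family AICc, AICc differences, and Akaike weights, and
#' identifies the best model (greatest weight). Exact ties are broken in
#' favour of the model with fewer parameters, then canonical family order,
#' and flagged. Families with non-finite log-likelihoods, and sites with
#' `S < min_richness`, are excluded with a recorded reason.
#'
#' @param fits list of `sad_fit` objects (as from [fit_all()]).
#' @param site_id site label carried into the result.
#' @param dataset_id dataset label carried into the result.
#' @param min_richness smallest S eligible for model selection; the default
#'   4 is the smallest value for which the 2-parameter AICc correction is
#'   defined (n - K - 1 >= 1).
#' @return An `sad_site_comparison`: list with `site_id`, `dataset_id`,
#'   `S`, `table` (data frame: family, loglik, K, aicc, delta_aicc, weight,
#'   best, included, reason), `best_family`, `tie`, `excluded`,
#'   `exclude_reason`.
#' @export
compare_site <- function(fits, site_id = NULL, dataset_id = NULL,
                         min_richness = 4) {
  fams <- vapply(fits, `[[`, "", "family")
  S <- fits[[1]]$S
  tab <- data.frame(
    family = fams,
    loglik = vapply(fits, `[[`, 0, "loglik"),
    K = vapply(fits, `[[`, 0L, "K"),
    aicc = NA_real_,
    delta_aicc = NA_real_,
    weight = NA_real_,
    best = FALSE,
    tie = FALSE,
    included = FALSE,
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
  res <- structure(
    list(site_id = site_id %||% "site", dataset_id = dataset_id %||% "dataset",
         S = S, table = tab, best_family = NA_character_, tie = FALSE,
         excluded = FALSE, exclude_reason = NA_character_),
    class = "sad_site_comparison"
  )
  if (is.na(S) || S < min_richness) {
    res$excluded <- TRUE
    res$exclude_reason <- "low_richness"
    res$table$reason <- "low_richness"
    return(res)
  }
  for (i in seq_len(nrow(tab))) {
    if (!is.finite(tab$loglik[i])) {
      tab$reason[i] <- "nonfinite_loglik"
    } else if (S - tab$K[i] - 1 < 1) {
      tab$reason[i] <- "small_sample"
    } else {
      tab$aicc[i] <- aicc(tab$loglik[i], tab$K[i], S)
      tab$included[i] <- TRUE
    }
  }
  if (sum(tab$included) < 2) {
    res$table <- tab
    res$excluded <- TRUE
    res$exclude_reason <- "fewer_than_two_models"
    return(res)
  }
  inc <- tab$included
  tab$delta_aicc[inc] <- tab$aicc[inc] - min(tab$aicc[inc])
  tab$weight <- akaike_weights(ifelse(inc, tab$aicc, NA_real_))
  wmax <- max(tab$weight[inc])
  top <- which(inc & abs(tab$weight - wmax) <= 1e-12)
  tie <- length(top) > 1
  if (tie) {
    # fewer parameters first, then canonical order (row order is canonical)
    top <- top[order(tab$K[top], top)]
  }
  best <- top[1]
  tab$best[best] <- TRUE
  tab$tie[inc] <- tie
  res$table <- tab
  res$best_family <- tab$family[best]
  res$tie <- tie
  res
}

#' Best-fitting model of a site comparison
#'
#' @param comparison an `sad_site_comparison` from [compare_site()].
#' @return The family name with the greatest Akaike weight, or `NA` if the
#'   site was excluded.
#' @export
best_model <- function(comparison) {
  stopifnot(inherits(comparison, "sad_site_comparison"))
  comparison$best_family
}

#' Per-family deviation from the site's mean log-likelihood
#'
#' For one site, each family's maximized log-likelihood minus the mean over
#' the four families. Positive values mean the model fits better than the
#' average of the candidate set; the deviations sum to zero by
#' construction. Sites with any non-finite log-likelihood return all `NA`.
#'
#' @param fits list of `sad_fit` objects for one site.
#' @return Named numeric vector of deviations (nats), one per family.
#' @export
loglik_deviation <- function(fits) {
  ll <- vapply(fits, `[[`, 0, "loglik")
  names(ll) <- vapply(fits, `[[`, "", "family")
  if (any(!is.finite(ll))) return(ll * NA_real_)
  ll - mean(ll)
}

#' @export
print.sad_site_comparison <- function(x, ...) {
  cat(sprintf("<sad_site_comparison> site '%s' (S = %s)%s\n", x$site_id,
              x$S, if (x$excluded) paste0(" EXCLUDED: ", x$exclude_reason) else ""))
  print(x$table[, c("family", "loglik", "K", "aicc", "delta_aicc", "weight", "best")],
        row.names = FALSE, digits = 6)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
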