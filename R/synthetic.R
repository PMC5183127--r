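# Synthetic community collections with the gross statistical structure of
# large SAD compilations: many sites, species richness from a handful to a
# few hundred, strongly right-skewed integer abundances with many
# singletons. Each site gets its own sub-seed derived from the master seed
# by a counter scheme, so any single site can be regenerated without
# replaying the whole collection.

#' Specify a synthetic community collection
#'
#' The specification fixes the generating family (or mixture of families),
#' the per-site parameter ranges (drawn uniformly), the richness
#' distribution (log-uniform between `S_range[1]` and `S_range[2]`), the
#' number of sites, and the master seed. Defaults mimic the gross
#' structure of compiled survey data: richness log-uniform on [4, 300] and
#' heavy-tailed abundances with a substantial singleton fraction.
#'
#' @param n_sites number of communities to generate.
#' @param families generating family per site: one name, or several to
#'   sample uniformly per site.
#' @param S_range richness range (log-uniform draw), `S_range[1] >= 1`.
#' @param p_range log-series shape range.
#' @param mu_range,sigma_range Poisson lognormal parameter ranges.
#' @param k_range,q_range negative binomial parameter ranges.
#' @param s_range Zipf exponent range.
#' @param seed master seed (integer).
#' @return An object of class `sad_synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 100,
                           families = sad_families(),
                           S_range = c(4, 300),
                           p_range = c(0.9, 0.999),
                           mu_range = c(0, 2),
                           sigma_range = c(0.5, 1.5),
                           k_range = c(1, 5),
                           q_range = c(0.05, 0.5),
                           s_range = c(1.2, 2.5),
                           seed = 1) {
  families <- match.arg(families, sad_families(), several.ok = TRUE)
  if (length(families) == 0) stop("no generating families given", call. = FALSE)
  stopifnot(n_sites >= 1, length(S_range) == 2, S_range[1] >= 1,
            S_range[1] <= S_range[2])
  rng_ok <- function(r, lo, hi) length(r) == 2 && r[1] <= r[2] && r[1] > lo && r[2] < hi
  if (!rng_ok(p_range, 0, 1)) stop("p_range must lie in (0, 1)", call. = FALSE)
  if (!rng_ok(sigma_range, 0, Inf)) stop("sigma_range must be positive", call. = FALSE)
  if (!rng_ok(k_range, 0, Inf)) stop("k_range must be positive", call. = FALSE)
  if (!rng_ok(q_range, 0, 1)) stop("q_range must lie in (0, 1)", call. = FALSE)
  if (!rng_ok(s_range, 1, Inf)) stop("s_range must lie in (1, Inf)", call. = FALSE)
  if (!(length(mu_range) == 2 && mu_range[1] <= mu_range[2])) {
    stop("mu_range must be an increasing pair", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites), families = families,
         S_range = S_range, p_range = p_range, mu_range = mu_range,
         sigma_range = sigma_range, k_range = k_range, q_range = q_range,
         s_range = s_range, seed = as.integer(seed)),
    class = "sad_synthetic_spec")
}

# counter-scheme sub-seed: deterministic in (master, counter), bounded
# below 2^31 so it is always a valid set.seed() argument
site_subseed <- function(master, i) {
  h <- (as.double(master) %% 65521)
  as.integer((h * 69621 + as.double(i) * 181081) %% 2147483562) + 1L
}

draw_site_params <- function(spec, family) {
  u <- function(r) stats::runif(1, r[1], r[2])
  switch(family,
    logseries = list(p = u(spec$p_range)),
    poisson_lognormal = list(mu = u(spec$mu_range), sigma = u(spec$sigma_range)),
    neg_binom = list(k = u(spec$k_range), q = u(spec$q_range)),
    zipf = list(s = u(spec$s_range)))
}

#' Generate a synthetic community collection with ground truth
#'
#' For each site: draw richness S (log-uniform), a generating family, and
#' its parameters from the specified ranges, then sample S abundances from
#' the zero-truncated distribution. The returned ground-truth table holds
#' the family, parameters, richness and the abundance sub-seed of every
#' site, so each site is independently reproducible via [sad_sample()].
#'
#' @param spec an `sad_synthetic_spec` from [synthetic_spec()].
#' @return List with `communities` (list of `sad_community`) and `truth`
#'   (data frame: site_id, family, S, par1_name, par1, par2_name, par2,
#'   design_seed, abundance_seed).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "sad_synthetic_spec"))
  communities <- vector("list", spec$n_sites)
  truth <- vector("list", spec$n_sites)
  for (i in seq_len(spec$n_sites)) {
    design_seed <- site_subseed(spec$seed, 2 * i - 1)
    abundance_seed <- site_subseed(spec$seed, 2 * i)
    set.seed(design_seed)
    S <- round(exp(stats::runif(1, log(spec$S_range[1]), log(spec$S_range[2]))))
    S <- max(S, 1)
    family <- if (length(spec$families) == 1) spec$families else
      sample(spec$families, 1)
    params <- draw_site_params(spec, family)
    ab <- sad_sample(family, params, S, seed = abundance_seed)
    sid <- sprintf("site_%04d", i)
    communities[[i]] <- community(ab, site_id = sid, dataset_id = family)
    pv <- unlist(params)
    truth[[i]] <- data.frame(
      site_id = sid, family = family, S = S,
      par1_name = names(pv)[1], par1 = pv[[1]],
      par2_name = if (length(pv) >= 2) names(pv)[2] else NA_character_,
      par2 = if (length(pv) >= 2) pv[[2]] else NA_real_,
      design_seed = design_seed, abundance_seed = abundance_seed,
      stringsAsFactors = FALSE)
  }
  list(communities = communities, truth = do.call(rbind, truth))
}

#' Write a synthetic collection to CSV files
#'
#' @param spec an `sad_synthetic_spec`.
#' @param communities_path output CSV of long-format abundances (readable
#'   by [read_communities()]).
#' @param truth_path optional output CSV of the ground-truth table.
#' @return The generated collection, invisibly.
#' @export
write_collection <- function(spec, communities_path, truth_path = NULL) {
  coll <- generate_collection(spec)
  long <- do.call(rbind, lapply(coll$communities, function(co) {
    data.frame(site_id = co$site_id,
               species_id = sprintf("sp_%04d", seq_len(co$S)),
               abundance = co$abundances,
               dataset_id = co$dataset_id,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, communities_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(coll$truth, truth_path, row.names = FALSE)
  }
  invisible(coll)
}

#' Model-selection and parameter recovery experiment
#'
#' Generates a collection from `spec`, runs the full fit-and-select chain,
#' and reports per generating family: parameter bias and RMSE (for the
#' matching fitted family), the proportion of sites where the generating
#' family is best by AICc, the proportion where it has the highest raw
#' log-likelihood, and its mean Akaike weight.
#'
#' @param spec an `sad_synthetic_spec`.
#' @param min_richness passed to [run_comparison()].
#' @return List with `report` (one row per generating family), `run` (the
#'   `sad_run`), and `truth`.
#' @export
recovery_experiment <- function(spec, min_richness = 4) {
  coll <- generate_collection(spec)
  run <- run_comparison(coll$communities, min_richness = min_richness)
  res <- run$results
  truth <- coll$truth

  report <- lapply(unique(truth$family), function(fam) {
    tr <- truth[truth$family == fam, , drop = FALSE]
    rr <- res[res$site_id %in% tr$site_id & res$included, , drop = FALSE]
    own <- rr[rr$family == fam, , drop = FALSE]
    m <- match(own$site_id, tr$site_id)
    err1 <- own$par1 - tr$par1[m]
    err2 <- own$par2 - tr$par2[m]
    sites <- unique(rr$site_id)
    best_fam <- vapply(sites, function(s) {
      g <- rr[rr$site_id == s, ]
      g$family[which.max(g$weight)]
    }, "")
    bestll_fam <- vapply(sites, function(s) {
      g <- rr[rr$site_id == s, ]
      g$family[which.max(g$loglik)]
    }, "")
    data.frame(
      family = fam,
      n_sites = length(sites),
      par1_bias = mean(err1), par1_rmse = sqrt(mean(err1^2)),
      par2_bias = mean(err2), par2_rmse = sqrt(mean(err2^2)),
      prop_best_aicc = mean(best_fam == fam),
      prop_best_loglik = mean(bestll_fam == fam),
      mean_weight = mean(own$weight),
      stringsAsFactors = FALSE)
  })
  list(report = do.call(rbind, report), run = run, truth = truth)
}
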