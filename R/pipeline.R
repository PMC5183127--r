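# End-to-end runner: read long-format community tables, fit and compare
# all candidate models per site, write per-site and summary tables.

#' Read communities from a long-format CSV
#'
#' Expects a UTF-8 CSV with header columns `site_id`, `species_id`,
#' `abundance`, and optionally `dataset_id` (defaulting to the file stem).
#' Each distinct `site_id` becomes one community. Abundances must be
#' strictly positive integers — a decimal or non-positive abundance is a
#' hard error naming the offending row — and duplicated
#' (site, species) pairs are rejected.
#'
#' @param path CSV file path.
#' @return List of `sad_community` objects (possibly empty, with a warning,
#'   for a header-only file).
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("site_id", "species_id", "abundance")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("no data rows in ", path)
    return(list())
  }
  if (!("dataset_id" %in% names(df))) {
    df$dataset_id <- tools::file_path_sans_ext(basename(path))
  }
  ab <- suppressWarnings(as.numeric(df$abundance))
  bad <- which(!is.finite(ab) | ab < 1 | ab != floor(ab))
  if (length(bad) > 0) {
    stop(sprintf("invalid abundance %s at row %d (site '%s', species '%s'): must be a positive integer",
                 df$abundance[bad[1]], bad[1], df$site_id[bad[1]],
                 df$species_id[bad[1]]), call. = FALSE)
  }
  key <- paste(df$site_id, df$species_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate (site, species) pair at row %d: ('%s', '%s')",
                 d, df$site_id[d], df$species_id[d]), call. = FALSE)
  }
  sites <- split(df, factor(df$site_id, levels = unique(df$site_id)))
  lapply(sites, function(g) {
    community(ab[match(paste(g$site_id, g$species_id, sep = "\r"), key)],
              site_id = g$site_id[1], dataset_id = g$dataset_id[1],
              species_id = g$species_id)
  })
}

#' Fit and compare all models across a collection of communities
#'
#' The workhorse of the package: for every community, fits the selected
#' families by maximum likelihood, computes AICc, AICc differences and
#' Akaike weights, flags the best model, and assembles dataset-level
#' summaries (the tabular equivalents of best-model counts, weight
#' distributions, and per-site log-likelihood deviations). Fitting is
#' deterministic, so a rerun on the same input reproduces the output
#' byte for byte.
#'
#' @param input path to a communities CSV (see [read_communities()]), or a
#'   list of `sad_community` objects.
#' @param output_dir optional directory; when given, writes
#'   `site_results.csv` (one row per site x family), `best_model_counts.csv`,
#'   `loglik_deviations.csv`, `exclusions.csv` and `run_metadata.json`.
#' @param seed integer recorded in the run metadata (fitting itself uses no
#'   randomness).
#' @param min_richness smallest S eligible for model selection (default 4,
#'   see [compare_site()]).
#' @param families subset of `sad_families()` to compare.
#' @return An `sad_run`: list with `results` (per site x family data
#'   frame), `best_counts`, `deviations`, `exclusions`, `config`.
#' @examples
#' cos <- list(community(c(5, 2, 1, 1, 9), site_id = "a"),
#'             community(c(50, 20, 10, 4, 2, 1, 1, 1), site_id = "b"))
#' run <- run_comparison(cos)
#' run$best_counts
#' @export
run_comparison <- function(input, output_dir = NULL, seed = NULL,
                           min_richness = 4, families = sad_families()) {
  communities <- if (is.character(input)) read_communities(input) else input
  stopifnot(is.list(communities))
  families <- match.arg(families, sad_families(), several.ok = TRUE)

  rows <- list()
  devs <- list()
  excl <- list()
  for (co in communities) {
    co <- as_community(co)
    fits <- fit_all(co, families = families)
    cmp <- compare_site(fits, site_id = co$site_id, dataset_id = co$dataset_id,
                        min_richness = min_richness)
    tab <- cmp$table
    pars <- lapply(fits, function(f) unlist(f$params))
    rows[[length(rows) + 1]] <- data.frame(
      site_id = co$site_id,
      dataset_id = co$dataset_id,
      S = co$S,
      family = tab$family,
      par1 = vapply(pars, function(p) if (length(p) >= 1) p[[1]] else NA_real_, 0),
      par2 = vapply(pars, function(p) if (length(p) >= 2) p[[2]] else NA_real_, 0),
      loglik = tab$loglik,
      K = tab$K,
      aicc = tab$aicc,
      delta_aicc = tab$delta_aicc,
      weight = tab$weight,
      best = tab$best,
      tie = tab$tie,
      converged = vapply(fits, function(f) isTRUE(f$converged), TRUE),
      at_boundary = vapply(fits, function(f) isTRUE(f$at_boundary), TRUE),
      included = tab$included,
      reason = tab$reason,
      stringsAsFactors = FALSE
    )
    if (cmp$excluded) {
      excl[[length(excl) + 1]] <- data.frame(
        site_id = co$site_id, dataset_id = co$dataset_id, S = co$S,
        reason = cmp$exclude_reason, stringsAsFactors = FALSE)
    }
    dv <- loglik_deviation(fits)
    if (all(is.finite(dv))) {
      devs[[length(devs) + 1]] <- data.frame(
        site_id = co$site_id, dataset_id = co$dataset_id,
        family = names(dv), deviation = unname(dv), stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(site_id = character(0))
  rownames(results) <- NULL
  deviations <- if (length(devs) > 0) do.call(rbind, devs) else
    data.frame(site_id = character(0))
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(site_id = character(0), reason = character(0))
  best_counts <- summarize_best_models(results)

  run <- structure(
    list(results = results, best_counts = best_counts,
         deviations = deviations, exclusions = exclusions,
         config = list(seed = seed, min_richness = min_richness,
                       families = families,
                       package_version = as.character(utils::packageVersion("sadcompare")))),
    class = "sad_run")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(output_dir, "site_results.csv"),
                     row.names = FALSE)
    utils::write.csv(best_counts, file.path(output_dir, "best_model_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(deviations, file.path(output_dir, "loglik_deviations.csv"),
                     row.names = FALSE)
    utils::write.csv(exclusions, file.path(output_dir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run$config, file.path(output_dir, "run_metadata.json"),
                         auto_unbox = TRUE, null = "null")
  }
  run
}

#' Best-model counts and proportions per dataset
#'
#' Tallies, for each dataset and overall (`dataset_id = "all"`), how often
#' each family was the best-fitting model by AICc among included sites.
#' Proportions within a dataset sum to 1; excluded sites are omitted from
#' the denominators.
#'
#' @param results per site x family data frame from [run_comparison()]
#'   (`$results`), or an `sad_run`.
#' @return Data frame with columns `dataset_id`, `family`, `n_best`,
#'   `n_sites`, `proportion`.
#' @export
summarize_best_models <- function(results) {
  if (inherits(results, "sad_run")) results <- results$results
  if (nrow(results) == 0 || !any(results$included)) {
    warning("no included sites to summarize")
    return(data.frame(dataset_id = character(0), family = character(0),
                      n_best = integer(0), n_sites = integer(0),
                      proportion = numeric(0)))
  }
  inc <- results[results$included, , drop = FALSE]
  one <- function(df, label) {
    sites <- unique(df$site_id)
    n_best <- vapply(sad_families(), function(fam) {
      sum(df$best[df$family == fam])
    }, 0L + 0)
    data.frame(dataset_id = label, family = sad_families(),
               n_best = as.integer(n_best), n_sites = length(sites),
               proportion = n_best / length(sites),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  parts <- lapply(split(inc, inc$dataset_id), function(df) one(df, df$dataset_id[1]))
  out <- rbind(one(inc, "all"), do.call(rbind, unname(parts)))
  rownames(out) <- NULL
  out
}

#' @export
print.sad_run <- function(x, ...) {
  n_sites <- length(unique(x$results$site_id))
  cat(sprintf("<sad_run> %d sites, %d excluded\n", n_sites, nrow(x$exclusions)))
  print(x$best_counts[x$best_counts$dataset_id == "all", ], row.names = FALSE)
  invisible(x)
}
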