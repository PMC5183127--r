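#' Construct a community (one site's abundance vector)
#'
#' A community is the unit of fitting: the vector of abundances (counts of
#' individuals) of the S species observed at one site.
#'
#' @param abundances vector of positive integer counts, one per species.
#' @param site_id opaque site label.
#' @param dataset_id opaque dataset label (used for per-dataset summaries).
#' @param species_id optional species labels (same length as `abundances`).
#' @return An object of class `sad_community` with elements `site_id`,
#'   `dataset_id`, `abundances`, `species_id`, and `S` (species richness).
#' @export
community <- function(abundances, site_id = "site", dataset_id = "dataset",
                      species_id = NULL) {
  abundances <- check_abundance(abundances)
  if (!is.null(species_id) && length(species_id) != length(abundances)) {
    stop("species_id must match abundances in length", call. = FALSE)
  }
  structure(
    list(site_id = as.character(site_id),
         dataset_id = as.character(dataset_id),
         abundances = abundances,
         species_id = species_id,
         S = length(abundances)),
    class = "sad_community"
  )
}

#' @export
print.sad_community <- function(x, ...) {
  cat(sprintf("<sad_community> site '%s' (dataset '%s'): S = %d species, N = %d individuals\n",
              x$site_id, x$dataset_id, x$S, sum(x$abundances)))
  invisible(x)
}

as_community <- function(x) {
  if (inherits(x, "sad_community")) return(x)
  community(x)
}
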