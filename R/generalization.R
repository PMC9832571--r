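#' Per-nest pollen proportions
#'
#' Grain counts of one nest (pooled over all counted microscope fields)
#' normalized to proportions. The proportion removes the effect of the
#' total number of grains counted per nest, giving a standardized measure
#' of plant abundance per nest.
#'
#' @param grain_counts named non-negative numeric vector: plant taxon ->
#'   grain count for one nest.
#' @return named numeric vector of proportions summing to 1.
#' @export
nest_pollen_proportions <- function(grain_counts) {
  if (length(grain_counts) == 0 || is.null(names(grain_counts)))
    md_contract_error("grain_counts must be a named vector")
  if (anyNA(grain_counts) || any(grain_counts < 0))
    md_validation_error("grain counts must be non-negative")
  total <- sum(grain_counts)
  if (total <= 0)
    md_validation_error("all grain counts zero for this nest")
  grain_counts / total
}

#' Summed standardized abundance across nests
#'
#' Sums each plant taxon's per-nest proportion over all examined nests of
#' a bee species; the result totals the number of nests and is the
#' abundance measure from which both the Shannon generalization score and
#' the main-resource set are derived.
#'
#' @param per_nest list of named proportion vectors (one per nest).
#' @return named numeric vector: plant taxon -> summed proportion.
#' @export
species_abundance_across_nests <- function(per_nest) {
  if (length(per_nest) == 0)
    md_contract_error("at least one nest is required")
  stacked <- unlist(lapply(per_nest, function(p) p))
  taxa <- unlist(lapply(per_nest, names))
  out <- tapply(stacked, taxa, sum)
  setNames(as.numeric(out), names(out))
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over relative abundances, with zero
#' abundances contributing nothing. Used here as a diet-generalization
#' score: H = 0 for a strict monolectic diet, H = log(k) for a uniform
#' diet over k plant taxa.
#'
#' @param abundances non-negative numeric vector (need not be normalized).
#' @param base logarithm base; natural log by default.
#' @return non-negative numeric scalar.
#' @export
shannon_index <- function(abundances, base = exp(1)) {
  if (anyNA(abundances) || any(abundances < 0))
    md_validation_error("abundances must be non-negative")
  total <- sum(abundances)
  if (total <= 0)
    md_validation_error("all abundances zero: Shannon index undefined")
  p <- abundances[abundances > 0] / total
  -sum(p * log(p, base = base))
}

#' Diet generalization scores for all bee species
#'
#' For each bee species: normalize each examined nest's pollen grain
#' counts to proportions, sum those proportions across nests, and take the
#' Shannon diversity of the summed abundances.
#'
#' @param pollen validated pollen-sample table.
#' @param nests validated nest-record table (maps nest ids to bee taxa).
#' @param base logarithm base for [shannon_index()].
#' @return data.frame with `bee_taxon`, `shannon_h`, `n_nests` (nests with
#'   pollen data), sorted by `bee_taxon`.
#' @export
generalization_scores <- function(pollen, nests, base = exp(1)) {
  taxa <- sort(unique(nests$bee_taxon[nests$nest_id %in% pollen$nest_id]))
  if (length(taxa) == 0)
    md_contract_error("no pollen samples match any nest record")
  rows <- lapply(taxa, function(bt) {
    totals <- species_pollen_totals(pollen, nests, bt)
    data.frame(bee_taxon = bt,
               shannon_h = shannon_index(totals, base = base),
               n_nests = round(sum(totals)))
  })
  do.call(rbind, rows)
}
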