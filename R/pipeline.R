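#' Run the full SPN discovery pipeline on one cohort
#'
#' Convenience driver: z-score the expression matrix, run the greedy
#' search from every seed gene, BH-adjust the subnetwork p-values,
#' build the three permutation nulls, and filter the primary
#' subnetworks into SPNs. Patients are then clustered on the SPN
#' activity matrix and labeled good/poor outcome.
#'
#' @param expression genes x samples matrix (one proliferation tertile's
#'   cohort, typically).
#' @param network an `interaction_network`.
#' @param survival survival annotation.
#' @param config [search_config()].
#' @param null_trials permutation trials per null variant (0 skips the
#'   permutation filter and keeps all primary subnetworks).
#' @param seed master integer seed for the permutation streams.
#' @param quantile_prob null-threshold quantile.
#' @return List of class `spn_pipeline_result`: `pns` (all primary
#'   subnetworks, FDR-adjusted), `spns` (the survivors), `nulls`,
#'   `activity` (SPN activity matrix), `stratification` (clustered and
#'   outcome-labeled patients with log-rank statistics), `z`.
#'   `stratification` is `NULL` when no SPN survives.
#' @export
discover_spns <- function(expression, network, survival,
                          config = search_config(), null_trials = 50L,
                          seed = 1L, quantile_prob = 0.95) {
  z <- suppressWarnings(zscore_expression(expression))
  pns <- fdr_adjust(greedy_search(z, network, survival, config))
  nulls <- NULL
  spns <- pns
  if (null_trials > 0L && length(pns) > 0L) {
    variants <- c("gene-label", "within-gene-expression", "survival-time")
    nulls <- lapply(seq_along(variants), function(i) {
      build_null(expression, network, survival, variants[i],
                 n_trials = null_trials, config = config,
                 seed = (seed + 1009L * i) %% .Machine$integer.max,
                 quantile_prob = quantile_prob)
    })
    spns <- filter_spns(pns, nulls)
  }
  activity <- NULL
  strat <- NULL
  if (length(spns) > 0L) {
    activity <- build_activity_matrix(z, spns)
    if (ncol(activity) >= 2L && any(dist(t(activity)) > 0)) {
      strat <- label_outcome(cluster_patients(activity), survival)
    }
  }
  structure(list(pns = pns, spns = spns, nulls = nulls,
                 activity = activity, stratification = strat, z = z),
            class = "spn_pipeline_result")
}

#' Jaccard similarity of two gene sets
#'
#' @param a,b character vectors.
#' @return |intersection| / |union|.
#' @export
jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Best Jaccard recovery of planted sets among top subnetworks
#'
#' For each planted gene set, the maximum Jaccard similarity achieved
#' by any of the `top_n` highest-scoring subnetworks.
#'
#' @param spns `subnetwork_list` (sorted by descending S).
#' @param planted list of planted gene sets.
#' @param top_n number of top subnetworks considered.
#' @return Numeric vector, one value per planted set.
#' @export
recovery_jaccard <- function(spns, planted, top_n = 10L) {
  top <- head(spns, top_n)
  vapply(planted, function(truth) {
    if (length(top) == 0L) return(0)
    max(vapply(top, function(s) jaccard(s$members, truth), numeric(1L)))
  }, numeric(1L))
}
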