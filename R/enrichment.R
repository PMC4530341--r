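#' Fisher's exact gene-set enrichment of a subnetwork
#'
#' One-sided (over-representation) Fisher's exact test of the overlap
#' between a subnetwork's members and each gene set, against a fixed
#' background universe: raw_p = P[X >= k] under the hypergeometric
#' distribution with the set intersected with the background. P-values
#' are Bonferroni-corrected over the number of sets tested for the
#' subnetwork; a set is enriched when the adjusted p is below
#' `alpha`.
#'
#' @param members character vector of the subnetwork's gene ids (must
#'   lie in `background`).
#' @param sets a `gene_set_collection` (see [read_gmt()]) or named list
#'   of character vectors.
#' @param background character vector: the gene universe (e.g. genes
#'   present in both the expression matrix and the network).
#' @param alpha adjusted-p enrichment cutoff.
#' @return data.frame with one row per set: `set`, `overlap` (k),
#'   `spn_size` (n), `set_size` (K), `background_size` (N),
#'   `odds_ratio`, `raw_p`, `adjusted_p`, `enriched`; sorted by
#'   `adjusted_p`.
#' @export
fisher_enrich <- function(members, sets, background, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background universe")
  members <- intersect(unique(members), background)
  if (length(members) == 0L) stop("no subnetwork member lies in the background")
  N <- length(background)
  n <- length(members)
  res <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], background)
    K <- length(set)
    k <- length(intersect(members, set))
    raw_p <- if (K == 0L) 1 else
      phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    or <- odds_ratio(k, n, K, N)
    data.frame(set = nm, overlap = k, spn_size = n, set_size = K,
               background_size = N, odds_ratio = or, raw_p = raw_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  m <- nrow(out)
  out$adjusted_p <- pmin(1, out$raw_p * m)
  out$enriched <- out$adjusted_p < alpha
  out[order(out$adjusted_p, out$set), , drop = FALSE]
}

# sample odds ratio of the 2x2 overlap table (Inf when a margin is
# degenerate in the enriched direction)
odds_ratio <- function(k, n, K, N) {
  a <- k
  b <- n - k
  c_ <- K - k
  d <- N - n - K + k
  if (b == 0L || c_ == 0L) return(Inf)
  (a * d) / (b * c_)
}

#' Enrichment matrix over a list of subnetworks
#'
#' @param spns `subnetwork_list`.
#' @param sets gene-set collection.
#' @param background gene universe.
#' @param alpha adjusted-p cutoff.
#' @return Logical matrix (subnetworks x sets): `TRUE` where the set is
#'   enriched in the subnetwork after Bonferroni correction.
#' @export
enrichment_matrix <- function(spns, sets, background, alpha = 0.05) {
  mat <- t(vapply(seq_along(spns), function(i) {
    res <- fisher_enrich(spns[[i]]$members, sets, background, alpha)
    res$enriched[match(names(sets), res$set)]
  }, logical(length(sets))))
  if (length(sets) == 1L) mat <- matrix(mat, ncol = 1L)
  dimnames(mat) <- list(sprintf("SPN%d", seq_along(spns)), names(sets))
  mat
}
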