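#' Permute a dataset for a null model
#'
#' Three null variants, each destroying one link the discovery pipeline
#' exploits while conserving the expression value multiset:
#' \describe{
#'   \item{gene-label}{row identifiers of the expression matrix are
#'     randomly reassigned to rows; the network is untouched, so the
#'     mapping between network positions and expression profiles is
#'     broken.}
#'   \item{within-gene-expression}{each gene's values are independently
#'     permuted across samples, breaking gene-gene co-expression and
#'     the expression-survival link.}
#'   \item{survival-time}{the (time, event) pairs are permuted jointly
#'     across samples.}
#' }
#' Uses the current RNG state.
#'
#' @param expression genes x samples matrix.
#' @param survival survival annotation data.frame.
#' @param variant one of `"gene-label"`, `"within-gene-expression"`,
#'   `"survival-time"`.
#' @return List with permuted `expression` and `survival`.
#' @export
permute_dataset <- function(expression, survival,
                            variant = c("gene-label",
                                        "within-gene-expression",
                                        "survival-time")) {
  variant <- match.arg(variant)
  expr <- expression
  surv <- survival
  if (variant == "gene-label") {
    rownames(expr) <- rownames(expr)[sample.int(nrow(expr))]
    expr <- expr[order(rownames(expr)), , drop = FALSE]
  } else if (variant == "within-gene-expression") {
    for (i in seq_len(nrow(expr))) {
      expr[i, ] <- expr[i, sample.int(ncol(expr))]
    }
  } else {
    perm <- sample.int(nrow(surv))
    surv$time <- surv$time[perm]
    surv$event <- surv$event[perm]
  }
  list(expression = expr, survival = surv)
}

#' Build a permutation null distribution of adjusted S scores
#'
#' Runs the full primary-subnetwork discovery (z-score, greedy search,
#' FDR adjustment) on `n_trials` independently permuted datasets and
#' pools all adjusted S scores into one null background; the threshold
#' is the empirical 95% quantile (linear interpolation). A trial that
#' yields no subnetwork contributes a score of 0. Trial RNG streams are
#' derived from `seed` by trial index so trials are reproducible
#' individually.
#'
#' @param expression genes x samples matrix (unpermuted).
#' @param network an `interaction_network`.
#' @param survival survival annotation.
#' @param variant null variant, see [permute_dataset()].
#' @param n_trials number of permutation trials.
#' @param config [search_config()] for the per-trial searches.
#' @param seed master integer seed for the trial streams.
#' @param quantile_prob quantile defining the threshold.
#' @return List of class `permutation_null`: `variant`, `n_trials`,
#'   `null_scores`, `threshold`.
#' @export
build_null <- function(expression, network, survival, variant,
                       n_trials = 50L, config = search_config(),
                       seed = 1L, quantile_prob = 0.95) {
  stopifnot(n_trials >= 1L)
  scores <- numeric(0)
  for (trial in seq_len(n_trials)) {
    set.seed((seed + 7919L * trial) %% .Machine$integer.max)
    perm <- permute_dataset(expression, survival, variant)
    z <- suppressWarnings(zscore_expression(perm$expression))
    pns <- fdr_adjust(greedy_search(z, network, perm$survival, config))
    trial_scores <- if (length(pns) == 0L) 0 else
      vapply(pns, `[[`, numeric(1L), "adjusted_s")
    scores <- c(scores, trial_scores)
  }
  structure(list(variant = variant, n_trials = n_trials,
                 null_scores = scores,
                 threshold = unname(quantile(scores, quantile_prob,
                                             type = 7))),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null (%s): %d trials, %d pooled scores, 95%% threshold %.3f\n",
              x$variant, x$n_trials, length(x$null_scores), x$threshold))
  invisible(x)
}

#' Filter primary subnetworks into SPNs
#'
#' A primary subnetwork survives when its FDR-adjusted S score strictly
#' exceeds the thresholds of all three permutation nulls (gene-label,
#' within-gene-expression, survival-time). Input order is preserved.
#'
#' @param pns `subnetwork_list` with `adjusted_s` filled (see
#'   [fdr_adjust()]).
#' @param nulls list of three `permutation_null` objects, one per
#'   variant.
#' @return The surviving subnetworks, class `subnetwork_list`.
#' @export
filter_spns <- function(pns, nulls) {
  variants <- vapply(nulls, `[[`, character(1L), "variant")
  need <- c("gene-label", "within-gene-expression", "survival-time")
  if (!setequal(variants, need))
    stop("need exactly the three null variants: ",
         paste(need, collapse = ", "))
  thresholds <- vapply(nulls, `[[`, numeric(1L), "threshold")
  keep <- vapply(pns, function(s) {
    if (is.null(s$adjusted_s)) stop("run fdr_adjust() before filter_spns()")
    all(s$adjusted_s > thresholds)
  }, logical(1L))
  structure(pns[keep], class = "subnetwork_list")
}
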