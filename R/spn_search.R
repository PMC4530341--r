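#' Row-wise z-score transform of an expression matrix
#'
#' Each gene's values g_ij are transformed to z_ij = (g_ij - u_i) / s_i,
#' where u_i and s_i are the gene's mean and (n-1 denominator) standard
#' deviation across the samples in scope. Genes with zero variance carry
#' no information for the activity score and are dropped with a warning.
#'
#' @param expr numeric genes x samples matrix.
#' @return Matrix of the same shape (minus dropped constant rows) with
#'   row means 0 and row standard deviations 1.
#' @export
zscore_expression <- function(expr) {
  validate_expression(expr)
  sdv <- apply(expr, 1L, sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (all(const)) stop("all genes are constant; cannot z-score")
  if (any(const)) {
    warning(sprintf("dropping %d constant gene(s): %s", sum(const),
                    paste(head(rownames(expr)[const], 5L), collapse = ", ")))
    expr <- expr[!const, , drop = FALSE]
    sdv <- sdv[!const]
  }
  (expr - rowMeans(expr)) / sdv
}

#' Subnetwork activity
#'
#' The activity of a gene set in patient j is the mean of the members'
#' z-scores, x_j = mean_i z_ij. This is the Cox covariate the search
#' optimises.
#'
#' @param z z-scored expression matrix from [zscore_expression()].
#' @param members character vector of member gene ids.
#' @return Named per-sample numeric vector.
#' @export
subnetwork_activity <- function(z, members) {
  missing <- setdiff(members, rownames(z))
  if (length(missing) > 0L)
    stop("gene(s) absent from the z-score matrix: ",
         paste(missing, collapse = ", "))
  colMeans(z[members, , drop = FALSE])
}

#' Cox proportional-hazards score of an activity vector
#'
#' Fits the single-covariate model H(t)/H0(t) = exp(beta * x) by
#' partial-likelihood maximisation (Efron handling of ties) and scores
#' it with the likelihood-ratio chi-square test (1 df). The score is
#' S = -ln(p). A constant covariate is degenerate: S = 0, p = 1,
#' beta = 0. Monotone-likelihood divergence is capped at |beta| <= 20
#' with a warning.
#'
#' @param x per-sample activity values.
#' @param time survival times (> 0).
#' @param event 0/1 event indicators; at least 2 events required.
#' @return List with `beta`, `chisq`, `raw_p`, `score_s`.
#' @export
cox_score <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  event <- as.integer(event)
  if (sum(event) == 0L) stop("no events in the survival data")
  if (var(x) == 0) {
    message("constant activity covariate: degenerate Cox score")
    return(list(beta = 0, chisq = 0, raw_p = 1, score_s = 0))
  }
  ord <- order(time)
  fit <- cox_lrt1(as.numeric(x[ord]), as.numeric(time[ord]), event[ord])
  if (fit[3L] > 0)
    warning("monotone likelihood: beta capped at |beta| <= 20")
  s <- chisq_to_score(fit[2L])
  list(beta = fit[1L], chisq = fit[2L], raw_p = exp(-s), score_s = s)
}

# S = -ln(upper-tail chi-square(1) p), computed on the log scale so very
# significant subnetworks do not underflow to p = 0 prematurely
chisq_to_score <- function(chisq) {
  -pchisq(chisq, df = 1L, lower.tail = FALSE, log.p = TRUE)
}

#' Greedy-search configuration
#'
#' @param max_size maximum subnetwork size the search may grow to.
#' @param min_report_size smallest subnetwork size reported.
#' @param min_delta_s minimum improvement in score S for a move to be
#'   accepted. Because S = -ln(p), the default of 2 demands that every
#'   added or deleted gene improve the Cox evidence by a factor
#'   exp(2) ~ 7.4 in p-value. A meaningful evidence threshold is needed
#'   because each step selects the best of a large candidate frontier:
#'   with a near-zero threshold the maximum of many chance fluctuations
#'   is always "an improvement" and the search inflates subnetworks to
#'   `max_size` with passenger genes.
#' @param min_rel_improve optional additional requirement that an
#'   accepted addition improve S by this fraction of the current score
#'   (0 disables; greedy subnetwork searches in this field sometimes
#'   use an improvement rate of ~0.05).
#' @param enforce_connectivity whether the deletion step must leave the
#'   member set connected in the network.
#' @param keep_trace record the accepted move sequence per seed.
#' @return List of class `search_config`.
#' @export
search_config <- function(max_size = 20L, min_report_size = 2L,
                          min_delta_s = 2, min_rel_improve = 0,
                          enforce_connectivity = TRUE,
                          keep_trace = FALSE) {
  stopifnot(max_size >= 2L, min_report_size <= max_size, min_delta_s > 0,
            min_rel_improve >= 0)
  structure(list(max_size = as.integer(max_size),
                 min_report_size = as.integer(min_report_size),
                 min_delta_s = min_delta_s,
                 min_rel_improve = min_rel_improve,
                 enforce_connectivity = isTRUE(enforce_connectivity),
                 keep_trace = isTRUE(keep_trace)),
            class = "search_config")
}

#' Greedy search for primary subnetworks
#'
#' Every gene present in both the z-score matrix and the network serves
#' once as the initiating seed. From the current member set the search
#' repeatedly (a) scores the addition of every network neighbour and
#' accepts the one yielding the maximal increase of score S, then (b)
#' after each accepted addition, repeatedly scores the removal of each
#' member whose removal leaves the set connected, performing the single
#' removal that most increases S, until no removal improves. The search
#' stops when no addition improves S by more than `min_delta_s` (and by
#' the relative margin `min_rel_improve`) or `max_size` is reached. Results of size >= `min_report_size` are
#' deduplicated by member set (first-found kept, seeds visited in
#' lexicographic order) and returned sorted by descending S.
#'
#' Ties in candidate score are broken by the lexicographically smallest
#' gene id, making the search deterministic.
#'
#' @param z z-scored expression matrix.
#' @param network an `interaction_network`.
#' @param survival survival annotation data.frame (`sample_id`, `time`,
#'   `event`) covering the z-score matrix's samples.
#' @param config a [search_config()].
#' @return List of primary subnetworks, each a list with `members`
#'   (sorted), `seed`, `raw_p`, `score_s`, `beta`, `adjusted_p` (NA
#'   until [fdr_adjust()]); class `subnetwork_list`. When
#'   `config$keep_trace`, each element carries a `trace` of accepted
#'   move scores.
#' @export
greedy_search <- function(z, network, survival, config = search_config()) {
  samples <- intersect(colnames(z), survival$sample_id)
  if (length(samples) < 10L) stop("need >= 10 samples shared by z and survival")
  genes <- sort(intersect(rownames(z), network$nodes))
  if (length(genes) < 2L)
    stop("z-score matrix and network share fewer than 2 genes")
  surv <- survival[match(samples, survival$sample_id), ]
  ord <- order(surv$time)
  time_s <- as.numeric(surv$time[ord])
  event_s <- as.integer(surv$event[ord])
  if (sum(event_s) < 2L) stop("need >= 2 events")
  zs <- z[, samples, drop = FALSE][, ord, drop = FALSE]

  score_cols <- function(act) {
    # act: n x k matrix of candidate activities (already in sorted order)
    fit <- cox_lrt_cols(act, time_s, event_s)
    list(beta = fit[, 1L], s = chisq_to_score(fit[, 2L]))
  }

  found <- list()
  seen_keys <- character()
  for (seed in genes) {
    res <- grow_from_seed(seed, zs, network, genes, score_cols, config)
    if (length(res$members) < config$min_report_size) next
    key <- paste(sort(res$members), collapse = "|")
    if (key %in% seen_keys) next
    seen_keys <- c(seen_keys, key)
    sn <- list(members = sort(res$members), seed = seed,
               raw_p = exp(-res$score_s), score_s = res$score_s,
               beta = res$beta, adjusted_p = NA_real_)
    if (config$keep_trace) sn$trace <- res$trace
    found[[length(found) + 1L]] <- sn
  }
  keys <- vapply(found, function(s) paste(s$members, collapse = "|"), "")
  svals <- vapply(found, `[[`, numeric(1L), "score_s")
  found <- found[order(-svals, keys)]
  structure(found, class = "subnetwork_list")
}

# one greedy trajectory; returns members, score, beta, trace
grow_from_seed <- function(seed, zs, network, genes, score_cols, config) {
  n <- ncol(zs)
  members <- seed
  cur_sum <- zs[seed, ]
  fit0 <- score_cols(matrix(cur_sum, ncol = 1L))
  cur_s <- fit0$s[1L]
  cur_beta <- fit0$beta[1L]
  tracing <- isTRUE(config$keep_trace)
  trace <- if (tracing)
    data.frame(move = "init", gene = seed, score_s = cur_s,
               stringsAsFactors = FALSE)

  repeat {
    m <- length(members)
    if (m >= config$max_size) break
    cand <- intersect(network_neighbors(network, members), genes)
    if (length(cand) == 0L) break
    act <- (t(zs[cand, , drop = FALSE]) + cur_sum) / (m + 1)
    fit <- score_cols(act)
    best_s <- max(fit$s)
    if (!(best_s > cur_s + config$min_delta_s &&
          best_s > cur_s * (1 + config$min_rel_improve))) break
    pick <- which(fit$s == best_s)
    pick <- pick[order(cand[pick])][1L]
    gene <- cand[pick]
    members <- c(members, gene)
    cur_sum <- cur_sum + zs[gene, ]
    cur_s <- best_s
    cur_beta <- fit$beta[pick]
    if (tracing)
      trace <- rbind(trace, data.frame(move = "add", gene = gene,
                                       score_s = cur_s))

    # deletion phase: single best removal at a time while S improves
    repeat {
      m <- length(members)
      if (m < 2L) break
      removable <- members
      if (config$enforce_connectivity && m > 2L) {
        keep <- vapply(removable, function(g) {
          is_connected_subset(network, setdiff(members, g))
        }, logical(1L))
        removable <- removable[keep]
      }
      if (length(removable) == 0L) break
      act <- (cur_sum - t(zs[removable, , drop = FALSE])) / (m - 1)
      fit <- score_cols(act)
      best_s <- max(fit$s)
      if (!(best_s > cur_s + config$min_delta_s)) break
      pick <- which(fit$s == best_s)
      pick <- pick[order(removable[pick])][1L]
      gene <- removable[pick]
      members <- setdiff(members, gene)
      cur_sum <- cur_sum - zs[gene, ]
      cur_s <- best_s
      cur_beta <- fit$beta[pick]
      if (tracing)
        trace <- rbind(trace, data.frame(move = "delete", gene = gene,
                                         score_s = cur_s))
    }
  }
  list(members = members, score_s = cur_s, beta = cur_beta, trace = trace)
}

#' Benjamini-Hochberg adjustment of primary subnetwork p-values
#'
#' Fills `adjusted_p` by the BH step-up over the raw p-values
#' (p = exp(-S)) and records the adjusted score -ln(adjusted_p) as
#' `adjusted_s`.
#'
#' @param pns `subnetwork_list` from [greedy_search()].
#' @return The list with `adjusted_p` and `adjusted_s` filled.
#' @export
fdr_adjust <- function(pns) {
  if (length(pns) == 0L) return(pns)
  raw <- vapply(pns, `[[`, numeric(1L), "raw_p")
  adj <- p.adjust(raw, method = "BH")
  for (i in seq_along(pns)) {
    pns[[i]]$adjusted_p <- adj[i]
    pns[[i]]$adjusted_s <- -log(adj[i])
  }
  pns
}

#' @export
print.subnetwork_list <- function(x, ...) {
  cat(sprintf("subnetwork_list: %d subnetworks\n", length(x)))
  for (i in seq_len(min(length(x), 10L))) {
    s <- x[[i]]
    cat(sprintf("  [%d] S = %.3f (p = %.3g, beta = %.3f, %d genes): %s\n",
                i, s$score_s, s$raw_p, s$beta, length(s$members),
                paste(head(s$members, 8L), collapse = ", ")))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}
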