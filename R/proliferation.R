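#' Proliferation metagene score
#'
#' Per-sample mean expression of the metagene's member genes. Metagene
#' genes absent from the matrix are skipped with a warning; if none are
#' present that is an error.
#'
#' @param expr genes x samples expression matrix.
#' @param metagene character vector of metagene gene ids.
#' @return Named per-sample numeric vector.
#' @export
metagene_score <- function(expr, metagene) {
  present <- intersect(metagene, rownames(expr))
  if (length(present) == 0L)
    stop("none of the metagene genes are present in the expression matrix")
  missing <- setdiff(metagene, present)
  if (length(missing) > 0L)
    warning(sprintf("%d metagene gene(s) absent, skipped: %s",
                    length(missing),
                    paste(head(missing, 5L), collapse = ", ")))
  colMeans(expr[present, , drop = FALSE])
}

#' Partition samples into proliferation tertiles
#'
#' Ranked-split mode sorts samples by metagene score and cuts them into
#' three equal-as-possible groups (top third = high); this reproduces
#' exactly equal group sizes. Hierarchical mode clusters samples by
#' average-linkage Euclidean clustering on the metagene submatrix, cuts
#' the dendrogram into 3 clusters and labels them high/inter/low by
#' descending mean metagene score. Ties in score are broken by sample
#' id, so the split is invariant to input column order.
#'
#' @param expr genes x samples expression matrix.
#' @param metagene metagene gene ids.
#' @param mode `"ranked-split"` (default) or `"hierarchical"`.
#' @return data.frame with columns `sample_id`, `label` (factor
#'   high/inter/low) and `metagene_score`; class `tertile_assignment`.
#' @export
assign_tertiles <- function(expr, metagene,
                            mode = c("ranked-split", "hierarchical")) {
  mode <- match.arg(mode)
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 samples to form tertiles")
  score <- metagene_score(expr, metagene)
  ids <- colnames(expr)
  if (mode == "ranked-split") {
    ord <- order(-score, ids)
    base <- n %/% 3L
    sizes <- rep(base, 3L)
    extra <- n %% 3L
    if (extra >= 1L) sizes[1L] <- sizes[1L] + 1L
    if (extra >= 2L) sizes[2L] <- sizes[2L] + 1L
    lab <- character(n)
    lab[ord] <- rep(c("high", "inter", "low"), times = sizes)
  } else {
    present <- intersect(metagene, rownames(expr))
    sub <- t(expr[present, , drop = FALSE])
    hc <- hclust(dist(sub, method = "euclidean"), method = "average")
    cl <- cutree(hc, k = 3L)
    cl_means <- tapply(score, cl, mean)
    rank_lab <- c("high", "inter", "low")[rank(-cl_means, ties.method = "first")]
    lab <- rank_lab[cl]
  }
  out <- data.frame(sample_id = ids,
                    label = factor(lab, levels = c("high", "inter", "low")),
                    metagene_score = unname(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("tertile_assignment", "data.frame")
  out
}

#' Train a nearest shrunken centroid tertile classifier
#'
#' Standard shrunken-centroid fit on the metagene submatrix: per-class
#' centroids, pooled within-class standard deviation s_i plus the
#' median(s_i) fudge term s0, and soft-thresholding of the standardized
#' centroid differences d_ik by `delta`. At `delta = 0` the shrunken
#' centroids equal the raw class means.
#'
#' @param expr genes x samples expression matrix (training cohort).
#' @param metagene metagene gene ids (the classifier's feature space).
#' @param labels a `tertile_assignment` (or data.frame with `sample_id`
#'   and `label`) covering the samples.
#' @param delta shrinkage threshold, >= 0.
#' @return List of class `nsc_model`: `genes`, `classes`, `overall`
#'   (overall centroid), `centroids` (genes x classes shrunken),
#'   `s` (pooled sd), `s0`, `delta`, `priors`.
#' @export
nsc_train <- function(expr, metagene, labels, delta = 0) {
  stopifnot(delta >= 0)
  present <- intersect(metagene, rownames(expr))
  if (length(present) == 0L) stop("no metagene genes in expression matrix")
  lab <- labels$label[match(colnames(expr), labels$sample_id)]
  if (anyNA(lab)) stop("labels missing for some samples")
  lab <- factor(lab, levels = c("high", "inter", "low"))
  counts <- table(lab)
  if (any(counts < 2L)) stop("every class needs >= 2 samples")
  x <- expr[present, , drop = FALSE]
  n <- ncol(x)
  k <- nlevels(lab)
  overall <- rowMeans(x)
  cent <- vapply(levels(lab), function(cl) {
    rowMeans(x[, lab == cl, drop = FALSE])
  }, numeric(length(present)))
  # pooled within-class sd
  ss <- rowSums(vapply(levels(lab), function(cl) {
    xc <- x[, lab == cl, drop = FALSE]
    rowSums((xc - cent[, cl])^2)
  }, numeric(length(present))))
  s <- sqrt(ss / (n - k))
  s0 <- median(s)
  nk <- as.numeric(counts)
  mk <- sqrt(1 / nk + 1 / n)
  # standardized difference, soft-thresholded
  shrunk <- cent
  for (j in seq_len(k)) {
    d <- (cent[, j] - overall) / (mk[j] * (s + s0))
    d_shr <- sign(d) * pmax(abs(d) - delta, 0)
    shrunk[, j] <- overall + mk[j] * (s + s0) * d_shr
  }
  structure(list(genes = present, classes = levels(lab), overall = overall,
                 centroids = shrunk, s = s, s0 = s0, delta = delta,
                 priors = setNames(nk / n, levels(lab))),
            class = "nsc_model")
}

#' Assign samples to proliferation tertiles with an NSC model
#'
#' Each sample is assigned to the class minimising the discriminant
#' score: squared distance to the shrunken centroid, standardised by
#' (s_i + s0)^2, minus 2 log prior. Model genes missing from the new
#' cohort are imputed at the overall centroid with a warning. Exact
#' ties are broken by the fixed class order high > inter > low.
#'
#' @param model an `nsc_model` from [nsc_train()].
#' @param expr genes x samples expression matrix (new cohort).
#' @return A `tertile_assignment` data.frame for the new samples (the
#'   `metagene_score` column is the mean over the model genes present).
#' @export
nsc_assign <- function(model, expr) {
  genes <- model$genes
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L) stop("no model genes in the new cohort")
  x <- matrix(model$overall, nrow = length(genes), ncol = ncol(expr),
              dimnames = list(genes, colnames(expr)))
  x[present, ] <- expr[present, , drop = FALSE]
  if (length(present) < length(genes))
    warning(sprintf("%d model gene(s) missing; imputed at overall centroid",
                    length(genes) - length(present)))
  w <- 1 / (model$s + model$s0)^2
  scores <- vapply(model$classes, function(cl) {
    d2 <- colSums(w * (x - model$centroids[, cl])^2)
    d2 - 2 * log(model$priors[[cl]])
  }, numeric(ncol(x)))
  if (ncol(x) == 1L) scores <- matrix(scores, nrow = 1L,
                                      dimnames = list(colnames(x),
                                                      model$classes))
  pick <- apply(scores, 1L, function(row) which(row == min(row))[1L])
  lab <- factor(model$classes[pick], levels = c("high", "inter", "low"))
  out <- data.frame(sample_id = colnames(expr), label = lab,
                    metagene_score = unname(colMeans(
                      expr[present, , drop = FALSE])),
                    stringsAsFactors = FALSE)
  class(out) <- c("tertile_assignment", "data.frame")
  out
}
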