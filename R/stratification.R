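#' Subnetwork activity matrix
#'
#' One row per subnetwork: the mean z-score of its member genes in each
#' sample.
#'
#' @param z z-scored expression matrix.
#' @param spns `subnetwork_list`.
#' @return Numeric subnetworks x samples matrix with rownames
#'   `SPN1..SPNk`.
#' @export
build_activity_matrix <- function(z, spns) {
  if (length(spns) == 0L) stop("no subnetworks supplied")
  act <- t(vapply(spns, function(s) subnetwork_activity(z, s$members),
                  numeric(ncol(z))))
  rownames(act) <- sprintf("SPN%d", seq_along(spns))
  colnames(act) <- colnames(z)
  act
}

#' Frequency-weighted subnetwork activity matrix
#'
#' Weights each member gene by the number of subnetworks it appears in:
#' activity = sum_i w_i z_ij / sum_i w_i. With uniform membership
#' frequencies this reduces to the plain mean.
#'
#' @inheritParams build_activity_matrix
#' @return Numeric subnetworks x samples matrix.
#' @export
weighted_activity <- function(z, spns) {
  if (length(spns) == 0L) stop("no subnetworks supplied")
  all_members <- unlist(lapply(spns, `[[`, "members"))
  freq <- table(all_members)
  act <- t(vapply(spns, function(s) {
    w <- as.numeric(freq[s$members])
    colSums(w * z[s$members, , drop = FALSE]) / sum(w)
  }, numeric(ncol(z))))
  rownames(act) <- sprintf("SPN%d", seq_along(spns))
  colnames(act) <- colnames(z)
  act
}

#' Cluster patients into two subgroups on subnetwork activity
#'
#' Average-linkage agglomerative clustering of patients on Euclidean
#' distances between their activity vectors, dendrogram cut into
#' exactly two groups; the activity-space centroid of each group is
#' recorded.
#'
#' @param act subnetworks x samples activity matrix.
#' @return List of class `patient_stratification`: `sample_ids`,
#'   `cluster` (1/2 per sample), `centroids` (subnetworks x 2 matrix).
#' @export
cluster_patients <- function(act) {
  if (ncol(act) < 2L) stop("need >= 2 patients to cluster")
  pts <- t(act)
  d <- dist(pts, method = "euclidean")
  if (all(d == 0)) stop("all patients have identical activity; cannot cluster")
  hc <- hclust(d, method = "average")
  cl <- unname(cutree(hc, k = 2L))
  centroids <- vapply(1:2, function(k) {
    colMeans(pts[cl == k, , drop = FALSE])
  }, numeric(nrow(act)))
  if (nrow(act) == 1L) centroids <- matrix(centroids, nrow = 1L)
  rownames(centroids) <- rownames(act)
  colnames(centroids) <- c("1", "2")
  structure(list(sample_ids = colnames(act), cluster = cl,
                 centroids = centroids),
            class = "patient_stratification")
}

#' Label the two patient subgroups as good / poor outcome
#'
#' The subgroup with the larger Kaplan-Meier survival estimate at 5
#' years (60 months) is the good-outcome group; a tie is broken by the
#' larger mean observed time. The log-rank test between the two groups
#' is attached.
#'
#' @param strat a `patient_stratification`.
#' @param survival survival annotation covering the stratified samples.
#' @param horizon time at which KM survival is compared (months).
#' @return The stratification with `outcome_label` (factor good/poor per
#'   sample), `centroids` relabeled `good`/`poor`, `logrank_chisq`,
#'   `logrank_p`.
#' @export
label_outcome <- function(strat, survival, horizon = 60) {
  surv <- survival[match(strat$sample_ids, survival$sample_id), ]
  if (anyNA(surv$sample_id)) stop("survival annotation missing for some samples")
  km_at <- vapply(1:2, function(k) {
    idx <- strat$cluster == k
    km_survival_at(surv$time[idx], surv$event[idx], horizon)
  }, numeric(1L))
  good <- if (km_at[1L] != km_at[2L]) which.max(km_at) else {
    means <- vapply(1:2, function(k) mean(surv$time[strat$cluster == k]),
                    numeric(1L))
    which.max(means)
  }
  lab <- ifelse(strat$cluster == good, "good", "poor")
  strat$outcome_label <- factor(lab, levels = c("good", "poor"))
  colnames(strat$centroids)[c(good, 3L - good)] <- c("good", "poor")
  strat$centroids <- strat$centroids[, c("good", "poor"), drop = FALSE]
  if (sum(surv$event) > 0L) {
    lr <- logrank_test(surv$time, surv$event, strat$outcome_label)
    strat$logrank_chisq <- lr$chisq
    strat$logrank_p <- lr$p
  } else {
    strat$logrank_chisq <- NA_real_
    strat$logrank_p <- NA_real_
  }
  strat
}

# KM survival probability at a time point (last estimate carried
# forward when follow-up ends earlier)
km_survival_at <- function(time, event, at) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, times = at, extend = TRUE)
  s$surv[1L]
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator with right censoring.
#'
#' @param time survival times.
#' @param event 0/1 event indicators.
#' @return data.frame with `time`, `n_risk`, `n_event`, `surv` (the
#'   right-continuous step function evaluated at each observed time).
#' @export
km_curve <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) comparing event incidence over
#' the pooled risk sets, with its upper-tail p-value.
#'
#' @param time survival times.
#' @param event 0/1 event indicators.
#' @param group two-level grouping factor/vector.
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly two non-empty groups")
  if (sum(event) == 0L) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chisq <- unname(sd$chisq)
  list(chisq = chisq, p = pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Classify a held-out cohort with trained SPNs
#'
#' z-scores are computed within the test cohort, the SPN activity
#' matrix is built (SPN members missing from the test matrix are
#' dropped per subnetwork with a warning; an SPN losing all members is
#' dropped), and patients are divided into good/poor outcome groups
#' either by re-clustering the test cohort (`"cluster"`) or by
#' assigning each patient to the nearer training centroid in activity
#' space (`"nearest-centroid"`).
#'
#' @param spns `subnetwork_list` of trained SPNs.
#' @param train_centroids subnetworks x 2 centroid matrix with columns
#'   `good`/`poor` (from [label_outcome()]); required in
#'   nearest-centroid mode.
#' @param test_expr genes x samples expression matrix of the new
#'   cohort.
#' @param test_survival survival annotation of the new cohort (used for
#'   the log-rank evaluation; may be `NULL` in nearest-centroid mode).
#' @param mode `"nearest-centroid"` (default) or `"cluster"`.
#' @return A `patient_stratification` with `outcome_label` and, when
#'   survival is supplied, the log-rank statistics.
#' @export
classify_cohort <- function(spns, train_centroids = NULL, test_expr,
                            test_survival = NULL,
                            mode = c("nearest-centroid", "cluster")) {
  mode <- match.arg(mode)
  z <- suppressWarnings(zscore_expression(test_expr))
  kept <- logical(length(spns))
  trimmed <- spns
  for (i in seq_along(spns)) {
    present <- intersect(spns[[i]]$members, rownames(z))
    lost <- length(spns[[i]]$members) - length(present)
    if (length(present) == 0L) {
      warning(sprintf("SPN %d has no genes in the test cohort; dropped", i))
      next
    }
    if (lost > 0L)
      warning(sprintf("SPN %d: %d member gene(s) missing in test cohort",
                      i, lost))
    trimmed[[i]]$members <- present
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("no SPN retains any gene in the test cohort")
  trimmed <- structure(trimmed[kept], class = "subnetwork_list")
  act <- t(vapply(trimmed, function(s) subnetwork_activity(z, s$members),
                  numeric(ncol(z))))
  rownames(act) <- sprintf("SPN%d", which(kept))
  colnames(act) <- colnames(z)

  if (mode == "cluster") {
    strat <- cluster_patients(act)
    if (is.null(test_survival)) stop("cluster mode needs test survival data")
    return(label_outcome(strat, test_survival))
  }
  if (is.null(train_centroids)) stop("nearest-centroid mode needs centroids")
  cen <- train_centroids[kept, , drop = FALSE]
  d_good <- colSums((act - cen[, "good"])^2)
  d_poor <- colSums((act - cen[, "poor"])^2)
  lab <- ifelse(d_good <= d_poor, "good", "poor")
  strat <- structure(list(sample_ids = colnames(act),
                          cluster = ifelse(lab == "good", 1L, 2L),
                          centroids = cen,
                          outcome_label = factor(lab,
                                                 levels = c("good", "poor"))),
                     class = "patient_stratification")
  if (!is.null(test_survival) &&
      nlevels(droplevels(strat$outcome_label)) == 2L) {
    surv <- test_survival[match(strat$sample_ids, test_survival$sample_id), ]
    lr <- logrank_test(surv$time, surv$event, strat$outcome_label)
    strat$logrank_chisq <- lr$chisq
    strat$logrank_p <- lr$p
  }
  strat
}

#' Classification metrics against the metastasis event
#'
#' A poor-outcome prediction counts as "predicted metastatic": tp =
#' poor & event, fp = poor & no event, tn = good & no event, fn =
#' good & event. Undefined precision or recall (empty denominator) is
#' reported as 0 with a flag.
#'
#' @param outcome_label factor good/poor per sample.
#' @param event 0/1 metastasis indicator per sample.
#' @return List with `tp`, `fp`, `tn`, `fn`, `accuracy`, `precision`,
#'   `recall`, `precision_defined`, `recall_defined`.
#' @export
classification_metrics <- function(outcome_label, event) {
  stopifnot(length(outcome_label) == length(event))
  poor <- outcome_label == "poor"
  event <- as.logical(event)
  tp <- sum(poor & event)
  fp <- sum(poor & !event)
  tn <- sum(!poor & !event)
  fn <- sum(!poor & event)
  prec_def <- (tp + fp) > 0L
  rec_def <- (tp + fn) > 0L
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = if (prec_def) tp / (tp + fp) else 0,
       recall = if (rec_def) tp / (tp + fn) else 0,
       precision_defined = prec_def, recall_defined = rec_def)
}

#' Repeated stratified k-fold cross-validation of the SPN pipeline
#'
#' Per repeat: samples are split into k folds stratified by the event
#' indicator; for each fold, primary subnetworks are discovered on the
#' training 9/10 (z-scored within the training part), filtered by the
#' three permutation nulls with `null_trials` trials each (when
#' `null_trials` is 0, or when no subnetwork survives, the top
#' `fallback_top` subnetworks by adjusted S are used), patients in the
#' training part are clustered and outcome-labeled, and the held-out
#' fold is classified by nearest training centroid. Held-out labels are
#' pooled across folds and evaluated by the log-rank test. Across
#' repeats each sample's final label is the majority vote (ties broken
#' toward good). A fold drawing zero events is re-drawn, at most 10
#' times.
#'
#' @param expression genes x samples matrix.
#' @param network an `interaction_network`.
#' @param survival survival annotation.
#' @param k number of folds.
#' @param repeats number of repeats.
#' @param config [search_config()] for the per-fold searches.
#' @param null_trials permutation trials per null variant within each
#'   fold (0 disables the filter).
#' @param fallback_top number of top subnetworks used when the filter
#'   leaves none.
#' @param seed master integer seed.
#' @return List of class `cv_result`: `labels` (final per-sample
#'   factor), `logrank_p` (log-rank p of the majority-vote labels),
#'   `repeat_p` (per-repeat pooled log-rank p-values), `per_repeat`
#'   (matrix of labels, samples x repeats).
#' @export
cross_validate <- function(expression, network, survival, k = 10L,
                           repeats = 1L, config = search_config(),
                           null_trials = 0L, fallback_top = 5L,
                           seed = 1L) {
  samples <- intersect(colnames(expression), survival$sample_id)
  n <- length(samples)
  if (n < 2L * k) stop("need at least 2k samples")
  surv <- survival[match(samples, survival$sample_id), ]
  per_repeat <- matrix(NA_character_, nrow = n, ncol = repeats,
                       dimnames = list(samples, NULL))
  repeat_p <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed((seed + 104729L * r) %% .Machine$integer.max)
    folds <- stratified_folds(surv$event, k, max_redraw = 10L)
    labels <- setNames(rep(NA_character_, n), samples)
    for (f in seq_len(k)) {
      test_idx <- folds == f
      tr_samples <- samples[!test_idx]
      te_samples <- samples[test_idx]
      tr_expr <- expression[, tr_samples, drop = FALSE]
      z <- suppressWarnings(zscore_expression(tr_expr))
      tr_surv <- surv[!test_idx, ]
      pns <- fdr_adjust(greedy_search(z, network, tr_surv, config))
      if (length(pns) == 0L) stop("no subnetworks found in fold ", f)
      spns <- pns
      if (null_trials > 0L) {
        nulls <- lapply(c("gene-label", "within-gene-expression",
                          "survival-time"), function(v) {
          build_null(tr_expr, network, tr_surv, v, n_trials = null_trials,
                     config = config,
                     seed = (seed + 31L * r + 7L * f) %% .Machine$integer.max)
        })
        spns <- filter_spns(pns, nulls)
      }
      if (length(spns) == 0L)
        spns <- structure(head(pns, fallback_top), class = "subnetwork_list")
      act <- build_activity_matrix(z, spns)
      strat <- label_outcome(cluster_patients(act), tr_surv)
      pred <- classify_cohort(spns, strat$centroids,
                              expression[, te_samples, drop = FALSE],
                              mode = "nearest-centroid")
      labels[te_samples] <- as.character(pred$outcome_label)
    }
    per_repeat[, r] <- labels
    repeat_p[r] <- logrank_test(surv$time, surv$event,
                                factor(labels, levels = c("good", "poor")))$p
  }
  votes_good <- rowSums(per_repeat == "good")
  final <- factor(ifelse(votes_good * 2L >= repeats, "good", "poor"),
                  levels = c("good", "poor"))
  names(final) <- samples
  p <- if (nlevels(droplevels(final)) == 2L)
    logrank_test(surv$time, surv$event, final)$p else 1
  structure(list(labels = final, logrank_p = p, repeat_p = repeat_p,
                 per_repeat = per_repeat),
            class = "cv_result")
}

# stratified fold assignment; redraws until every fold has >= 1 event
stratified_folds <- function(event, k, max_redraw = 10L) {
  n <- length(event)
  for (attempt in seq_len(max_redraw)) {
    folds <- integer(n)
    for (e in unique(event)) {
      idx <- which(event == e)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ev_per_fold <- tapply(event, folds, sum)
    if (length(ev_per_fold) == k && all(ev_per_fold > 0)) return(folds)
    message("fold with zero events; re-drawing folds")
  }
  stop("could not draw folds with events in every fold after ",
       max_redraw, " attempts")
}
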