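#!/usr/bin/env Rscript
# Stratify patients into good / poor outcome groups with the SPNs.
#
# Clusters training patients on the SPN activity matrix (average
# linkage, Euclidean), labels the cluster with higher 5-year KM
# survival "good", evaluates with the log-rank test, then classifies
# the held-out cohort by nearest training centroid. Run 04 first.

suppressPackageStartupMessages(library(spnsurv))

expr <- read_expression("results/simulated/train/expression.tsv")
surv <- read_survival("results/simulated/train/survival.tsv")
test_expr <- read_expression("results/simulated/test/expression.tsv")
test_surv <- read_survival("results/simulated/test/survival.tsv")
spns <- read_subnetworks("results/spns.json")
spns <- structure(spns, class = "subnetwork_list")
stopifnot(length(spns) > 0L)

z <- suppressWarnings(zscore_expression(expr))
act <- build_activity_matrix(z, spns)
strat <- label_outcome(cluster_patients(act), surv)
cat(sprintf("training split: %d good / %d poor, log-rank p = %.3g\n",
            sum(strat$outcome_label == "good"),
            sum(strat$outcome_label == "poor"), strat$logrank_p))

pred <- classify_cohort(spns, strat$centroids, test_expr, test_surv,
                        mode = "nearest-centroid")
cat(sprintf("held-out split: %d good / %d poor, log-rank p = %.3g\n",
            sum(pred$outcome_label == "good"),
            sum(pred$outcome_label == "poor"), pred$logrank_p))
met <- classification_metrics(pred$outcome_label, test_surv$event)
cat(sprintf("held-out accuracy %.3f, precision %.3f, recall %.3f\n",
            met$accuracy, met$precision, met$recall))

for (grp in c("good", "poor")) {
  idx <- pred$outcome_label == grp
  km <- km_curve(test_surv$time[idx], test_surv$event[idx])
  write.table(km, sprintf("results/km_test_%s.tsv", grp), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
lab <- data.frame(sample_id = pred$sample_ids,
                  outcome = as.character(pred$outcome_label))
write.table(lab, "results/test_outcome_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/km_test_{good,poor}.tsv and test_outcome_labels.tsv\n")
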