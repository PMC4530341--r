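#!/usr/bin/env Rscript
# Stratify patients into proliferation tertiles.
#
# Scores every sample by the proliferation metagene (mean expression
# of its member genes), cuts the cohort into three equal tertiles
# (P-high / P-inter / P-low), and trains a nearest shrunken centroid
# classifier that assigns held-out samples to a tertile. Run
# 01_simulate.R first.

suppressPackageStartupMessages(library(spnsurv))

train_expr <- read_expression("results/simulated/train/expression.tsv")
test_expr <- read_expression("results/simulated/test/expression.tsv")
truth <- jsonlite::read_json("results/simulated/train/truth.json")
metagene <- unlist(truth$metagene_genes)

tert <- assign_tertiles(train_expr, metagene, mode = "ranked-split")
print(table(tert$label))
truth_lab <- unlist(truth$tertile_truth)
cat(sprintf("agreement with ground truth: %.1f%%\n",
            100 * mean(as.character(tert$label) == truth_lab)))

model <- nsc_train(train_expr, metagene, tert, delta = 0)
pred <- nsc_assign(model, test_expr)
test_truth <- unlist(jsonlite::read_json(
  "results/simulated/test/truth.json")$tertile_truth)
cat(sprintf("NSC held-out tertile agreement: %.1f%%\n",
            100 * mean(as.character(pred$label) == test_truth)))

dir.create("results", showWarnings = FALSE)
write.table(tert, "results/tertiles_train.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pred, "results/tertiles_test.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/tertiles_{train,test}.tsv\n")
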