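#!/usr/bin/env Rscript
# Filter primary subnetworks into SPNs by three permutation nulls.
#
# Rebuilds the discovery on 50 permuted datasets per null variant
# (gene labels, within-gene expression, survival times), pools the
# adjusted S scores of each null, and keeps the primary subnetworks
# whose adjusted S exceeds all three 95% quantiles. Run 03 first.

suppressPackageStartupMessages(library(spnsurv))

expr <- read_expression("results/simulated/train/expression.tsv")
net <- read_network("results/simulated/train/network_edges.tsv")
surv <- read_survival("results/simulated/train/survival.tsv")
pns <- read_subnetworks("results/primary_subnetworks.json")
pns <- structure(lapply(pns, function(s) {
  s$adjusted_s <- -log(s$adjusted_p)
  s
}), class = "subnetwork_list")

variants <- c("gene-label", "within-gene-expression", "survival-time")
nulls <- lapply(seq_along(variants), function(i) {
  n <- build_null(expr, net, surv, variants[i], n_trials = 50L,
                  config = search_config(), seed = 20260927L + 1009L * i)
  print(n)
  scores <- data.frame(variant = variants[i], adjusted_s = n$null_scores)
  write.table(scores, sprintf("results/null_scores_%d.tsv", i),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n
})

spns <- filter_spns(pns, nulls)
cat(sprintf("%d of %d primary subnetworks survive all three filters\n",
            length(spns), length(pns)))
print(spns)
write_subnetworks(spns, "results/spns.json", network = net)
cat("wrote results/spns.json\n")
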