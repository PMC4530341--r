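#!/usr/bin/env Rscript
# Gene-set enrichment of the SPNs.
#
# Tests each SPN for over-representation in a gene-set collection
# (Fisher's exact / hypergeometric upper tail, Bonferroni-corrected per
# SPN over the sets tested). For the synthetic study the collection is
# built from the simulation truth: one set per planted module (padded
# with random genes) plus random decoy sets, so enrichment should tag
# SPN/planted-module pairs and nothing else. Run 04 first.

suppressPackageStartupMessages(library(spnsurv))

expr <- read_expression("results/simulated/train/expression.tsv")
net <- read_network("results/simulated/train/network_edges.tsv")
truth <- jsonlite::read_json("results/simulated/train/truth.json")
planted <- lapply(truth$planted, unlist)
spns <- structure(read_subnetworks("results/spns.json"),
                  class = "subnetwork_list")
stopifnot(length(spns) > 0L)

background <- intersect(rownames(expr), net$nodes)
set.seed(20260927L)
sets <- list()
for (i in seq_along(planted)) {
  sets[[sprintf("PLANTED_MODULE_%d", i)]] <-
    union(planted[[i]], sample(background, 10L))
}
for (i in 1:20) {
  sets[[sprintf("DECOY_%02d", i)]] <- sample(background, 15L)
}

mat <- enrichment_matrix(spns, sets, background)
cat("enriched (SPN x set) pairs:\n")
print(which(mat, arr.ind = TRUE))
write.table(mat, "results/enrichment_matrix.tsv", sep = "\t",
            quote = FALSE)

all_res <- do.call(rbind, lapply(seq_along(spns), function(i) {
  cbind(spn = sprintf("SPN%d", i),
        fisher_enrich(spns[[i]]$members, sets, background))
}))
write.table(all_res, "results/enrichment_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/enrichment_matrix.tsv and enrichment_tests.tsv\n")
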