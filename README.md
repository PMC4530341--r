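# spnsurv

Discovery of **survival prognostic subnetworks (SPNs)** in gene
expression cohorts, constrained by a protein functional-interaction
network and stratified by tumor proliferative capacity. The package is
aimed at computational biologists studying network markers of patient
outcome — e.g. distant metastasis-free survival (DMFS) in breast
cancer — and at anyone who wants a fully testable, self-contained
implementation of greedy Cox-scored subnetwork search with
permutation-based significance filtering.

## The method

1. **Proliferation tertiles.** Samples are scored by a proliferation
   metagene (mean expression of its member genes) and cut into three
   equal tertiles: P-high, P-inter, P-low. New cohorts are assigned to
   tertiles by a nearest shrunken centroid classifier trained on the
   metagene submatrix.
2. **Subnetwork scoring.** Within a tertile, expression is
   row-standardized, z<sub>ij</sub> = (g<sub>ij</sub> − u<sub>i</sub>)/σ<sub>i</sub>;
   the activity of a connected gene set in patient j is the mean
   x<sub>j</sub> of its members' z-scores. A single-covariate Cox
   proportional-hazards model H(t)/H₀(t) = exp(β·x) is scored by
   S = −ln p of the likelihood-ratio χ²(1) test.
3. **Greedy search.** Every gene seeds a search that repeatedly adds
   the neighboring gene maximizing S (and greedily deletes members
   while S improves, keeping the set connected). Deduplicated results
   are the primary subnetworks (PNs); their p-values are BH-adjusted.
4. **Permutation filtering.** PNs must exceed the pooled 95% null
   quantile of adjusted S under three permutation schemes — gene
   labels, within-gene expression, survival times — to become SPNs.
5. **Patient stratification.** Patients are clustered on the
   SPN-activity matrix (average linkage, Euclidean), the cluster with
   higher 5-year Kaplan–Meier survival is labeled *good* outcome, and
   groups are compared by the log-rank test; held-out cohorts are
   classified by nearest training centroid. Repeated stratified
   10-fold cross-validation and Fisher's-exact gene-set enrichment
   (Bonferroni per SPN) complete the pipeline.

A synthetic-data module generates the whole study — scale-free
network, planted survival-associated connected modules, exponential
survival with calibrated censoring, and a proliferation metagene with
ground-truth tertiles — so every stage is testable offline.

## Worked example

The numbered scripts under `analysis/` run the full study on a
simulated cohort (500 genes, 250 + 250 patients, three planted
modules, β = 1.5, ~30% censoring):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_stratify_proliferation.R
Rscript analysis/03_discover_subnetworks.R
Rscript analysis/04_permutation_filter.R
Rscript analysis/05_stratify_survival.R
Rscript analysis/06_cross_validation.R
Rscript analysis/07_enrichment.R
```

Representative output (script 03–05):

```
planted-set recovery (Jaccard, top-10 PNs): 0.83, 0.8, 0.83
9 of 52 primary subnetworks survive all three filters
training split: 248 good / 2 poor, log-rank p = 2.37e-10
held-out split: 239 good / 11 poor, log-rank p = 2.75e-09
held-out accuracy 0.364, precision 0.909, recall 0.060
```

Reading this: the top primary subnetworks recover each planted module
at Jaccard ≥ 0.8; nine survive all three permutation nulls; and the
SPN-based split of an *independent* cohort separates survival at
p ≈ 3×10⁻⁹. The good/poor groups are very unbalanced here — with a
continuous unimodal risk factor, average-linkage clustering isolates a
small extreme-risk group (a documented limitation; the log-rank
evaluation is unaffected). Precision 0.91 means poor-outcome calls are
almost always true metastases, while recall is low because only the
extreme group is called poor.

Or in R, from the shipped miniature fixtures:

```r
library(spnsurv)
expr <- read_expression(system.file("extdata", "example_expression.tsv",
                                    package = "spnsurv"))
net  <- read_network(system.file("extdata", "example_network.sif",
                                 package = "spnsurv"))
surv <- read_survival(system.file("extdata", "example_survival.tsv",
                                  package = "spnsurv"))
z <- zscore_expression(expr)
pns <- fdr_adjust(greedy_search(z, net, surv, search_config()))
print(pns)
```

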