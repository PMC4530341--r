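---
title: "Methods: proliferation-dependent survival prognostic subnetwork discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proliferation-dependent survival prognostic subnetwork discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gene signatures for breast-cancer prognosis rarely replicate between
cohorts, in part because individual genes are noisy readouts of the
pathways that actually drive metastasis. Network-marker methods address
this by searching a protein functional-interaction (FI) network for
*connected* gene sets whose joint expression predicts outcome, so that
each marker corresponds to a coherent piece of signaling biology rather
than an arbitrary gene list. `spnsurv` implements such a pipeline with
one additional structural idea: tumors are first stratified by
proliferative capacity, and subnetwork markers are discovered
separately within each proliferation stratum, because the biology
driving metastasis differs between highly and lowly proliferative
tumors.

## The model

**Proliferation tertiles.** Each sample is scored by a proliferation
metagene: the mean expression of a fixed set of cell-cycle /
proliferation genes. Samples are cut into three equal tertiles
(P-high, P-inter, P-low) by the ranked scores. Ranked splitting is the
default because it reproduces exactly equal group sizes; an
average-linkage hierarchical mode (Euclidean distance on the metagene
submatrix, dendrogram cut at k = 3, clusters labeled by descending mean
score) is retained since clustering is the textbook description of the
procedure, but clustering does not guarantee equal groups, which the
ranked split does. New cohorts are assigned to tertiles by a nearest
shrunken centroid (NSC) classifier trained on the metagene submatrix;
the shrinkage threshold defaults to 0 (plain pooled-standardized
nearest centroid) because no value is established for this application,
and at 0 the classifier is the least parameterized member of the
family.

**Subnetwork activity and score.** Within a tertile's cohort,
expression is row-standardized, z_ij = (g_ij − u_i)/σ_i with the
sample (n−1) standard deviation. Two conventions exist for this
transform — centering only, or centering and scaling — and the scaled
form is used here: without dividing by σ_i, high-variance genes
dominate every average they enter. The activity of a gene set in
patient j is the unweighted mean x_j of its members' z-scores. The
activity is scored by a single-covariate Cox proportional-hazards
model, H(t)/H0(t) = exp(β·x), fitted by partial-likelihood
maximization with Efron handling of ties, and summarized by
S = −ln p of the likelihood-ratio χ²(1) test. The likelihood-ratio
test is used for the "chi-square test on the Cox model" because it is
the default reported by standard survival software and asymptotically
equivalent to the Wald and score forms. S uses the natural logarithm
so that p = exp(−S) exactly.

A frequency-weighted activity variant (each gene weighted by the
number of subnetworks containing it) is provided for sensitivity
analysis; with uniform membership frequencies it reduces to the plain
mean.

**Greedy search.** Every gene present in both the expression matrix
and the network seeds one search. The current set repeatedly adds the
neighboring gene that maximally increases S; after each accepted
addition, single-gene deletions that most increase S are applied while
the set stays connected. Results of size ≥ 2 are deduplicated by
member set and ranked by S; Benjamini–Hochberg adjustment over
p = exp(−S) gives each primary subnetwork (PN) an adjusted score.
BH is used for "controlling the FDR" as the standard step-up
controller. Ties in candidate score break to the lexicographically
smallest gene id, and seeds are visited in sorted order, so the search
is a pure function of its inputs.

**Stopping rule.** A move is accepted only if it improves S by at
least `min_delta_s = 2` nats, i.e. improves the Cox LRT p-value by a
factor e² ≈ 7.4. The threshold matters: each step takes the maximum
over a frontier of 20–50 candidate genes, and the maximum of that many
chance fluctuations is essentially always positive, so with a
near-zero tolerance the search inflates every subnetwork to the size
cap with passenger genes. Requiring a meaningful evidence gain per
gene stops growth once the genuine signal is absorbed. An optional
relative-improvement rate (`min_rel_improve`, default 0) can be added
on top; the size cap (`max_size = 20`) is a guard rail that a
well-calibrated stopping rule rarely reaches. The deletion step may
remove the original seed; connectivity of the remaining set is always
enforced because the markers are interpreted as connected pieces of
the interaction network.

**Permutation filtering.** PNs are filtered by three null models, each
destroying one link the search exploits while conserving the
expression-value multiset: (1) gene labels permuted against the rows
(breaking the network–expression correspondence), (2) each gene's
values permuted independently across samples (breaking co-expression
and the expression–survival link), (3) the (time, event) pairs
permuted jointly across patients. For each variant the full discovery
(search + BH) is re-run on each permuted dataset and all adjusted S
scores are pooled into one null background; the threshold is the
pooled empirical 95% quantile (linear-interpolation quantile). Pooling
across trials, rather than per-trial maxima, follows the reading of
the three trials as a single "null background"; a trial yielding no
subnetwork contributes a score of 0 so that empty trials weaken rather
than inflate the threshold. A PN survives only if its adjusted S
strictly exceeds *all three* thresholds; survivors are the survival
prognostic subnetworks (SPNs). The thresholds are applied to adjusted
(not raw) scores since the trials are described as producing
subnetworks "together with adjusted S scores". Trial RNG streams
derive from a master seed by trial index, so null distributions are
reproducible and individually re-runnable.

**Patient stratification.** Patients are clustered on the SPN ×
patient activity matrix by average-linkage agglomerative clustering on
Euclidean distances and the dendrogram is cut into two groups. The
group with the larger Kaplan–Meier survival estimate at 5 years (60
months) is labeled good outcome, the other poor; a tie breaks to the
larger mean observed time. "Average survival" under censoring is not
well defined, and the 5-year KM estimate operationalizes the >5y /
<5y outcome description while handling censoring correctly. The two
groups are compared by the standard two-group log-rank test. Held-out
cohorts are z-scored within themselves, reduced to SPN activities
(SPNs losing member genes are trimmed, SPNs losing all members
dropped), and each patient is assigned to the nearer training centroid
in activity space; whole-cohort re-clustering is available as an
alternative mode since de novo subgroup formation is how validation
cohorts are sometimes presented.

**Cross-validation.** Repeated stratified 10-fold cross-validation:
subnetworks are discovered on each 9/10, the held-out fold is
classified by nearest training centroid, pooled held-out labels are
evaluated by the log-rank test, and across repeats each sample's
consensus label is the majority vote. Folds are stratified by the
event indicator so every fold contains events; an event-free fold
draw is rejected and redrawn (at most 10 times). Permutation trials
inside each fold are configurable and usually reduced or disabled —
the filter multiplies the search cost by 3 × trials, and
cross-validation assesses the discovery-plus-classification procedure
rather than the final significance calls.

**Enrichment.** Each SPN is tested against a gene-set collection
(GMT) by the one-sided Fisher's exact test — the hypergeometric upper
tail P[X ≥ k] of the overlap — against the background universe of
genes present in both the expression matrix and the network (the
actual search space; using a larger universe would overstate
enrichment). P-values are Bonferroni-corrected per SPN over the number
of sets tested, and a set is called enriched below adjusted p < 0.05.
The one-sided tail is used because only over-representation is asked.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
so every stage is testable without external downloads:

* **Network**: Barabási–Albert preferential attachment (default) with
  mean degree 4, or Erdős–Rényi; gene ids are shared with the
  expression matrix.
* **Expression**: i.i.d. standard normal background per gene (log-scale
  units).
* **Planted modules**: vertex-disjoint connected sets grown by random
  breadth-first expansion. Each planted set shares a latent per-sample
  risk factor r_j ~ N(0,1) added to its members with loading 0.8,
  giving within-module correlation ≈ 0.39 — comparable to real
  co-expression modules — while keeping marginal variances near 1.
* **Module placement**: planted sets avoid hubs (member degree ≤ 10)
  and keep pairwise graph distance ≥ 3. Both rules exist to make the
  planted truth well-posed rather than to help any particular search:
  for mean-activity Cox scoring, merging two informative same-direction
  modules *always* increases the score (covariances add while averaging
  shrinks variance), so modules placed adjacent to each other are not
  separately identifiable by any score-maximizing method — the union is
  genuinely the better marker. Separation by at least two linker genes
  restores per-module identifiability, and hub exclusion keeps module
  boundaries meaningful (a hub belongs to many neighborhoods at once).
  Module-recovery benchmarks in network biology make the same choices.
* **Survival**: exponential times with hazard
  h_j = h0 · exp(β · Σ_s a_sj), where a_sj is module s's mean z-score
  activity in sample j; with several planted modules each contributes
  its own term with the same β. The exponential (constant-baseline)
  model is the simplest proportional-hazards law to invert, and Cox
  scoring is baseline-agnostic. Censoring times are independent
  exponentials whose rate is calibrated by root-finding so the expected
  censored fraction matches the target (default 30%), preserving
  non-informative censoring.
* **Proliferation structure**: a metagene block (default 20 genes,
  disjoint from planted modules so proliferation does not confound the
  survival signal) is shifted by −s, 0, +s across three equal
  ground-truth tertiles (default s = 2).

What the generator does **not** emulate: microarray noise models,
intensity-dependent variance, batch effects, correlated background
genes outside modules, and proliferation–survival coupling (in real
breast tumors proliferation itself is prognostic). Passing tests
therefore demonstrate that the machinery is correct and recovers
planted structure under clean conditions, not that the biological
findings of any particular cohort would reproduce.

## Numerical choices

* Cox fits run in compiled code (Newton–Raphson with step-halving,
  convergence at |gradient| < 1e−9, |β| capped at 20 under monotone
  likelihood) because the greedy search evaluates 10⁵–10⁶ fits per
  cohort; the fit matches `survival::coxph` to 1e−6 and an independent
  brute-force partial-likelihood oracle to 1e−3 in S (both asserted in
  the test suite).
* S is computed on the log scale (`pchisq(..., log.p = TRUE)`) so very
  significant subnetworks do not saturate at p = 0.
* Constant activity vectors are degenerate, scored S = 0, p = 1, β = 0.
* Genes with zero variance are dropped before z-scoring with a warning.
* The empirical null quantile uses R's default linear-interpolation
  definition (type 7).
* Ties everywhere (candidate genes, tertile scores, NSC classes) break
  by fixed label order then lexicographic id, so every stage is
  deterministic given its seed.

## Problem sizes used by the tests

The test suite and the acceptance script exercise the pipeline at
sizes a single workstation handles comfortably: cohorts of 60–500
genes and 60–250 samples, 20 pinned-seed replicates for
planted-module recovery (500 genes, 250 samples, 3 planted modules of
5–8 genes, β = 1.2, 30% censoring), 50 permutation trials per null
variant, and 20 global-null replicates for filter calibration.
Permutation trial counts are configurable; production analyses of
real cohorts would raise them (e.g. to 1000) without any code change.

## Known limitations

* Average-linkage clustering of unimodal activity profiles often cuts
  off a small extreme-risk group rather than producing balanced
  subgroups; the log-rank evaluation is still valid, but group-size
  ratios are unstable across cohorts, and in cross-validation the
  resulting label imbalance costs the pooled log-rank test most of its
  power. Real cohorts, whose subnetwork activities are closer to
  bimodal (markers dysregulated in a patient subgroup), give more
  balanced splits; a `risk_bimodality` option in the generator lets
  this regime be explored, though with several independent planted
  modules patient activities then occupy mixture corners rather than
  two clean subgroups.
* The greedy search is a heuristic: it attains a large fraction of the
  exhaustive-search optimum on small instances (asserted in tests) but
  has no global guarantee.
* Single-covariate Cox scoring ignores clinical covariates; the
  package deliberately does not model treatment, ER status or other
  adjusters.
* The permutation filter's gene-label null preserves co-expression and
  survival association while scrambling network positions, so its
  threshold is the most conservative of the three on strongly
  modular data.
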