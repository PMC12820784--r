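---
title: "Methods: spatial niches, cell circuits and severity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial niches, cell circuits and severity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecircuit)
```

# Overview

`nichecircuit` implements a sequence of analyses over single-cell spatial
maps of inflamed tissue: discovery of multicellular niches from local
cell-type composition, niche-constrained inference of ligand-receptor
communication, prioritization of driver ligands through a transcription
factor (TF) voting funnel, additive-versus-synergistic classification of
dual-cytokine responses, and association of a derived gene signature with
ordinal disease severity. The motivating biology is the cross-talk between
activated macrophages and inflammation-associated fibroblasts (IAFs), the
disease-expanded, IL11-expressing fibroblast state in inflammatory bowel
disease, but every step is generic over cell types, ligands and conditions.

Because the real atlases behind such studies are tens of gigabytes, the
package ships a synthetic tissue and cohort generator with planted ground
truth; all tests and the acceptance script run against it.

# Niche discovery

**Model.** A niche is a recurrent microenvironment: cells whose 30-um
neighborhoods have similar cell-type composition. For each cell we count,
within the same tissue section (sample), the cells of every type at
Euclidean distance at most `r_um` (closed predicate, default 30 um); the
focal cell is included in its own neighborhood, so an isolated cell has
total count 1. K-means is run on these composition vectors for each
candidate `k` (default 5-35) and the mean silhouette width selects `k`
(argmax; ties to the smallest `k`).

**Numerical choices.** Rows are clustered as raw counts by default: raw
counts let dense and sparse tissue compartments (e.g. epithelium versus
muscularis) separate even when their type proportions are similar. A
`proportions = TRUE` switch row-normalizes instead, since either convention
is defensible and the choice genuinely matters near density gradients.
K-means uses 10 seeded restarts per `k`, keeping the best within-cluster
sum of squares (ties keep the lowest restart index). The silhouette is
evaluated on a seeded uniform subsample (cap 10,000 rows by default;
analyses here use 1,500-2,000) because the full silhouette is quadratic in
cells; the distance matrix is computed once and reused across all `k`.
Identical composition rows for every cell are rejected as degenerate.
The neighborhood search uses a per-sample grid index of bin width `r_um`;
its output is defined (and tested) to equal the brute-force all-pairs
computation exactly.

**Enrichment.** Cell-type enrichment per niche uses the chi-squared test of
independence on the niches-by-types contingency table with degrees of
freedom `(N - 1)(C - 1)`. Per-cell standardized residuals
`(obs - exp) / sqrt(exp (1 - row/n) (1 - col/n))` give two-sided
normal-tail p-values, Bonferroni-corrected over all `N x C` table cells; a
pair is *enriched* when the corrected p is below 0.05 and the residual is
positive. Niches or types with zero totals are dropped with a warning and
the degrees of freedom recomputed.

# Differential abundance

Cell-type (or niche) abundance shifts between two conditions are tested
with a maximum-likelihood Dirichlet-multinomial regression:
`y_s ~ DirMult(n_s, alpha_s)` with `log alpha_sc = beta0_c + beta_c x_s`,
the condition effect of a declared reference category pinned to zero so
relative shifts are identifiable. A pseudocount of 0.001 is added to every
count before fitting. Each non-reference category is tested by a
likelihood-ratio test against the model with its `beta_c` fixed at zero,
with Benjamini-Hochberg correction; categories with q below 20% are called
credible. This is a deliberate frequentist counterpart of Bayesian
spike-and-slab compositional models: the decision rule actually applied
(FDR < 20% on per-category condition effects) is reproducible without
MCMC, at the cost of posterior effect-size summaries.

The reported fold change is of *fitted relative proportions*
(`log2(pi_c(disease) / pi_c(control))`), labelled as such, since fold
change of raw counts is not well-defined under compositional constraints.

**Numerics.** The log-likelihood is evaluated through
`lbeta(A, n) - lgamma(n)` and `lgamma(y) - lbeta(alpha, y)` rather than raw
`lgamma` differences: at large concentrations `lgamma(A) - lgamma(n + A)`
cancels catastrophically and creates spurious optima. Optimization is
bounded L-BFGS-B (|parameter| <= 50, `factr = 1e4`) with the analytic
digamma gradient. Because one niche's expansion renormalizes the
composition of the niches it shares tissue with, small negative effects on
co-resident types are genuine signal, not false positives — the null
simulations in the test suite use tables with no planted effect at all.

# Communication inference

**Markers.** One-vs-rest Wilcoxon rank-sum per (gene, type) on logTP10K
normalized expression (library-size 10,000, log1p), BH-adjusted within
type, with log fold change of pseudocounted means and expressing-cell
fractions. A separate specificity filter implements the strict
disease-fibroblast marker rule (p < 0.05, log fold change > 3, expressed in
> 25% of the foreground and < 10% of the background).

**Scoring.** For each ligand-receptor pair and ordered (sender, receiver)
type pair: the interaction is *relevant* when both genes are expressed in
more than `tau_expr` (default 5%) of the respective populations, and
*significant* when additionally the ligand is a DE-upregulated gene of the
sender or the receptor of the receiver — the analysis is DE-driven rather
than permutation-driven. The score is the product of the two genes' mean
normalized expressions after per-gene min-max scaling across cell types.
This form is bounded in [0, 1], monotone in both partners, and — because a
gene whose mean is constant across types scales to zero — immune to noise
amplification on flat housekeeping genes. No score formula is canonical
here; the product of scaled means was chosen as the simplest statistic with
those three properties.

**Spatial constraint and network.** An interaction survives only if sender
and receiver are both enriched in at least one common niche. Edge weight is
the sum of significant interaction scores per (sender, receiver); an edge
exists only with at least one significant interaction. Weights are
invariant to input order, raising `tau_expr` never adds interactions, and
removing the niche constraint never decreases a weight (all property
tested).

**Proximity profile.** For every receiver-type cell, the distance to the
nearest sender-type cell in the same sample, summarized per distance bin
(default edges 0, 30, 60, 100, 200, Inf um — the bin layout is a reporting
choice, not part of the model) as count, mean normalized expression and
expressing fraction of a query gene.

# Ligand prioritization

TFs driving the target population are selected by two routes: (i) target
markers intersected with a TF universe (rank-sum p < 0.05, positive fold
change — the marker-route p threshold is exposed as a knob since only the
route's outcome, not its cutoff, is conventionally reported), and (ii) TFs
with mean activity difference > 0.75 versus background at rank-sum
p < 0.01. Each TF in the union votes for its top-10 ligands by regulatory
potential (ties broken lexicographically so votes are reproducible);
ligands with at least 5 votes are kept, then restricted to those with a
cognate receptor expressed in more than 5% of target cells. Family
expansion of the shortlist is an optional user-supplied table join, not
hard-coded biology. The funnel is monotone (larger TF sets can only grow
votes; larger vote thresholds can only shrink the list), and under
exchangeable regulatory-potential columns the chance that any of 150 decoy
ligands reaches 5 votes from 8 TFs is about 1% (union bound
`150 * P(Bin(8, 10/150) >= 5)`), verified by simulation.

# Activation scoring

**Synergy.** For baseline `X` and single-stimulus increments `dA`, `dB`,
the additive expectation is `X + dA + dB` and the synergistic
(multiplicative-fold) expectation is `X (1 + dA/X)(1 + dB/X)`, exceeding
the additive one by exactly `dA dB / X`; either zero increment collapses
the two. An observed dual response is classified against the additive
expectation with 10% relative tolerance by default — the published analyses
print the two expectations and argue by comparison, so no canonical formal
decision rule exists and the tolerance is exposed.

**Signature derivation.** Effector genes are those down in the
knockout and up in the activation DE tables at adjusted p < 0.05; the core
signature further intersects regulator-bound genes and cell-type-specific
transcripts. Refinement keeps core genes that are individually predictive
of severity (per-gene ordered probit, one-sided, Bonferroni over the core),
so refined ⊆ core ⊆ effector by construction.

**ssGSEA.** Genes are ranked by expression descending (ties broken by gene
label for determinism); the score sums, over all positions, the difference
between the weighted in-set ECDF (weights = descending rank to the power
`alpha`, default 0.25) and the unweighted out-of-set ECDF. The running-sum
(not maximum-deviation) single-sample variant is used; being rank-based the
score is invariant under strictly monotone transforms.

**Ordered probit.** `P(y = j) = Phi(tau_j - beta z) - Phi(tau_{j-1} - beta z)`
fit by BFGS on `(beta, tau_1, log-gaps)` — the log-gap reparameterization
enforces strictly increasing cutpoints. Cutpoints initialize at the
empirical marginal quantiles; standard errors come from the observed
information; the reported p is the one-sided Wald test for `beta > 0`.
Complete separation (predictor perfectly ordering the categories) is
detected from the data before fitting and raises an informative error,
since the slope MLE is then unbounded. The implementation is checked
against `glm(probit)` at two categories and `MASS::polr` at four.

**Deconvolution markers.** A plain three-way filter on a DE table: raw
p < 1e-8, log-scale fold change >= 0.75, background expressing fraction
< 20%.

# The synthetic data generator

`generate_tissue()` places cells by a homogeneous spatial Poisson process
within axis-aligned rectangular niche regions (rectangles are the simplest
geometry whose planted labels are unambiguous), draws types from per-niche
compositions, and draws counts from type-specific negative-binomial
programs (shared size 5; negative-binomial rather than Poisson because UMI
data are overdispersed). The default density of 50 cells per 1e4 um^2
reproduces a median of ~14 neighbors within 30 um, typical of dense
intestinal mucosa. The planted circuit scales the receiver target-gene mean
by `1 + (max_induction - 1) exp(-d / decay_um)` (defaults: 8-fold at
contact, 50 um decay) with `d` the distance to the nearest sender cell.
Condition effects multiply per-type composition weights within each niche
and renormalize. One master seed drives an explicit per-sample seed stream,
so enlarging a simulation never perturbs the samples already generated.

The canned configurations fix the study conditions used throughout the
tests and analyses: `config_four_niche()` (four separated 500 x 500 um
blocks, each 70% one type — separation exceeds twice the neighborhood
radius so planted labels are exact), `config_circuit()` (a sender/receiver
co-occupancy strip abutting a wide receiver field, so nearest-sender
distances populate every proximity bin), and `config_atlas()` (both, plus a
3-fold disease expansion of the receiver type). `generate_cohort()` gives
each subject a latent signature level `s ~ N(0,1)`, shifts the 50 signature
genes by `s` on the log scale, and bins `u ~ N(beta_true s, 1)` at fixed
marginal quantiles into ordinal severity. `generate_lr_resources()` builds
a regulatory-potential matrix with planted ligands guaranteed inside
(scores 1.5-2) or outside (score 0) each TF's top-10 against 150
uniform-score decoys, plus a TF-activity matrix with a planted mean shift.

What the generator deliberately omits: tissue morphology, segmentation
error, doublets, batch effects, multi-subunit receptors, and spatially
varying density within a niche. Passing tests therefore demonstrate
correctness of the statistical machinery on data satisfying the model's
assumptions, not robustness to the artefacts of real spatial platforms.

# Problem sizes and determinism

The shipped analyses and tests use sizes chosen to make every property
measurable on a laptop: 5,000-cell tissues for niche recovery (10 seeds),
~2,000-cell circuit tissues for network and proximity recovery, 100-200
simulations for null calibrations, 500-subject cohorts for probit recovery,
and a ~20,000-cell four-niche atlas for the end-to-end pipeline run. Every
random draw descends from one integer seed via `seed_stream()`; rerunning
any stage with the same config yields byte-identical outputs, which the
pipeline verifies by md5 digest in its manifest.

# Worked example

```{r example, eval = FALSE}
tis <- generate_tissue(config_four_niche(seed = 1))
comp <- neighborhood_composition(tis$cells, r_um = 30)
model <- fit_niches(comp, k_range = 2:8, seed = 2, sil_cap = 1500)
model$k_selected                      # 4
enr <- niche_enrichment(model$labels, tis$cells$cell_type)
subset(enr, enriched)                 # one dominant type per niche
```

# Known limitations

* The abundance model supports one binary condition (plus an optional
  batch factor is out of scope); multi-level designs are not implemented.
* "Significant" interactions are DE-supported, not permutation-tested; a
  permutation null would be a natural extension but is not the default
  behaviour modelled here.
* The silhouette subsample trades exactness of model selection for speed;
  with very unbalanced niches a small subsample can under-represent rare
  niches.
* Gene symbols are matched exactly and case-sensitively across tables;
  cross-species or alias harmonization is the caller's responsibility.
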