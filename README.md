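# nichecircuit

Spatial niche discovery and niche-constrained cell–cell communication
analysis for single-cell spatial transcriptomics, with downstream driver
ligand prioritization, dual-cytokine synergy statistics, and signature-based
ordinal severity scoring.

The package is aimed at analysts of spatial atlases of inflamed tissue who
want to ask, end to end: *which multicellular microenvironments (niches)
does a tissue contain; which cell types expand in disease; which
ligand–receptor circuits operate inside shared niches — for example
activated macrophages inducing IL11 in inflammation-associated fibroblasts
(IAFs); which ligands drive the receiver's transcriptional program; and
does a signature of that program track clinical severity?* Because the real
atlases behind such questions are huge, the package includes a synthetic
tissue/cohort generator with planted ground truth, so the whole pipeline is
testable and demonstrable offline.

## Methods at a glance

* **Niches** — for every cell, count cells of each type within r = 30 µm in
  the same section (focal cell included); k-means over the composition
  vectors for k in a candidate range (default 5–35); the mean silhouette
  width selects k. Cell-type enrichment per niche by the χ² test of
  independence, d.f. = (N−1)(C−1), with standardized residuals
  (obs − exp)/√(exp(1 − row/n)(1 − col/n)) converted to two-sided p-values
  and Bonferroni-corrected over all N·C cells.
* **Differential abundance** — maximum-likelihood Dirichlet-multinomial
  regression y_s ~ DirMult(n_s, α_s), log α_sc = β0_c + β_c x_s with the
  reference category's β pinned to 0, pseudocount 0.001, per-category
  likelihood-ratio tests, BH correction, credible at FDR < 20%.
* **Communication** — an interaction (sender S, ligand L) → (receiver R,
  receptor G) is *relevant* if L and G are expressed in > 5% of S and R
  respectively, *significant* if additionally L ∈ DE-up(S) or G ∈ DE-up(R);
  score = product of min–max-scaled (across types) mean logTP10K
  expressions ∈ [0,1]; interactions must have S and R co-enriched in a
  common niche; edge weight = Σ significant scores.
* **Ligand funnel** — TFs selected by marker expression and by activity
  (mean difference > 0.75, p < 0.01); each TF votes for its top-10 ligands
  by regulatory potential; keep ligands with ≥ 5 votes and a receptor
  expressed in > 5% of target cells.
* **Synergy** — E_add = X + ΔA + ΔB; E_syn = X·(1 + ΔA/X)·(1 + ΔB/X) =
  E_add + ΔA·ΔB/X.
* **Severity** — single-sample gene-set enrichment (running-sum, rank
  weight exponent α = 0.25) of a derived signature per subject, then
  ordered probit P(y = j) = Φ(τ_j − βz) − Φ(τ_{j−1} − βz) with a one-sided
  test for β > 0; per-gene refinement with Bonferroni correction.

See `vignettes/spatial-cell-circuits.Rmd` for assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(nichecircuit)

tis   <- generate_tissue(config_four_niche(seed = 1))   # 4 planted niches, ~5,000 cells
comp  <- neighborhood_composition(tis$cells, r_um = 30)
median(rowSums(comp))
#> [1] 14

model <- fit_niches(comp, k_range = 2:8, seed = 2, sil_cap = 1500)
model
#> niche_model: k = 4 selected from { 2-8 } by silhouette ( 0.593 ); 4971 cells
mclust::adjustedRandIndex(model$labels, tis$truth$niche)
#> [1] 0.989
```

The silhouette argmax recovers the planted niche count (k = 4) and the
labels match the planted regions almost perfectly (ARI ≈ 0.99); the median
neighborhood size of 14 cells reflects the default tissue density. On a
planted-circuit tissue the full communication chain puts the macrophage →
fibroblast edge on top:

```r
tc  <- generate_tissue(config_circuit(seed = 21))
de  <- detect_markers(tc$expr, tc$cells$cell_type)
lr  <- lr_database(data.frame(ligand = c("IL1B", "HK1"),
                              receptor = c("IL1R1", "HK2")))
sc  <- score_interactions(tc$expr, tc$cells$cell_type, de, lr)
mdl <- fit_niches(neighborhood_composition(tc$cells, 30), k_range = 2:4, seed = 2)
net <- build_network(constrain_by_niche(sc, niche_enrichment(mdl$labels, tc$cells$cell_type)))
net$edges[which.max(net$edges$weight), ]
#>   sender receiver weight n_significant_interactions
#> 2 ActMac      IAF      1                          1

proximity_profile(tc$cells, tc$expr, "ActMac", "IAF", "IL11")[, c("bin", "n", "mean_expr")]
#>         bin   n mean_expr
#> 1    [0,30) 188      8.46
#> 2   [30,60)  40      8.09
#> 3  [60,100)  36      7.83
#> 4 [100,200)  91      7.28
#> 5 [200,Inf) 216      7.03
```

IL11 in IAFs decays monotonically with distance to the nearest activated
macrophage, as planted (8-fold induction, 50 µm decay).

## The analysis workflow

`analysis/01_simulate_atlas.R` … `analysis/06_score_severity.R` are thin
numbered drivers that run the pipeline stage by stage on a multi-sample
synthetic atlas, writing plain-file outputs under `results/pipeline/` (cell
tables, niche labels, enrichment, abundance, network, proximity profile,
ligand shortlist, severity fit) plus a digest manifest. Each takes an
optional seed argument: `Rscript analysis/01_simulate_atlas.R 1`. The same
orchestration is available programmatically via `run_pipeline()` /
`pipeline_config()`.

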