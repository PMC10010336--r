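# wpcna — weighted protein coexpression network analysis

`wpcna` is an R package for the network-based analysis of quantitative
(TMT) proteomics cohorts, of the kind used to dissect tumor tissue
proteomes: it detects coexpression modules in a protein abundance matrix,
summarizes them by eigenproteins and hub proteins, stratifies patients by
consensus clustering on a module's hub signature, and relates the strata
to overall survival. It is aimed at computational biologists who have a
proteins-by-samples log2-ratio matrix and a clinical table, and who want
the complete workflow — normalization to survival curves — as tested,
scriptable R functions rather than a collection of one-off scripts.

## The model

Given log2 abundances, the package builds a **signed weighted
coexpression network**: from pairwise biweight midcorrelations
`cor_ij`, the adjacency

    a_ij = ((1 + cor_ij) / 2)^beta

with the soft threshold `beta` chosen so the connectivity distribution is
consistent with scale-free topology. Adjacency is converted to the
**topological overlap matrix**

    TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
    L_ij = sum_u a_iu a_uj,  k_i = sum_u a_iu

and proteins are clustered by average linkage on `1 - TOM`; dynamic
branch cutting (minimum module size 50 by default) yields modules M1, M2,
… ordered by size, with unassigned proteins in M0. Each module is
summarized by its **eigenprotein** (ME, the first principal component of
the standardized member submatrix); **kME** is a protein's Pearson
correlation with an ME and defines the intramodular hubs. Patients are
stratified on a module's top-50 kME signature by **subsampled k-means
consensus clustering** (1,000 iterations, 80% of items and features per
round, complete-linkage cut of the consensus matrix), and the high/low
strata are compared by Kaplan–Meier/log-rank and Cox
proportional-hazards models. A synthetic-data generator with planted
modules, group shifts, TMT batch offsets and module-linked exponential
survival makes every stage verifiable against ground truth.

## Worked example

Simulate a 600-protein, 60-sample cohort with five planted modules
(module 2 linked to survival with log hazard ratio 1 per factor unit),
then run the full pipeline:

```r
library(wpcna)

cfg <- sim_config(n_proteins = 600, n_samples = 60,
                  module_sizes = c(150, 130, 120, 100, 60),
                  background_count = 40, kme_target = 0.85,
                  n_batches = 3, batch_sd = 0.2,
                  survival = list(linked_module = 2, log_hazard_per_unit = 1,
                                  baseline_scale = 20, censor_rate = 0.2),
                  seed = 11)
sim <- simulate_proteome(cfg)
res <- run_pipeline(sim$abundance, sim$clinical, top_fraction = 1,
                    min_size = 40, iterations = 200, seed = 5)
res
```

```
Coexpression pipeline run
Weighted protein coexpression network
  proteins: 600, samples: 60
  correlation: bicor, soft-threshold beta: 20 (auto-selected)
  modules: 5 (M1=170, M2=131, M3=120, M4=102, M5=60), unassigned (M0): 17
  signature M2 stratification: log-rank p = 1.79e-05
```

All five planted modules are recovered (adjusted Rand index vs truth
0.93; `adjusted_rand_index(res$network$modules,
sim$truth$module_of_protein)`), the survival-linked module M2 is the one
whose hub signature best separates survival, and the Cox model on the
strata confirms the planted direction — the signature-low group has
about a quarter of the high group's hazard:

```r
summary(res$network)
```

```
Coexpression modules (bicor, beta = 20)
 module size explained_variance top_hub
     M1  170              0.749  P00022
     M2  131              0.829  P00163
     M3  120              0.788  P00327
     M4  102              0.721  P00462
     M5   60              0.762  P00506
unassigned (M0): 17
```

```r
res$survival$cox
```

```
Cox proportional hazards (Efron ties): 60 subjects, 50 events
              coef    hr    se     z  p_value
signaturelow -1.28 0.279 0.316 -4.05 5.21e-05
```

Real data enter through `read_abundance()` (TSV with a `protein_id`
column) and `read_clinical()` (TSV with `sample_id`, optional `group`,
`batch`, `os_months`, `os_event` and covariates); `normalize = TRUE`
applies median-ratio/log2/per-batch-centering normalization to linear
ratios first. Individual stages are exported (`wpcna()`,
`consensus_matrix()`, `stratify_module_signature()`, `cox_fit()`,
`differential_expression()`, `enrich_hypergeometric()`, …) for use
outside the pipeline; see the vignette in `vignettes/` for the methods
and their assumptions.

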