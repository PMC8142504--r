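# immunosubtypes

Discovery and characterization of immune-related tumor subtypes from bulk
expression cohorts.

Tumors with similar histology can differ sharply in how much immune
infiltrate they carry, and that difference tracks prognosis and the odds of
responding to immune-checkpoint blockade. This package implements the full
analytical arc used to expose such structure in a cohort of gene × sample
expression data:

1. **Prognostic screen** — per-gene univariate Cox proportional-hazards
   fits over a list of immune-related genes; genes with Wald *p* < 0.05 are
   kept, and genes with unscaled MAD ≤ 0.5 are dropped as uninformative.
2. **NMF consensus subtyping** — Kullback–Leibler ("brunet") nonnegative
   matrix factorization *A* ≈ *WH* over ranks 2–6 with multi-restart
   consensus matrices; the rank maximizing the cophenetic correlation is
   selected (dispersion and mean silhouette are reported alongside), and
   cluster labels are harmonized so `sub1` is the immune-enriched subtype.
3. **Immune scores** — rank-based single-sample enrichment (ssGSEA) for
   28 immune cell types plus the formula scores: stromal/immune/combined
   (sum identity), IIS and TIS (NES means), CYT = √(GZMA·PRF1), a
   min–max-normalized 18-gene APM score, TMB (nonsynonymous variants/Mb
   from MAF), and checkpoint/IFN-γ/CD8 signature means; Wilcoxon group
   tests and Pearson "strong correlation" screening (r > 0.5, p < 0.05).
4. **DEGs + preranked GSEA** — Mann–Whitney tests with BH FDR and the
   thresholds p < 0.01, FDR < 0.05, |log2FC| > 1; Subramanian running-sum
   GSEA on the log2FC ranking with a gene-set permutation null.
5. **Mutation landscape** — per-subtype gene mutation frequencies,
   classification counts, the six-class pyrimidine-collapsed SNV spectrum,
   and driver-gene chi-square/Fisher comparisons.
6. **Random-forest classifier** — Cox-screened DEGs, mtry = 2 / 500 trees,
   repeated stratified ten-fold cross-validation over importance-ranked
   nested gene subsets, ROC/AUC, and cross-cohort concordance via per-gene
   rank normalization.
7. **Subclass mapping** — mutual SNR-marker enrichment between the
   subtypes of two cohorts (e.g. discovered subtypes vs immunotherapy
   responders), permutation p-values, Fisher-combined and
   Bonferroni-adjusted.
8. **Co-expression modules** — scale-free soft-threshold selection,
   topological overlap, static-cut module detection, eigengenes,
   module–trait statistics, and cross-cohort hub-gene intersection.

A negative-binomial synthetic-cohort generator (`simulate_cohort()`) plants
a two-subtype immune program with subtype-linked survival and mutation
burden, so the entire pipeline is testable offline; `run_pipeline()`
orchestrates everything from a YAML/list config deterministically.

## Worked example

```r
library(immunosubtypes)

co  <- simulate_cohort(cohort_config(seed = 1))   # 500 genes x 60 samples
scr <- screen_irgs(co$expression, co$clinical,
                   c(co$program_gene_ids, sprintf("GENE%04d", 1:100)))
scr
#> ScreenResult: 200 genes tested, 65 at p<0.05, 65 after MAD>0.5

st <- assign_subtypes(normalize_expression(co$expression)[scr$mad_retained_genes, ],
                      rank_range = 2:6, n_restarts = 20, seed = 1)
st$metrics
#>   k cophenetic dispersion mean_silhouette best_objective
#> 2 2      1.000      1.000           1.000           2603
#> 3 3      0.993      0.721           0.804           2459
#> 4 4      0.973      0.639           0.475           2351
#> 5 5      0.958      0.625           0.407           2257
#> 6 6      0.944      0.673           0.376           2165
st$assignment
#> SubtypeAssignment [cohort], k=2:
#> sub1 sub2
#>   30   30
```

The cophenetic coefficient peaks at rank 2 (1.000 vs 0.993 at rank 3), so
two subtypes are selected; here they coincide exactly with the planted
labels. The immune-enriched subtype separates on every immune score, and
membership in the immune-poor subtype carries the planted survival hazard:

```r
gs <- synthetic_gene_sets(co)
cs <- composite_scores(co$expression, gs, maf = co$maf)
wilcoxon_test(cs$scores$immune, unclass(st$assignment)[cs$scores$sample_id])
#> W = 900, p = 3.02e-11

cl <- co$clinical
fit_cox(as.integer(unclass(st$assignment)[cl$sample_id] == "sub2"),
        cl$os_time, cl$os_event)
#> CoxFit: n=60, events=43, converged=TRUE
#>   covariate  beta    hr     se    z         p lower95 upper95
#> 1         x 1.271 3.565 0.3445 3.69 0.0002246   1.815   7.003
```

The fitted hazard ratio of 3.57 (95% CI 1.8–7.0) for sub2 vs sub1 recovers
the generator's planted hazard ratio of 3. A complete multi-cohort run —
three cohorts, an immunotherapy cohort, all eight stages, byte-identical on
re-execution — is:

```r
cfg <- demo_config("demo_inputs", seed = 1)
run_pipeline(cfg, "demo_out")
```

## Layout

```
R/                  implementation (io, synthetic data, survival screen, NMF,
                    scoring, DEG/GSEA, classifier, SubMap, modules, pipeline)
src/                C++ multiplicative KL-NMF updates
inst/extdata/       APM and signature gene-set fixtures (GMT)
inst/scripts/       thin CLI wrapper (simulate / run)
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette: models, parameters, design decisions
```
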