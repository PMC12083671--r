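# zknock

Summary-statistic knockoff inference for GWAS, robust to sample
relatedness and study overlap.

## What it does, and for whom

Genome-wide association studies usually test each variant marginally and
control the family-wise error rate; for polygenic traits this misses many
small-effect loci. Model-X knockoffs control the false discovery rate
(FDR) for *conditional* tests instead, but classical constructions need
individual-level genotypes. `zknock` implements the summary-statistic
route: given marginal Z-scores and an LD correlation matrix, it draws M
Gaussian knockoff copies of the Z-score vector per LD block,

    Ztilde = P Z + E,   E ~ N(0, V),

with `P = 1_M (x) (I - D Sigma^-1)`,
`V = I_M (x) D + J_M (x) (D - D Sigma^-1 D)`, `D = diag(s)` from the
equicorrelated rule `s_j = min((M+1)/M * lambda_min(Sigma), 1)`. Variants
are scored by `T = Z^2` against `T_m = Ztilde_m^2`, combined into the
multiple-knockoff statistic

    W = (T - median_m T_m) * 1{T >= max_m T_m},

and selected by the (kappa, tau) filter at a user-chosen FDR level q.

The package is aimed at statistical geneticists who have GWAS summary
statistics (possibly from mixed-model score tests on related samples, or
from a meta-analysis of overlapping studies) plus an external LD panel,
and at methodologists who want a reproducible simulation harness for
FDR/power behavior of knockoff selection under relatedness. It includes:

* `sumstat_table()`, `read_sumstats()`, `z_from_p()` — summary-statistic
  I/O and two-sided p/Z conversion;
* `regularize_ld()`, `single_linkage_clusters()`,
  `choose_representatives()`, `partition_blocks()` — LD conditioning and
  |r| > 0.75 pruning to cluster representatives;
* `solve_s()`, `conditional_params()`, `sample_knockoff_z()`,
  `importance_and_W()`, `select_fdr()`, `ghostknockoff()` — the knockoff
  machinery;
* `fit_null_lmm()`, `lmm_score_test()`, `fit_null_logistic_mixed()`,
  `glmm_score_test()`, `fixed_effect_test()` — marginal tests with a
  fast block-kinship path;
* `estimate_study_correlation()`, `optimal_weights()`, `combine_z()`,
  `meta_analyze()` — overlap-aware meta-analysis;
* `generate_haplotype_pool()`, `gene_drop_families()`,
  `relationship_from_pedigree()`, `simulate_phenotypes()`,
  `sample_scheme()`, `relatedness_K()` — the simulation engine
  (three-generation pedigrees, gene dropping, case-control ascertainment);
* `scenario_config()`, `run_replicates()`, `report_selection()`,
  `merge_loci()`, `run_pipeline()` — benchmark harness and end-to-end
  pipeline (also exposed as a CLI in `inst/cli/zknock.R`).

## Worked example

A replicated benchmark: three-generation pedigree genotypes (300 families
of 10 by gene dropping), quantitative phenotypes with variance component
theta = 4, linear mixed-model score tests, GhostKnockoff selection at
q = 0.1 with M = 5 knockoffs:

```r
library(zknock)
cfg <- scenario_config(genotype = "pedigree", trait = "quantitative",
                       test = "mixed_score", analysis = "ghost",
                       theta = 4, replicates = 50, seed = 1)
res <- run_replicates(cfg)
print(res)
#> Scenario: pedigree / quantitative / mixed_score / ghost (theta=4, q=0.1, M=5)
#> Replicates: 50 (failed: 0); representatives: 303
#> Empirical FDR: 0.0426 (SE 0.0129)
#> Empirical power: 0.2420 (SE 0.0345)
```

The mean false discovery proportion (0.043) sits below the nominal level
q = 0.1 — the selection filter spends less than its FDR budget — while
about a quarter of the ten causal clusters are recovered per replicate at
this sample size. Selections come with cluster context: after a real-data
run, `report_selection()` attaches cluster members in high LD
(|r| >= 0.75) with at least the representative's signal strength, and
`merge_loci()` collapses selections into loci at a 1 Mb gap.

For a file-based run, `run_pipeline()` takes a manifest (paths to the
summary-statistic table, the LD matrix and its variant sidecar, plus
q/M/cutoff/seed) and writes the selection, neighbor and loci tables with
a resolved-manifest JSON next to them.

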