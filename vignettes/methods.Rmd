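---
title: "Summary-statistic knockoff inference for GWAS: models and design"
author: "zknock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistic knockoff inference for GWAS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zknock)
```

## The problem

Conventional GWAS tests each variant marginally and controls the
family-wise error rate. For polygenic traits, controlling the false
discovery rate (FDR) instead recovers many small-effect loci — but naive
FDR procedures applied to marginal tests break down because nearby
variants are correlated through linkage disequilibrium (LD). Model-X
knockoffs solve this by testing *conditional* independence: each variant
is compared against a synthetic negative-control copy that is exchangeable
with it under the null.

Classical knockoff constructions need individual-level genotypes. This
package implements the summary-statistic route: given only marginal
Z-scores and an LD reference panel, it draws M knockoff copies of the
Z-score vector directly and applies the multiple-knockoff selection
filter. Because the input is just `(Z, Sigma)`, the same machinery accepts
Z-scores from mixed-model score tests (which absorb sample relatedness)
and from overlap-aware meta-analysis — the two settings the simulation
harness in this package is built to probe.

## The knockoff model on the Z-score scale

For one LD block with correlation matrix $\Sigma$ (unit diagonal), the
joint law of the original Z-vector and its $M$ knockoff copies is the
$(M+1)p$-dimensional Gaussian with covariance

$$
I_{M+1} \otimes D \; + \; J_{M+1} \otimes (\Sigma - D),
\qquad D = \mathrm{diag}(s),
$$

which is positive semidefinite iff $s \ge 0$ and
$(M+1)\Sigma - M D \succeq 0$. Knockoffs are sampled from the conditional
law

$$
\tilde Z = P Z + E, \qquad E \sim N(0, V),
$$

with $P = 1_M \otimes (I - D\Sigma^{-1})$ and
$V = I_M \otimes D + J_M \otimes (D - D\Sigma^{-1}D)$. `solve_s()`
implements the equicorrelated rule
$s_j = \min\{\tfrac{M+1}{M}\lambda_{\min}(\Sigma),\, 1\}$ (default), plus a
coordinate-ascent log-determinant variant for small blocks; both are
followed by a shrink-and-clip repair so the joint covariance passes a
numerical PSD check at tolerance $10^{-8}$. Sampling uses the exchangeable
structure of $V$ directly: a rotation whose first direction is the
equi-weight vector block-diagonalizes $V$ into one
$(M+1)D - M D\Sigma^{-1}D$ block and $M-1$ copies of $D$, so a draw costs
two $p$-dimensional matrix-vector products rather than a $pM \times pM$
factorization.

Importance is $T = Z^2$ against $T_m = \tilde Z_m^2$. Per variant,
$\kappa$ records whether the original beat all its knockoffs, $\tau$ the
gap between the winner and the median of the rest, and

$$
W = \left(T - \mathrm{median}_m T_m\right)\,
    \mathbf{1}\{T \ge \max_m T_m\} .
$$

`select_fdr()` applies the multiple-knockoff threshold: the smallest
positive $\tau$ value $t$ with

$$
\frac{1/M + \tfrac1M\,\#\{j : \kappa_j \ge 1,\ \tau_j \ge t\}}
     {\max(1,\ \#\{j : \kappa_j = 0,\ \tau_j \ge t\})} \le q .
$$

With a single candidate and $M = 5$, the estimate is $1/5$, so the
candidate is selected at $q = 0.2$ but not at $q = 0.1$ — the offset
$1/M$ is why several knockoff copies make low target levels usable.

Conventions worth stating: for even $M$ the median is the midpoint of the
two central order statistics; the threshold comparison uses
$\tau_j \ge t$ (the threshold is attained by construction); and selection
is monotone in $q$.

## Z-scores in and out

`z_from_p()` uses the two-sided convention $|z| = \Phi^{-1}(1 - p/2)$ with
the sign supplied by the direction of effect (a sign or a signed beta). A
signed beta of exactly zero maps to $+1$ with a warning rather than
dropping the variant. P-values below $10^{-300}$ are clamped there, so
$|z|$ stays finite on its way into the knockoff sampler — an underflowing
GWAS hit loses nothing that matters at that magnitude.

## LD conditioning, clustering, representatives

Eq. above needs $\Sigma^{-1}$, so `regularize_ld()` shrinks toward the
identity, $R' = (1-\lambda)R + \lambda I$, taking the smallest $\lambda$
on the grid $\{0, 0.001, 0.01, 0.05, 0.1, 0.25\}$ that lifts the smallest
eigenvalue to $10^{-4}$.

Variants in near-perfect LD cannot be distinguished by any conditional
test, so tightly linked variants are first collapsed:
`single_linkage_clusters()` agglomerates at distance $1 - |r|$ and cuts so
that no two clusters are cross-correlated above 0.75 in absolute value.
Absolute correlation is the right notion here because importance is
sign-free ($T = Z^2$). Each cluster is represented by its member with the
largest sum of absolute within-cluster correlations (ties to the lowest
index, for determinism). After selection, `report_selection()` attaches
cluster members that are both in high LD with a selected representative
($|r| \ge 0.75$) and at least as significant marginally — the
representative stands for the cluster, and fine-mapping within it is out
of scope.

Block boundaries (BED-style, half-open) are accepted but not bundled;
without them each chromosome is one block, which is valid but slower.

## Mixed-model association tests

The generative model for a phenotype with family structure is
$g(\mu) = X\alpha + G\beta + b$, $b \sim N(0, \theta\Phi)$, where $\Phi$
is the additive relationship matrix. `fit_null_lmm()` maximizes the
Gaussian likelihood with $\mathrm{Cov}(y) = \theta\Phi + \sigma^2 I$ by a
1-D profile over $h = \theta/(\theta+\sigma^2)$ using the
eigendecomposition of $\Phi$; ML rather than REML, because the goal is a
calibrated score test (whose variance uses the $n$-denominator), not
unbiased component estimation. When $\Phi$ is block-diagonal with
identical families — the `kinship_blocks()` fast path — only the small
within-family matrix is decomposed and the rotation is applied by
reshaping, which is what makes 200-replicate benchmarks with 3000 samples
run in seconds.

The score test is the efficient score
$U = g^\top \hat V^{-1}(y - X\hat\alpha)$ with variance
$g^\top \hat V^{-1} g - g^\top \hat V^{-1} X (X^\top \hat V^{-1} X)^{-1}
X^\top \hat V^{-1} g$; a variant with variance below $10^{-12}$ is
declared monomorphic and reported as $(p = 1, +1)$. With $\Phi = I$ this
reduces exactly to the ordinary linear score test.

Binary traits use penalized quasi-likelihood: iterate the logistic
working response and weights, refit the working linear mixed model, and
refresh $\theta$ by maximizing the working Gaussian likelihood, to joint
tolerance $10^{-6}$. Two caveats are deliberate and documented: PQL's
variance component is attenuated for rare binary traits (at 10%
prevalence, a true $\theta = 1$ is typically estimated well below 1), yet
the resulting *score test* remains close to calibrated, which is what FDR
control needs; and there is no saddle point correction for extreme
case-control imbalance. Separation (probabilities pinned at 0 or 1)
raises an error rather than returning garbage.

Wald and likelihood-ratio variants (`fixed_effect_test()`) exist because
knockoff selection should be robust to which flavor of marginal test
produced the Z-scores; for linear models all three are closed-form and
vectorized.

## Meta-analysis with sample overlap

For $L$ studies with possibly shared samples, null Z-scores correlate
across studies. `estimate_study_correlation()` estimates $Cor.S$ as the
Pearson correlation of per-study Z over LD-pruned representatives that
look null in both studies ($|Z| < 1.96$) — pruning removes LD-driven and
signal-driven correlation so what remains reflects overlap (about
$n_{\text{shared}}/\sqrt{n_i n_j}$). At least 200 shared usable variants
per pair are required. The truncation to null-ish variants attenuates the
estimate slightly; this bias is second-order for the normalization below.

Weights solve
$\min_w w^\top Cor.S\, w$ s.t. $\sum_l w_l \sqrt{n_l} = 1$, $w \ge 0$,
via a small active-set iteration (pseudo-inverse on the free set, so
duplicated studies get the minimum-norm even split). The $\sqrt{n}$ scale
in the constraint is the power-maximizing convention: it reproduces
$w_l = 1/(L\sqrt{n})$ for equal-n independent studies and makes the meta
Z grow like $\sqrt{n}$ under alternatives. The combined score is

$$
Z_j = h_j \sum_l w_l c_{lj} Z_{lj}, \qquad
h_j = \Big(\sum_{s,t} w_s w_t c_{sj} c_{tj}\, Cor.S_{st}\Big)^{-1/2},
$$

where $c_{lj}$ flags whether study $l$ observed variant $j$; $h_j$
restores unit null variance under any observation pattern, and a variant
seen in one study passes through unchanged. Allele harmonization is
deliberately minimal: exact match on (chrom, pos, ref, alt), sign flip on
swapped ref/alt, drop anything else with a log message.

## What the synthetic-data engine emulates

The simulation engine reproduces a specific study design: a European-like
haplotype pool, three-generation pedigrees filled by gene dropping, and
(mixed) generalized linear phenotypes.

**Haplotype pool.** Real coalescent haplotypes are emulated by
thresholding a latent stationary AR(1) Gaussian process at per-site
quantiles, giving binary haplotypes that hit their target allele
frequencies (log-uniform on $[0.005, 0.5]$, then a MAF $\ge 0.01$ filter)
with positively correlated neighbors. Thresholding attenuates
correlation: a latent coefficient of 0.9 yields allele correlations
almost never above 0.75, i.e. no clustering at the pruning cutoff. The
default `ld_decay = 0.97` was chosen so that a 400-site pool yields
roughly 300 cluster representatives — tight multi-variant clusters exist,
as in real LD, without degenerating. What this model does *not* emulate:
recombination gradients, mutation-age/frequency coupling, and long-range
LD; conclusions from passing tests are about the inference machinery, not
about any specific human LD landscape.

**Pedigree and kinship.** The default family has ten members across three
generations (two founding grandparents, two of their children, two
married-in spouses, four grandchildren). `relationship_from_pedigree()`
implements the additive-relationship recursion; on the default pedigree it
reproduces the expected entries (parent-offspring and full siblings 0.5,
avuncular 0.25, first cousins 0.125) exactly. Gene dropping transmits one
whole haplotype per parent (zero recombination, appropriate for a short
region), so dosage correlations between relatives converge to $\Phi$.

**Phenotypes.** Quantitative: $y = X_1 + G\beta + b + \epsilon$ with
$X_1 \sim N(0,1)$, $b \sim N(0, \theta\Phi)$ and
$\mathrm{Var}(\epsilon) = 8 - \theta$, so total variance is invariant to
$\theta \in \{1, 4, 7\}$ and power is comparable across relatedness
levels. Dichotomous: $\mathrm{logit}(\pi) = \beta_0 + X_1 + G\beta + b$
(an independent $N(0,1)$ term replaces $b$ in the unrelated model), with
$\beta_0$ calibrated by bisection so the Monte-Carlo prevalence is 10%.
Effect sizes follow $|\beta_j| = \sqrt{a/(10\,\mathrm{Var}(G_j))}$ over
10 causal representatives — half protective, half risk — so the causal
variants jointly explain $a$ (1 for quantitative, 2.5 for binary traits)
when uncorrelated.

**Ascertainment.** Three case-control schemes, ordered by induced
within-family phenotype concordance: individual sampling (A), whole-family
sampling (B), and all-cases-from-case-families with controls only from
control families (C). The statistic $K$ — the mean over families, among
those contributing at least one selected pair, of the fraction of
same-family pairs concordant in case status — is exactly 1 under scheme C
by construction; families with no pair are excluded from the average
because their per-family ratio is undefined. Quotas exceeding what the
foundation data contains (e.g. 5000 cases from 10,000 individuals at 10%
prevalence) are clamped to availability with a warning.

## The benchmark harness

`run_replicates()` wires the modules into a replicated experiment. The LD
panel is computed once from the haplotype pool (mirroring real usage,
where the panel is external to the study) so the knockoff model
$(s, P, V)$ is constructed once per scenario; per replicate, genotypes,
phenotypes, marginal tests and the knockoff draw (seed
`base + 10000 + replicate`) are fresh. True positives are counted with
cluster credit: a selected representative is correct iff its cluster
contains a causal variant — since causal variants are drawn among
representatives, this coincides with exact identity here but keeps the
definition stable if causal non-representatives are ever allowed.
Comparator analyses: `individual_knockoff` draws second-order knockoff
*genotype* copies with the same $(s, P, V)$ and re-runs the marginal test
on them; `meta_ghost` splits the sample into two disjoint half-studies and
feeds the weighted meta Z-scores into the same filter.

Problem sizes are the package's desk-scale defaults: 200 replicates of
300 ten-member families (or 3000 unrelated individuals) over a 400-site
pool (~300 representatives), $M = 5$, $q = 0.1$, chosen so a scenario
completes in seconds-to-minutes on one CPU; every dimension is a
`scenario_config()` knob. With ten causal variants among ~300
representatives and one causal cluster falsely swapped in per ~10
selections, the Monte-Carlo standard error of the mean FDP at 200
replicates is about 0.01, which is the resolution at which the FDR
claims in the test suite are asserted.

## Numerical choices and degenerate inputs

* LD shrinkage grid and eigenvalue floor $10^{-4}$; sub-block reuse of an
  already-conditioned panel applies no further shrinkage.
* $s$ repair: shrink by 0.99 until the joint covariance clears
  $-10^{-8}$, then clip negatives to zero; $s = 0$ reproduces
  $\tilde Z = Z$ exactly (a valid, powerless construction).
* Monomorphic variants: score variance below $10^{-12}$ reports
  $(p = 1, +1)$ with a warning; causal-effect assignment resamples them.
* P-value floor $10^{-300}$; conversions round-trip to $10^{-10}$
  relative error down to that floor.
* Representative and threshold ties: lowest index wins; threshold uses
  $\ge$.
* PQL: Brent over $\theta$ on $[0, 50]$, narrowed around the previous
  estimate after the first outer iteration (re-widened if the optimum
  pins at the window edge); explicit boundary comparison against
  $\theta = 0$.
* Degenerate meta inputs: a singular $Cor.S$ yields the minimum-norm
  weights; variants observed nowhere are excluded with a message.

## Known limitations

* The LD panel must cover the tested variants; there is no sparse or
  banded LD storage, so blocks beyond a few thousand variants are
  impractical.
* PQL underestimates $\theta$ for rare binary traits; the score test
  stays usable, but the reported component should not be interpreted as
  heritability.
* No saddle point correction for severe case-control imbalance; no
  allele liftover or strand inference beyond exact/swapped matching; no
  X-chromosome or inbred pedigrees ($\Phi_{ii} \ne 1$ unsupported).
* The equicorrelated $s$ is conservative for strongly heterogeneous
  blocks; the `ldet` variant helps only for small blocks.
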