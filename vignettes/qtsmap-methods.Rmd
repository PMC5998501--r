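---
title: "Methods: full-model QTS mapping with epistasis and environment interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-model QTS mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `qtsmap`, the design
choices made where the methodology was genuinely open, the numerical
conventions, and what the synthetic-data validation does and does not
demonstrate.

## The full genetic model

A quantitative trait observed on accession *k* in environment *h* is
decomposed as

$$y_{kh} = \mu + \sum_i a_i x_{A_{ik}} + \sum_i d_i x_{D_{ik}}
 + \sum_{i<j}\left(aa_{ij}x_{AA} + ad_{ij}x_{AD} + da_{ij}x_{DA} + dd_{ij}x_{DD}\right)
 + e_h + \text{(G$\times$E terms)} + \varepsilon_{kh}$$

where $x_A \in \{1, 0, -1\}$ and $x_D \in \{0, 1, 0\}$ code the QQ/Qq/qq
genotypes at each quantitative trait SNP (QTS), the four digenic epistasis
coefficients are elementwise products of the two loci's columns
($x_{AA} = x_{A_i}x_{A_j}$, $x_{AD} = x_{A_i}x_{D_j}$,
$x_{DA} = x_{D_i}x_{A_j}$, $x_{DD} = x_{D_i}x_{D_j}$), and each
gene-environment (G×E) term pairs a random per-environment effect (ae, de,
aae, ade, dae, dde) with the same coefficient as its fixed counterpart.
Genetic effects are fixed; the environment main effect, all G×E effects
and the residual are random with variances $\sigma^2_E$,
$\sigma^2_{\cdot E}$ (one per genetic effect) and $\sigma^2_\varepsilon$.

Q is taken to be the **major** allele, so effect signs are relative to the
major-allele homozygote. The convention matters only for signs: relabeling
the alleles at a locus flips the sign of $a$ (and swaps the ad/da roles in
its pairs) while leaving dominance terms, test statistics and heritabilities
unchanged, which the test suite asserts. The $x_{DA}$ coefficient, not
written out explicitly in some presentations of the model, is completed by
symmetry as $x_{D_i} x_{A_j}$.

## Two-stage estimation

The number and identity of QTSs is unknown a priori, so estimation runs in
two stages, scans first and the full model last.

**Scan stage.** `scan_1d()` tests the joint (a, d) effect of one locus and
`scan_2d()` the joint (aa, ad, da, dd) block of a pair, given both loci's
main effects. Both absorb the environment as fixed blocks and use ordinary
F statistics; with two or more environments the interaction columns
($x \times$ environment contrasts) are tested separately as a
variance-ratio F. This deliberate approximation keeps the scans cheap
enough for permutation calibration; the exchangeable random-effect
treatment of G×E is reserved for the final model. Missing genotypes are
mean-imputed per locus at the scan stage only.

**Experiment-wise thresholds.** `permutation_threshold()` permutes the
accession-to-phenotype assignment *within each environment* (replicates
follow their accession), so the environment main effect is preserved under
the null. The familywise maximum F over all scanned loci (or pairs) is
recorded per permutation and the empirical $(1-\alpha)$ quantile is the
threshold. The default of 1000 permutations at $\alpha = 0.05$ follows the
convention for this analysis; the packaged demonstration pipeline uses 200
to keep the integration test quick, a size at which the test suite still
verifies the experiment-wise error empirically (0.05 ± 0.02 over 200 null
experiments in the acceptance suite, which uses the full 1000).

**Full model.** `fit_qts_model()` assembles all selected QTSs and pairs
into one design and samples the posterior by Gibbs: the fixed block from
its multivariate normal conditional (flat prior, Cholesky precomputed),
each random effect from its scalar normal conditional, and the variance
components from inverse-gamma conditionals. Posterior means are the point
estimates; per-effect significance is summarized as a Wald
$-\log_{10} p$ from the posterior mean/sd ratio against a standard
normal — the convention used for the printed effect tables, with the
experiment-wise permutation threshold remaining the formal significance
criterion at the scan stage. Defaults are 20,000 iterations with 2,000
burn-in and thinning 1; the examples and tests use 2,000–5,000 iterations,
which the split-chain potential-scale-reduction diagnostic (computed for
every fixed effect, warning above 1.1) shows to be ample at these problem
sizes.

Two numerical details matter. First, a fixed genetic effect is exactly
confounded with the mean of its own per-environment interaction effects
(the likelihood identifies only $a_i + \overline{ae_{ih}}$); a plain Gibbs
scheme mixes very slowly along that flat direction. The sampler therefore
interleaves a recentering sweep — sampling the shift along each flat
direction from its exact Gaussian conditional and moving it between the
fixed effect and its random effects — which restores fast mixing without
changing the posterior. The same sweep links the intercept and the
environment main effects. Second, with only a handful of environments each
G×E variance component rests on just H draws, so no weak prior makes the
component parameter simultaneously well-calibrated and unbiased: a light
(Jeffreys-like, shape 0.5) inverse-gamma prior is used for sampling, which
keeps the fixed effects' credible intervals honest about interaction
uncertainty, while the heritability summaries use the *realized* component
— the posterior mean of the average squared interaction effect, which the
data identify directly — rather than the weakly-identified variance
parameter. Null components collapse toward zero under both summaries.

Degenerate design columns (monomorphic loci, empty two-locus cells) and
collinear columns are dropped and logged; observations from accessions
with missing genotypes at selected loci are dropped and counted.

## Heritability

For a fixed effect $b$ on coefficient column $x$ the phenotypic-variance
contribution is $b^2\,\mathrm{Var}(x)$ with the realized
(equal-accession-weight) variance of the column; for a G×E class with
variance component $\sigma^2$ it is $\sigma^2\,\mathrm{E}[x^2]$ — the
realized variance the class contributes across environments. The
denominator $V_P$ is the variance of the *environment-centered*
phenotypes: the environment main effect is excluded, a choice forced by
the observation that published totals for these traits reach 93%, which
is implausible if the environment main effect sat in the denominator. It
is switchable via the `V_P` argument.

Per-effect values are marginal (covariances between non-orthogonal
coefficient columns ignored), matching the field's per-effect tables; on
panels where selected QTSs are correlated the marginal class sums can
exceed 100%, so `heritability(model, method = "joint")` also offers the
joint decomposition, computing each class's variance from its summed
contribution and the total from the whole genetic prediction. The
pipeline additionally thins significant loci (keeping the strongest hit
per LD cluster above r² = 0.5) before the full model, which keeps the
marginal partition interpretable in practice.

`true_heritabilities()` applies the same formulas to a simulated
architecture with $V_P$ defined as the sum of all components plus the
residual variance, making it an exact oracle when causal loci are
(near-)independent; recovery tests therefore place causal loci on
distinct chromosomes at frequencies near 0.5, where the marginal
decomposition is exact in expectation.

The genotypic correlation $r_g$ between two traits is computed as the
Pearson correlation, across accessions, of the two models' total predicted
genetic values (main plus epistatic effects, no environment terms); the
phenotypic $r_p$ uses accession means pooled over environments. Both
levels are conventions, stated here because the estimators are not
uniquely determined by the quantities they mimic.

## GMDR prescreening

Scanning all SNP pairs (let alone triples) genome-wide is infeasible, so a
generalized multifactor dimensionality reduction (GMDR) filter runs first.
For a quantitative trait the GMDR score is the residual under the null
model — the grand mean, or environment-stratified means when the
environment covariate is included. Accessions are binned into multilocus
genotype cells; cells with positive mean training score are labeled
high-risk (empty cells low-risk); the testing statistic is the balanced
accuracy of sign(score) against the cell label on held-out folds (10-fold
cross-validation by default), and cross-validation consistency counts
folds above chance. These concrete instantiations — score, threshold 0,
balanced accuracy — are the standard GMDR conventions; the published
analyses this package mirrors leave them to their references, so the
screened-set sizes per trait are not reproduction targets. Panels larger
than the beam width replace exhaustive higher-order enumeration with a
two-stage beam (top marginal SNPs seed pairs and triples); the exhaustive
path remains for oracle tests. Both strategies — with and without the
environment covariate — are run and their retained sets unioned.

## Superior-genotype design

`design_superior()` finds the exact optimum of the genetic value over the
allowed genotype space: homozygotes only for line designs (GSL, SL), all
three genotypes for hybrids (GSH, SH). Loci are partitioned into connected
components of the epistasis graph; isolated loci are optimized
independently and components are enumerated exhaustively (vectorized and
chunked; components above 20 loci are refused with guidance, a size that
does not arise at realistic model scales). Ties break lexicographically
(QQ < Qq < qq). The genetic value excludes $\mu$ and the environment main
effect — designs compare genotypes, not locations. Environment-specific
designs add the posterior-mean G×E effects of the chosen environment,
including epistasis-by-environment terms (switchable via
`include_epistasis_gxe`), since those designs exist precisely to exploit
gene-by-environment interaction. Heterozygous designs are allowed
per-locus without cross-locus parental feasibility constraints: any single
heterozygote is realizable from two homozygous parents, and pedigree-level
planning is out of scope.

## The synthetic-data generator

The generator emulates the study design the package targets: ~316
accessions in two subpopulations, three environments with three
replicates, MAF ≥ 0.01, LD with an r² half-decay distance around 160 kb.
Its mechanisms, chosen as the simplest standard models with the right
testable signatures:

* **Subpopulations** via Balding–Nichols: per-SNP subpopulation
  frequencies drawn from a beta around a shared ancestral frequency with
  parameter F = `divergence`, which equals the expected Hudson F~st~ (the
  test suite verifies ±0.05 at n = 2000).
* **LD** via a Gaussian-copula autoregression along each chromosome with
  latent correlation $\exp(-d \ln 2 / (2L))$ at distance $d$, so pairwise
  r² halves at $L$ = `ld_block_bp`. The rate constant is calibrated to
  make the half-decay distance equal the named parameter — a raw per-bp
  rate of $1/L$ would put the half-decay at ≈ 0.35 L.
* **Genotypes** by thresholding independent haplotype copies at the
  subpopulation frequency: Hardy–Weinberg within subpopulation. A
  deterministic MAF floor flips the haplotypes nearest the threshold when
  a SNP's empirical MAF falls short, preserving LD and seeded
  reproducibility.
* **Phenotypes** drawn exactly from the full model: environment effects
  once per environment, each G×E effect once per (effect, environment),
  residuals per observation. In the generator Q is the *counted* allele
  (`recode_major = FALSE` coding), so planted signs are directly
  interpretable.

What the generator does **not** emulate: inbreeding (real cotton
accessions are largely selfing, with far lower heterozygosity than
Hardy–Weinberg at intermediate frequency — consequently the 30%
heterozygosity QC rule removes many mid-frequency synthetic SNPs, which is
correct filter behavior exercised deliberately in tests), missingness
patterns (injected separately via `degrade_panel()`), tetraploid
homoeology, selection or pedigree structure. Passing tests on this
generator therefore demonstrate the statistical machinery under the
model's own assumptions, not robustness to the ways real panels violate
them.

One consequence worth knowing: with only three environments, the realized
variance of any single G×E effect (three draws) scatters widely around its
parameter, so per-seed class-heritability comparisons against the oracle
are intrinsically noisy; validation averages over 20 independent seeds,
where agreement within 3 percentage points is the demonstrated behavior.
Two-stage scanning also inherits the familiar "phantom epistasis" of
marginal pair tests — a pair sharing one locus with a true epistatic pair
can exceed the threshold because the omitted interaction leaks into its
test — which the joint full-model fit then resolves by shrinking the
spurious pair's effects.

## Problem sizes and defaults

Defaults mirror the target study: 316 accessions, 3 environments × 3
replicates, MAF 0.01, call rate 0.70, heterozygosity 0.30, adjacency 5 bp,
depth 60–6500× (applied only when depth metadata exists), LD pruning at
r² 0.1 in 50-SNP windows, 1000 permutations at α 0.05, 20,000 Gibbs
iterations, GMDR retention ~1000 SNPs per trait. The packaged
demonstration configuration scales the stochastic stages to a
300-accession, 1000-SNP panel with 200 permutations and 2,000 iterations;
the validation suite uses 316 × 1000 with 4,000–5,000 iterations and
20 seeds for parameter recovery, and 200 null experiments of 200 × 200
for threshold calibration. These sizes were chosen so the full
demonstration remains interactive on a laptop while keeping every
statistical claim testable.

## Known limitations

* The scan-stage F statistics are an approximation to the mixed-model
  scan; their calibration is guaranteed by the permutation thresholds,
  not by the F reference distribution.
* Per-effect −log₁₀p from the full model is a Wald summary of the
  posterior, not a frequentist tail probability.
* No kinship/polygenic background term: the model deliberately mirrors
  the published analysis, which relies on GMDR prescreening, permutation
  thresholds and a post-hoc subpopulation chi-square check
  (`subpop_genotype_chisq()`, Bonferroni-adjusted) rather than a
  structure covariate.
* Replicate-agreement QC flags but does not drop, and triple technical
  measurements are averaged before the replicate check; both are
  conventions where the source protocols are silent.
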