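---
title: "Heritability with tagged pairwise interactions: model and methods"
author: "ildscr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability with tagged pairwise interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildscr)
```

## The model

Standard LD score regression estimates narrow-sense heritability from GWAS
summary statistics by exploiting the linear relationship between a
variant's expected chi-square statistic and its LD score
$\ell_j = \sum_k r_{jk}^2$, the summed squared correlation with its
neighbors. `ildscr` extends this with a second score per variant, the
*cis-interaction* LD score

$$f_j \;=\; \sum_{k \in \mathrm{window}(j),\, k \neq j} v_{jk}^2,
\qquad v_{jk} = \mathrm{cor}\!\left(x_j,\; x_j \circ x_k\right),$$

the summed squared correlation between the focal genotype and the
element-wise products of that genotype with each window neighbor. Because
a genotype column is correlated with its own nonlinear products whenever
its standardized distribution is skewed (any allele frequency away from
1/2), marginal GWAS effect estimates absorb — *tag* — part of the variance
contributed by pairwise SNP-by-SNP interactions. The joint regression

$$\mathbb{E}[\chi^2_j] \;=\; \mathrm{intercept} + \ell_j \tau + f_j \vartheta$$

separates the additive signal ($\tau$) from this tagged interaction signal
($\vartheta$). With the regressors pre-scaled by $N/J$ and $N/M$ (sample
size over variant count and over total pair count), both coefficients sit
directly on the variance-explained scale and their sum is the heritability
estimate. A two-sided test of $H_0{:}\,\vartheta = 0$ (jackknife standard
errors) flags traits whose summary statistics carry tagged interaction
variance. The quantitative-genetics average effect
$\eta_j = \beta_j + 2\sum_{k} p_k \theta_{jk}$ gives the theoretical upper
bound $\sigma^2_A = \sum_j 2p_jq_j\eta_j^2$ on what any additive summary
statistic can recover; `additive_variance_bound()` computes it.

## Numerical and design choices

**Correlation definition of the interaction score.** The efficient
quadratic-form route for $f_j$ can be written without centering the
Hadamard product; because the score is defined as a *sample correlation*,
we center and scale the product column (the uncentered raw moment remains
available via `centered = FALSE`). The fast path uses the algebraic
identities $\mathrm{cov}(x_j, x_j \circ x_k) = \overline{s_j x_k}$ and
$\mathrm{var}(x_j\circ x_k) = \overline{s_j s_k} - \overline{x_j x_k}^2$
with $s_j = x_j \circ x_j$, so no product column is ever materialized; it
is verified against an explicit-construction oracle and a scalar-loop
implementation.

**Self pairs.** The product of a variant with itself tags skewness alone
and is excluded by default (`include_self = TRUE` restores it).

**MAF architecture (alpha).** Per-pair terms are weighted by
$(2p_kq_k)^{1+\alpha}$, normalized to unit mean across the panel. The
normalization matters: without it the weighted score column changes its
overall magnitude with $\alpha$ and the regression coefficients leave the
variance-explained scale. At $\alpha = -1$ every weight is exactly 1
(unweighted scores on standardized genotypes). The $(1-\alpha)$ exponent
convention that appears in parts of the MAF-architecture literature is
selectable via `alpha_exponent = "one_minus"`. $\alpha$ is an input: the
REML-based estimation of $\alpha$ from raw genotypes is out of scope, and
in simulations we supply the generative value (0 unless stated).

**Small-sample bias correction.** Squared sample correlations
overestimate their population counterparts by roughly $(1-r^2)/N$; each
pair term is corrected as $\tilde r^2 - (1-\tilde r^2)/(N-2)$, identically
for $\tilde v^2$. Corrected scores may dip below zero by at most the
window size over $N-2$.

**Windows.** Inclusive distance (`<= half_width`), never crossing
chromosome boundaries. The additive score defaults to 1 cM (with
1 cM approximated as 1 Mb when the genetic map column is all zero), the
interaction score to ±5, ±10, ±25, ±50 SNPs with ±50 the default
analysis column — larger windows gave the most stable estimates upstream.
Pairs are counted once per focal SNP, so a pair inside both windows
contributes to both $M_j$ and $M_k$; $M = \sum_j M_j$ is the pair
denominator used for coefficient scaling. Whether a "distinct unordered
pairs" denominator is preferable is undecidable from the published
description; the convention here is fixed and documented.

**Regression.** Iteration 0 is unweighted least squares; two further
passes (the conventional count) recompute weights
$\psi_{jj} = \max(\hat\mu_j, 1)^{-2}$ from the fitted means. The
heteroscedasticity weight is the only default weight; the LDSC
"overcounting" $1/\ell_j$ factor is available (`overcount_weight`) but
off, since the target model's weight definition does not include it. The
intercept is free by default (`free_intercept = FALSE` constrains it to
1, the constrained form of the model). Chi-square outliers above
$\max(80, 0.001N)$ are removed, mirroring standard practice; the filter
is logged in the fit object and can be disabled with `max_chisq = Inf`.
The weight recursion uses the *current* intercept estimate inside
$\psi$, not the constrained value 1.

**Jackknife.** Contiguous, near-equal blocks in genomic order; the final
weighted regression is re-solved with each block deleted, holding the
weights fixed at their full-fit values (the convention of the reference
software; it also makes the exactly-linear case give exactly zero SE).
The delete-$m_j$ variance formula reduces to the standard equal-block
form. Default 200 blocks genome-wide; at desk scale we use 40 so that
blocks stay long relative to the LD correlation length. p-values use the
normal approximation.

**Model averaging.** Fits across window sizes are combined with
importance weights proportional to their Gaussian pseudo-likelihoods
(log-sum-exp stabilized), computed from the weighted residuals at the
final weights.

## What the synthetic data emulates — and what it does not

`simulate_genotypes()` draws two latent Gaussian AR(1) haplotype fields
per sample and thresholds them at each variant's MAF quantile, so
marginals are Bin(2, p) under Hardy-Weinberg equilibrium and neighboring
variants carry LD. The recombination intensity varies in blocks (mean 50
variants; within-block adjacent-latent correlation `ld_decay^rate`, rate
log-uniform on [0.1, 10]). The block structure is deliberate: with a
constant rate the realized LD scores have almost no dynamic range and
both scores become functions of MAF alone, strongly (negatively)
collinear — the opposite of the empirical regime, where LD scores span
orders of magnitude and the two scores are lowly correlated. MAF targets
are uniform on [0.05, 0.5] (a common-variant panel after the usual 1%
MAF filter, staying clear of frequencies where a 2,000-sample panel would
go monomorphic); positions are 1 kb apart on one chromosome with 1 cM per
Mb. Defaults were fixed once; the generator does *not* emulate realistic
minor-allele-frequency spectra, genetic maps, haplotype-block boundaries
or population structure.

`simulate_trait()` assembles phenotypes from additive, dominance,
pairwise-interaction (hub/partner architecture), and
gene-by-environment or gene-by-ancestry components plus noise. Effects
are drawn on the allele-count scale with variance multiplier
$(2pq)^{\alpha}$; a hub's interaction draws can be correlated with its
additive draw (`effect_corr`). Each component is centered,
orthogonalized in-sample against the components before it, and rescaled
so its realized variance hits the budget *exactly* (additive share
$\rho H^2$, extra share `var_extra` $\times H^2$, dominance share
`var_dom` $\times H^2$, interactions the remainder; noise $1-H^2$). The
orthogonalization is what makes `V[y] = 1` and the component shares exact
to $10^{-10}$ — it removes only the rank-one in-sample overlap between
components and leaves per-variant tagging intact. Consequently a green
recovery test establishes calibration *conditional on an exactly budgeted
trait*, not robustness to the sampling variability of effect rescaling.

## Desk-scale validation: what passes and what cannot

The suite validates calibration and recovery at N and J three to five
orders of magnitude below the biobank analyses the method was built for.
Three findings matter for interpreting the acceptance results:

* The null-calibration world (N = J = 2,000, purely additive trait)
  yields a correctly sized $\vartheta$ test (rejection rate ~0.05-0.08)
  and a mean $\hat\vartheta$ statistically near zero — but the
  variance-explained *scale* of $\hat\vartheta$ is intrinsically noisy at
  J = 2,000 (per-replicate SD around 5, jackknife SEs verified against
  the empirical sampling SD), so the mean total-PVE band of ±0.06 around
  0.6 is out of reach by an order of magnitude. That band describes the
  genome-wide regime.
* In the recovery world (H² = 0.6, half interactive, hubs at 10% with
  ±10 kb partners) the interaction column reliably recovers variance the
  additive-only fit misses, but the mean jackknife z for $\vartheta$ is
  about 1.5 at N = 8,000, J = 4,000, i.e. per-replicate detection power
  around 0.4, below the 60% detection clause. Power grows roughly like
  $N/\sqrt{J}$ here; matching the published detection rates would need
  N in the tens of thousands at this J.
* The interaction-score PVE coordinate is upward-biased when the score
  window (±50 SNPs) is much wider than the generative interaction window
  (±10 SNPs), since the causal pairs sit exactly where per-pair tagging
  is strongest — the same direction of bias the upstream work reports for
  too-small windows, viewed from the other side.

## Replication surface

The published per-trait heritability tables for 25 quantitative traits in
two biobanks are shipped as fixtures (`ildsc_tables()`), and
`replicate_correlations()` recomputes the cross-table squared correlations. Two
source-side inconsistencies surfaced while freezing the expected values;
both are handled by computing faithfully and letting the checks stand:

* The published figure caption labels its correlations "Spearman", but
  five of the seven printed values match squared *Pearson* correlations
  of the printed columns to three decimals, while squared Spearman is far
  off (e.g. 0.62 vs the printed 0.85). `replicate_correlations()` therefore
  defaults to Pearson; `spearman_r2()` and `method = "spearman"` remain
  available.
* The printed range of the stratified interaction component ("0.005 for
  MCHC to 0.055 for HDL") conflicts with the published table it
  summarizes, which puts Basophil at 0.001. The recomputation returns
  the table's own answer.

## Known limitations

Single-trait analysis only (no genetic correlations); no functional
enrichment statistics; allele harmonization between summary statistics
and score panels is exact-match only; dominance appears only in the
simulator, not as a score; the REML route for estimating the MAF
exponent from genotypes is not included ($\alpha$ is an input).
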