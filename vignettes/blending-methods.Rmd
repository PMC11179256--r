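---
title: "Heterogeneity-aware blending of GWAS summary statistics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity-aware blending of GWAS summary statistics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Polygenic risk scores (PRS) built from a single GWAS are limited by that
study's sample size. Often a second, related study exists — the same trait in
another ancestry, or a genetically correlated disease in the same population —
whose information is partially transferable. Fixed-effect meta-analysis
borrows all of it and is biased wherever the true effects differ; using the
proximal study alone is unbiased and noisy. `prsblend` takes the middle road
at single-SNP resolution: it borrows the adjunct study exactly where the data
cannot tell the two studies apart, and falls back to the proximal estimate
where they visibly disagree.

The package produces a *complete* derived summary-statistics set (effects,
standard errors, p-values, effective sample sizes) plus a matching blended LD
reference, so the output drops unchanged into downstream PRS tools.

# The model

## Per-SNP heterogeneity: Cochran's Q with shared controls

For SNP $j$ with allele-aligned estimates $\hat\beta_1, \hat\beta_2$ and
standard errors $\sigma_1, \sigma_2$,

$$Q = \frac{(\hat\beta_1-\hat\beta_2)^2}
           {\sigma_1^2+\sigma_2^2-2\rho\sigma_1\sigma_2},
  \qquad Q \sim \chi^2_1 \text{ under homogeneity.}$$

$\rho$ is the correlation between the two estimators induced by shared
subjects. Case-control designs that re-use a control pool are the common
case; there

$$\rho = \frac{n_{sc}\sqrt{\tfrac{n_{1ctl}\,n_{2ctl}}{n_{1cas}\,n_{2cas}}}
             + n_{sctl}\sqrt{\tfrac{n_{1cas}\,n_{2cas}}{n_{1ctl}\,n_{2ctl}}}}
            {\sqrt{n_1 n_2}},$$

a function of sample sizes only, applied genome-wide as a single scalar
(`estimate_overlap_rho()`). For quantitative traits the analogue is
$n_{shared}/\sqrt{n_1 n_2}$. The correctness of this reconstruction is not
taken on faith: the test suite simulates null case-control GWAS pairs over a
shared control pool and checks that the empirical $\mathrm{corr}(\hat\beta_1,
\hat\beta_2)$ matches the formula, and that the adjusted $Q$ test has nominal
type-I error while the unadjusted ($\rho = 0$) test is visibly conservative —
shared controls make the estimators positively correlated, so ignoring
$\rho$ over-states the variance of $\hat\beta_1-\hat\beta_2$.

## From p-values to blending weights: the two-groups local FDR

The blending weight is $\pi_j = \Pr(H_0 \mid p_j)$, the local false discovery
rate of the Q-test p-value. The estimator is deliberately a standard
two-groups construction:

* $\pi_0$ by the Storey smoother: $\pi_0(\lambda) = \#\{p>\lambda\}/(m(1-\lambda))$
  on the grid $\lambda = 0.05, 0.10, \dots, 0.95$, a cubic smoothing spline
  (3 df) through the curve, evaluated at $\lambda = 0.95$, clipped to $(0,1]$.
  A fixed-$\lambda$ variant is available for small panels.
* the marginal density on the probit scale: $x = \Phi^{-1}(p)$, Gaussian KDE
  with Silverman's rule bandwidth, and
  $\mathrm{lfdr}(p) = \pi_0\,\varphi(x)/\hat f(x)$, since $\varphi$ is the
  null density of $x$.
* monotonization: lfdr is made non-decreasing in $p$ by a cumulative-maximum
  pass. Large $p$ means no heterogeneity evidence, so the weight on the
  meta-analysis must not decrease with $p$.

Q statistics of exactly zero give $p = 1$; these are retained by clamping to
$1-10^{-12}$ (they belong at full meta-analysis weight). P-values that
underflow to zero at extreme heterogeneity are clamped to the smallest
positive double — maximal evidence against the null, not missing data.

## The blend and its derived statistics

With the fixed-effect meta-analysis
$\beta_{12} = (w_1\hat\beta_1+w_2\hat\beta_2)/(w_1+w_2)$, $w_i = 1/\sigma_i^2$,
the blended effect is

$$\beta_{blend} = (1-\pi)\,\hat\beta_1 + \pi\,\beta_{12}.$$

Treating $\pi$ as a fixed plug-in weight, the variance follows from the joint
distribution of $(\hat\beta_1, \beta_{12})$:

$$\mathrm{Var}(\beta_{blend}) = (1-\pi)^2\sigma_1^2
  + \pi^2 \mathrm{Var}(\beta_{12})
  + 2\pi(1-\pi)\,\mathrm{Cov}(\hat\beta_1,\beta_{12}),$$

with $\mathrm{Var}(\beta_{12}) = (w_1^2\sigma_1^2+w_2^2\sigma_2^2
+2w_1w_2\rho\sigma_1\sigma_2)/(w_1+w_2)^2$ and
$\mathrm{Cov}(\hat\beta_1,\beta_{12}) =
(w_1\sigma_1^2+w_2\rho\sigma_1\sigma_2)/(w_1+w_2)$. Ignoring the estimation
noise of $\pi$ is a documented limitation of the plug-in construction; the
acceptance suite verifies the SE formula against Monte-Carlo SDs of the
blended estimator over a $(\sigma_1,\sigma_2,\rho,\pi)$ grid at $10^6$ draws
per cell, to 2%.

P-values are two-sided normal. The reported effective sample size defaults to
the SE-implied convention $n_{eff} = (2\,AF(1-AF)\,\sigma_{blend}^2)^{-1}$,
capped at $N_1+N_2-n_{shared}$, so LD-aware PRS tools that scale by $N$ see
the variance gain; the alternative $(1-\pi)N_1+\pi(N_1+N_2)$ is exposed via
`n_eff_method = "weighted"`. SNPs absent from the adjunct study pass through
with their proximal statistics untouched. Blended rows report the proximal
allele frequency — the target population is the proximal one.

## The blended LD reference

Downstream methods need the correlation structure of the *blended*
estimates, not of either panel. Writing the blend as a linear combination
with per-SNP loadings $a_i = (1-\pi_i) + \pi_i w_{1i}/(w_{1i}+w_{2i})$ on
study 1 and $b_i = \pi_i w_{2i}/(w_{1i}+w_{2i})$ on study 2,

$$\mathrm{Cov}(\beta_{blend,i},\beta_{blend,j}) =
  a_ia_j R^{(1)}_{ij}\sigma_{1i}\sigma_{1j}
 + b_ib_j R^{(2)}_{ij}\sigma_{2i}\sigma_{2j}
 + \rho\left(a_ib_j \bar R_{ij}\sigma_{1i}\sigma_{2j}
           + a_jb_i \bar R_{ji}\sigma_{1j}\sigma_{2i}\right),$$

normalized to a correlation matrix per LD block. The cross-study LD term uses
$\bar R = (R^{(1)}+R^{(2)})/2$: the exact cross-panel LD is unobservable from
two marginal panels, and at $\rho = 0$ — the cross-ancestry regime, where the
panels genuinely differ — the term vanishes, so the approximation is only
active when the two studies share subjects and hence, in practice, a
population. The formula is validated against a Monte-Carlo oracle that
simulates genotypes at the target LD, runs both GWAS, blends, and measures
the empirical correlation of blended estimates across replicates (maximum
deviation tolerance 0.05).

Proximal-only SNPs enter with $a = 1, b = 0$ (implemented as
$\sigma_2 = \infty$), which reduces their rows to the proximal panel exactly.

# The synthetic-data generator

The simulator exists so every claim above can be tested without external
data. It emulates:

* **Genetic architectures with a controllable sharing composition.** A
  fraction $P$ of the `n_causal` causal SNPs is shared between the two traits
  with a within-SNP effect correlation `cor` (bivariate normal draws); the
  remainder are trait-specific and disjoint. Over all causal SNPs the
  realized genetic correlation is $P \cdot cor$ — the composition identity —
  so the same rG can be diffuse ($P=1$, weak `cor`) or concentrated
  ($P<1$, strong `cor`). The constructor enforces the identity rather than
  re-balancing silently.
* **Exact heritability partition.** Effects live on the standardized-genotype
  scale. Each component (shared, trait-specific, penetrant) is rescaled so
  its summed squared effects hit its share of $h^2$ exactly per replicate;
  rescaling per trait is by a positive constant and so never distorts the
  effect correlation. High-penetrance SNPs get fixed alternating-sign effects
  of equal magnitude, so their stated share of the non-shared heritability
  (default 5% over 5 SNPs) is exact by construction, not in expectation.
* **Block-structured genotypes.** Dosages are two thresholded multivariate
  normal gametes (Hardy–Weinberg by construction) with an AR(1) dosage-LD
  target within blocks. Because correlations between Bernoulli indicators
  with different frequencies are bounded above (Fréchet), the target is
  capped at 95% of the attainable bound per pair; the latent gamete
  correlation achieving each capped target is found by numerically inverting
  the thresholded-Gaussian correlation (Plackett identity, 16-point
  Gauss–Legendre quadrature, vectorized bisection to $2^{-34}$). The
  *designed* dosage LD — the forward map of the calibrated latent matrix —
  is what `target_ld()` returns and what realized LD is tested against.
* **Phenotypes.** $y = G_{std}\beta + e$ with the noise variance set from the
  realized genetic variance so $\mathrm{var}(G\beta)/\mathrm{var}(y) = h^2$
  in expectation.
* **Two GWAS routes.** Individual-level (per-SNP linear regression on
  standardized dosages, verified against `lm()`) and a fast analytic sampler
  that draws $\hat\beta \sim N(R\beta,\; R/n)$ per block with cross-study
  correlation $\rho$ — the two routes are checked against each other in
  distribution. A shared-control case-control generator exercises the
  overlap correlation.

What it does **not** emulate: realistic MAF and LD spectra (blocks are
homogeneous AR(1), real LD is not), population structure, relatedness,
imputation error, or liability-scale binary traits (the binary mode is a
labels-on-null design for calibration). Passing tests therefore demonstrate
internal correctness of the formulas and the qualitative adaptivity of the
method under controlled architectures — not performance on any particular
real dataset.

# Numerical choices

* QC filter convention: $\sigma_{SS} = 2/\sqrt{N\sigma_\beta^2}$ and
  $\sigma_G = \sqrt{2\,AF(1-AF)}$ with removal rules
  $\sigma_{SS} < 0.5\,\sigma_G$, $\sigma_{SS} > \sigma_G + 0.1$,
  $\sigma_{SS} < 0.1$, $\sigma_G < 0.05$ — the LDpred2-recommended
  summary-statistic checks.
* PSD repair of blended LD blocks by eigenvalue clipping at 0 (tolerance
  $10^{-8}$) followed by diagonal re-normalization — chosen over
  nearest-correlation iteration for speed; blended blocks are near-PSD by
  construction so the repair is a perturbation.
* Degenerate blending weights short-circuit through unit loadings so the
  $\pi \equiv 0$ and $\pi \equiv 1$ limits reproduce the proximal panel and
  the symmetric blend bit-exactly.
* Strand-ambiguous pairs (A/T, C/G) are dropped by default during
  harmonization; allele mismatches and indels are always dropped, and every
  exclusion is counted in a report.
* Monomorphic columns, zero-length overlaps, non-positive Q denominators and
  infeasible compositions are hard errors, not warnings.
* Written summary statistics use shortest-exact decimal formatting so the
  read/write round trip is lossless.

# Validation problem sizes

The package validates itself at sizes chosen to give tight Monte-Carlo
noise while staying comfortable on a laptop: 20,000 null SNPs for Q-test
calibration (3-binomial-SD bands at $\alpha \in \{0.05, 0.01\}$); 25,000
replicates of the CD/UC-shaped shared-control design for the $\rho$ oracle
(tolerance $\pm 0.02$); $10^6$ draws per cell of the blended-SE grid (2%);
3,000 replicates per cell of the LD-blend oracle on 5-SNP blocks (0.05); and
the headline predictive comparison at $n = 4{,}000$ training subjects split
50/50, $m = 10{,}000$ SNPs, $h^2 = 0.5$, 1,000 causal SNPs, 20 seeded
replicates per architecture with a 1,500-subject held-out cohort. The same
conditions back `scripts/acceptance.R`.

On the headline comparison: with concentrated sharing ($P = 0.5$,
$cor = 1$, plus five penetrant SNPs) the blend is expected to beat both the
proximal-only and the meta-analysis baselines in mean test-set $r^2$. With
diffuse sharing ($P = 1$, $cor = 0.5$) the correct expectation is *near*
equality with the meta-analysis: because the per-SNP effects still differ
(the effect correlation is 0.5, not 1), a small genuine advantage of
adaptive blending persists, so the suite asserts non-inferiority within
noise and a bounded relative difference rather than exact equality.

# Known limitations

* $\pi$ is plugged in as known; its estimation uncertainty is not propagated
  into the blended SEs.
* One scalar $\rho$ genome-wide; per-SNP overlap (e.g. SNP-dependent missing
  subjects) is out of scope.
* Two studies only; no random-effects heterogeneity model.
* The cross-panel LD approximation $\bar R$ is a modeling choice outside the
  $\rho = 0$ regime.
* The lfdr estimator needs a few hundred p-values to be stable; small panels
  should use the fixed-$\lambda$ $\pi_0$ variant.
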