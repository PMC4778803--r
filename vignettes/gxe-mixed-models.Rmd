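---
title: "Correcting population structure in gene-by-environment GWAS with two random effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting population structure in gene-by-environment GWAS with two random effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxelmm)
```

## The problem

A gene-by-environment GWAS fits, for each variant $r$,

$$y = \mu + \beta_r X_r + \delta D + \gamma_r\, D \cdot X_r + \varepsilon,$$

where $X_r$ is the dosage, $D$ the environmental exposure, and the GEI
effect $\gamma_r$ is the coefficient of interest. Under a polygenic
architecture the residual of this single-variant model contains the
effects of all other variants and all other interactions. Individuals who
are genetically related therefore share the first part of that residual,
and individuals who are related *and share an exposure* share the second
part. Plain least squares assumes independent residuals, so population
structure inflates not only the SNP statistics (the classical GWAS
confounding) but also the GEI statistics — a route to spurious
interactions that a genetic-kinship-only mixed model does not close.

## The model

`gxelmm` implements a linear mixed model with two random effects:

$$y = \mu + \beta_r X_r + \delta D + \gamma_r\, D\cdot X_r + u + v + e,
\qquad
\operatorname{var}(y) = \sigma_g^2 K + \sigma_d^2 K^D + \sigma_e^2 I .$$

* $K$ is the standardized-genotype relationship matrix
  ([`compute_grm()`]): $K_{ij} = \frac1m \sum_s
  (x_{is}-2p_s)(x_{js}-2p_s)/(2p_s(1-p_s))$ with sample allele
  frequencies, missing dosages mean-imputed per variant, monomorphic
  variants excluded (and $m$ counting retained variants only). The tested
  marker stays in $K$: that choice makes residual inflation visible as
  $\lambda_{GC} > 1$ rather than hiding it, and leave-one-chromosome-out
  construction is deliberately out of scope.
* $K^D$ is the GxE kinship ([`gxe_kinship()`]). For a binary exposure,
  $K^D_{ij} = K_{ij}$ when $D_i = D_j$ and $0$ otherwise. For a
  continuous exposure, $K^D_{ij} = K_{ij} f(D_i, D_j)$ with a similarity
  kernel $f \in [0,1]$, $f(d,d)=1$: either $1 - |D_i - D_j|/R$ (range
  kernel) or $1 - |\Phi(z_i)-\Phi(z_j)|$ on standardized exposures
  (normal-CDF kernel). Which kernel suits a study depends on the scale of
  the exposure; the package recommends neither by default. $K^D$ is not
  forced positive semidefinite — masking entries can break PSD — because
  only the combined $\Sigma$ must be positive definite, and that is
  checked where $\Sigma$ is factorised.

Three comparison models share the fixed-effect design and differ only in
$\Sigma$: **OLS** ($\Sigma = I$), **one RE**
($\Sigma = \hat\sigma_g^2 K + \hat\sigma_e^2 I$), and **two RE**
($\Sigma = \hat\sigma_g^2 K + \hat\sigma_d^2 K^D + \hat\sigma_e^2 I$).
A fourth comparator, `pc_x_env`, stays in the OLS family but adds the top
kinship eigenvectors and their products with $D$ as fixed covariates.

## Estimation

`fit_reml()` estimates the variance components by average-information
REML with one initial EM step. Starting values split the phenotypic
variance equally across components. Convergence requires the restricted
log-likelihood to move by less than `1e-6` *and* every interior
component's score to fall below `1e-4`; both are tunable. Components
driven negative are clamped at $10^{-6}$ times the phenotypic variance
and flagged `boundary`; a component pinned at that floor with a negative
score is dropped from the AI system for that step (an active-set update),
which keeps the boundary from corrupting the step for the free
components. If an AI step cannot find an uphill point by halving, the
iteration falls back to an EM step, which cannot decrease the restricted
likelihood. Standard errors come from the inverse AI matrix; variance
*fractions* and their delta-method standard errors are in
`variance_fractions()`.

With a single kinship every iteration runs in the eigenbasis of $K$ (one
decomposition, then $O(n)$ per iteration); with two kinships each
iteration factorises $\Sigma$ by Cholesky. The two paths agree to
numerical precision and are both exposed through `method=` for testing.

Variance components are estimated **once per phenotype** under the null
fixed-effect design (intercept + exposure + covariates, no variant), and
the resulting $\Sigma$ is reused for every variant. `gxe_scan()`
factorises $\Sigma$ once, rotates $y$ and the shared covariates, and then
each variant costs one small least-squares fit. The SNP and GEI tests are
marginal Wald-type $F$ statistics $(\hat\beta/\text{se})^2$ on
$F(1, n-p)$ from the full interaction model, with the residual variance
estimated from the rotated residuals; at GWAS sample sizes this matches
the normal approximation, at toy sizes the $F$ reference is testable. A
2-df joint test of $(\beta_r, \gamma_r)$ is reported as `p_joint` but is
not used in inflation summaries, which treat the SNP and GEI families
separately. Samples missing a dosage are dropped for that variant only
(complete cases), with $\Sigma$ re-factorised on the remaining samples;
rank-deficient designs (monomorphic variants, or a variant carried only
by exposed samples) yield a retained row with missing p-values and a
`rank_deficient` note.

Calibration is summarised by the genomic-control inflation factor
$\lambda_{GC}$: the median of the 1-df $\chi^2$ equivalents of the
p-values divided by $0.4549364$.

## What the simulator emulates

`sim_config()` / `simulate_gxe_study()` generate the null study used
throughout: two populations diverged under a Balding–Nichols model
(ancestral frequencies uniform above the MAF floor, population
frequencies Beta-distributed at divergence `fst`, dosages binomial;
variants whose realized minor allele frequency falls below the floor in
either population are rejected and redrawn), a dichotomous exposure
assigned within populations (balanced, or biased with ratio $r$ in one
population and $1-r$ in the other), and a phenotype drawn from
$N(0, \sigma_g^2 K + \sigma_d^2 K^D + \sigma_e^2 I)$ with **no causal
variant**, so every test is null and both statistic families should give
$\lambda_{GC} \approx 1$.

Defaults are the study conditions of the package's calibration
experiments: 1,000 individuals per population, 10,000 variants, 5% MAF
floor, balanced exposure, variance fractions $(0.4, 0.2, 0.4)$, and
`fst = 0.004` — the order of divergence between two close European
populations. Each replicate draws a fresh genotype panel, so replicates
are fully independent.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent given the population frequencies), ascertained
case-control sampling, assortative or selective exposure correlated with
genotype, and real allele-frequency spectra. Inflation under the
polygenic null is driven by structure rather than LD, so calibration
conclusions carry over, but absolute inflation magnitudes on real chip
data (where LD concentrates differentiation) are only approximated;
results tied to a specific genotyped cohort should be read as
order-of-magnitude comparable, not numerically identical.

## Numerical choices and degenerate inputs

* Kinship symmetry is enforced to `1e-8` on read; genetic-role matrices
  are additionally checked positive semidefinite to the same relative
  tolerance.
* `simulate_phenotype()` floors eigenvalues at $10^{-8}$ of the largest
  (with a warning) if the combined covariance is numerically indefinite.
* QQ sort order breaks p-value ties by variant id, so outputs are
  byte-stable.
* A single master seed derives per-stage and per-replicate sub-seeds
  (`derive_seeds()`), so any replicate can be regenerated alone and
  reruns are bitwise identical.
* Degenerate exposures error early: a constant exposure has no range for
  the range kernel and no spread for the normal-CDF kernel.
* Monomorphic variants are dropped from the GRM average; an
  all-monomorphic panel is an estimation error, not a silent zero matrix.

## Quality control

The phenotype filters mirror common expression-GWAS practice: a
Shapiro–Wilk normality screen at $\alpha = 0.05$
(`normality_filter()`), and an outlier screen that counts values more
than 2 SD from the mean and drops a phenotype at 5 or more
(`outlier_filter()`; mean and SD are computed in a single pass, outliers
included). Variant QC (`genotype_qc()`) defaults to MAF $\ge 10\%$, HWE
$p \ge 10^{-4}$, and missingness $\le 5\%$. The HWE default is the 1-df
$\chi^2$ goodness-of-fit test without continuity correction — the
simplest defensible choice — with the standard exact test behind
`hwe_method = "exact"`. `quantile_normalize()` maps values to
$\Phi^{-1}((\text{rank}-0.5)/n)$ with tied ranks averaged, whole-sample
or within exposure group.

## A worked null study

A desk-scale version of the calibration experiment (small enough to run
in seconds; the full-scale conditions are in the next section):

```{r example}
cfg <- sim_config(n_per_pop = 150, m_variants = 1500, fst = 0.05, seed = 42)
st <- simulate_gxe_study(cfg)
fit <- fit_reml(st$y, list(genetic = st$K, gxe = st$KD), D = st$D)
fit

ols <- gxe_scan(st$G, st$y, st$D, model = "ols")
two <- gxe_scan(st$G, st$y, st$D, model = "two_re", vc = fit,
                K = st$K, KD = st$KD)
c(ols = inflation_factor(ols$p_gei), two_re = inflation_factor(two$p_gei))
```

The OLS inflation factor on GEI statistics sits above one while the
two-RE scan is calibrated; single replicates carry median noise of a few
percent, so systematic statements use `run_replicates()` medians.

## Experiment sizes

The package's calibration experiments use 20 replicates of the default
configuration (2,000 individuals, 10,000 variants). The
inflation-versus-$\sigma_d^2$ grid runs at 250 individuals per
population, 2,500 variants and `fst = 0.05`, with $\sigma_g^2 =
\sigma_e^2$ holding their ratio fixed as $\sigma_d^2$ sweeps
$\{0, 0.05, 0.1, 0.15, 0.2\}$: the stronger divergence resolves the
approximately linear inflation-variance relationship clearly at this
scale, while at very weak structure the trend is comparable to median
sampling noise. These sizes are the package's own choices; the
full-scale configuration is one `sim_config()` call away.

## Known limitations

* Binary-trait (logistic) GEI models, case-only designs, and
  score/likelihood-ratio alternatives to the Wald $F$-test are out of
  scope.
* One environment at a time; no multi-environment GxE decomposition, no
  bivariate REML, no BLUP prediction.
* The GxE kinship inherits whatever the genetic kinship captured; with
  leave-one-chromosome-out kinships unsupported, proximal contamination
  of the tested marker is accepted by design (see above).
* The REML fit is dense ($O(n^3)$ per iteration with two kinships);
  cohorts beyond a few tens of thousands of samples would need low-rank
  or conjugate-gradient machinery that this package does not provide.
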