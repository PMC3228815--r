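---
title: "Joint hierarchical modelling of grouped rare and common variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint hierarchical modelling of grouped rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvhglm)
```

## The model

Rare variants individually carry too little information for single-marker
tests, so collapsing methods summarize a group of variants by a *genetic
score* — a weighted burden $S_{ik} = \sum_{j \in G_k} b_j z_{ij}$ of
minor-allele dosages $z_{ij} \in \{0, 1, 2\}$ — and test its regression
coefficient. Fixed weights fail when a group mixes risk and protective
variants: equal weights cancel the signal. `rvhglm` fits the
*multiplicative* generalized linear model

$$h\!\left(\mathrm{E}[y_i]\right) \;=\; \beta_0 + \mathbf{x}_i'\boldsymbol\beta
  + \sum_{k=1}^{K} g_k \sum_{j \in G_k} b_j\, z_{ij},$$

estimating the group effects $g_k$ (the cumulative association of group
$k$) and the per-variant weights $b_j$ (relative importance within the
group) jointly. Any of the four supported exponential families
(gaussian, binomial, poisson, Gamma) may be used; dispersion is estimated
for gaussian/Gamma under the scale-invariant prior $p(\phi) \propto 1/\phi$.

The product $g_k b_j$ is not identified without prior information, so the
weights carry an informative hierarchical prior

$$b_j \sim \mathrm{N}(\mu_j, \tau_j^2), \qquad
  \tau_j \sim \mathrm{half\text{-}Cauchy}(0, s_{k[j]}),$$

with prefixed prior means $\mu_j$ (1 by default, giving the simple burden
sum as the baseline; functional scores in $(0,1]$ may be supplied instead)
and group-specific scales $s_k$ estimated from the data. The half-Cauchy
scale mixture has an infinite density spike at $\mu_j$ and Cauchy tails:
weights of variants that carry no individual evidence collapse exactly to
their prior means (so a null group's score reduces to the plain burden sum
and its test stays calibrated), while strongly deviating variants —
including protective variants needing a negative weight — escape with a
bounded penalty. Group effects and covariate coefficients get the weakly
informative prior $g_k \sim \mathrm{N}(0, \psi_k)$,
$\psi_k \sim \mathrm{Gamma}(0.5, 0.5)$, which leaves well-identified
coefficients essentially untouched but keeps coefficients of low-variance
predictors (rare-variant scores) in a reasonable range. The intercept has
a diffuse normal prior (variance $10^6$).

Because the linear predictor obeys the identity
$$\textstyle g_k \sum_j b_j z_{ij} \;=\; g_k \sum_j \mu_j z_{ij}
  \;+\; \sum_j g_k (b_j - \mu_j)\, z_{ij},$$
the fit decomposes into the fixed-weight baseline plus per-variant
deviations. The *adjusted main effect* of variant $j$ is
$\theta_j = g_{k[j]}(b_j - \mu_j)$, with the delta-method standard error
$\mathrm{SE}(\theta_j)^2 = g^2\,\mathrm{Var}(b_j) +
(b_j-\mu_j)^2\,\mathrm{Var}(g)$. The cross-covariance between $\hat g$ and
$\hat b_j$ is not available from the alternating conditional fits and is
omitted — a known limitation; the reported adjusted-effect intervals are
approximate. The total per-variant effect $g_k b_j$ is reported alongside.
The identity is asserted numerically (to $10^{-8}$ per individual) after
every fit.

## Fitting: EM within IWLS

`bhglm()` finds posterior modes for a fixed design by augmented iterative
weighted least squares: each step solves the working least-squares system
augmented with one pseudo-observation per penalized coefficient (response
= prior mean, weight = expected prior precision, scaled by the dispersion
for gaussian/Gamma so the prior lives on the coefficient scale), then
updates the hyperparameters (E-step) and the dispersion. `rvhglm()`
alternates one such step for the group-effect model (covariates and scores
with the weights held fixed) and one for the weight model (per-variant
predictors $g_{k[j]} z_{ij}$, with the covariate part as an offset) until
the glm-style criterion $|D_t - D_{t-1}|/(|D_t| + 0.1) < 10^{-5}$ on the
deviance of the group-effect model is met (`max_outer = 200`). Standard
errors come from the inverse augmented normal-equations matrix at the
mode; two-sided p-values use a normal reference for binomial/poisson and a
t reference with residual degrees of freedom when the dispersion is
estimated. Group-effect p-values are additionally Benjamini–Hochberg
adjusted across the $K$ groups. Non-convergence is flagged on the returned
object, never raised, so simulation harnesses can count such fits.

Initialization: intercept at the link of the mean response, covariate and
group effects at 0, weights at their prior means, $\tau_j^2 = 1$,
$\psi = 1$, $s_k = 0.5$, $\phi = 1$. With these values the first outer
iteration reproduces the fixed-weight (Simple/Weighted-Sum) model, a
useful anchor.

### Numerical treatment of the half-Cauchy E-step

Three design choices here were genuinely open and matter in practice:

* **Exact expected precision.** The expected prior precision uses the
  exact conditional expectation under the half-Cauchy mixture,
  $\mathrm{E}[1/\tau_j^2 \mid d_j, s] = (2/d_j^2)\big/(e^{x}E_1(x)) - 1/s^2$
  with $d_j = b_j - \mu_j$, $x = d_j^2/(2s^2)$ and $E_1$ the exponential
  integral (computed by a series / continued-fraction pair accurate to
  machine precision). Unlike a plug-in pass through the two-level
  inverse-gamma representation (available as `halfcauchy_estep()` and
  `group_scale_update()`), the exact form preserves the prior's spike —
  its precision diverges as $d \to 0$ — which is what pins null weights
  and keeps group-level type-I error calibrated. A deviation floor
  ($d_{\mathrm{floor}} = 0.01$, i.e. deviations below 1% of a weight unit
  are treated as zero) keeps the precision finite.
* **Global per-weight mode decisions.** The penalized profile objective of
  a single weight has at most two local minima: the spike at $\mu_j$ and a
  stationary point in the Cauchy tail. A local EM step only slides into
  the nearest basin, so after each solve the fitter compares the two
  objective values per weight (using the coordinate-wise profile
  likelihood) and keeps the global one. This comparison depends on $s_k$:
  a collapsed scale in a group with no evidence of deviation raises the
  escape threshold, while a moderate scale in a group with real signal
  lowers it — the mechanism that separates causal from null groups.
* **Group scales and coefficient variances.** $s_k$ is updated as the
  marginal maximum a posteriori of $t_k = 1/s_k^2$ under the
  Gamma(0.5, 0.5) hyperprior, with each weight's *sampling noise
  deconvolved*: the likelihood of $s$ uses
  $p(\hat\delta_j \mid s) = \int \mathrm{N}(\hat\delta_j \mid d, 1/i_j)\,
  p_{\mathrm{hc}}(d \mid s)\, \mathrm{d}d$, where $\hat\delta_j$ is the
  coordinate-wise profile deviation and $i_j$ its likelihood information
  (Gauss-type quadrature over the latent deviation; one-dimensional
  optimization per group, $s_k \in [0.01, 100]$). Deconvolution is what
  lets the scale discriminate: a null group's deviations are explained by
  sampling noise alone, so $s_k$ collapses and the escape bar rises to
  roughly $|z| \approx 4$; a group with genuine deviations drives $s_k$
  up toward their scale, lowering the bar to roughly $|z| \approx 2.5$ —
  group-level evidence sharing that per-variant statistics cannot
  provide. The Gamma(0.5, 0.5) variance $\psi$ of group
  effects and covariates is updated to its conditional posterior mean
  $\mathrm{E}[\psi \mid g] = |g|K_1(|g|)/K_0(|g|)$ evaluated at the
  posterior second moment $\sqrt{\hat g^2 + \mathrm{Var}(\hat g)}$; the
  conditional mode (exported as `group_effect_variance_update()`)
  collapses to its floor for small $|g|$ and would visibly over-shrink
  null effects, breaking p-value uniformity, whereas the mean form is
  near-inert for small effects and range-constraining for large ones.

These choices are pinned by exact-equivalence tests: with effectively flat
priors the fitter matches classical ML; with fixed gaussian precisions it
matches the ridge closed form; `scale_mode = "weights_fixed"` is
numerically identical to fitting the burden scores directly; and forcing
the estimated scales to 0.5 reproduces `scale_mode = "fixed"`.

## Model variants

* `scale_mode = "estimated"` — the full model (default).
* `scale_mode = "fixed"` (default scale 0.5) — the fixed-scale reduction.
* `scale_mode = "weights_fixed"` — $b_j \equiv \mu_j$: the Simple-Sum
  model for $\mu_j = 1$, a Weighted-Sum model for functional-score means.
* `fit_all_variants()` — drops the group structure and fits every
  variant's main effect under a zero-centred half-Cauchy prior (each
  variant its own scale group); group-level inference then uses the
  unadjusted minimum p-value over a group (`group_min_pvalue()`), which is
  intentionally anti-conservative and serves as a comparator.

Groups must contain at least two variants; singleton "groups" (e.g. the
two common non-synonymous variants of a resequenced gene) are modelled as
ordinary covariates, which `build_model_frame()` automates.

## What the simulator emulates

`scenario_catalog()` / `simulate_scenario()` reproduce a resequencing
study of one candidate gene in ~3000 individuals: 80 variants in three
groups (10 common + 26 rare + 44 rare; sample size 3008) or six groups,
plus a binary-trait layout with 61 variants at n = 1499; a 3-level
ancestry factor (probabilities 0.2/0.6/0.2), age ~ Uniform(18, 65), sex ~
Bernoulli(0.5) and BMI ~ N(28, 5) as covariates; and two singleton common
variants treated as covariates. Common MAFs are Uniform(0.01, 0.5); rare
MAFs are log-uniform down to the singleton frequency $1/(2n)$. Per-variant
effects are Uniform$[0, \beta_h]$ with
$\beta_h = \sqrt{3 h \sigma_e^2 / ((1-h)\sum_j 2q_j(1-q_j))}$, so a
group's realized variance fraction matches the target heritability $h$ in
expectation, and each effect is flipped protective with probability
`p.neg`. The continuous trait adds N(0, $0.2^2$) residuals (the log-scale
triglyceride residual SD); the binary trait labels the upper half of the
continuous trait as affected. Covariate and singleton true effects default
to fixed plausible values on the log-trait scale (ancestry 0.10/0.05, age
0.002 per year, sex 0.10, BMI 0.01 per unit; singletons 0 and −0.10) —
they are nuisance structure, not quantities under test.

What the generator does *not* emulate: linkage disequilibrium (variants
are drawn independently under Hardy–Weinberg proportions), genotyping
error or missingness mechanisms, population stratification beyond the
ancestry main effect, and the empirical site-frequency spectrum of any
particular gene. Passing simulation checks therefore demonstrates
calibration and relative power under idealized independent genotypes, not
performance on LD-structured real data.

## Operating characteristics checked by the test-suite

At the study's conditions (n = 3008, group heritability 0.5–0.7%,
`p.neg` = 0.4 for mixed-sign groups), the test suite verifies with
modest replicate counts (200–400 replicates, chosen to keep the default
test run to a few minutes per check): null-group significance frequency
near the nominal 5% level with approximately uniform p-values; power of
the joint model exceeding the Simple-Sum model under mixed effect signs
(disjoint Wilson 95% intervals); the minimum-p comparator showing the
largest null-group inflation; and mean realized group heritability within
±0.002 of the 0.007 target over 500 simulated datasets.
`scripts/acceptance.R` recomputes these quantities end to end.

## Known limitations

* The delta-method SE of adjusted effects omits the $g$–$b$
  cross-covariance (conditional alternating fits never form it).
* Mode-finding is local in the coefficient vector jointly even though each
  weight's pin-versus-escape decision is made globally; rare flip-flopping
  of borderline weights can slow convergence (the deviance criterion still
  terminates, and non-convergence is reported).
* Per-variant weights are only informative for variants whose individual
  evidence clears the escape threshold (roughly $|z| \gtrsim 3$); below
  it they sit at their prior means by design.
* Group scales are estimated by conditional MAP, not marginal likelihood;
  with very small groups (J = 2–3) the scale estimate is weakly
  identified and mostly follows its hyperprior.

## A worked example

```{r example, eval = FALSE}
sc <- scenario_catalog("three_groups", "b", 3008)
ds <- simulate_scenario(sc, trait = "continuous", seed = 1)
geno <- drop_non_segregating(ds$genotypes)
groups <- lapply(ds$groups, intersect, colnames(geno$dosage))
covdf <- ds$pheno[, c("race", "age", "sex", "bmi")]
X <- cbind(model.matrix(~ ., covdf)[, -1], ds$singletons)

fit <- rvhglm(ds$pheno$y, X, geno$dosage, groups)
print(fit)
head(summary(fit), 12)
plot(fit)
```
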