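# rvhglm — hierarchical GLMs for grouped rare and common variants

`rvhglm` is an R package for association analysis of candidate genes or
regions in which many rare and common variants are analysed **jointly, in
multiple groups, together with covariates**. It is aimed at statistical
geneticists analysing resequencing data: instead of testing one collapsed
burden score per gene with fixed weights — which loses power when a group
mixes risk and protective variants — it fits the multiplicative
hierarchical generalized linear model

```
h(E[y_i]) = beta_0 + x_i' beta + sum_k g_k * sum_{j in G_k} b_j z_ij
```

where `z_ij` is the minor-allele dosage (0/1/2), `g_k` is the **group
effect** (cumulative association of variant group `G_k` through its
genetic score `S_ik = sum_j b_j z_ij`), and `b_j` are per-variant
**weights** estimated from the data under a half-Cauchy scale-mixture
prior centred at prior means `mu_j` (1 by default, or functional scores).
Group and covariate effects carry weakly informative N(0, psi),
psi ~ Gamma(0.5, 0.5) priors. Posterior modes and standard errors are
found by an alternating EM-within-IWLS algorithm; inference is Wald-style
with Benjamini–Hochberg adjustment across groups, and per-variant
*adjusted main effects* `g_k (b_j - mu_j)` get delta-method standard
errors. Reduced models (fixed scale, fixed weights / Simple-Sum,
all-variants main effects) are built in, as are a scenario simulator with
heritability-calibrated effects and a power / type-I replicate engine.

## A worked example

```r
library(rvhglm)

# simulate one replicate of the three-group candidate-gene design:
# n = 3008, groups of 10 common / 26 rare / 44 rare variants, the rare
# non-synonymous group (G2) explaining 0.7% heritability with 40% of its
# effects protective, plus ancestry/age/sex/BMI covariates and two
# singleton common variants
sc  <- scenario_catalog("three_groups", "b", 3008)
ds  <- simulate_scenario(sc, trait = "continuous", seed = 7)
geno   <- drop_non_segregating(ds$genotypes)
groups <- lapply(ds$groups, intersect, colnames(geno$dosage))
X <- cbind(model.matrix(~ ., transform(ds$pheno[, c("race", "age", "sex", "bmi")],
                                       race = factor(race)))[, -1],
           ds$singletons)

fit <- rvhglm(ds$pheno$y, X, geno$dosage, groups)
print(fit)
```

```
Multiplicative hierarchical GLM for grouped variants
  family: gaussian ( identity link ); scale mode: estimated 
  n = 3008 ; groups: G1 (J=10), G2 (J=22), G3 (J=42) 
  outer iterations: 6 (converged) 

Group effects:
        estimate          se        p     p_bh
G1  0.0004298617 0.002058633 8.35e-01 8.35e-01
G2 -0.0541213692 0.010790489 5.59e-07 1.68e-06
G3  0.0107984165 0.007968091 1.75e-01 2.63e-01
```

The causal group G2 is detected (`p_bh = 1.7e-6`) even though 40% of its
variants carry protective effects — two of its estimated weights flip
sign, de-cancelling the score — while the two null groups stay at their
nominal level. On the same data the Simple-Sum model
(`rvhglm(..., scale_mode = "weights_fixed")`) gives `p = 0.008` for G2;
across replicates of this scenario the joint model detects G2 at the 0.01
level about four times as often (see the acceptance script below). `summary(fit)` returns the
full result table (covariates, group effects with BH-adjusted p-values,
weights, adjusted per-variant effects with ±2 SE bounds), `plot(fit)`
draws the effect plot, and `write_rvhglm_tsv(fit, path)` exports the
table.

Real data come in through `read_genotypes()` (dosage TSV or biallelic
VCF), `read_phenotypes()`, `read_groups()` and `build_model_frame()`
(id-join, mean imputation of missing genotypes, MAF classification at the
1% threshold, dummy expansion, singleton routing). Power studies run via
`run_study()` / `compare_methods()`, or from the shell through
`inst/cli/rvhglm` (`fit`, `simulate` and `power` subcommands).

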