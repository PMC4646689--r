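# pedliab

Pedigree-based liability-threshold models for binary traits in family
studies.

`pedliab` is for epidemiologists and quantitative geneticists analysing a
disease phenotype collected on extended pedigrees — the setting of large
population family cohorts in which every participant refers relatives, so
families are of variable size and structure and include married-in,
non-genetic members. The package covers the full analysis cycle for such a
study: pedigree validation and relationship computation, Bayesian
variance-component estimation on the liability scale, kinship-dyad
phenotypic correlations, post-stratification of sample estimates to
population frequencies, and a retrospective-to-cumulative lifetime
prevalence correction — together with a synthetic family-study generator
with known truth, so every stage is testable without access to restricted
cohort data.

## The model

A binary trait is modelled through a latent liability. For individual *i*,

    l_i = x_i' b + a_i + c_i + e_i,      y_i = 1{ l_i > 0 }

where `a ~ N(0, A V_A)` with **A** the numerator relationship matrix of
expected additive genetic relationships computed from the pedigree
(`a_ij` = 0.5 for parent–offspring and full siblings, 0.125 for first
cousins, diagonal `1 + F_i`), `c` is a family-group (shared environment)
effect common to all members of a self-reported extended family including
non-genetic relatives, and `e` is the link residual. Heritability is
reported on the liability scale,

    h2 = V_A / (V_A + V_C + V_resid + d),

with `d` the distribution-specific variance of the link (`pi^2/3` for
logit; for the probit formulation the fixed unit residual *is* the
distribution-specific variance). Fitting is by Gibbs sampling: truncated
normal (Albert–Chib) augmentation for the probit link, Pólya-Gamma
augmentation for the logit link, with the genetic effect conditioned on the
sparse inverse of **A** assembled directly by Henderson's rules (a dense
**A** is never formed). Bivariate-by-sex and three-category (age-of-onset,
illness-course) models sample 2×2 genetic and environmental covariance
matrices, giving stratum heritabilities and the genetic correlation
`r_G = G_12 / sqrt(G_11 G_22)` per posterior draw.

## Worked example

Simulate a 300-family cohort with known truth (liability heritability 0.40,
family-environment share 0.10, prevalence 13.5%), fit the probit animal
model, and estimate the full-sibling jackknife correlation:

```r
library(pedliab)

cfg <- simulation_config(n_families = 300, h2_true = 0.4, c2_true = 0.1,
                         target_prevalence = 0.135, seed = 42)
ds <- simulate_dataset(cfg)
ds
#> simulated family-study dataset
#> pedigree: 2321 individuals, 933 founders, 300 family groups
#>   sex: 1374 female / 947 male / 0 unknown
#>   phenotyped: 2316  affected: 294 (prevalence 0.127)

spec <- liability_model_spec("binary", fixed_effects = c("age", "sex"),
                             family_effect = TRUE, link = "probit")
mc <- mcmc_config(n_chains = 4, n_iter = 5000, n_burnin = 1000, thin = 5, seed = 7)
fit <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, mc)
fit
#> liability-threshold pedigree model (binary, probit link)
#>    4 chains, 3200 pooled draws, 2316 phenotyped individuals
#>  parameter   mean hpd_lower hpd_upper rhat
#>        V_A 1.6732  6.04e-01     2.944 1.04
#>        V_C 0.2491  4.61e-06     0.514 1.00
#>         h2 0.5540  3.55e-01     0.726 1.05
#>         c2 0.0871  1.93e-06     0.179 1.02

sibs <- extract_dyads(ds$pedigree, "full_siblings")
jackknife_dyad_correlation(sibs, ds$phenotypes, n_replicates = 500, seed = 1)
#> full_siblings: r = 0.115 (95% CI 0.011 to 0.228), 267 families
```

The posterior mean `h2` of 0.55 carries a wide 95% HPD interval
(0.36–0.73) that covers the generating value 0.40: at 300 families a binary
trait pins variance components only loosely, which is why the package's
recovery checks run at 1,000 families. `c2` (0.09, HPD 0.00–0.18) brackets
the generating 0.10, and the full-sibling phenotypic correlation of 0.12 on
the observed 0/1 scale is what a 0.40-heritable liability trait at 13%
prevalence produces. At the default scale (4 chains × 13,000 iterations)
this fit takes about a minute on one core.

The same stages run end-to-end as a configured, seeded pipeline:

```r
run_pipeline(list(seed = 1, out_dir = "run1",
                  simulation = list(n_families = 200)))
```

which writes the simulated data, informative-relationship counts, fit
draws and summaries, dyad correlations, prevalence estimates, and a
`report.md`/`report.json` assembled purely from the stage files (see also
`inst/scripts/run_pipeline.R` for a shell entry point).

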