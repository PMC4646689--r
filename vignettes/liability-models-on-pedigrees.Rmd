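---
title: "Liability-threshold variance components on extended pedigrees: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold variance components on extended pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models it fits, the generative model behind its synthetic family
studies, the numerical conventions it commits to, and the places where a
genuinely open design question was settled one way rather than another.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The liability-threshold animal model

A binary disease phenotype on a pedigree is modelled through a latent
liability per individual,

$$ l_i = \mathbf{x}_i'\boldsymbol\beta + a_i + c_i + e_i,
   \qquad y_i = \mathbf{1}\{l_i > 0\}, $$

with three random parts:

* **Additive genetic effect** $\mathbf{a} \sim N(0, \mathbf{A}\,V_A)$,
  where $\mathbf{A}$ is the numerator relationship matrix of expected
  additive relationships computed from the pedigree by the tabular
  recursion (founders unrelated, $a_{kk} = 1 + F_k$). The sampler never
  forms $\mathbf{A}$ densely: it conditions on the sparse
  $\mathbf{A}^{-1}$ assembled by Henderson's rules, with
  Mendelian-sampling variances adjusted for parental inbreeding
  (coefficients by the Meuwissen–Luo algorithm). $\mathbf{A}^{-1}$ has
  $O(n)$ non-zeros, so fits scale to tens of thousands of individuals.
* **Family-group environment** $c$, constant within a self-reported
  extended-family label. Because that label also covers married-in,
  non-genetic relatives (spouses, in-laws), it captures shared environment
  rather than re-absorbing genetic variance — the pedigree's finer-grained
  relationship structure claims the genetic part. Omitting $c$ when it is
  real inflates $\hat h^2$; a directional test asserts exactly this
  attenuation pattern.
* **Link residual** $e$: standard normal under the probit formulation,
  standard logistic under logit.

Heritability is reported on the liability scale. The package's convention,
chosen to satisfy both the logit formula
$h^2 = V_A / (\sum V + \pi^2/3)$ and the probit threshold model:

$$ h^2 = \frac{V_A}{V_A + V_C + V_{\mathrm{resid}} + d}, \qquad
   d = \begin{cases} \pi^2/3 & \text{logit} \\ 0 & \text{probit,} \end{cases} $$

where $V_{\mathrm{resid}}$ is whatever residual the sampler fixed on the
link scale. For the probit fits $V_{\mathrm{resid}} = 1$ *is* the
distribution-specific variance, so nothing further is added; adding another
unit there would double-count the threshold residual. A logit fit with an
explicitly fixed unit residual (the convention of some MCMC mixed-model
software) passes that 1 through `v_resid` and the $\pi^2/3$ on top, which
reproduces the conventional categorical-model denominator. The formula is
deliberately not scale-free: a test asserts that rescaling all components
without rescaling $d$ changes $h^2$.

## Samplers

**Probit (default).** Albert–Chib augmentation: truncated-normal latent
liabilities, conjugate Gaussian updates for $\boldsymbol\beta$ (prior
$N(0, 100\,\mathbf{I})$ by default), single-site Gibbs sweeps for the
breeding values over the sparse $\mathbf{A}^{-1}$ neighbourhood, conjugate
family-effect and variance updates. The probit is the default because its
augmentation is exact — every conditional is sampled in closed form.

**Logit.** The link conventional for odds-ratio reporting is available for
the binary model via Pólya-Gamma augmentation, with the PG(1, z) draw
implemented by the Devroye alternating-series sampler. Odds ratios are
exponentiated per draw and summarised by the posterior mean of
$e^\beta$ with an HPD interval of the exponentiated draws; probit fits
refuse the transformation, since their coefficients are not log odds.

**Two-trait models.** The bivariate-by-sex model gives every individual a
record in the column of their sex and a structurally missing value in the
other; the three-category onset/course models use two latent utilities
against a zero baseline (multinomial probit with identity residual
covariance — fixed, because a free residual covariance is not identified
from categorical data). Both sample $2\times2$ genetic and
family-environment covariance matrices; $r_G = G_{12}/\sqrt{G_{11}G_{22}}$
is computed *per draw* and then summarised (the ratio of summaries is a
different and wrong quantity; a regression test asserts the per-draw
route). The marginal heritability of affected category $k$ — its
heritability against being unaffected, excluding the other affected
category — is formalised as the diagonal-based ratio
$G_{kk}/(G_{kk} + C_{kk} + 1)$. The cross-sex covariance is identified only
through opposite-sex relative pairs, so the sex fit counts and reports
them, and warns when there are none. The cross-sex family-environment
correlation is left free (not constrained), since nothing in the model
requires the shared-environment correlation between sexes to be unity.

**Priors.** No priors are hard-coded. The default is the
parameter-expanded formulation: a working scale $\alpha \sim N(0,1)$
multiplying working effects whose variance gets an inverse-gamma(1/2, 1/2)
prior, which makes the implied prior on $\sqrt{V_A}$ half-Cauchy with
scale 1 — weakly informative and far better mixing than a plain
inverse-gamma near zero. A plain inverse-gamma(0.001, 0.001) (univariate)
or inverse-Wishart($\nu_0 = 3$, $\mathbf{I}$) (2×2) is available for
comparability with common mixed-model defaults; the small-pedigree oracle
test runs under the plain prior so that the grid integration can use the
same closed-form density. Default chain plan: 4 chains × 13,000
iterations, 3,000 burn-in, thinning 10 — desk-scale (about a minute for
6,000–8,000 individuals on one core), with convergence monitored by the
potential-scale-reduction statistic across independently seeded chains
(flagged above 1.1); the categorical models were moved up to this length
after shorter chains left $r_G$ above that threshold.

**pMCMC** is two-sided by convention: twice the smaller tail fraction at
zero, floored at $1/n$ (a finite sample cannot witness a smaller tail than
one draw's worth). **HPD intervals** are the shortest window of
$\lceil 0.95 n \rceil$ sorted draws, first window reported on ties.

## The synthetic family-study generator

The generator stands in for a population family cohort in which
recruitment propagates through referred relatives. What it emulates:

* extended multi-generation families of variable size built from two
  templates — nuclear (couple plus 1–4 children) and three-generation
  (grandparent couple, their adult children with married-in spouses,
  grandchildren) — each family carrying a single `family_group` label that
  includes the married-in members;
* a 59% female share overall (couple members are one of each sex;
  unpaired members are drawn with a compensating probability so the
  marginal hits the target);
* a binary trait at 13.5% prevalence generated from the liability model
  itself, with $V_A$ and $V_C$ implied by the targets
  $(h^2, c^2)$ via $V_A = h^2 V_e / (1 - h^2 - c^2)$ so the liability-scale
  proportions are exact by construction;
* interview ages by generation (grandparents ≈ 72–74, parents ≈ 48–53,
  children ≈ 23–26, floored at 18), giving the mid-life-heavy age profile
  of such cohorts; ages of onset for affected individuals from a normal
  profile (mean 31.7, SD 12.3) truncated to [11, age at interview];
* sociodemographic factors (income, education, occupation, deprivation
  quintile, smoking, drinking, cohabitation) with explicit
  no-response/unknown levels and configurable liability-scale effects
  (default: a female excess of 0.55 on the probit scale, consistent with a
  roughly 2.7 odds ratio);
* a small excluded fraction (0.4%) whose status is missing-with-flag but
  whose relatives remain informative, emulating diagnoses screened out of
  the case definition;
* under a strata model, two correlated liabilities per individual by
  bivariate Mendelian sampling with matrix-valued genetic covariance
  $\mathbf{G}$ (off-diagonal $r_G\sqrt{G_{11}G_{22}}$, positive
  semi-definiteness checked) and family-environment analogue $\mathbf{C}$.

Numerical choices inside the generator:

* **Intercept calibration.** The threshold intercept solves
  $\mathbb{E}_x \int \Phi(\mu + x'\beta + z)\,\phi(z; 0, V_A + V_C)\,dz =
  \text{target}$ — closed form under probit, 30-node Gauss–Hermite
  quadrature under logit — so the marginal prevalence matches the target
  up to binomial noise (a calibration test asserts 3-SE agreement).
* **Mendelian sampling** uses the inbreeding-adjusted variance
  $V_A(1 - (F_s + F_d)/2)/2$; with the non-inbred default templates this
  is exactly $V_A/2$, and a Monte-Carlo test confirms the founder variance
  and the parent–offspring covariance $V_A/2$.
* **Stratum assignment.** An individual is affected when either liability
  exceeds its threshold; if both do, the larger *standardised* liability
  decides, and the tie frequency is reported. For the sex model the
  individual's sex selects which liability is expressed. Per-stratum
  marginal prevalences are calibrated separately (sex: 15.8%/9.1% scaled
  to the target; onset/course: half the target each by default), so the
  overall prevalence is approximately — not exactly — the target, the
  two affected categories overlapping slightly.
* **Seeding.** One global seed; per-family substreams derive from it by
  counter-based splitting, so growing `n_families` leaves earlier families
  byte-identical (asserted), and each downstream stage (covariates,
  liabilities, exclusions) draws from its own named substream.
* **Recall bias.** The generator exposes an optional upward shift of
  reported onset with age at interview, off by default: no defensible
  generative form for that bias is available, so the default tells the
  truth and the knob exists for sensitivity analyses.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: ascertainment beyond family-structured
recruitment (no screening on health status, no differential
participation), genotypes of any kind, longitudinal or repeated measures,
cohort effects in prevalence, non-additive genetic variance, and
covariate-dependent missingness. Recovery results at the study scale say
the estimator is consistent with its own generative model at that size;
they do not certify the model against real-world confounding.

## Other stages

**Informative relationships.** A relative pair is counted when both
members have non-missing phenotypes and at least one is affected — the
configuration under which a pair constrains variance components most; the
exact counting rule behind published tables of this kind is rarely stated,
so the rule is an explicit, configurable argument
(`rule = "both_nonmissing"` counts all complete pairs) and the table
reports sibling links through the mother and through the father separately
alongside full siblings and the four grandparental lines.

**Kinship dyad correlations.** Larger families contribute more pairs, so
each jackknife replicate samples one eligible pair per family (the
`family_group` label, matching how such families are accounted) and
computes the Pearson correlation of the 0/1 statuses — the phi
coefficient on the observed scale. 500 replicates give a mean and an
empirical 2.5/97.5-percentile interval; the percentile convention is a
documented choice (a normal approximation is available), since "a mean and
95% confidence intervals" does not pin one down. Replicates with a
zero-variance phenotype are recorded as undefined and excluded with a
count. Pair orientation follows the extraction convention and is fixed, so
a family set with no sampling choice yields identical replicates and a
zero-width interval. An orthant-probability oracle (the bivariate-normal
upper quadrant computed by one-dimensional quadrature) fixes the expected
phi for simulated sib pairs, and the jackknife mean must match it to 3 SE.

**Population inference.** Post-stratification weights multiply three
factors — population age-band × sex frequency over sample count, quintile
population share over sample share (a deprivation quintile index is
uniform in the population by construction; individuals with an unavailable
quintile keep a neutral factor of 1, mirroring the explicit
"unavailable" level kept in the fixed effects), and inverse family-group
size — normalised to sum to one. Age bands default to 5-year bins from 18
to 90+ (configurable; the convention is ours). The design-based weighted
prevalence is the weighted mean of statuses; the model-based mode follows
the coefficient-weighting description literally up to the link step:
because a weighted sum of log-odds coefficients has no prevalence
interpretation on its own, the default maps the population linear
predictor through the inverse link *integrating the genetic plus family
random effects by quadrature*, and the literal single-inverse-link variant
sits behind `link_scale = TRUE` for comparison. Both are exposed rather
than guessing which produced any particular published figure.
Kaplan–Meier age-of-onset curves per interview-age group censor unaffected
individuals at interview and are computed by `survival::survfit`, with
cumulative incidence $1 - S(t)$ returned alongside.

**Prevalence correction.** Retrospective lifetime prevalence under-counts
relative to cumulative designs. The correction model here is a
reconstruction of that idea, not a reimplementation of any particular
published code (whose form is not available): study pairs contribute
binomial likelihoods for their retrospective and cumulative counts linked
by a study log-ratio $r_j \sim N(\mu_r, \sigma_r^2)$; the current sample's
retrospective prevalence gets a conjugate Beta posterior; the predicted
cumulative prevalence is $p_{\mathrm{retro}} e^{r_{\mathrm{new}}}$ with
$r_{\mathrm{new}}$ from the population ratio distribution, truncated at 1
with the frequency logged. Priors: $\mu_r \sim N(0,1)$ and
$\sigma_r^2 \sim \mathrm{IG}(2.5, 0.03)$, concentrating the between-study
SD of the log-ratio around 0.1–0.2 — with a single study pair the
heterogeneity is otherwise unidentified, and this weakly-informative choice
makes the degenerate-evidence limit behave (ratio-2 evidence with huge
counts roughly doubles the estimate). Sampling is random-walk Metropolis
within Gibbs in plain R; the data are a handful of counts, so no compiled
sampler is warranted. Its output is checked for qualitative behaviour
(monotonicity in the evidence ratios, hyperparameter recovery, the
large-sample limit), never against any specific published corrected value.

## Problem sizes and runtime

The recovery suites run at 1,000 families (≈ 7,600 individuals): the
univariate smoke suite is 3 replicates of the probit fit with 4 × 13,000
iterations, and the illness-course ordering suite (recurrent stratum
simulated with twice the single stratum's additive variance, $r_G = 0.9$)
runs at the same scale after 500 families proved too noisy to order the
marginal heritabilities reliably — at roughly 230 cases per stratum the
posterior ordering flipped in a substantial fraction of replicates, which
is itself a statement about the power of such stratified analyses. The
smoke thresholds (HPD coverage in ≥ 2 of 3, ordering in ≥ 2 of 3) are the
3-replicate analogues of a ≥ 90%-of-20 nightly criterion. The
small-pedigree oracle check runs 50 individuals against a full
grid-integration posterior (Gauss–Hermite over parental breeding values,
children integrated in closed form) and agrees in posterior means to
within Monte-Carlo error.

## Known limitations

* The bivariate and categorical models are probit-only; logit is offered
  for the univariate model. Liability-scale summaries are comparable
  across links through the $d$ convention above.
* Single-site Gibbs sweeps mix more slowly than blocked samplers for very
  high $h^2$ or deep inbreeding; the parameter-expanded priors mitigate
  this, and the convergence diagnostic will flag the failure mode.
* Variance-component posteriors for rare binary traits are wide and
  right-skewed at desk scale; posterior means sit above the mode, so
  point-estimate comparisons at a few hundred families are noisy (the
  worked example in the README shows exactly this).
* Missing covariates are handled complete-case with logged exclusions
  (plus explicit no-response factor levels); there is no imputation.
* The correction module's hierarchy is a structural reconstruction;
  applying it to real study pairs requires the user to supply and defend
  the evidence table.
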