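# Shared small dataset for the fit tests (kept small: the statistical
# recovery properties are exercised at scale in test-acceptance.R).
small_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- simulate_dataset(simulation_config(n_families = 120, seed = 23))
    }
    ds
  }
})

fast_mcmc <- function(seed = 5, chains = 2) {
  mcmc_config(
    n_chains = chains, n_iter = 800, n_burnin = 200, thin = 2, seed = seed
  )
}

test_that("identical seed, data and configuration reproduce draws exactly", {
  ds <- small_dataset()
  spec <- liability_model_spec("binary", fixed_effects = "sex")
  f1 <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc())
  f2 <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc())
  expect_identical(f1$draws, f2$draws)
  # a different seed moves the draws
  f3 <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc(seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("derived liability quantities respect their ranges", {
  ds <- small_dataset()
  spec <- liability_model_spec("binary", fixed_effects = c("age", "sex"))
  fit <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc())
  expect_true(all(fit$draws[, "h2"] >= 0 & fit$draws[, "h2"] <= 1))
  expect_true(all(fit$draws[, "c2"] >= 0 & fit$draws[, "c2"] <= 1))
  expect_true(all(fit$draws[, "V_A"] >= 0))
  expect_s3_class(fit$summaries, "data.frame")
  # pMCMC reported for coefficients only
  s <- fit$summaries
  expect_true(all(!is.na(s$pmcmc[s$parameter %in% fit$coef_names])))
  expect_true(all(is.na(s$pmcmc[s$parameter == "h2"])))
})

test_that("the logit fit runs via Polya-Gamma augmentation and supports odds ratios", {
  ds <- small_dataset()
  spec <- liability_model_spec("binary", fixed_effects = "sex", link = "logit")
  fit <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc())
  or <- odds_ratios(fit)
  expect_true(all(or$odds_ratio > 0))
  # the simulated female excess (liability coefficient 0.55) should surface
  # as an odds ratio above 1
  expect_gt(or$odds_ratio[or$term == "sexfemale"], 1)
})

test_that("rank-deficient fixed effects fail naming the aliased columns", {
  ds <- small_dataset()
  cv <- ds$covariates
  cv$smoking2 <- cv$smoking # perfect alias
  spec <- liability_model_spec("binary", fixed_effects = c("smoking", "smoking2"))
  expect_error(
    fit_univariate(spec, ds$pedigree, ds$phenotypes, cv, fast_mcmc()),
    "aliased columns: .*smoking2"
  )
})

test_that("phenotyped ids missing from the pedigree are rejected", {
  ds <- small_dataset()
  ph <- rbind(ds$phenotypes[1:5, ], transform(ds$phenotypes[1, ], id = "ghost"))
  spec <- liability_model_spec("binary", fixed_effects = character(0))
  expect_error(
    fit_univariate(spec, ds$pedigree, ph, ds$covariates, fast_mcmc()),
    "absent from the pedigree: ghost"
  )
})

test_that("r_G is a per-draw transformation, not a ratio of summaries", {
  cfg <- simulation_config(
    n_families = 120, seed = 29, strata_model = "sex", rg_true = 0.8
  )
  ds <- simulate_dataset(cfg)
  spec <- liability_model_spec("bivariate_sex", fixed_effects = "age")
  fit <- fit_bivariate_sex(spec, ds$pedigree, ds$phenotypes, ds$covariates, fast_mcmc())
  g11 <- fit$draws[, "V_A_1"]
  g22 <- fit$draws[, "V_A_2"]
  g12 <- fit$draws[, "V_A_cross"]
  expect_equal(fit$draws[, "r_G"], g12 / sqrt(g11 * g22))
  expect_true(all(abs(fit$draws[, "r_G"]) <= 1 + 1e-8))
  # on these skewed variance draws the ratio-of-means differs
  expect_false(isTRUE(all.equal(
    mean(fit$draws[, "r_G"]), mean(g12) / sqrt(mean(g11) * mean(g22))
  )))
  expect_gt(fit$n_informative_cross_pairs, 0)
})

test_that("an all-one-sex phenotype set leaves the cross-sex correlation prior-dominated", {
  cfg <- simulation_config(n_families = 60, seed = 31, strata_model = "sex")
  ds <- simulate_dataset(cfg)
  ph <- ds$phenotypes
  male <- ds$pedigree$ind$sex[match(ph$id, ds$pedigree$ind$id)] == "male"
  ph$status[male] <- NA # only female phenotypes remain
  spec <- liability_model_spec("bivariate_sex", fixed_effects = character(0))
  expect_warning(
    fit_bivariate_sex(spec, ds$pedigree, ph, ds$covariates, fast_mcmc(chains = 2)),
    "prior-dominated"
  )
})

test_that("categorical fits validate their response structure", {
  cfg <- simulation_config(n_families = 60, seed = 37, strata_model = "course")
  ds <- simulate_dataset(cfg)
  ph <- ds$phenotypes
  spec <- liability_model_spec("categorical_course", fixed_effects = character(0))
  expect_error(
    fit_categorical(spec, ds$pedigree, ph, ds$covariates, fast_mcmc()),
    "factor column"
  )
  ph$response <- ph$stratum
  # empty category is named
  ph2 <- ph
  ph2$response[ph2$response == "recurrent"] <- NA
  ph2$response <- factor(ph2$response, levels = c("absent", "single", "recurrent"))
  expect_error(
    fit_categorical(spec, ds$pedigree, ph2, ds$covariates, fast_mcmc()),
    "empty response category: recurrent"
  )
  # wrong baseline ordering is rejected
  ph3 <- ph
  ph3$response <- factor(as.character(ph3$stratum),
    levels = c("single", "absent", "recurrent")
  )
  expect_error(
    fit_categorical(spec, ds$pedigree, ph3, ds$covariates, fast_mcmc()),
    "baseline"
  )
})

test_that("a categorical fit returns marginal heritabilities and correlations in range", {
  cfg <- simulation_config(
    n_families = 150, seed = 41, strata_model = "course", va_ratio = 2,
    rg_true = 0.9
  )
  ds <- simulate_dataset(cfg)
  ph <- ds$phenotypes
  ph$response <- ph$stratum
  spec <- liability_model_spec("categorical_course", fixed_effects = "age")
  fit <- fit_categorical(spec, ds$pedigree, ph, ds$covariates, fast_mcmc())
  expect_setequal(fit$trait_names, c("single", "recurrent"))
  expect_true(all(fit$draws[, "h2_single"] >= 0 & fit$draws[, "h2_single"] <= 1))
  expect_true(all(fit$draws[, "h2_recurrent"] >= 0 & fit$draws[, "h2_recurrent"] <= 1))
  expect_true(all(abs(fit$draws[, "r_G"]) <= 1 + 1e-8))
})

test_that("omitting a real family-environment effect inflates heritability", {
  cfg <- simulation_config(
    n_families = 500, seed = 43, h2_true = 0.3, c2_true = 0.2,
    covariate_effects = NULL
  )
  ds <- simulate_dataset(cfg)
  mc <- mcmc_config(n_chains = 2, n_iter = 2500, n_burnin = 500, thin = 5, seed = 9)
  with_c <- fit_univariate(
    liability_model_spec("binary", fixed_effects = character(0), family_effect = TRUE),
    ds$pedigree, ds$phenotypes, ds$covariates, mc
  )
  without_c <- fit_univariate(
    liability_model_spec("binary", fixed_effects = character(0), family_effect = FALSE),
    ds$pedigree, ds$phenotypes, ds$covariates, mc
  )
  expect_gt(mean(without_c$draws[, "h2"]), mean(with_c$draws[, "h2"]))
})

test_that("mcmc_config validates its invariants", {
  expect_error(mcmc_config(n_iter = 100, n_burnin = 200), "exceed")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(
    liability_model_spec("bivariate_sex", link = "logit"),
    "binary response only"
  )
})
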