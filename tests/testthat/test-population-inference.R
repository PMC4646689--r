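toy_sample <- function() {
  data.frame(
    id = paste0("i", 1:8),
    age_at_interview = c(25, 25, 25, 25, 60, 60, 60, 60),
    sex = rep(c("female", "male"), 4),
    simd_quintile = factor(rep("q3", 8)),
    family_group = paste0("f", 1:8)
  )
}

self_weighting_pop <- function(sample_df) {
  band <- cut(sample_df$age_at_interview, c(seq(18, 90, by = 5), Inf),
    right = FALSE, labels = seq(18, 90, by = 5), include.lowest = TRUE
  )
  tab <- as.data.frame(table(age_band = band, sex = sample_df$sex))
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "count"
  tab
}

test_that("a self-weighting sample of singleton families gets uniform weights", {
  s <- toy_sample()
  w <- build_weights(s, self_weighting_pop(s))
  expect_equal(w$weight, rep(1 / 8, 8))
  expect_equal(sum(w$weight), 1, tolerance = 1e-10)
  # and the weighted prevalence is exactly the raw proportion
  y <- c(1, 0, 0, 0, 1, 0, 0, 0)
  expect_equal(weighted_prevalence(y, w)$prevalence, mean(y))
})

test_that("stratum weights are proportional to population over sample shares", {
  # two strata, population 50/50, sample 80/20
  s <- data.frame(
    id = paste0("i", 1:10),
    age_at_interview = c(rep(25, 8), rep(60, 2)),
    sex = "female",
    family_group = paste0("f", 1:10)
  )
  pop <- data.frame(age_band = c("18", "40"), sex = "female", count = c(50, 50))
  w <- build_weights(s, pop, age_breaks = c(18, 40, 90))
  # young weight ~ 0.5/0.8, old ~ 0.5/0.2, normalised
  ratio <- w$weight[9] / w$weight[1]
  expect_equal(ratio, (50 / 2) / (50 / 8))
  expect_equal(sum(w$weight), 1, tolerance = 1e-10)

  # weights are invariant to rescaling the population table
  pop2 <- transform(pop, count = count * 1000)
  w2 <- build_weights(s, pop2, age_breaks = c(18, 40, 90))
  expect_equal(w2$weight, w$weight)
})

test_that("family weights are inverse family size", {
  s <- toy_sample()
  s$family_group <- c(rep("big", 4), paste0("f", 5:8))
  w <- build_weights(s, self_weighting_pop(s))
  expect_equal(w$w_family[1], 0.25)
  expect_equal(w$w_family[5], 1)
})

test_that("missing population cells error; missing SIMD stays neutral", {
  s <- toy_sample()
  pop <- self_weighting_pop(s)
  expect_error(
    build_weights(s, pop[pop$sex == "female", ]),
    "missing sampled age/sex cell"
  )
  s2 <- toy_sample()
  s2$simd_quintile <- factor(c(rep("q1", 4), rep("unavailable", 4)),
    levels = c("q1", "unavailable")
  )
  w <- build_weights(s2, self_weighting_pop(s2))
  expect_true(all(w$w_simd[5:8] == 1))
})

test_that("weighted prevalence reproduces direct stratified calculations", {
  # uniform weights, 27 affected of 200 -> 13.5%
  w <- data.frame(id = paste0("i", 1:200), weight = rep(1 / 200, 200))
  y <- c(rep(1, 27), rep(0, 173))
  expect_equal(weighted_prevalence(y, w)$prevalence, 0.135)

  # two strata weighted (0.5, 0.5) with prevalences 0.10 and 0.20 -> 0.15
  y2 <- c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80))
  w2 <- data.frame(id = seq_along(y2), weight = rep(c(0.5 / 100, 0.5 / 100), each = 100))
  expect_equal(weighted_prevalence(y2, w2)$prevalence, 0.15)
  expect_error(
    weighted_prevalence(y2, transform(w2, weight = weight * 2)),
    "normalised"
  )
})

test_that("weighting corrects deliberately unbalanced sampling; raw means do not", {
  set.seed(11)
  # population truth: stratum A prevalence 0.10 (90% of people),
  # stratum B prevalence 0.30 (10%); sample is half A half B
  n <- 4000
  stratum <- rep(c("A", "B"), each = n / 2)
  y <- ifelse(stratum == "A", rbinom(n, 1, 0.10), rbinom(n, 1, 0.30))
  s <- data.frame(
    id = seq_len(n),
    age_at_interview = ifelse(stratum == "A", 25, 60),
    sex = "female",
    family_group = seq_len(n)
  )
  pop <- data.frame(age_band = c("18", "40"), sex = "female", count = c(90, 10))
  w <- build_weights(s, pop, age_breaks = c(18, 40, 90))
  truth <- 0.9 * 0.10 + 0.1 * 0.30
  est <- weighted_prevalence(y, w)
  se <- sqrt(truth * (1 - truth) / est$n_eff)
  expect_lt(abs(est$prevalence - truth), 3 * se)
  expect_gt(abs(mean(y) - truth), 3 * se) # naive mean is biased
  # design-based estimate lies between the stratum prevalences
  expect_gt(est$prevalence, min(mean(y[stratum == "A"]), mean(y[stratum == "B"])))
  expect_lt(est$prevalence, max(mean(y[stratum == "A"]), mean(y[stratum == "B"])))
})

test_that("model-based weighted prevalence tracks the design-based estimate", {
  ds <- simulate_dataset(simulation_config(n_families = 150, seed = 51))
  spec <- liability_model_spec("binary", fixed_effects = "sex")
  mc <- mcmc_config(n_chains = 2, n_iter = 1500, n_burnin = 500, thin = 5, seed = 3)
  fit <- fit_univariate(spec, ds$pedigree, ds$phenotypes, ds$covariates, mc)
  samp <- ds$covariates
  samp$family_group <- ds$pedigree$ind$family_group[match(samp$id, ds$pedigree$ind$id)]
  w <- build_weights(samp, self_weighting_pop(samp))
  status <- ds$phenotypes$status[match(samp$id, ds$phenotypes$id)]
  des <- weighted_prevalence(status, w)
  mod <- weighted_prevalence(fit, w, covariates = ds$covariates, method = "model")
  expect_true(mod$prevalence > 0 && mod$prevalence < 1)
  expect_lt(abs(mod$prevalence - des$prevalence), 0.05)
  # the literal link-scale variant is exposed but differs (no random-effect
  # integration), pulling the estimate away from the observed proportion
  lit <- weighted_prevalence(fit, w,
    covariates = ds$covariates, method = "model",
    link_scale = TRUE
  )
  expect_false(isTRUE(all.equal(lit$prevalence, mod$prevalence)))
})

test_that("attributable risk is a prevalence difference with draw-level intervals", {
  expect_equal(attributable_risk(0.158, 0.091)$risk_difference, 0.067)
  expect_equal(attributable_risk(0.2, 0.2)$risk_difference, 0)
  set.seed(5)
  ar <- attributable_risk(rbeta(1000, 40, 200), rbeta(1000, 20, 200))
  expect_true(ar$ci[1] < ar$risk_difference & ar$risk_difference < ar$ci[2])
  expect_error(attributable_risk(1.2, 0.5), "\\[0, 1\\]")
})

test_that("onset survival curves reproduce a hand-computed product-limit table", {
  # one group, 10 records: events at ages 20, 25 (x2), 35, 40;
  # censoring at 22, 25, 30, 45, 50
  ph <- data.frame(
    id = 1:10,
    status = c(1, 0, 1, 1, 0, 1, 0, 1, 0, 0),
    age_at_interview = c(50, 22, 50, 50, 25, 50, 30, 50, 45, 50),
    age_of_onset = c(20, NA, 25, 25, NA, 35, NA, 40, NA, NA)
  )
  out <- onset_survival_curves(ph, age_groups = c(18, Inf))
  # hand-computed risk sets: t=20 n=10 (1 event); t=25 n=8 (2 events,
  # the id censored at 25 still at risk); t=35 n=4 (1 event); t=40 n=3
  # (1 event; remaining are the censors at 45 and 50)
  expect_equal(out$survival[out$age == 20], 0.9)
  expect_equal(out$survival[out$age == 25], 0.9 * 6 / 8)
  expect_equal(out$survival[out$age == 35], 0.9 * 6 / 8 * 3 / 4)
  expect_equal(out$survival[out$age == 40], 0.9 * 6 / 8 * 3 / 4 * 2 / 3)
  expect_equal(out$cum_incidence, 1 - out$survival)

  # all affected at one onset age: step to zero there
  ph2 <- data.frame(
    id = 1:5, status = 1, age_at_interview = 50, age_of_onset = 33
  )
  out2 <- onset_survival_curves(ph2, age_groups = c(18, Inf))
  expect_equal(out2$survival[out2$age == 33], 0)

  # no events: survival identically 1
  ph3 <- data.frame(
    id = 1:5, status = 0, age_at_interview = c(30, 40, 50, 60, 70),
    age_of_onset = NA
  )
  out3 <- onset_survival_curves(ph3, age_groups = c(18, Inf))
  expect_true(all(out3$survival == 1))

  # onset after interview age is invalid
  ph4 <- transform(ph2, age_of_onset = 60)
  expect_error(onset_survival_curves(ph4), "onset")

  # grouping by interview age yields one curve per group
  out5 <- onset_survival_curves(ph, age_groups = c(18, 40, Inf))
  expect_equal(length(unique(out5$group)), 2)
})
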