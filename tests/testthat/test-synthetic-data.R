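test_that("simulated pedigrees are deterministic and stable under family-count growth", {
  cfg <- simulation_config(n_families = 50, seed = 13)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1$ind, p2$ind)

  # counter-based substreams: the first 50 families are unchanged at 60
  cfg2 <- simulation_config(n_families = 60, seed = 13)
  p3 <- simulate_pedigree(cfg2)
  first50 <- p3$ind[p3$ind$family_group %in% unique(p1$ind$family_group), ]
  rownames(first50) <- NULL
  expect_identical(first50[c("id", "sire", "dam", "family_group")],
    p1$ind[c("id", "sire", "dam", "family_group")])
})

test_that("a single nuclear-template family has the expected structure", {
  cfg <- simulation_config(
    n_families = 1, seed = 2,
    template_probs = c(nuclear = 1, extended = 0),
    children_probs = c(0, 1) # exactly 2 children
  )
  ped <- simulate_pedigree(cfg)
  expect_equal(n_individuals(ped), 4)
  expect_equal(sum(ped$ind$founder), 2)
  expect_equal(length(unique(ped$ind$family_group)), 1)
})

test_that("observed female share hits the target within binomial error", {
  cfg <- simulation_config(n_families = 2000, seed = 21)
  ped <- simulate_pedigree(cfg)
  n <- n_individuals(ped)
  share <- mean(ped$ind$sex == "female")
  se <- sqrt(0.59 * 0.41 / n)
  expect_lt(abs(share - 0.59), 3 * se)
})

test_that("zero heritability gives identically zero breeding values", {
  cfg <- simulation_config(n_families = 20, seed = 3, h2_true = 0, c2_true = 0.2)
  ped <- simulate_pedigree(cfg)
  liab <- simulate_liabilities(ped, cfg)
  expect_true(all(liab$a == 0))
  expect_gt(stats::var(liab$c_env), 0)
})

test_that("founder breeding-value variance and parent-offspring covariance match theory", {
  # 10,000 founders: Var(a) ~ V_A within Monte-Carlo error
  cfg <- simulation_config(n_families = 1, seed = 5, h2_true = 0.5, c2_true = 0)
  va <- cfg$h2_true / (1 - cfg$h2_true) # probit: V_A = h2 * 1 / (1 - h2)
  n <- 10000
  founders <- pedigree(paste0("f", 1:n), NA, NA, "female", paste0("g", 1:n))
  liab <- simulate_liabilities(founders, cfg, seed = 7)
  se_var <- va * sqrt(2 / (n - 1)) # SE of a normal-sample variance
  expect_lt(abs(stats::var(liab$a) - va), 3 * se_var)

  # 10,000 parent-offspring pairs: Cov(a_p, a_o) ~ V_A / 2
  m <- 10000
  trio_ped <- pedigree(
    id = c(paste0("s", 1:m), paste0("d", 1:m), paste0("k", 1:m)),
    sire = c(rep(NA, 2 * m), paste0("s", 1:m)),
    dam = c(rep(NA, 2 * m), paste0("d", 1:m)),
    sex = rep(c("male", "female", "female"), each = m)
  )
  liab2 <- simulate_liabilities(trio_ped, cfg, seed = 8)
  a <- liab2$a[match(paste0("s", 1:m), liab2$id)]
  k <- liab2$a[match(paste0("k", 1:m), liab2$id)]
  # SE of the sample covariance of bivariate normals
  se_cov <- sqrt((va * va + (va / 2)^2) / m)
  expect_lt(abs(stats::cov(a, k) - va / 2), 3 * se_cov)
})

test_that("the calibrated intercept hits the target prevalence for both links", {
  for (link in c("probit", "logit")) {
    cfg <- simulation_config(
      n_families = 1200, seed = 11, link = link,
      target_prevalence = 0.135
    )
    ds <- simulate_dataset(cfg)
    p <- mean(ds$phenotypes$status, na.rm = TRUE)
    n <- sum(!is.na(ds$phenotypes$status))
    expect_lt(abs(p - 0.135), 3 * sqrt(0.135 * 0.865 / n))
  }
})

test_that("sibling concordance increases monotonically with heritability", {
  conc <- vapply(c(0, 0.2, 0.4, 0.6), function(h2) {
    cfg <- simulation_config(
      n_families = 2500, seed = 31, h2_true = h2, c2_true = 0.05,
      template_probs = c(nuclear = 1, extended = 0),
      children_probs = c(0, 1), # sib pairs
      covariate_effects = NULL
    )
    ped <- simulate_pedigree(cfg)
    liab <- simulate_liabilities(ped, cfg)
    kids <- !ped$ind$founder
    k1 <- which(kids)[c(TRUE, FALSE)]
    k2 <- which(kids)[c(FALSE, TRUE)]
    mean(liab$status[k1] == 1 & liab$status[k2] == 1)
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
})

test_that("pure family environment makes sibling and spouse-pair concordance comparable", {
  cfg <- simulation_config(
    n_families = 3000, seed = 41, h2_true = 0, c2_true = 0.3,
    template_probs = c(nuclear = 0, extended = 1), covariate_effects = NULL
  )
  ped <- simulate_pedigree(cfg)
  liab <- simulate_liabilities(ped, cfg)
  status <- liab$status
  idx <- match(ped$ind$id, liab$id)

  concordance <- function(pairs_i, pairs_j) {
    s1 <- status[idx[pairs_i]]
    s2 <- status[idx[pairs_j]]
    mean(s1 == 1 & s2 == 1)
  }
  sibs <- extract_dyads(ped, "full_siblings")
  r_sib <- concordance(match(sibs$id_i, ped$ind$id), match(sibs$id_j, ped$ind$id))
  # spouse pairs: co-parents who are not genetic relatives
  kids <- ped$ind[!ped$ind$founder, ]
  sp <- unique(kids[c("sire_idx", "dam_idx")])
  sp <- sp[sp$sire_idx > 0 & sp$dam_idx > 0, ]
  r_sp <- concordance(sp$sire_idx, sp$dam_idx)
  # both concordances arise from the same shared-environment variance
  n_pairs <- min(nrow(sibs), nrow(sp))
  expect_lt(abs(r_sib - r_sp), 3 * sqrt(2 * 0.05 / n_pairs))
})

test_that("perfectly correlated strata share breeding values; uncorrelated do not", {
  ped <- pedigree(paste0("f", 1:10000), NA, NA, "female")
  cfg1 <- simulation_config(
    n_families = 1, seed = 6, strata_model = "course",
    rg_true = 1, rc_true = 0, va_ratio = 1
  )
  st <- simulate_strata(ped, cfg1, seed = 61)
  expect_lt(max(abs(st$a[, 1] - st$a[, 2])), 1e-8)

  cfg0 <- simulation_config(
    n_families = 1, seed = 6, strata_model = "course",
    rg_true = 0, rc_true = 0, va_ratio = 1
  )
  st0 <- simulate_strata(ped, cfg0, seed = 62)
  expect_lt(abs(stats::cor(st0$a[, 1], st0$a[, 2])), 3 / sqrt(10000))
})

test_that("the sex strata model expresses exactly one status column per individual", {
  cfg <- simulation_config(n_families = 150, seed = 8, strata_model = "sex")
  ped <- simulate_pedigree(cfg)
  st <- simulate_strata(ped, cfg)
  n_obs <- rowSums(!is.na(st$status))
  expect_true(all(n_obs == 1))
  female <- ped$ind$sex == "female"
  expect_true(all(!is.na(st$status[female, 1])))
  expect_true(all(!is.na(st$status[!female, 2])))
})

test_that("datasets round-trip through write_dataset / read_dataset", {
  cfg <- simulation_config(n_families = 30, seed = 17, strata_model = "course")
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$pedigree$ind, ds$pedigree$ind)
  expect_equal(back$phenotypes$status, ds$phenotypes$status)
  expect_equal(back$phenotypes$age_of_onset, ds$phenotypes$age_of_onset)
  expect_equal(as.character(back$phenotypes$stratum), as.character(ds$phenotypes$stratum))
  expect_equal(back$covariates$income, ds$covariates$income)
  # truth JSON carries the full generating configuration
  expect_equal(back$truth$h2_true, cfg$h2_true)
  expect_equal(back$truth$seed, cfg$seed)
  expect_true(all(c("n_families", "c2_true", "target_prevalence", "link",
    "rg_true", "va_ratio", "onset_cutoff_age") %in% names(back$truth)))
})

test_that("phenotype internal consistency: onset, episodes, exclusions", {
  cfg <- simulation_config(n_families = 300, seed = 19, strata_model = "course",
    bipolar_fraction = 0.02)
  ds <- simulate_dataset(cfg)
  ph <- ds$phenotypes
  aff <- !is.na(ph$status) & ph$status == 1
  expect_true(all(ph$age_of_onset[aff] <= ph$age_at_interview[aff]))
  rec <- aff & ph$stratum == "recurrent"
  sng <- aff & ph$stratum == "single"
  expect_true(all(ph$episode_count[rec] >= 2))
  expect_true(all(ph$episode_count[sng] == 1))
  expect_true(all(is.na(ph$status[ph$excluded])))
  expect_gt(sum(ph$excluded), 0)
})
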