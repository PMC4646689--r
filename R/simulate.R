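#' Configuration for the family-study simulator
#'
#' Defines the generative truth for a synthetic family study: extended,
#' multi-generation pedigrees with married-in spouses, a binary trait
#' generated from a liability with additive-genetic and family-environment
#' variance plus a link-specific residual, and optional correlated liabilities
#' across strata (sex, age-of-onset, illness course).
#'
#' Variance targets are expressed as liability-scale proportions: with the
#' residual variance fixed by the link (1 for probit, pi^2/3 for logit),
#' `V_A = h2 * V_e / (1 - h2 - c2)` and `V_C = c2 * V_e / (1 - h2 - c2)`, so
#' that `V_A / (V_A + V_C + V_e) = h2` exactly.
#'
#' @param n_families number of families to simulate.
#' @param template_probs probabilities of the family templates: `nuclear`
#'   (couple plus children) and `extended` (three generations with married-in
#'   spouses, all sharing one family-group label).
#' @param children_probs distribution of the number of children per couple
#'   (1 to `length(children_probs)`).
#' @param female_fraction target marginal share of females (couple members are
#'   one of each sex; unpaired individuals are drawn to hit the target overall).
#' @param h2_true liability-scale heritability of the (first) trait.
#' @param c2_true family-environment proportion of liability variance.
#' @param target_prevalence marginal prevalence of the binary trait.
#' @param link `"probit"` or `"logit"` residual for the liability.
#' @param strata_model `NULL` for a single binary trait, or one of `"sex"`,
#'   `"onset"`, `"course"` for two correlated liabilities.
#' @param rg_true,rc_true genetic and family-environment correlations between
#'   the two stratum liabilities.
#' @param va_ratio ratio of the second stratum's additive variance to the
#'   first's (e.g. 2 makes the recurrent trait twice as heritable a target).
#' @param stratum_prevalence length-2 vector of per-stratum marginal
#'   prevalences; default splits `target_prevalence` equally (for
#'   `strata_model = "sex"` the defaults are the female/male rates 0.158 and
#'   0.091 scaled to the target).
#' @param onset_cutoff_age years separating earlier from later onset.
#' @param covariate_effects named numeric vector of liability-scale
#'   coefficients, names `"age"` (per year, centred) or `"variable:level"`
#'   (e.g. `"sex:female"`).
#' @param bipolar_fraction fraction of individuals excluded from diagnosis
#'   (status missing-with-flag, relatives retained), emulating screened-out
#'   bipolar cases.
#' @param current_fraction fraction of affected individuals in a current
#'   episode at interview.
#' @param onset_recall_shift optional upward recall-bias shift (years) added
#'   to reported onset for older interviewees; off (0) by default.
#' @param seed integer seed; all per-family substreams derive from it by
#'   counter-based splitting so earlier families are unchanged when
#'   `n_families` grows.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_families = 1000,
                              template_probs = c(nuclear = 0.45, extended = 0.55),
                              children_probs = c(0.3, 0.35, 0.25, 0.1),
                              female_fraction = 0.59,
                              h2_true = 0.4,
                              c2_true = 0.1,
                              target_prevalence = 0.135,
                              link = c("probit", "logit"),
                              strata_model = NULL,
                              rg_true = 0.9,
                              rc_true = 0.5,
                              va_ratio = 1,
                              stratum_prevalence = NULL,
                              onset_cutoff_age = 40,
                              covariate_effects = c("sex:female" = 0.55),
                              bipolar_fraction = 0.004,
                              current_fraction = 0.18,
                              onset_recall_shift = 0,
                              seed = 1L) {
  link <- match.arg(link)
  if (h2_true < 0 || c2_true < 0 || h2_true + c2_true >= 1) {
    stop("h2_true + c2_true must lie in [0, 1)")
  }
  if (abs(rg_true) > 1 || abs(rc_true) > 1) stop("rg_true and rc_true must lie in [-1, 1]")
  if (!is.null(strata_model)) {
    strata_model <- match.arg(strata_model, c("sex", "onset", "course"))
  }
  if (is.null(stratum_prevalence)) {
    stratum_prevalence <- if (identical(strata_model, "sex")) {
      target_prevalence * c(0.158, 0.091) / 0.135
    } else {
      rep(target_prevalence / 2, 2)
    }
  }
  cfg <- list(
    n_families = as.integer(n_families),
    template_probs = template_probs / sum(template_probs),
    children_probs = children_probs / sum(children_probs),
    female_fraction = female_fraction,
    h2_true = h2_true, c2_true = c2_true,
    target_prevalence = target_prevalence,
    link = link,
    strata_model = strata_model,
    rg_true = rg_true, rc_true = rc_true, va_ratio = va_ratio,
    stratum_prevalence = stratum_prevalence,
    onset_cutoff_age = onset_cutoff_age,
    covariate_effects = covariate_effects,
    bipolar_fraction = bipolar_fraction,
    current_fraction = current_fraction,
    onset_recall_shift = onset_recall_shift,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# residual variance fixed by the link
link_residual_variance <- function(link) {
  if (link == "logit") pi^2 / 3 else 1
}

# liability-scale variance components implied by (h2, c2) targets
true_variances <- function(cfg) {
  ve <- link_residual_variance(cfg$link)
  s <- 1 - cfg$h2_true - cfg$c2_true
  list(va = cfg$h2_true * ve / s, vc = cfg$c2_true * ve / s, ve = ve)
}

# deterministic substream seed (counter-based split below 2^31)
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 69069 + stream * 30011) %% 2147483629 + 1)
}

#' Simulate a family-study pedigree
#'
#' Families are drawn independently from the configured templates. A
#' `nuclear` family is a founder couple and their children. An `extended`
#' family spans three generations: a grandparent couple, two or three of
#' their adult children each with (usually) a married-in spouse, and
#' grandchildren. Every member of a family, including non-genetic married-in
#' spouses, carries the same `family_group` label. Each family uses its own
#' seed derived from `cfg$seed` by counter-based splitting, so the first `k`
#' families are identical for any `n_families >= k`.
#'
#' @param cfg a [simulation_config()].
#' @return a [pedigree] object with ages stored in attribute `"ages"`
#'   (a data.frame `id`, `age_at_interview`).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  fams <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    set.seed(substream_seed(cfg$seed, f))
    tmpl <- sample(names(cfg$template_probs), 1, prob = cfg$template_probs)
    fams[[f]] <- if (tmpl == "nuclear") sim_family_nuclear(f, cfg) else sim_family_extended(f, cfg)
  }
  recs <- do.call(rbind, fams)

  # assign sexes of unpaired members so the overall female share hits target
  set.seed(substream_seed(cfg$seed, 0L))
  free <- which(recs$sex == "?")
  n_total <- nrow(recs)
  n_couple_female <- sum(recs$sex == "female")
  p <- (cfg$female_fraction * n_total - n_couple_female) / length(free)
  p <- min(max(p, 0), 1)
  recs$sex[free] <- ifelse(stats::runif(length(free)) < p, "female", "male")

  ped <- pedigree(recs$id, recs$sire, recs$dam, recs$sex, recs$family_group)
  ages <- data.frame(id = recs$id, age_at_interview = recs$age)
  attr(ped, "ages") <- ages[match(ped$ind$id, ages$id), ]
  ped
}

fam_id <- function(f, i) sprintf("F%04d_I%02d", f, i)

rage <- function(n, mean, sd, min_age = 18) {
  pmax(round(stats::rnorm(n, mean, sd)), min_age)
}

sim_family_nuclear <- function(f, cfg) {
  n_kids <- sample(seq_along(cfg$children_probs), 1, prob = cfg$children_probs)
  ids <- fam_id(f, seq_len(2 + n_kids))
  fg <- sprintf("FAM%04d", f)
  data.frame(
    id = ids,
    sire = c(NA, NA, rep(ids[1], n_kids)),
    dam = c(NA, NA, rep(ids[2], n_kids)),
    sex = c("male", "female", rep("?", n_kids)),
    family_group = fg,
    age = c(rage(1, 53, 7), rage(1, 51, 7), rage(n_kids, 26, 5)),
    stringsAsFactors = FALSE
  )
}

sim_family_extended <- function(f, cfg) {
  fg <- sprintf("FAM%04d", f)
  counter <- 0L
  nid <- function() {
    counter <<- counter + 1L
    fam_id(f, counter)
  }
  rows <- list()
  push <- function(id, sire, dam, sex, age) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex,
      family_group = fg, age = age, stringsAsFactors = FALSE
    )
  }
  gf <- nid(); gm <- nid()
  push(gf, NA, NA, "male", rage(1, 74, 5))
  push(gm, NA, NA, "female", rage(1, 72, 5))
  n_mid <- sample(2:3, 1)
  for (m in seq_len(n_mid)) {
    child <- nid()
    child_sex <- if (stats::runif(1) < 0.5) "female" else "male"
    push(child, gf, gm, child_sex, rage(1, 48, 6))
    if (stats::runif(1) < 0.8) {
      spouse <- nid()
      spouse_sex <- if (child_sex == "female") "male" else "female"
      push(spouse, NA, NA, spouse_sex, rage(1, 48, 6))
      n_gk <- sample(1:3, 1)
      for (k in seq_len(n_gk)) {
        gk <- nid()
        sire <- if (child_sex == "male") child else spouse
        dam <- if (child_sex == "female") child else spouse
        push(gk, sire, dam, "?", rage(1, 23, 4))
      }
    }
  }
  do.call(rbind, rows)
}

# --- liabilities ------------------------------------------------------------

#' Simulate additive-genetic and family-environment liability components
#'
#' Breeding values are generated by Mendelian sampling down the topological
#' order: founders draw `a ~ N(0, V_A)`; an offspring draws
#' `a = (a_s + a_d)/2 + N(0, V_A (1 - (F_s + F_d)/2) / 2)` with parental
#' inbreeding coefficients from [inbreeding()]. The family-environment
#' component is shared within `family_group`. The liability is
#' `intercept + xb + a + c + e` with `e` standard normal (probit) or standard
#' logistic (logit); the intercept is calibrated numerically so the marginal
#' prevalence matches `cfg$target_prevalence` (Gauss-Hermite integration over
#' the Gaussian `a + c` under logit).
#'
#' @param ped a [pedigree] object.
#' @param cfg a [simulation_config()].
#' @param xb optional per-individual fixed-effect contribution (pedigree
#'   order); defaults to 0.
#' @param seed seed for this stage (defaults to a substream of `cfg$seed`).
#' @return data.frame in pedigree order with columns `id`, `a`, `c_env`,
#'   `liability`, `status`, and attribute `"intercept"`.
#' @export
simulate_liabilities <- function(ped, cfg, xb = NULL, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "simulation_config"))
  v <- true_variances(cfg)
  n <- n_individuals(ped)
  if (is.null(xb)) xb <- numeric(n)
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, 900001L) else seed)

  a <- mendelian_sample(ped, v$va)
  fams <- ped$ind$family_group
  cf <- stats::rnorm(length(unique(fams)), 0, sqrt(v$vc))
  c_env <- cf[match(fams, unique(fams))]
  e <- if (cfg$link == "logit") stats::rlogis(n) else stats::rnorm(n)

  mu <- calibrate_intercept(xb, v$va + v$vc, cfg$target_prevalence, cfg$link)
  liab <- mu + xb + a + c_env + e
  out <- data.frame(
    id = ped$ind$id, a = a, c_env = c_env, liability = liab,
    status = as.integer(liab > 0)
  )
  attr(out, "intercept") <- mu
  out
}

# univariate Mendelian sampling of breeding values down the pedigree
mendelian_sample <- function(ped, va) {
  ind <- ped$ind
  n <- nrow(ind)
  if (va == 0) return(numeric(n))
  f <- inbreeding(ped)
  a <- numeric(n)
  z <- stats::rnorm(n)
  for (i in seq_len(n)) {
    s <- ind$sire_idx[i]; d <- ind$dam_idx[i]
    if (s == 0L && d == 0L) {
      a[i] <- z[i] * sqrt(va)
    } else if (s > 0L && d > 0L) {
      msv <- va * (1 - (f[s] + f[d]) / 2) / 2
      a[i] <- (a[s] + a[d]) / 2 + z[i] * sqrt(msv)
    } else {
      p <- max(s, d)
      msv <- va * (3 - f[p]) / 4 # one parent unknown
      a[i] <- a[p] / 2 + z[i] * sqrt(msv)
    }
  }
  a
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention)
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  idx <- order(ev$values)
  list(nodes = ev$values[idx], weights = (ev$vectors[1, idx]^2) * sqrt(pi))
}

# P(liability > 0) marginalised over N(0, vrand) random effects, averaged
# over the fixed-effect offsets xb
marginal_prevalence <- function(mu, xb, vrand, link) {
  if (link == "probit") {
    mean(stats::pnorm((mu + xb) / sqrt(1 + vrand)))
  } else {
    gh <- gauss_hermite(30)
    z <- sqrt(2 * vrand) * gh$nodes
    w <- gh$weights / sqrt(pi)
    mean(vapply(
      xb,
      function(x) sum(w * stats::plogis(mu + x + z)),
      numeric(1)
    ))
  }
}

calibrate_intercept <- function(xb, vrand, target, link) {
  stats::uniroot(
    function(mu) marginal_prevalence(mu, xb, vrand, link) - target,
    interval = c(-20, 10), tol = 1e-8
  )$root
}

# bivariate Mendelian sampling with matrix-valued G (2x2)
mendelian_sample_biv <- function(ped, G) {
  ind <- ped$ind
  n <- nrow(ind)
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("genetic covariance matrix is not positive semi-definite")
  Gh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  f <- inbreeding(ped)
  a <- matrix(0, n, 2)
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  for (i in seq_len(n)) {
    s <- ind$sire_idx[i]; d <- ind$dam_idx[i]
    if (s == 0L && d == 0L) {
      a[i, ] <- Gh %*% Z[i, ]
    } else if (s > 0L && d > 0L) {
      sc <- sqrt((1 - (f[s] + f[d]) / 2) / 2)
      a[i, ] <- (a[s, ] + a[d, ]) / 2 + sc * (Gh %*% Z[i, ])
    } else {
      p <- max(s, d)
      sc <- sqrt((3 - f[p]) / 4)
      a[i, ] <- a[p, ] / 2 + sc * (Gh %*% Z[i, ])
    }
  }
  a
}

#' Simulate a stratified dataset with two correlated liabilities
#'
#' Draws two breeding values per individual by bivariate Mendelian sampling
#' with genetic covariance `G` (off-diagonal `rg_true * sqrt(G11 G22)`) and a
#' shared family-environment pair with covariance `C`, then assigns strata:
#'
#' * `sex`: the individual's sex selects which liability is expressed; the
#'   status for the other sex's column is structurally missing.
#' * `onset` / `course`: an individual is affected when either liability
#'   exceeds its threshold; when both do, the larger standardised liability
#'   decides the category (the tie frequency is reported in attribute
#'   `"tie_fraction"`).
#'
#' @inheritParams simulate_liabilities
#' @return list with per-individual `a` (n x 2), `c_env` (n x 2),
#'   `liability` (n x 2), `status` (n x 2 of 0/1, `NA` for the unexpressed sex
#'   column), and `category` (0 = absent, 1, 2).
#' @export
simulate_strata <- function(ped, cfg, xb = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(cfg$strata_model)) stop("cfg$strata_model must be set")
  v <- true_variances(cfg)
  va1 <- v$va
  va2 <- v$va * cfg$va_ratio
  vc1 <- v$vc
  vc2 <- v$vc # family environment variance shared scale across strata
  G <- matrix(c(va1, cfg$rg_true * sqrt(va1 * va2), cfg$rg_true * sqrt(va1 * va2), va2), 2)
  C <- matrix(c(vc1, cfg$rc_true * sqrt(vc1 * vc2), cfg$rc_true * sqrt(vc1 * vc2), vc2), 2)
  n <- n_individuals(ped)
  if (is.null(xb)) xb <- numeric(n)
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, 900002L) else seed)

  a <- mendelian_sample_biv(ped, G)
  fams <- ped$ind$family_group
  ufam <- unique(fams)
  cf <- if (all(C == 0)) {
    matrix(0, length(ufam), 2)
  } else {
    ev <- eigen(C, symmetric = TRUE)
    if (min(ev$values) < -1e-8) stop("family-environment covariance matrix is not positive semi-definite")
    Ch <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    t(Ch %*% matrix(stats::rnorm(2 * length(ufam)), 2))
  }
  c_env <- cf[match(fams, ufam), , drop = FALSE]
  e <- if (cfg$link == "logit") {
    matrix(stats::rlogis(2 * n), n, 2)
  } else {
    matrix(stats::rnorm(2 * n), n, 2)
  }

  # per-trait intercepts calibrated to per-stratum marginal prevalence
  tot <- c(va1 + vc1, va2 + vc2)
  mu <- vapply(
    1:2,
    function(t) calibrate_intercept(xb, tot[t], cfg$stratum_prevalence[t], cfg$link),
    numeric(1)
  )
  liab <- sweep(a + c_env + e, 2, mu, "+") + xb

  sd_tot <- sqrt(tot + link_residual_variance(cfg$link))
  std <- sweep(liab, 2, sd_tot, "/")
  over <- liab > 0
  category <- integer(n)
  category[over[, 1] & !over[, 2]] <- 1L
  category[over[, 2] & !over[, 1]] <- 2L
  both <- over[, 1] & over[, 2]
  category[both] <- ifelse(std[both, 1] >= std[both, 2], 1L, 2L)

  status <- matrix(NA_integer_, n, 2)
  if (cfg$strata_model == "sex") {
    female <- ped$ind$sex == "female"
    status[female, 1] <- as.integer(liab[female, 1] > 0)
    status[!female, 2] <- as.integer(liab[!female, 2] > 0)
    category <- ifelse(female, ifelse(status[, 1] == 1, 1L, 0L),
      ifelse(status[, 2] == 1, 2L, 0L)
    )
  } else {
    status[, 1] <- as.integer(category == 1L)
    status[, 2] <- as.integer(category == 2L)
  }
  structure(
    list(
      a = a, c_env = c_env, liability = liab, status = status,
      category = category, intercepts = mu, G = G, C = C
    ),
    tie_fraction = mean(both)
  )
}

# --- covariates -------------------------------------------------------------

covariate_levels <- function() {
  list(
    income = c(
      "10k-30k", "less_10k", "30k-50k", "50k-70k", "more_70k",
      "no_response"
    ),
    education = c(
      "university", "post_secondary", "upper_secondary",
      "lower_secondary", "primary", "unknown"
    ),
    occupation = c(
      "employed", "student", "homemaker", "retired",
      "unemployed_seeking", "unemployed_disabled", "no_response"
    ),
    simd_quintile = c("q3", "q1_most_deprived", "q2", "q4", "q5_least_deprived", "unavailable"),
    smoking = c("non_smoker", "ex_smoker", "current_smoker", "no_response"),
    drinking = c("non_drinker", "ex_drinker", "current_drinker", "no_response"),
    cohabiting = c("yes", "no", "no_response")
  )
}

covariate_probs <- function() {
  list(
    income = c(0.34, 0.12, 0.25, 0.12, 0.07, 0.10),
    education = c(0.30, 0.25, 0.18, 0.15, 0.08, 0.04),
    occupation = c(0.62, 0.04, 0.06, 0.14, 0.03, 0.04, 0.07),
    simd_quintile = c(0.20, 0.12, 0.16, 0.24, 0.26, 0.02),
    smoking = c(0.55, 0.26, 0.17, 0.02),
    drinking = c(0.10, 0.03, 0.85, 0.02),
    cohabiting = c(0.65, 0.33, 0.02)
  )
}

#' Simulate sociodemographic covariates for a pedigree
#'
#' Categorical factors mirror a population family study: income band,
#' educational attainment, occupation, deprivation quintile (SIMD-style),
#' smoking and drinking status, and cohabitation, each with an explicit
#' no-response/unknown level; reference levels are the modal categories.
#' Age at interview comes from the pedigree generator.
#'
#' @param ped a [pedigree] from [simulate_pedigree()].
#' @param cfg a [simulation_config()].
#' @param seed stage seed (defaults to a substream of `cfg$seed`).
#' @return data.frame keyed by `id` with `sex`, `age_at_interview` and the
#'   categorical factors (first level = reference).
#' @export
simulate_covariates <- function(ped, cfg, seed = NULL) {
  set.seed(if (is.null(seed)) substream_seed(cfg$seed, 900003L) else seed)
  ind <- ped$ind
  n <- nrow(ind)
  ages <- attr(ped, "ages")
  age <- if (is.null(ages)) rage(n, 49, 14) else ages$age_at_interview
  out <- data.frame(id = ind$id, sex = ind$sex, age_at_interview = age)
  lv <- covariate_levels()
  pr <- covariate_probs()
  for (v in names(lv)) {
    out[[v]] <- factor(sample(lv[[v]], n, replace = TRUE, prob = pr[[v]]), levels = lv[[v]])
  }
  out
}

# fixed-effect liability contribution from named covariate effects
covariate_xb <- function(covariates, effects) {
  n <- nrow(covariates)
  xb <- numeric(n)
  if (!length(effects)) return(xb)
  for (nm in names(effects)) {
    if (nm == "age") {
      xb <- xb + effects[[nm]] * (covariates$age_at_interview - mean(covariates$age_at_interview))
    } else {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2 || is.null(covariates[[parts[1]]])) {
        stop("unknown covariate effect: ", nm)
      }
      xb <- xb + effects[[nm]] * (as.character(covariates[[parts[1]]]) == parts[2])
    }
  }
  xb
}

# --- full dataset -----------------------------------------------------------

#' Simulate a complete family-study dataset
#'
#' Runs the pedigree, covariate and liability generators and assembles the
#' phenotype table: binary status (with a bipolar-analogue excluded fraction
#' coded missing-with-flag), age at interview, age of onset for affected
#' individuals, episode count, current-episode flag, and — under a strata
#' model — the stratum category.
#'
#' @param cfg a [simulation_config()].
#' @return a `simulated_dataset`: list with `pedigree`, `phenotypes`,
#'   `covariates`, `truth` (the config plus implied variances), and for
#'   strata models the latent `strata` draw.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  ped <- simulate_pedigree(cfg)
  covars <- simulate_covariates(ped, cfg)
  xb <- covariate_xb(covars, cfg$covariate_effects)

  strata <- NULL
  if (is.null(cfg$strata_model)) {
    liab <- simulate_liabilities(ped, cfg, xb)
    status <- liab$status
    category <- NULL
  } else {
    strata <- simulate_strata(ped, cfg, xb)
    category <- strata$category
    status <- as.integer(category > 0L)
  }

  set.seed(substream_seed(cfg$seed, 900004L))
  n <- n_individuals(ped)
  excluded <- stats::runif(n) < cfg$bipolar_fraction
  status[excluded] <- NA_integer_

  age <- covars$age_at_interview
  onset <- rep(NA_real_, n)
  episodes <- rep(NA_integer_, n)
  current <- integer(n)
  aff <- which(!is.na(status) & status == 1L)
  for (i in aff) {
    onset[i] <- draw_onset(age[i], cfg, if (is.null(category)) 0L else category[i])
    episodes[i] <- if (!is.null(category) && !is.null(cfg$strata_model) &&
      cfg$strata_model == "course") {
      if (category[i] == 2L) 2L + stats::rpois(1, 1.5) else 1L
    } else {
      1L + stats::rpois(1, 0.7)
    }
    current[i] <- as.integer(stats::runif(1) < cfg$current_fraction)
  }

  phen <- data.frame(
    id = ped$ind$id,
    status = status,
    excluded = excluded,
    age_at_interview = age,
    age_of_onset = onset,
    episode_count = episodes,
    current_episode = current
  )
  if (!is.null(cfg$strata_model)) {
    lab <- switch(cfg$strata_model,
      sex = c("absent", "female_mdd", "male_mdd"),
      onset = c("absent", "earlier", "later"),
      course = c("absent", "single", "recurrent")
    )
    phen$stratum <- factor(lab[ifelse(is.na(status), NA, category + 1L)], levels = lab)
  }

  v <- true_variances(cfg)
  structure(
    list(
      pedigree = ped, phenotypes = phen, covariates = covars,
      truth = c(unclass(cfg), v), strata = strata
    ),
    class = "simulated_dataset"
  )
}

# onset age consistent with interview age and (for onset strata) category
draw_onset <- function(age, cfg, category) {
  cutoff <- cfg$onset_cutoff_age
  lo <- 11
  hi <- age
  if (!is.null(cfg$strata_model) && cfg$strata_model == "onset") {
    if (category == 1L) hi <- min(age, cutoff) else lo <- cutoff + 1e-9
  }
  if (hi <= lo) return(min(age, lo))
  # truncated normal around the population onset profile
  m <- 31.7; s <- 12.3
  plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
  x <- stats::qnorm(stats::runif(1, plo, phi), m, s)
  x <- x + cfg$onset_recall_shift * max(0, (age - 40) / 40)
  round(min(max(x, lo), hi))
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated family-study dataset\n")
  print(x$pedigree)
  st <- x$phenotypes$status
  cat(
    "  phenotyped:", sum(!is.na(st)), " affected:", sum(st == 1, na.rm = TRUE),
    sprintf("(prevalence %.3f)\n", mean(st, na.rm = TRUE))
  )
  if (!is.null(x$truth$strata_model)) cat("  strata model:", x$truth$strata_model, "\n")
  invisible(x)
}

#' Write a simulated dataset to a directory
#'
#' Emits `pedigree.txt` (the [read_pedigree()] format), `phenotypes.csv`,
#' `covariates.csv` and `truth.json`; the files round-trip losslessly through
#' [read_dataset()].
#'
#' @param ds a `simulated_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(ds$pedigree, file.path(dir, "pedigree.txt"))
  utils::write.csv(ds$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  utils::write.csv(ds$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  truth <- ds$truth
  truth$template_probs <- as.list(truth$template_probs)
  truth$covariate_effects <- as.list(truth$covariate_effects)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `pedigree.txt`, `phenotypes.csv`,
#'   `covariates.csv` and `truth.json`.
#' @return list with `pedigree`, `phenotypes`, `covariates`, `truth`.
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.txt"))
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"))
  covars <- utils::read.csv(file.path(dir, "covariates.csv"), stringsAsFactors = FALSE)
  lv <- covariate_levels()
  for (v in names(lv)) {
    if (!is.null(covars[[v]])) covars[[v]] <- factor(covars[[v]], levels = lv[[v]])
  }
  if ("stratum" %in% names(phen)) phen$stratum <- factor(phen$stratum)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  list(pedigree = ped, phenotypes = phen, covariates = covars, truth = truth)
}
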