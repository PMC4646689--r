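#' Specify a liability-threshold pedigree model
#'
#' @param response `"binary"` (affected/unaffected), `"bivariate_sex"`
#'   (status expressed in the column of the individual's sex, missing in the
#'   other), `"categorical_onset"` or `"categorical_course"` (three-level
#'   responses with an unaffected baseline and two latent affected
#'   propensities).
#' @param fixed_effects covariate names to adjust for; `"age"` and `"sex"`
#'   are always available, the sociodemographic factors (income, education,
#'   occupation, simd_quintile, smoking, drinking, cohabiting) optionally.
#'   For `bivariate_sex` the sex covariate is excluded automatically.
#' @param family_effect include the extended family-group random effect
#'   (shared environment) in addition to the additive genetic effect.
#' @param link `"probit"` (Albert-Chib truncated-normal augmentation,
#'   residual fixed at 1) or `"logit"` (Polya-Gamma augmentation; binary
#'   response only).
#' @param baseline_category name of the unaffected baseline for categorical
#'   responses.
#' @param onset_cutoff years separating earlier from later onset.
#' @return a `liability_model_spec` list.
#' @export
liability_model_spec <- function(response = c("binary", "bivariate_sex",
                                              "categorical_onset", "categorical_course"),
                                 fixed_effects = c("age", "sex"),
                                 family_effect = TRUE,
                                 link = c("probit", "logit"),
                                 baseline_category = "absent",
                                 onset_cutoff = 40) {
  response <- match.arg(response)
  link <- match.arg(link)
  if (link == "logit" && response != "binary") {
    stop("logit link is available for the binary response only; the ",
         "bivariate and categorical models use the probit formulation")
  }
  if (response == "bivariate_sex") fixed_effects <- setdiff(fixed_effects, "sex")
  structure(
    list(
      response = response, fixed_effects = fixed_effects,
      family_effect = family_effect, link = link,
      baseline_category = baseline_category, onset_cutoff = onset_cutoff
    ),
    class = "liability_model_spec"
  )
}

#' MCMC configuration for the Gibbs samplers
#'
#' Default chain lengths (4 chains of 13,000 iterations, 3,000 burn-in,
#' thinning 10) target desk-scale runtimes; all are overridable. Variance
#' priors: `"px"` (default) is the parameter-expanded formulation — a working
#' scale `alpha ~ N(0, 1)` times an inverse-gamma(1/2, 1/2) working variance,
#' equivalent to a half-Cauchy(scale 1) prior on the genetic standard
#' deviation in the univariate case; `"ig"` is a plain
#' inverse-gamma(`ig_shape`, `ig_rate`) prior (inverse-Wishart
#' (`nu0`, `s0 * I`) for the 2x2 covariance models).
#'
#' @param n_chains number of independently seeded chains (>= 2 for
#'   convergence checks).
#' @param n_iter,n_burnin,thin chain length, burn-in, thinning interval.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @param prior `"px"` or `"ig"`.
#' @param ig_shape,ig_rate inverse-gamma hyperparameters for `prior = "ig"`.
#' @param nu0,s0 inverse-Wishart degrees of freedom and scale multiplier for
#'   the 2x2 covariance models.
#' @param beta_prior_var prior variance of fixed-effect coefficients.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 13000, n_burnin = 3000,
                        thin = 10, seed = 1L, prior = c("px", "ig"),
                        ig_shape = 0.001, ig_rate = 0.001,
                        nu0 = 3, s0 = 1, beta_prior_var = 100) {
  prior <- match.arg(prior)
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin")
  if (thin < 1) stop("thin must be >= 1")
  structure(
    list(
      n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
      n_burnin = as.integer(n_burnin), thin = as.integer(thin),
      seed = as.integer(seed), prior = prior,
      ig_shape = ig_shape, ig_rate = ig_rate, nu0 = nu0, s0 = s0,
      beta_prior_var = beta_prior_var
    ),
    class = "mcmc_config"
  )
}

# --- shared plumbing --------------------------------------------------------

# full-pattern CSC pieces of the sparse A-inverse
ainv_csc <- function(ped) {
  M <- methods::as(methods::as(a_inverse(ped), "generalMatrix"), "CsparseMatrix")
  list(p = M@p, i = M@i, x = M@x)
}

# design matrix over the given ids; errors on rank deficiency naming columns
build_design <- function(ids, covariates, fixed_effects) {
  if (!length(fixed_effects)) {
    X <- matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
    attr(X, "keep") <- rep(TRUE, length(ids))
    return(X)
  }
  cv <- covariates[match(ids, covariates$id), , drop = FALSE]
  df <- data.frame(row.names = seq_along(ids))
  for (v in fixed_effects) {
    if (v == "age") {
      df$age <- cv$age_at_interview
    } else if (v == "sex") {
      df$sex <- factor(cv$sex, levels = c("male", "female", "unknown"))
      df$sex <- droplevels(df$sex)
    } else {
      if (is.null(cv[[v]])) stop("covariate not found: ", v)
      df[[v]] <- cv[[v]]
    }
  }
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message(sum(!keep), " individual(s) dropped for missing covariates")
  }
  X <- stats::model.matrix(~., df[keep, , drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  attr(X, "keep") <- keep
  X
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 48271 + chain * 104729) %% 2147483629 + 1)
}

pooled <- function(chains) do.call(rbind, chains)

# posterior summary table: mean, 95% HPD, pMCMC (coefficients), R-hat
summarise_fit <- function(chains, coef_names) {
  draws <- pooled(chains)
  rhat <- if (length(chains) >= 2) check_convergence(chains)$rhat else rep(NA_real_, ncol(draws))
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    hpd_lower = NA_real_, hpd_upper = NA_real_,
    pmcmc = NA_real_,
    rhat = rhat,
    row.names = NULL
  )
  for (k in seq_len(ncol(draws))) {
    h <- hpd_interval(draws[, k])
    out$hpd_lower[k] <- h[1]
    out$hpd_upper[k] <- h[2]
    if (colnames(draws)[k] %in% coef_names) out$pmcmc[k] <- pmcmc(draws[, k])
  }
  out
}

new_liability_fit <- function(chains, spec, mcmc, coef_names, extra = list()) {
  fit <- c(
    list(
      draws = pooled(chains), chains = chains, spec = spec, mcmc = mcmc,
      link = spec$link, coef_names = coef_names,
      summaries = summarise_fit(chains, coef_names)
    ),
    extra
  )
  class(fit) <- "liability_fit"
  fit
}

#' @export
print.liability_fit <- function(x, ...) {
  cat(
    "liability-threshold pedigree model (", x$spec$response, ", ",
    x$link, " link)\n",
    sep = ""
  )
  cat(
    "  ", length(x$chains), "chains,", nrow(x$draws), "pooled draws,",
    x$n_obs, "phenotyped individuals\n"
  )
  key <- !x$summaries$parameter %in% x$coef_names
  print(x$summaries[key, c("parameter", "mean", "hpd_lower", "hpd_upper", "rhat")],
    row.names = FALSE, digits = 3
  )
  invisible(x)
}

# --- univariate fit ---------------------------------------------------------

#' Fit the univariate binary liability model
#'
#' Gibbs sampling of the animal model for a 0/1 trait: fixed effects, an
#' additive-genetic random effect conditioned on the pedigree A matrix
#' (through its sparse inverse), and optionally a family-group
#' (shared-environment) random effect. Individuals with missing status
#' (including the excluded bipolar-analogue cases) contribute no likelihood
#' but remain in the pedigree, informing relatives' breeding values.
#' Liability-scale heritability is derived per draw via [liability_h2()];
#' chains are independently seeded and pooled for summaries.
#'
#' @param spec a [liability_model_spec()] with `response = "binary"`.
#' @param ped a [pedigree] object covering every phenotyped id.
#' @param phenotypes data.frame with `id` and `status` (0/1/NA).
#' @param covariates data.frame keyed by `id` with the fixed-effect columns.
#' @param mcmc an [mcmc_config()].
#' @return a `liability_fit` with pooled `draws` (fixed effects, `V_A`,
#'   `V_C`, `h2`, `c2`), per-chain draws, and a `summaries` table.
#' @export
fit_univariate <- function(spec, ped, phenotypes, covariates = NULL,
                           mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "liability_model_spec"), spec$response == "binary")
  dat <- align_phenotypes(ped, phenotypes)
  X <- build_design(dat$ids, covariates, spec$fixed_effects)
  keep <- attr(X, "keep")
  ids <- dat$ids[keep]
  y <- dat$status[keep]
  pid <- match(ids, ped$ind$id) - 1L
  fams <- unique(ped$ind$family_group)
  fid <- match(ped$ind$family_group[pid + 1L], fams) - 1L
  csc <- ainv_csc(ped)

  px <- mcmc$prior == "px"
  igs <- if (px) 0.5 else mcmc$ig_shape
  igr <- if (px) 0.5 else mcmc$ig_rate
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(chain_seed(mcmc$seed, ch))
    dr <- gibbs_liability_uni(
      y, X, pid, fid, n_individuals(ped), length(fams),
      csc$p, csc$i, csc$x,
      mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
      spec$family_effect, spec$link == "logit", px,
      igs, igr, mcmc$beta_prior_var
    )
    colnames(dr) <- c(colnames(X), "V_A", "V_C")
    vr <- if (spec$link == "probit") 1 else 0
    dr <- cbind(dr,
      h2 = liability_h2(dr[, "V_A"], dr[, "V_C"], vr, spec$link),
      c2 = liability_h2(dr[, "V_C"], dr[, "V_A"], vr, spec$link)
    )
    chains[[ch]] <- dr
  }
  fit <- new_liability_fit(chains, spec, mcmc, colnames(X),
    extra = list(n_obs = length(y))
  )
  fit
}

# align phenotypes to the pedigree; keep non-missing statuses
align_phenotypes <- function(ped, phenotypes) {
  missing_ids <- setdiff(phenotypes$id, ped$ind$id)
  if (length(missing_ids)) {
    stop(
      "phenotyped id(s) absent from the pedigree: ",
      paste(utils::head(missing_ids, 5), collapse = ", ")
    )
  }
  ok <- !is.na(phenotypes$status)
  list(ids = as.character(phenotypes$id[ok]), status = as.integer(phenotypes$status[ok]))
}

# --- bivariate by sex -------------------------------------------------------

#' Fit the bivariate-by-sex liability model
#'
#' Treats female and male disease status as two traits: each individual has
#' a 0/1 record in the column for their sex and a structurally missing
#' observation in the other. Samples 2x2 additive-genetic (`G`) and
#' family-environment (`C`) covariance matrices; the cross-sex genetic
#' correlation `r_G = G12 / sqrt(G11 G22)` is computed per draw (likewise
#' `r_C`), and sex-specific heritabilities come from the diagonals. The
#' cross-sex covariance is identified only through opposite-sex relative
#' pairs, whose informative count is reported (a warning is issued when it is
#' zero, in which case `r_G` is prior-dominated).
#'
#' @inheritParams fit_univariate
#' @param spec a [liability_model_spec()] with `response = "bivariate_sex"`.
#' @return a `liability_fit` with trait-wise draws (`V_A_female`, `V_A_male`,
#'   covariance `V_A_cross`, the `V_C_*` analogues, `h2_female`, `h2_male`,
#'   `c2_female`, `c2_male`, `r_G`, `r_C`).
#' @export
fit_bivariate_sex <- function(spec, ped, phenotypes, covariates = NULL,
                              mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "liability_model_spec"), spec$response == "bivariate_sex")
  dat <- align_phenotypes(ped, phenotypes)
  sex <- ped$ind$sex[match(dat$ids, ped$ind$id)]
  known <- sex %in% c("female", "male")
  if (!all(known)) message(sum(!known), " unknown-sex individual(s) excluded")
  ids <- dat$ids[known]
  y <- dat$status[known]
  trait <- ifelse(sex[known] == "female", 0L, 1L)

  X <- build_design(ids, covariates, spec$fixed_effects)
  keep <- attr(X, "keep")
  ids <- ids[keep]; y <- y[keep]; trait <- trait[keep]

  n_pairs <- count_opposite_sex_pairs(ped, ids, y)
  if (n_pairs == 0) {
    warning("no informative opposite-sex relative pairs: r_G is prior-dominated")
  }
  fit <- fit_two_trait(
    spec, ped, ids, y, trait, X, mcmc,
    mode = 0L, trait_names = c("female", "male")
  )
  fit$n_informative_cross_pairs <- n_pairs
  fit
}

# informative opposite-sex pairs among parent-child and full-sib dyads
count_opposite_sex_pairs <- function(ped, ids, y) {
  status <- rep(NA_integer_, n_individuals(ped))
  status[match(ids, ped$ind$id)] <- y
  sexv <- ped$ind$sex
  n <- 0L
  for (cl in c("parent_child", "full_siblings")) {
    d <- extract_dyads(ped, cl)
    i <- match(d$id_i, ped$ind$id)
    j <- match(d$id_j, ped$ind$id)
    ok <- !is.na(status[i]) & !is.na(status[j]) &
      sexv[i] != sexv[j] & (status[i] == 1L | status[j] == 1L)
    n <- n + sum(ok)
  }
  n
}

# shared two-trait engine (sex and categorical models)
fit_two_trait <- function(spec, ped, ids, y, trait, X, mcmc, mode, trait_names) {
  pid <- match(ids, ped$ind$id) - 1L
  fams <- unique(ped$ind$family_group)
  fid <- match(ped$ind$family_group[pid + 1L], fams) - 1L
  csc <- ainv_csc(ped)
  px <- mcmc$prior == "px"

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(chain_seed(mcmc$seed, ch))
    dr <- gibbs_liability_biv(
      y, trait, X, pid, fid, n_individuals(ped), length(fams),
      csc$p, csc$i, csc$x, mode,
      mcmc$n_iter, mcmc$n_burnin, mcmc$thin,
      spec$family_effect, px, mcmc$nu0, mcmc$s0, mcmc$beta_prior_var
    )
    cn <- c(
      paste0(rep(colnames(X), 2), "_", rep(trait_names, each = ncol(X))),
      "V_A_1", "V_A_cross", "V_A_2", "V_C_1", "V_C_cross", "V_C_2"
    )
    colnames(dr) <- cn
    g11 <- dr[, "V_A_1"]; g22 <- dr[, "V_A_2"]; g12 <- dr[, "V_A_cross"]
    c11 <- dr[, "V_C_1"]; c22 <- dr[, "V_C_2"]; c12 <- dr[, "V_C_cross"]
    extra <- cbind(
      liability_h2(g11, c11, 1, "probit"),
      liability_h2(g22, c22, 1, "probit"),
      liability_h2(c11, g11, 1, "probit"),
      liability_h2(c22, g22, 1, "probit"),
      g12 / sqrt(g11 * g22),
      ifelse(c11 * c22 > 0, c12 / sqrt(c11 * c22), 0)
    )
    colnames(extra) <- c(
      paste0("h2_", trait_names), paste0("c2_", trait_names), "r_G", "r_C"
    )
    chains[[ch]] <- cbind(dr, extra)
  }
  new_liability_fit(chains, spec, mcmc,
    coef_names = paste0(rep(colnames(X), 2), "_", rep(trait_names, each = ncol(X))),
    extra = list(n_obs = length(y), trait_names = trait_names)
  )
}

# --- categorical (onset / course) ------------------------------------------

#' Fit the three-category latent-liability model
#'
#' For age-of-onset (absent / earlier / later) or illness-course (absent /
#' single / recurrent) responses. Two latent traits each express a propensity
#' for one affected category against the unaffected baseline (multinomial-
#' probit utilities with identity residual covariance, baseline utility 0);
#' each random term yields a 2x2 covariance matrix. The marginal heritability
#' of category `k` — its heritability against being unaffected, excluding the
#' other affected category — is `G_kk / (G_kk + C_kk + 1)`.
#'
#' @inheritParams fit_univariate
#' @param spec a [liability_model_spec()] with `response =
#'   "categorical_onset"` or `"categorical_course"`.
#' @param phenotypes data.frame with `id` and a 3-level factor column
#'   `response` whose first level is the baseline (see
#'   [apply_onset_classification()]), `NA` = excluded from the likelihood.
#' @return a `liability_fit` with category-wise marginal heritabilities and
#'   the genetic/environment correlations between the affected categories.
#' @export
fit_categorical <- function(spec, ped, phenotypes, covariates = NULL,
                            mcmc = mcmc_config()) {
  stopifnot(
    inherits(spec, "liability_model_spec"),
    spec$response %in% c("categorical_onset", "categorical_course")
  )
  if (is.null(phenotypes$response)) {
    stop("phenotypes must carry a 3-level factor column `response`")
  }
  resp <- phenotypes$response
  if (!is.factor(resp) || nlevels(resp) != 3) {
    stop("`response` must be a factor with exactly 3 levels (baseline first)")
  }
  if (levels(resp)[1] != spec$baseline_category) {
    stop(
      "first factor level must be the baseline category '",
      spec$baseline_category, "'"
    )
  }
  counts <- table(resp)
  if (any(counts == 0)) {
    stop("empty response category: ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  ok <- !is.na(resp)
  ids0 <- as.character(phenotypes$id[ok])
  missing_ids <- setdiff(ids0, ped$ind$id)
  if (length(missing_ids)) {
    stop(
      "phenotyped id(s) absent from the pedigree: ",
      paste(utils::head(missing_ids, 5), collapse = ", ")
    )
  }
  y <- as.integer(resp[ok]) - 1L # 0 = baseline, 1, 2
  X <- build_design(ids0, covariates, spec$fixed_effects)
  keep <- attr(X, "keep")
  ids0 <- ids0[keep]; y <- y[keep]
  fit_two_trait(
    spec, ped, ids0, y, trait = integer(length(y)), X, mcmc,
    mode = 1L, trait_names = levels(resp)[2:3]
  )
}

#' Classify affected status by age of onset
#'
#' Produces the three-level response absent / earlier / later with onset at
#' or below the cutoff counted as earlier. Individuals interviewed at or
#' below the cutoff age cannot yet express a later onset, so (to avoid
#' separation) they are dropped from the classified response (`NA`), with the
#' dropped count reported in attribute `"n_dropped"` and a message.
#'
#' @param phenotypes data.frame with `status`, `age_at_interview`,
#'   `age_of_onset`.
#' @param cutoff_age onset cutoff in years (default 40).
#' @return `phenotypes` with an added factor column `response`
#'   (absent/earlier/later).
#' @export
apply_onset_classification <- function(phenotypes, cutoff_age = 40) {
  bad <- !is.na(phenotypes$age_of_onset) &
    phenotypes$age_of_onset > phenotypes$age_at_interview
  if (any(bad)) {
    stop(
      "age of onset exceeds age at interview for id(s): ",
      paste(utils::head(phenotypes$id[bad], 5), collapse = ", ")
    )
  }
  cls <- ifelse(
    is.na(phenotypes$status), NA_character_,
    ifelse(phenotypes$status == 0, "absent",
      ifelse(phenotypes$age_of_onset <= cutoff_age, "earlier", "later")
    )
  )
  drop <- phenotypes$age_at_interview <= cutoff_age
  n_dropped <- sum(drop & !is.na(cls))
  cls[drop] <- NA_character_
  message(n_dropped, " individual(s) interviewed at or below the cutoff dropped")
  phenotypes$response <- factor(cls, levels = c("absent", "earlier", "later"))
  attr(phenotypes, "n_dropped") <- n_dropped
  phenotypes
}

#' Classify affected status by illness course
#'
#' Builds the absent / single / recurrent response from episode counts
#' (recurrent = more than one episode).
#'
#' @param phenotypes data.frame with `status` and `episode_count`.
#' @return `phenotypes` with an added factor column `response`.
#' @export
apply_course_classification <- function(phenotypes) {
  cls <- ifelse(
    is.na(phenotypes$status), NA_character_,
    ifelse(phenotypes$status == 0, "absent",
      ifelse(phenotypes$episode_count >= 2, "recurrent", "single")
    )
  )
  phenotypes$response <- factor(cls, levels = c("absent", "single", "recurrent"))
  phenotypes
}
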