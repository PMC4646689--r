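#' Post-stratification weights for population inference
#'
#' Builds one weight per participant as the product of three factors,
#' rescaled to sum to 1:
#'
#' * age/sex: population frequency of the participant's age-band x sex cell
#'   divided by the sample count in that cell;
#' * deprivation quintile: population share (uniform by construction for a
#'   quintile index) divided by the sample share — individuals with an
#'   unavailable quintile keep a neutral factor of 1;
#' * family: the inverse of the participant's family-group size, so each
#'   family contributes equally.
#'
#' @param sample_df data.frame with `id`, `age_at_interview`, `sex`,
#'   `simd_quintile` (a factor; level `"unavailable"` allowed) and
#'   `family_group`.
#' @param pop_age_sex data.frame `age_band`, `sex`, `count` of population
#'   frequencies; bands are labelled by their lower bound from `age_breaks`.
#' @param pop_simd optional data.frame `simd_quintile`, `share` (defaults to
#'   equal shares over the quintile levels present in the sample).
#' @param age_breaks cut points defining age bands (default 5-year bins from
#'   18 to 90+).
#' @return a `weight_scheme`: data.frame `id`, `w_age_sex`, `w_simd`,
#'   `w_family`, `weight` (normalised; non-negative, summing to 1).
#' @export
build_weights <- function(sample_df, pop_age_sex, pop_simd = NULL,
                          age_breaks = c(seq(18, 90, by = 5), Inf)) {
  needed <- c("id", "age_at_interview", "sex", "family_group")
  if (!all(needed %in% names(sample_df))) {
    stop("sample_df must have columns: ", paste(needed, collapse = ", "))
  }
  band <- cut(sample_df$age_at_interview, age_breaks,
    right = FALSE, labels = utils::head(age_breaks, -1), include.lowest = TRUE
  )
  cell <- paste(band, sample_df$sex)
  pop_cell <- paste(pop_age_sex$age_band, pop_age_sex$sex)
  pop_n <- pop_age_sex$count[match(cell, pop_cell)]
  if (anyNA(pop_n)) {
    stop(
      "population table missing sampled age/sex cell(s): ",
      paste(utils::head(unique(cell[is.na(pop_n)]), 5), collapse = "; ")
    )
  }
  sample_n <- as.numeric(table(cell)[cell])
  w_age_sex <- pop_n / sample_n

  if (is.null(sample_df$simd_quintile)) {
    w_simd <- rep(1, nrow(sample_df))
  } else {
    sq <- as.character(sample_df$simd_quintile)
    quintiles <- setdiff(unique(sq), c("unavailable", NA))
    if (is.null(pop_simd)) {
      pop_simd <- data.frame(simd_quintile = quintiles, share = 1 / length(quintiles))
    }
    share <- pop_simd$share[match(sq, pop_simd$simd_quintile)]
    samp_share <- as.numeric(table(sq)[sq]) / sum(sq %in% quintiles)
    w_simd <- ifelse(is.na(share), 1, share / samp_share)
    missing_cells <- setdiff(quintiles, pop_simd$simd_quintile)
    if (length(missing_cells)) {
      stop(
        "population SIMD table missing sampled quintile(s): ",
        paste(missing_cells, collapse = ", ")
      )
    }
  }

  fam_size <- as.numeric(table(sample_df$family_group)[sample_df$family_group])
  w_family <- 1 / fam_size

  w <- w_age_sex * w_simd * w_family
  out <- data.frame(
    id = sample_df$id,
    w_age_sex = w_age_sex, w_simd = w_simd, w_family = w_family,
    weight = w / sum(w)
  )
  class(out) <- c("weight_scheme", "data.frame")
  out
}

#' Weighted prevalence of a binary trait
#'
#' Two estimators:
#'
#' * `method = "design"`: the weighted mean of observed 0/1 statuses, with a
#'   weighted-binomial (effective-sample-size) normal interval;
#' * `method = "model"`: per posterior draw of a logit/probit
#'   [fit_univariate()] fit, the fitted coefficients are multiplied by the
#'   weighted population share of their category and summed to a population
#'   linear predictor, which is mapped to the probability scale integrating
#'   the genetic + family random effects by quadrature
#'   (`link_scale = TRUE` skips the integration and applies the inverse link
#'   to the weighted coefficient sum alone); the interval is the HPD of the
#'   per-draw prevalences.
#'
#' @param x numeric 0/1 status vector (design mode) or a `liability_fit`
#'   (model mode).
#' @param weights a [build_weights()] scheme aligned to `x` (design mode:
#'   same order; model mode: same ids as the fit's covariates).
#' @param covariates covariate table used in the fit (model mode).
#' @param method `"design"` or `"model"`.
#' @param link_scale literal-coefficient variant of the model mode.
#' @return list with `prevalence`, `ci` (95%), `method`.
#' @export
weighted_prevalence <- function(x, weights, covariates = NULL,
                                method = c("design", "model"),
                                link_scale = FALSE) {
  method <- match.arg(method)
  w <- weights$weight
  if (abs(sum(w) - 1) > 1e-8) stop("weights must be normalised to sum to 1")
  if (method == "design") {
    y <- x
    ok <- !is.na(y)
    w <- w[ok] / sum(w[ok])
    p <- sum(w * y[ok])
    n_eff <- 1 / sum(w^2)
    se <- sqrt(max(p * (1 - p), 0) / n_eff)
    return(list(
      prevalence = p, ci = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
      method = "design", n_eff = n_eff
    ))
  }
  fit <- x
  stopifnot(inherits(fit, "liability_fit"))
  X <- build_design(weights$id, covariates, fit$spec$fixed_effects)
  keep <- attr(X, "keep")
  wk <- w[keep] / sum(w[keep])
  xbar <- as.numeric(crossprod(X, wk)) # weighted category shares, incl. intercept
  beta_draws <- fit$draws[, fit$coef_names, drop = FALSE]
  eta <- as.numeric(beta_draws %*% xbar)
  vrand <- fit$draws[, "V_A"] + fit$draws[, "V_C"]
  linkinv <- if (fit$link == "logit") stats::plogis else stats::pnorm
  if (link_scale) {
    prev <- linkinv(eta)
  } else if (fit$link == "probit") {
    prev <- stats::pnorm(eta / sqrt(1 + vrand))
  } else {
    gh <- gauss_hermite(30)
    wq <- gh$weights / sqrt(pi)
    prev <- vapply(seq_along(eta), function(k) {
      sum(wq * stats::plogis(eta[k] + sqrt(2 * vrand[k]) * gh$nodes))
    }, numeric(1))
  }
  list(
    prevalence = mean(prev), ci = hpd_interval(prev), method = "model",
    draws = prev
  )
}

#' Attributable risk (prevalence difference)
#'
#' The difference in outcome prevalence between an exposed and a reference
#' group, computed per posterior draw when draw vectors are supplied and
#' summarised by the mean and 95% HPD; scalars give a point estimate.
#'
#' @param prev_exposed,prev_reference prevalences in `[0, 1]` (scalars or
#'   equal-length draw vectors).
#' @return list with `risk_difference` and (for draws) `ci`.
#' @export
attributable_risk <- function(prev_exposed, prev_reference) {
  if (any(prev_exposed < 0 | prev_exposed > 1) ||
    any(prev_reference < 0 | prev_reference > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  d <- prev_exposed - prev_reference
  if (length(d) >= 100) {
    list(risk_difference = mean(d), ci = hpd_interval(d))
  } else {
    list(risk_difference = mean(d), ci = c(NA_real_, NA_real_))
  }
}

#' Current-episode counts by illness course
#'
#' Tabulates affected individuals flagged as being in a current episode at
#' interview, split into single and recurrent course (recurrent = more than
#' one episode), with their total.
#'
#' @param phenotypes data.frame with `status`, `episode_count`,
#'   `current_episode`.
#' @return list with `single`, `recurrent`, `total` counts and
#'   `fraction_of_affected` (current cases over all affected).
#' @export
current_episode_summary <- function(phenotypes) {
  aff <- !is.na(phenotypes$status) & phenotypes$status == 1
  cur <- aff & !is.na(phenotypes$current_episode) & phenotypes$current_episode == 1
  single <- sum(cur & phenotypes$episode_count == 1)
  recurrent <- sum(cur & phenotypes$episode_count >= 2)
  list(
    single = single, recurrent = recurrent, total = single + recurrent,
    fraction_of_affected = (single + recurrent) / sum(aff)
  )
}

#' Kaplan-Meier age-of-onset curves by interview-age group
#'
#' Affected individuals contribute an event at their onset age; unaffected
#' individuals are censored at their age at interview. The product-limit
#' estimator is computed per interview-age group and returned in tidy form
#' together with the cumulative incidence `1 - S(t)`.
#'
#' @param phenotypes data.frame with `status`, `age_at_interview`,
#'   `age_of_onset`.
#' @param age_groups cut points on age at interview defining the groups
#'   (default four groups 18-29, 30-44, 45-59, 60+).
#' @return data.frame with `group`, `age`, `n_risk`, `n_event`, `survival`,
#'   `cum_incidence`.
#' @export
onset_survival_curves <- function(phenotypes, age_groups = c(18, 30, 45, 60, Inf)) {
  ok <- !is.na(phenotypes$status)
  ph <- phenotypes[ok, , drop = FALSE]
  bad <- ph$status == 1 & (is.na(ph$age_of_onset) |
    ph$age_of_onset > ph$age_at_interview)
  if (any(bad)) {
    stop("affected individual(s) with missing onset or onset after interview age")
  }
  time <- ifelse(ph$status == 1, ph$age_of_onset, ph$age_at_interview)
  event <- ph$status
  grp <- cut(ph$age_at_interview, age_groups, right = FALSE, include.lowest = TRUE)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  strata_names <- if (is.null(sf$strata)) levels(droplevels(grp)) else sub("^grp=", "", names(sf$strata))
  lens <- if (is.null(sf$strata)) length(sf$time) else as.integer(sf$strata)
  data.frame(
    group = rep(strata_names, lens),
    age = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    survival = sf$surv,
    cum_incidence = 1 - sf$surv,
    row.names = NULL
  )
}
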