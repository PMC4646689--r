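#' Liability-scale heritability
#'
#' `h2 = V_A / (V_A + V_other + V_resid + d)` where `V_resid` is the residual
#' variance the sampler fixed on the link scale and `d` is the additional
#' distribution-specific variance of the link: `pi^2/3` for logit, `0` for
#' probit (the probit threshold model's unit residual *is* its
#' distribution-specific variance, so fits fix `V_resid = 1` and add
#' nothing further — the denominator is then `V_A + V_other + 1`).
#' Vectorised over posterior draws.
#'
#' @param v_a additive genetic variance (scalar or draws).
#' @param v_other sum of the other estimated variance components (e.g.
#'   the family-environment variance).
#' @param v_resid residual variance fixed on the link scale (1 for the
#'   probit fits; a logit fit with an explicit fixed residual passes it
#'   here).
#' @param link `"probit"` or `"logit"`.
#' @return heritability value(s) in `[0, 1]`.
#' @export
liability_h2 <- function(v_a, v_other = 0, v_resid = 1, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(v_a < 0) || any(v_other < 0) || any(v_resid < 0)) {
    stop("variance components must be non-negative")
  }
  d <- if (link == "logit") pi^2 / 3 else 0
  v_a / (v_a + v_other + v_resid + d)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; with ties the first (lowest) window is reported.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval probability mass (default 0.95).
#' @return length-2 numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("hpd_interval needs at least 100 draws")
  m <- ceiling(mass * n)
  s <- sort(draws)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  k <- which.min(widths) # which.min takes the first of tied minima
  c(s[k], s[k + m - 1])
}

#' Empirical MCMC p-value for a coefficient
#'
#' Twice the smaller of the posterior tail fractions at zero, floored at
#' `1/n` (a sample in which no draw crosses zero cannot claim a p-value
#' smaller than one draw's worth of mass).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return empirical two-sided p in `(0, 1]`.
#' @export
pmcmc <- function(draws) {
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("pmcmc needs at least 100 draws")
  max(1, 2 * min(sum(draws <= 0), sum(draws > 0))) / n
}

#' Odds ratios from fixed-effect coefficients
#'
#' Exponentiates logit-scale regression coefficients per posterior draw and
#' summarises by the posterior mean of `exp(beta)` with an HPD interval of
#' the exponentiated draws. Refuses probit fits, whose coefficients are not
#' log odds.
#'
#' @param x a `liability_fit` with `link = "logit"`, or a numeric vector of
#'   logit-scale coefficient draws (a single value is treated as a point
#'   estimate).
#' @param ... unused.
#' @return data.frame with columns `term`, `odds_ratio`, `ci_lower`,
#'   `ci_upper` (interval columns `NA` when fewer than 100 draws are given).
#' @export
odds_ratios <- function(x, ...) UseMethod("odds_ratios")

#' @rdname odds_ratios
#' @export
odds_ratios.numeric <- function(x, ...) {
  or <- exp(x)
  if (length(x) >= 100) {
    h <- hpd_interval(or)
    data.frame(term = "beta", odds_ratio = mean(or), ci_lower = h[1], ci_upper = h[2])
  } else {
    data.frame(
      term = if (is.null(names(x))) paste0("beta", seq_along(x)) else names(x),
      odds_ratio = or, ci_lower = NA_real_, ci_upper = NA_real_,
      row.names = NULL
    )
  }
}

#' @rdname odds_ratios
#' @export
odds_ratios.liability_fit <- function(x, ...) {
  if (x$link != "logit") {
    stop(
      "odds ratios require a logit-link fit; probit coefficients are ",
      "liability-scale probit shifts, not log odds"
    )
  }
  terms <- x$coef_names
  out <- lapply(terms, function(tm) {
    or <- exp(x$draws[, tm])
    h <- hpd_interval(or)
    data.frame(
      term = tm, odds_ratio = mean(or), ci_lower = h[1], ci_upper = h[2],
      pmcmc = pmcmc(x$draws[, tm])
    )
  })
  do.call(rbind, out)
}

#' Potential-scale-reduction convergence diagnostic
#'
#' Gelman-Rubin statistic per parameter across independently seeded chains
#' of equal post-burn-in length — the machine-checkable analogue of visually
#' overlaying per-chain sampling distributions. Values above `threshold`
#' (default 1.1) are flagged.
#'
#' @param x a `liability_fit`, or a list of draw matrices (one per chain,
#'   identical columns).
#' @param threshold flag limit for the statistic.
#' @return list with `rhat` (named vector), `flagged` (character vector of
#'   parameter names), `threshold`.
#' @export
check_convergence <- function(x, threshold = 1.1) {
  chains <- if (inherits(x, "liability_fit")) x$chains else x
  if (!is.list(chains) || length(chains) < 2) {
    stop("convergence check requires at least 2 chains")
  }
  n <- nrow(chains[[1]])
  if (!all(vapply(chains, nrow, integer(1)) == n)) {
    stop("chains must have equal post-burn-in length")
  }
  m <- length(chains)
  params <- colnames(chains[[1]])
  rhat <- vapply(seq_along(params), function(k) {
    draws <- vapply(chains, function(ch) ch[, k], numeric(n))
    w <- mean(apply(draws, 2, stats::var))
    b_over_n <- stats::var(colMeans(draws))
    if (w == 0) return(1)
    sqrt(((n - 1) / n * w + b_over_n) / w)
  }, numeric(1))
  names(rhat) <- params
  list(
    rhat = rhat,
    flagged = params[!is.na(rhat) & rhat > threshold],
    threshold = threshold
  )
}
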