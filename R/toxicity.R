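#' Logistic link functions
#'
#' Thin, overflow-safe wrappers around the standard logistic distribution
#' function used as the link in both the dose-toxicity and dose-efficacy
#' models.
#'
#' @param u Real number(s).
#' @param p Probability(ies) in (0, 1).
#' @return `logistic_cdf()` returns probabilities; `logistic_quantile()` the
#'   inverse.
#' @export
logistic_cdf <- function(u) stats::plogis(u)

#' @rdname logistic_cdf
#' @export
logistic_quantile <- function(p) stats::qlogis(p)

#' Probability of dose-limiting toxicity
#'
#' Evaluates the logistic dose-toxicity surface
#' `plogis(alpha0 + alpha1 x + alpha2 y + alpha3 x y)` with the alphas induced
#' by the corner-probability parameterization of [tox_params()]. Monotone
#' nondecreasing in each standardized dose.
#'
#' @param x,y Standardized doses (vectorized).
#' @param params A [tox_params()] object.
#' @return DLT probability(ies).
#' @export
prob_dlt <- function(x, y, params) {
  a <- tox_alphas(params)
  stats::plogis(a$a0 + a$a1 * x + a$a2 * y + a$a3 * x * y)
}

#' Prior specification for the dose-toxicity model
#'
#' Independent priors: `rho01 ~ Beta(a01, b01)`, `rho10 ~ Beta(a10, b10)`,
#' and conditional on those, the ratio `rho00 / min(rho01, rho10) ~
#' Beta(ar, br)`; the interaction `alpha3 ~ Gamma(shape, rate)`. The defaults
#' are informative: they place a DLT probability of about 0.33 on the
#' standardized anchor combination (0.33, 0.5), matching the single MTD
#' reported for the motivating cisplatin-cabazitaxel combination.
#'
#' @param rho01_shape,rho10_shape Length-2 Beta shape pairs.
#' @param ratio_shape Length-2 Beta shape pair for `rho00 / min(rho01, rho10)`.
#' @param alpha3_shape,alpha3_rate Gamma shape and rate for `alpha3`.
#' @return A `tox_prior` object.
#' @export
tox_prior <- function(rho01_shape = c(1.4, 5.6),
                      rho10_shape = c(1.4, 5.6),
                      ratio_shape = c(0.8, 7.2),
                      alpha3_shape = 0.8, alpha3_rate = 0.0384) {
  stopifnot(all(c(rho01_shape, rho10_shape, ratio_shape,
                  alpha3_shape, alpha3_rate) > 0))
  structure(list(rho01_shape = rho01_shape, rho10_shape = rho10_shape,
                 ratio_shape = ratio_shape, alpha3_shape = alpha3_shape,
                 alpha3_rate = alpha3_rate),
            class = "tox_prior")
}

tox_prior_vec <- function(prior) {
  c(prior$rho01_shape, prior$rho10_shape, prior$ratio_shape,
    prior$alpha3_shape, prior$alpha3_rate)
}

#' Draw from the toxicity prior
#'
#' Direct Monte Carlo draws of `(rho00, rho01, rho10, alpha3)` from the prior
#' of [tox_prior()] (no data). Used for prior-predictive checks such as
#' verifying the DLT probability the prior implies at the anchor combination.
#'
#' @param n Number of draws.
#' @param prior A [tox_prior()] object.
#' @return Tibble with columns `rho00, rho01, rho10, alpha3`.
#' @export
sample_tox_prior <- function(n, prior = tox_prior()) {
  rho01 <- stats::rbeta(n, prior$rho01_shape[1], prior$rho01_shape[2])
  rho10 <- stats::rbeta(n, prior$rho10_shape[1], prior$rho10_shape[2])
  r <- stats::rbeta(n, prior$ratio_shape[1], prior$ratio_shape[2])
  alpha3 <- stats::rgamma(n, shape = prior$alpha3_shape,
                          rate = prior$alpha3_rate)
  tibble::tibble(rho00 = r * pmin(rho01, rho10), rho01 = rho01,
                 rho10 = rho10, alpha3 = alpha3)
}

#' Unnormalized log posterior of the dose-toxicity model
#'
#' Reference (pure R) implementation: Bernoulli log likelihood of the DLT
#' outcomes plus the log prior in the ratio parameterization. Parameter
#' values violating the model invariants get `-Inf` rather than an error, so
#' the function can be used directly inside samplers and quadrature oracles.
#'
#' @param params A [tox_params()] object or a named list/vector with entries
#'   `rho00, rho01, rho10, alpha3`.
#' @param data Patient records: a data frame with columns `x`, `y`, `dlt`.
#' @param prior A [tox_prior()] object.
#' @return Log density (unnormalized).
#' @export
tox_log_posterior <- function(params, data, prior = tox_prior()) {
  p <- as.list(params)
  if (!(p$rho00 > 0 && p$rho00 < 1 && p$rho01 > 0 && p$rho01 < 1 &&
        p$rho10 > 0 && p$rho10 < 1 && p$alpha3 >= 0 &&
        p$rho00 <= min(p$rho01, p$rho10)))
    return(-Inf)
  r <- p$rho00 / min(p$rho01, p$rho10)
  lp <- stats::dbeta(r, prior$ratio_shape[1], prior$ratio_shape[2], log = TRUE) +
    stats::dbeta(p$rho01, prior$rho01_shape[1], prior$rho01_shape[2], log = TRUE) +
    stats::dbeta(p$rho10, prior$rho10_shape[1], prior$rho10_shape[2], log = TRUE) +
    stats::dgamma(p$alpha3, shape = prior$alpha3_shape,
                  rate = prior$alpha3_rate, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  if (nrow(data)) {
    pi_t <- prob_dlt(data$x, data$y,
                     tox_params(p$rho00, p$rho01, p$rho10, p$alpha3))
    lp <- lp + sum(ifelse(data$dlt == 1, log(pi_t), log1p(-pi_t)))
  }
  lp
}

#' Sample the dose-toxicity posterior
#'
#' Adaptive component-wise random-walk Metropolis on the unconstrained scale
#' (logit of the corner probabilities' ratio parameterization, log of the
#' interaction). Draws are returned on the natural scale together with
#' split-Rhat and effective-sample-size diagnostics.
#'
#' @param data Patient records (columns `x`, `y`, `dlt`); may have zero rows,
#'   in which case the draws target the prior.
#' @param prior A [tox_prior()] object.
#' @param n_draws Kept draws per chain.
#' @param seed Integer seed (all randomness flows through R's RNG).
#' @param chains,warmup Sampler settings.
#' @param ess_floor Minimum acceptable bulk ESS per parameter before the
#'   result is flagged.
#' @return A `tox_posterior`: list with tibble `draws` (columns
#'   `rho00, rho01, rho10, alpha3, .chain`), `diagnostics`, `flag`, and
#'   provenance (`n_obs`).
#' @export
sample_tox_posterior <- function(data, prior = tox_prior(), n_draws = 1000,
                                 seed = NULL, chains = 4, warmup = 1000,
                                 ess_floor = 400) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(data)) data <- tibble::tibble(x = numeric(), y = numeric(),
                                            dlt = integer())
  m <- mcmc_tox_cpp(as.integer(data$dlt), as.numeric(data$x),
                    as.numeric(data$y), tox_prior_vec(prior),
                    as.integer(chains), as.integer(warmup),
                    as.integer(n_draws))
  draws <- tibble::tibble(rho00 = m[, 1], rho01 = m[, 2], rho10 = m[, 3],
                          alpha3 = m[, 4], .chain = as.integer(m[, 5]))
  diag <- mcmc_diagnostics(draws, c("rho00", "rho01", "rho10", "alpha3"))
  new_posterior("tox_posterior", draws, diag, ess_floor, n_obs = nrow(data))
}

# shared posterior-object scaffolding -------------------------------------

new_posterior <- function(class, draws, diagnostics, ess_floor, n_obs) {
  flag <- any(diagnostics$rhat > 1.05, na.rm = TRUE) ||
    any(diagnostics$ess < ess_floor, na.rm = TRUE)
  structure(list(draws = draws, diagnostics = diagnostics,
                 flagged = flag, n_obs = n_obs),
            class = class)
}

# split-Rhat and a crude autocorrelation-based ESS, per parameter
mcmc_diagnostics <- function(draws, pars) {
  chains <- split(draws[pars], draws$.chain)
  out <- purrr::map_dfr(pars, function(p) {
    mats <- lapply(chains, function(ch) ch[[p]])
    half <- lapply(mats, function(v) {
      n <- length(v) %/% 2
      list(v[seq_len(n)], v[n + seq_len(n)])
    })
    segs <- unlist(half, recursive = FALSE)
    m <- length(segs); n <- length(segs[[1]])
    means <- vapply(segs, mean, numeric(1))
    vars <- vapply(segs, stats::var, numeric(1))
    W <- mean(vars); B <- n * stats::var(means)
    var_plus <- (n - 1) / n * W + B / n
    rhat <- if (W > 0) sqrt(var_plus / W) else NA_real_
    ess <- sum(vapply(mats, ess_one, numeric(1)))
    tibble::tibble(parameter = p, rhat = rhat, ess = ess)
  })
  out
}

ess_one <- function(v) {
  n <- length(v)
  if (stats::sd(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cut <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cut)]))
}

#' @export
print.tox_posterior <- function(x, ...) {
  cat("Dose-toxicity posterior:", nrow(x$draws), "draws,",
      x$n_obs, "observations\n")
  print(tidy(x))
  if (x$flagged) cat("NOTE: sampler diagnostics flagged (Rhat/ESS)\n")
  invisible(x)
}

#' EWOC percentile of the conditional MTD
#'
#' For each posterior draw of the toxicity parameters, solve the MTD curve for
#' the dose of the free agent given the fixed agent's dose, then take the
#' `alpha`-th empirical percentile (type-1 order-statistic quantile) across
#' draws. Under EWOC this bounds the posterior probability of assigning an
#' overdose by `alpha`. Solutions outside \[0,1\] are truncated to the nearest
#' bound after the percentile is taken; a `truncated` attribute reports it.
#'
#' @param post A `tox_posterior`.
#' @param fixed_dose Standardized dose of the fixed agent.
#' @param fixed_agent `"Y"` to solve for X given Y; `"X"` for Y given X.
#' @param alpha Feasibility bound in (0, 1).
#' @param theta_T Target DLT probability.
#' @return Standardized dose with attribute `truncated` (logical).
#' @export
conditional_mtd_percentile <- function(post, fixed_dose, fixed_agent = c("Y", "X"),
                                       alpha, theta_T = 0.33) {
  fixed_agent <- match.arg(fixed_agent)
  stopifnot(alpha > 0, alpha < 1)
  d <- post$draws
  # vectorized over draws: same algebra as mtd_x_given_y / mtd_y_given_x
  a0 <- stats::qlogis(d$rho00)
  A <- stats::qlogis(theta_T) - a0
  sol <- if (fixed_agent == "Y") {
    (A - (stats::qlogis(d$rho01) - a0) * fixed_dose) /
      (stats::qlogis(d$rho10) - a0 + d$alpha3 * fixed_dose)
  } else {
    (A - (stats::qlogis(d$rho10) - a0) * fixed_dose) /
      (stats::qlogis(d$rho01) - a0 + d$alpha3 * fixed_dose)
  }
  q <- stats::quantile(sol, probs = alpha, type = 1, names = FALSE)
  out <- min(max(q, 0), 1)
  attr(out, "truncated") <- (q < 0 || q > 1)
  out
}

#' Stage-I safety stopping rule
#'
#' Stop when the posterior probability that the DLT probability at the lowest
#' combination (0,0) exceeds `theta_T + margin` is larger than
#' `delta_theta1`: the trial's minimum dose is already too toxic.
#'
#' @param post A `tox_posterior`.
#' @param theta_T Target DLT probability.
#' @param delta_theta1 Posterior probability threshold (default 0.5).
#' @param margin Excess-toxicity margin added to `theta_T` (default 0.1).
#' @return Logical.
#' @export
stage1_safety_stop <- function(post, theta_T = 0.33, delta_theta1 = 0.5,
                               margin = 0.1) {
  mean(post$draws$rho00 > theta_T + margin) > delta_theta1
}
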