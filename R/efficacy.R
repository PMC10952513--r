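#' Stagewise dose-efficacy parameters
#'
#' One instance per stage: `plogis(beta0 + exp(beta1) x + exp(beta2) y +
#' beta3 x y)`. The main effects `psi = (beta1, beta2)` live on the log scale
#' so the efficacy surface is monotone nondecreasing in each dose;
#' `beta3 >= 0` encodes a synergistic interaction.
#'
#' @param beta0 Intercept on the logit scale.
#' @param beta1,beta2 Log-scale main effects of agents X and Y.
#' @param beta3 Nonnegative interaction on the logit scale.
#' @return An `eff_params` object.
#' @export
eff_params <- function(beta0, beta1, beta2, beta3 = 0) {
  stopifnot(length(beta0) == 1, length(beta1) == 1, length(beta2) == 1,
            length(beta3) == 1)
  if (beta3 < 0) stop("beta3 must be nonnegative")
  structure(list(beta0 = unname(beta0), beta1 = unname(beta1),
                 beta2 = unname(beta2), beta3 = unname(beta3)),
            class = "eff_params")
}

#' Probability of efficacy
#'
#' @param x,y Standardized doses (vectorized).
#' @param params An [eff_params()] object.
#' @return Efficacy probability(ies), monotone nondecreasing in each dose.
#' @export
prob_eff <- function(x, y, params) {
  stats::plogis(params$beta0 + exp(params$beta1) * x + exp(params$beta2) * y +
                  params$beta3 * x * y)
}

#' Prior specification for the EXNEX efficacy hierarchy
#'
#' Stage-specific intercepts get `N(b0_mean, b0_sd^2)` priors and interactions
#' `Gamma(b3_shape, b3_rate)`. The stage main-effect pairs `psi_S` follow a
#' bivariate-normal hierarchy: `psi_1 ~ BVN(mu, Phi)` always, while `psi_2` is
#' exchangeable with stage 1 (`BVN(mu, Phi)`) with prior probability `omega`
#' and otherwise draws from a weakly informative own prior
#' `BVN(0, R0)` with `R0 = 100 * [[1, zeta], [zeta, 1]]`. Hyperpriors:
#' `mu_k ~ N(eta_k, s_k^2)`, heterogeneity `tau_k ~ HalfNormal(z_k)`, and the
#' correlations `xi, zeta ~ U(0, 0.5)`.
#'
#' @param b0_mean,b0_sd Intercept prior (defaults -1.8, 3.16).
#' @param b3_shape,b3_rate Interaction Gamma prior (defaults 0.1, 0.1).
#' @param eta,s Length-2 hyperprior means and SDs for `mu` (defaults 0, 3.16).
#' @param z Length-2 half-normal scales for `tau` (default 0.5).
#' @param xi_max,zeta_max Upper bounds of the uniform priors (default 0.5).
#' @param omega Prior probability that `psi_2` is exchangeable with `psi_1`.
#' @return An `eff_prior` object.
#' @export
eff_prior <- function(b0_mean = -1.8, b0_sd = 3.16,
                      b3_shape = 0.1, b3_rate = 0.1,
                      eta = c(0, 0), s = c(3.16, 3.16),
                      z = c(0.5, 0.5), xi_max = 0.5, zeta_max = 0.5,
                      omega = 0.5) {
  stopifnot(b0_sd > 0, b3_shape > 0, b3_rate > 0, all(s > 0), all(z > 0),
            xi_max > 0, xi_max < 1, zeta_max > 0, zeta_max < 1,
            omega >= 0, omega <= 1)
  structure(list(b0_mean = b0_mean, b0_sd = b0_sd, b3_shape = b3_shape,
                 b3_rate = b3_rate, eta = eta, s = s, z = z,
                 xi_max = xi_max, zeta_max = zeta_max, omega = omega),
            class = "eff_prior")
}

eff_prior_vec <- function(prior) {
  c(prior$b0_mean, prior$b0_sd, prior$b3_shape, prior$b3_rate,
    prior$eta[1], prior$s[1], prior$eta[2], prior$s[2],
    prior$z[1], prior$z[2], prior$xi_max, prior$zeta_max, prior$omega)
}

bvn_logpdf_r <- function(a, b, m1, m2, s11, s12, s22) {
  det <- s11 * s22 - s12^2
  if (det <= 0) return(-Inf)
  d1 <- a - m1; d2 <- b - m2
  q <- (s22 * d1^2 - 2 * s12 * d1 * d2 + s11 * d2^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Joint log density of the EXNEX efficacy model
#'
#' Reference (pure R) implementation used by quadrature oracles and tests.
#' `all_params` is a named list with stage parameters `s1`, `s2` (each an
#' [eff_params()]), hypers `mu` (length 2), `tau` (length 2), `xi`, `zeta`.
#' The exchangeability indicator selects the prior branch for `psi_2`; pass
#' `NA` to marginalize over it with weights `(omega, 1 - omega)`.
#'
#' @param all_params Named list as above.
#' @param data_s1,data_s2 Data frames with columns `x`, `y`, `eff` (rows with
#'   missing `eff` are excluded).
#' @param prior An [eff_prior()] object.
#' @param exch_indicator 1 (exchangeable), 0 (nonexchangeable), or `NA` to
#'   marginalize.
#' @return Log density (unnormalized).
#' @export
eff_log_joint <- function(all_params, data_s1, data_s2, prior = eff_prior(),
                          exch_indicator = NA) {
  p1 <- all_params$s1; p2 <- all_params$s2
  mu <- all_params$mu; tau <- pmax(all_params$tau, 1e-6)
  xi <- all_params$xi; zeta <- all_params$zeta
  if (p1$beta3 < 0 || p2$beta3 < 0 || any(tau < 0) ||
      xi < 0 || xi > prior$xi_max || zeta < 0 || zeta > prior$zeta_max)
    return(-Inf)
  lp <- stats::dnorm(p1$beta0, prior$b0_mean, prior$b0_sd, log = TRUE) +
    stats::dnorm(p2$beta0, prior$b0_mean, prior$b0_sd, log = TRUE) +
    stats::dgamma(p1$beta3, prior$b3_shape, rate = prior$b3_rate, log = TRUE) +
    stats::dgamma(p2$beta3, prior$b3_shape, rate = prior$b3_rate, log = TRUE) +
    stats::dnorm(mu[1], prior$eta[1], prior$s[1], log = TRUE) +
    stats::dnorm(mu[2], prior$eta[2], prior$s[2], log = TRUE) +
    log(2) + stats::dnorm(tau[1], 0, prior$z[1], log = TRUE) +
    log(2) + stats::dnorm(tau[2], 0, prior$z[2], log = TRUE) -
    log(prior$xi_max) - log(prior$zeta_max)
  s11 <- tau[1]^2; s22 <- tau[2]^2; s12 <- xi * tau[1] * tau[2]
  lp <- lp + bvn_logpdf_r(p1$beta1, p1$beta2, mu[1], mu[2], s11, s12, s22)
  log_ex <- bvn_logpdf_r(p2$beta1, p2$beta2, mu[1], mu[2], s11, s12, s22)
  log_nex <- bvn_logpdf_r(p2$beta1, p2$beta2, 0, 0, 100, 100 * zeta, 100)
  omega <- prior$omega
  lp <- lp + if (is.na(exch_indicator)) {
    if (omega >= 1) log_ex
    else if (omega <= 0) log_nex
    else matrixStats_lse(c(log(omega) + log_ex, log1p(-omega) + log_nex))
  } else if (exch_indicator == 1) log_ex
  else if (exch_indicator == 0) log_nex
  else stop("exch_indicator must be 0, 1 or NA")
  ll <- function(dat, p) {
    dat <- dat[!is.na(dat$eff), , drop = FALSE]
    if (!nrow(dat)) return(0)
    pe <- prob_eff(dat$x, dat$y, p)
    sum(ifelse(dat$eff == 1, log(pe), log1p(-pe)))
  }
  lp + ll(data_s1, p1) + ll(data_s2, p2)
}

matrixStats_lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }

#' Fit the MAC efficacy model across stages
#'
#' Samples the joint posterior of both stages' dose-efficacy parameters and
#' the hierarchy's hyperparameters, with the stage-2 exchangeability mixture
#' marginalized inside the target density. The posterior exchangeability
#' weight is the mean of the per-draw branch responsibilities.
#'
#' @param data_s1,data_s2 Data frames with columns `x`, `y`, `eff`; rows with
#'   missing `eff` are dropped from the likelihood.
#' @param prior An [eff_prior()] object (carries `omega`).
#' @param n_draws Kept draws per chain.
#' @param seed Integer seed.
#' @param chains,warmup Sampler settings.
#' @param ess_floor Diagnostics floor, as in [sample_tox_posterior()].
#' @return An `eff_posterior`: tibble `draws` with per-stage parameters,
#'   hypers, per-draw exchangeability responsibility `w_exch`, plus
#'   `exch_weight`, diagnostics, and provenance.
#' @export
fit_mac <- function(data_s1, data_s2, prior = eff_prior(), n_draws = 1000,
                    seed = NULL, chains = 4, warmup = 1000, ess_floor = 400) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- function(d) {
    if (is.null(d)) return(tibble::tibble(x = numeric(), y = numeric(),
                                          eff = integer()))
    d[!is.na(d$eff), c("x", "y", "eff")]
  }
  d1 <- keep(data_s1); d2 <- keep(data_s2)
  m <- mcmc_eff_cpp(as.numeric(d1$x), as.numeric(d1$y), as.integer(d1$eff),
                    as.numeric(d2$x), as.numeric(d2$y), as.integer(d2$eff),
                    eff_prior_vec(prior), as.integer(chains),
                    as.integer(warmup), as.integer(n_draws))
  cn <- c("beta01", "beta11", "beta21", "beta31",
          "beta02", "beta12", "beta22", "beta32",
          "mu1", "mu2", "tau1", "tau2", "xi", "zeta", "w_exch", ".chain")
  draws <- tibble::as_tibble(as.data.frame(m))
  names(draws) <- cn
  draws$.chain <- as.integer(draws$.chain)
  core <- c("beta02", "beta12", "beta22", "beta32", "beta01", "beta11",
            "beta21", "mu1", "mu2")
  diag <- mcmc_diagnostics(draws, core)
  out <- new_posterior("eff_posterior", draws, diag, ess_floor,
                       n_obs = nrow(d1) + nrow(d2))
  out$exch_weight <- mean(draws$w_exch)
  out$omega <- prior$omega
  out
}

#' @export
print.eff_posterior <- function(x, ...) {
  cat("EXNEX efficacy posterior:", nrow(x$draws), "draws,",
      x$n_obs, "efficacy observations\n")
  cat(sprintf("  prior omega = %.2f, posterior exchangeability weight = %.3f\n",
              x$omega, x$exch_weight))
  if (x$flagged) cat("NOTE: sampler diagnostics flagged (Rhat/ESS)\n")
  invisible(x)
}

# stage-2 parameters per draw as a data.frame of eff_params fields
stage2_draws <- function(post) {
  d <- post$draws
  data.frame(beta0 = d$beta02, beta1 = d$beta12, beta2 = d$beta22,
             beta3 = d$beta32)
}

#' Posterior probability that stage-II efficacy exceeds a reference rate
#'
#' Fraction of posterior draws for which the stage-2 efficacy probability at
#' the given dose combination exceeds `p0`.
#'
#' @param post An `eff_posterior`.
#' @param x,y Standardized doses (vectorized; recycled together).
#' @param p0 Reference efficacy probability (standard of care).
#' @return Exceedance probability(ies).
#' @export
prob_eff_exceeds <- function(post, x, y, p0 = 0.15) {
  s2 <- stage2_draws(post)
  vapply(seq_along(x), function(i) {
    pe <- stats::plogis(s2$beta0 + exp(s2$beta1) * x[i] + exp(s2$beta2) * y[i] +
                          s2$beta3 * x[i] * y[i])
    mean(pe > p0)
  }, numeric(1))
}

#' Plug-in stage-II efficacy curve along an MTD curve
#'
#' Evaluates the stage-2 efficacy model at the coordinatewise posterior
#' medians of `(beta02, beta12, beta22, beta32)` along the one-to-one
#' `x -> (x, y(x))` parameterization of the MTD curve.
#'
#' @param post An `eff_posterior`.
#' @param curve An [mtd_curve()] with non-empty domain.
#' @return A function `x -> estimated stage-2 efficacy probability`.
#' @export
plugin_eff_curve <- function(post, curve) {
  if (!length(curve$x_domain))
    stop("MTD curve misses the unit square; no dose set to evaluate on")
  s2 <- stage2_draws(post)
  med <- eff_params(stats::median(s2$beta0), stats::median(s2$beta1),
                    stats::median(s2$beta2), stats::median(s2$beta3))
  function(x) {
    y <- mtd_y_given_x(x, curve$params, curve$theta_T, outside = "raw")
    prob_eff(x, y, med)
  }
}
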