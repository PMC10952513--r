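# Shared fixtures: small parameter sets, fast sampler settings, and the
# grid-integration oracle for the toxicity posterior.

fast_sampler <- list(chains = 2, warmup = 400, n_draws = 400, ess_floor = 50)

# a small design so full-trial engine tests stay quick
small_design <- function(...) {
  design_config(C1 = 4, n2 = 4, C2 = 2, m2 = 2, grid_size = 41,
                sampler = fast_sampler, ...)
}

example_tox_params <- function() tox_params(0.05, 0.20, 0.20, 5.715)

example_curve <- function() mtd_curve(example_tox_params(), 0.33)

# line curve from (0,1) to (1,0): rho01 = rho10 = theta_T, alpha3 = 0
line_curve <- function(theta_T = 0.33, rho00 = 0.05) {
  mtd_curve(tox_params(rho00, theta_T, theta_T, 0), theta_T)
}

make_tox_data <- function(n, params = example_tox_params(), seed = 42) {
  withr::with_seed(seed, {
    x <- runif(n); y <- runif(n)
    tibble::tibble(x = x, y = y,
                   dlt = rbinom(n, 1, prob_dlt(x, y, params)))
  })
}

make_eff_data <- function(n, params, seed = 42) {
  withr::with_seed(seed, {
    x <- runif(n); y <- runif(n)
    tibble::tibble(x = x, y = y,
                   eff = rbinom(n, 1, prob_eff(x, y, params)))
  })
}

# construct a tox_posterior object directly from given draws
fake_tox_posterior <- function(draws) {
  if (!".chain" %in% names(draws)) draws$.chain <- 1L
  structure(list(draws = draws, diagnostics = NULL, flagged = FALSE,
                 n_obs = 0L),
            class = "tox_posterior")
}

# construct an eff_posterior from stage-2 parameter draws (stage-1/hyper
# columns filled with zeros)
fake_eff_posterior <- function(beta02, beta12, beta22, beta32,
                               w_exch = 1, omega = 1) {
  n <- length(beta02)
  draws <- tibble::tibble(
    beta01 = 0, beta11 = 0, beta21 = 0, beta31 = 0,
    beta02 = beta02, beta12 = beta12, beta22 = beta22, beta32 = beta32,
    mu1 = 0, mu2 = 0, tau1 = 0.5, tau2 = 0.5, xi = 0.1, zeta = 0.1,
    w_exch = rep(w_exch, length.out = n), .chain = 1L)
  structure(list(draws = draws, diagnostics = NULL, flagged = FALSE,
                 n_obs = 0L, exch_weight = mean(draws$w_exch),
                 omega = omega),
            class = "eff_posterior")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Grid-integration oracle for the toxicity posterior on tiny datasets:
# integrates over (ratio, rho01, rho10) on a lattice and alpha3 by
# Gauss-like quadrature on a dense grid, using the same unnormalized log
# posterior as the sampler but evaluated independently of it.
tox_grid_posterior_means <- function(data, prior = tox_prior(),
                                     n_rho = 40, n_a3 = 48) {
  gr <- seq(1 / (2 * n_rho), 1 - 1 / (2 * n_rho), length.out = n_rho)
  # alpha3 grid on quantiles of its prior for good coverage of the tail
  qa <- seq(1 / (2 * n_a3), 1 - 1 / (2 * n_a3), length.out = n_a3)
  a3g <- qgamma(qa, shape = prior$alpha3_shape, rate = prior$alpha3_rate)
  g <- expand.grid(r = gr, p01 = gr, p10 = gr, a3 = a3g)
  g$rho00 <- g$r * pmin(g$p01, g$p10)
  lw <- dbeta(g$r, prior$ratio_shape[1], prior$ratio_shape[2], log = TRUE) +
    dbeta(g$p01, prior$rho01_shape[1], prior$rho01_shape[2], log = TRUE) +
    dbeta(g$p10, prior$rho10_shape[1], prior$rho10_shape[2], log = TRUE)
  # alpha3 prior weight cancels: grid points are equal-probability quantiles
  a0 <- qlogis(g$rho00)
  a1 <- qlogis(g$p10) - a0
  a2 <- qlogis(g$p01) - a0
  for (i in seq_len(nrow(data))) {
    eta <- a0 + a1 * data$x[i] + a2 * data$y[i] + g$a3 * data$x[i] * data$y[i]
    lw <- lw + if (data$dlt[i] == 1) plogis(eta, log.p = TRUE) else
      plogis(-eta, log.p = TRUE)
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  c(rho00 = sum(w * g$rho00), rho01 = sum(w * g$p01),
    rho10 = sum(w * g$p10), alpha3 = sum(w * g$a3))
}
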