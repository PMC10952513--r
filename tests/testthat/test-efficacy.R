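test_that("efficacy surface is monotone and reproduces plug-in algebra", {
  p <- eff_params(-1.2, 0.4, -0.3, 2)
  expect_equal(prob_eff(0, 0, p), plogis(-1.2))
  p0 <- eff_params(-1.2, 0.4, -0.3, 0)
  expect_equal(prob_eff(1, 1, p0),
               plogis(-1.2 + exp(0.4) + exp(-0.3)))
  withr::with_seed(11, {
    for (i in 1:20) {
      pp <- eff_params(rnorm(1), rnorm(1), rnorm(1), rexp(1))
      x <- runif(1); y <- runif(1); d <- runif(1, 0.01, 0.3)
      expect_gte(prob_eff(x + d, y, pp), prob_eff(x, y, pp))
      expect_gte(prob_eff(x, y + d, pp), prob_eff(x, y, pp))
    }
  })
})

test_that("EXNEX joint density degenerates correctly at omega = 0 and 1", {
  d1 <- make_eff_data(5, eff_params(-1, 0, 0, 1), seed = 1)
  d2 <- make_eff_data(5, eff_params(-1, 0, 0, 1), seed = 2)
  pars <- list(s1 = eff_params(-1.5, 0.2, -0.1, 0.5),
               s2 = eff_params(-1.2, 0.4, 0.3, 0.2),
               mu = c(0.1, -0.2), tau = c(0.4, 0.6), xi = 0.2, zeta = 0.3)
  for (om in c(0, 1)) {
    pr <- eff_prior(omega = om)
    expect_equal(eff_log_joint(pars, d1, d2, pr, exch_indicator = NA),
                 eff_log_joint(pars, d1, d2, pr, exch_indicator = om))
  }
  # for interior omega the marginalized density is the log-sum-exp mixture
  pr <- eff_prior(omega = 0.3)
  l1 <- eff_log_joint(pars, d1, d2, pr, exch_indicator = 1)
  l0 <- eff_log_joint(pars, d1, d2, pr, exch_indicator = 0)
  lm <- eff_log_joint(pars, d1, d2, pr, exch_indicator = NA)
  expect_equal(exp(lm), 0.3 * exp(l1) + 0.7 * exp(l0), tolerance = 1e-12)
  expect_error(eff_log_joint(pars, d1, d2, pr, exch_indicator = 2),
               "exch_indicator")
})

test_that("records with missing efficacy are excluded from the likelihood", {
  pars <- list(s1 = eff_params(-1, 0, 0, 0), s2 = eff_params(-1, 0, 0, 0),
               mu = c(0, 0), tau = c(0.3, 0.3), xi = 0.1, zeta = 0.1)
  pr <- eff_prior(omega = 0.5)
  d2 <- tibble::tibble(x = 0.5, y = 0.5, eff = NA_integer_)
  empty <- tibble::tibble(x = numeric(), y = numeric(), eff = integer())
  expect_equal(eff_log_joint(pars, empty, d2, pr),
               eff_log_joint(pars, empty, empty, pr))
})

test_that("MAC sampler matches a grid oracle for a decoupled stage-2 fit", {
  # omega = 0 with a negligible interaction prior reduces the stage-2
  # marginal to a 3-parameter logistic model with independent priors:
  # beta02 ~ N(-1.8, 3.16^2), psi_2 ~ N(0, 10^2) each (zeta ~ U(0, 1e-6))
  # a designed 6-patient toy with both outcomes at each informative corner,
  # so all three parameters are likelihood-identified
  d2 <- tibble::tibble(x = c(0, 0, 1, 1, 0, 0), y = c(0, 0, 0, 0, 1, 1),
                       eff = c(1L, 0L, 1L, 0L, 1L, 0L))
  pr <- eff_prior(omega = 0, b3_shape = 1, b3_rate = 1e6, zeta_max = 1e-6)
  empty <- tibble::tibble(x = numeric(), y = numeric(), eff = integer())
  post <- fit_mac(empty, d2, pr, n_draws = 4000, chains = 4, warmup = 1500,
                  seed = 21)
  # independent oracle: dense-grid integration over (beta02, beta12, beta22)
  g0 <- seq(-16, 12, length.out = 113)
  g1 <- seq(-24, 6, length.out = 121)
  gr <- expand.grid(b0 = g0, b1 = g1, b2 = g1)
  lw <- dnorm(gr$b0, -1.8, 3.16, log = TRUE) +
    dnorm(gr$b1, 0, 10, log = TRUE) + dnorm(gr$b2, 0, 10, log = TRUE)
  for (i in seq_len(nrow(d2))) {
    eta <- gr$b0 + exp(gr$b1) * d2$x[i] + exp(gr$b2) * d2$y[i]
    lw <- lw + if (d2$eff[i] == 1) plogis(eta, log.p = TRUE) else
      plogis(-eta, log.p = TRUE)
  }
  w <- exp(lw - max(lw)); w <- w / sum(w)
  expect_lt(abs(mean(post$draws$beta02) - sum(w * gr$b0)), 0.25)
  expect_lt(abs(mean(plogis(post$draws$beta02)) - sum(w * plogis(gr$b0))),
            0.02)
  # the efficacy probability at a reference dose is the decision-relevant
  # functional; require close agreement there
  pe_mcmc <- mean(plogis(post$draws$beta02 + exp(post$draws$beta12) * 0.5 +
                           exp(post$draws$beta22) * 0.5))
  pe_grid <- sum(w * plogis(gr$b0 + exp(gr$b1) * 0.5 + exp(gr$b2) * 0.5))
  expect_lt(abs(pe_mcmc - pe_grid), 0.03)
})

test_that("no-borrowing limit: stage-2 inference ignores stage-1 data at omega 0", {
  truth <- eff_params(-1, 0.3, 0.3, 0)
  d2 <- make_eff_data(40, truth, seed = 13)
  d1a <- make_eff_data(40, eff_params(2, 1, 1, 0), seed = 14)
  empty <- tibble::tibble(x = numeric(), y = numeric(), eff = integer())
  pr <- eff_prior(omega = 0)
  pa <- fit_mac(d1a, d2, pr, n_draws = 2000, chains = 2, warmup = 1000,
                seed = 31)
  pb <- fit_mac(empty, d2, pr, n_draws = 2000, chains = 2, warmup = 1000,
                seed = 32)
  for (dose in list(c(0.2, 0.8), c(0.7, 0.3))) {
    ea <- prob_eff_exceeds(pa, dose[1], dose[2], 0.15)
    eb <- prob_eff_exceeds(pb, dose[1], dose[2], 0.15)
    expect_equal(ea, eb, tolerance = 0.05)
  }
  expect_equal(pa$exch_weight, 0)
})

test_that("posterior exchangeability weight tracks cross-stage (in)consistency", {
  cons <- eff_params(-1.5, 0.6, 0.6, 0)
  d1 <- make_eff_data(200, cons, seed = 15)
  d2 <- make_eff_data(200, cons, seed = 16)
  post_c <- fit_mac(d1, d2, eff_prior(omega = 0.5), n_draws = 1500,
                    chains = 2, warmup = 1000, seed = 41)
  expect_gt(post_c$exch_weight, 0.5)

  # conflicting main effects: stage 1 strongly dose-responsive, stage 2 flat
  d1c <- make_eff_data(200, eff_params(-3, 1.8, 1.8, 0), seed = 17)
  d2c <- make_eff_data(200, eff_params(1.2, -6, -6, 0), seed = 18)
  post_d <- fit_mac(d1c, d2c, eff_prior(omega = 0.5), n_draws = 1500,
                    chains = 2, warmup = 1000, seed = 42)
  expect_lt(post_d$exch_weight, 0.5)
})

test_that("with no efficacy data the fit reproduces the prior", {
  empty <- tibble::tibble(x = numeric(), y = numeric(), eff = integer())
  post <- fit_mac(empty, empty, eff_prior(omega = 0.25), n_draws = 3000,
                  chains = 2, warmup = 1000, seed = 51)
  # prior probability of efficacy at the lowest combination: F(-1.8) ~ 0.14
  expect_lt(abs(median(plogis(post$draws$beta02)) - plogis(-1.8)), 0.03)
  # exchangeability weight collapses to the prior omega without data
  expect_lt(abs(post$exch_weight - 0.25), 0.05)
  expect_true(all(post$draws$xi >= 0 & post$draws$xi <= 0.5))
  expect_true(all(post$draws$zeta >= 0 & post$draws$zeta <= 0.5))
  expect_true(all(post$draws$beta32 >= 0))
})

test_that("borrowing sharpens main-effect estimates when stages agree", {
  cons <- eff_params(-1.5, 0.5, 0.5, 0)
  d1 <- make_eff_data(120, cons, seed = 19)
  d2 <- make_eff_data(120, cons, seed = 20)
  p_full <- fit_mac(d1, d2, eff_prior(omega = 1), n_draws = 1500,
                    chains = 2, warmup = 1000, seed = 61)
  empty <- tibble::tibble(x = numeric(), y = numeric(), eff = integer())
  p_none <- fit_mac(empty, d2, eff_prior(omega = 0), n_draws = 1500,
                    chains = 2, warmup = 1000, seed = 62)
  # the exchangeable hierarchy shrinks the stage-2 main effects toward the
  # shared mean, so their posterior spread contracts relative to the
  # own-prior (no-borrowing) fit
  expect_lt(sd(p_full$draws$beta12), sd(p_none$draws$beta12))
  expect_lt(sd(p_full$draws$beta22), sd(p_none$draws$beta22))
})

test_that("exceedance probabilities and plug-in curve match counting oracles", {
  post <- fake_eff_posterior(beta02 = qlogis(0.9) - 0.5, beta12 = -10,
                             beta22 = -10, beta32 = rep(0.5, 100))
  # all draws give pi_E = 0.9 at (1, 1) up to the tiny main effects
  expect_equal(prob_eff_exceeds(post, 1, 1, 0.15), 1)
  expect_equal(prob_eff_exceeds(post, 0.5, 0.5, 0), 1)

  # known exceedance fraction 0.37
  b0 <- qlogis(c(rep(0.30, 37), rep(0.10, 63)))
  post2 <- fake_eff_posterior(beta02 = b0, beta12 = -20, beta22 = -20,
                              beta32 = 0)
  expect_equal(prob_eff_exceeds(post2, 0.5, 0.5, 0.15), 0.37)

  # degenerate posterior: plug-in equals prob_eff at those values
  cv <- example_curve()
  post3 <- fake_eff_posterior(beta02 = rep(-1, 50), beta12 = 0.2,
                              beta22 = -0.3, beta32 = 1.5)
  f <- plugin_eff_curve(post3, cv)
  x <- 0.4
  y <- mtd_y_given_x(x, cv$params, cv$theta_T, outside = "raw")
  expect_equal(f(x), prob_eff(x, y, eff_params(-1, 0.2, -0.3, 1.5)))

  # medians from draws match the sort-based median
  withr::with_seed(3, b <- rnorm(1001))
  post4 <- fake_eff_posterior(beta02 = b, beta12 = b / 2, beta22 = b / 3,
                              beta32 = abs(b))
  f4 <- plugin_eff_curve(post4, cv)
  med <- sort(b)[501]
  expect_equal(f4(x),
               prob_eff(x, y, eff_params(med, med / 2, med / 3,
                                         sort(abs(b))[501])))
})
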