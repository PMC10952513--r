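test_that("design configuration enforces the sample-size identities", {
  cfg <- design_config()
  expect_equal(cfg$N1, cfg$C1 * cfg$m1)
  expect_equal(cfg$N2, cfg$n2 + cfg$C2 * cfg$m2)
  expect_equal(cfg$N1, 30)
  expect_equal(cfg$N2, 30)
  expect_error(design_config(m1 = 3), "m1 must equal 2")
  expect_error(design_config(delta_0 = 0.5, delta_u = 0.4), "delta_0")
})

test_that("the feasibility bound escalates from 0.25 by 0.05 and caps at 0.5", {
  cfg <- design_config()
  expect_true(is.na(duocomb:::ewoc_alpha(cfg, 1)))
  expect_equal(duocomb:::ewoc_alpha(cfg, 2), 0.25)
  expect_equal(duocomb:::ewoc_alpha(cfg, 3), 0.30)
  expect_equal(duocomb:::ewoc_alpha(cfg, 7), 0.50)
  expect_equal(duocomb:::ewoc_alpha(cfg, 15), 0.50)
})

test_that("stage I follows the alternating conditional-assignment pattern", {
  sc <- default_scenario(2, 1, "H1", "CA")
  cfg <- design_config(C1 = 5, n2 = 4, C2 = 2, m2 = 2,
                       sampler = fast_sampler)
  set.seed(71)
  s1 <- run_stage1(cfg, outcome_source(sc))
  r <- s1$records
  expect_equal(nrow(r), 10)
  # cohort 1: both patients at the starting combination
  expect_equal(unlist(r[1, c("x", "y")]), c(x = 0.33, y = 0.5))
  expect_equal(unlist(r[2, c("x", "y")]), c(x = 0.33, y = 0.5))
  # cohort 2 (even): patient 3 keeps y1 and gets a new x; patient 4 keeps x2
  expect_equal(r$y[3], r$y[1])
  expect_equal(r$x[4], r$x[2])
  # cohort 3 (odd): patient 5 keeps x3, patient 6 keeps y4
  expect_equal(r$x[5], r$x[3])
  expect_equal(r$y[6], r$y[4])
  # cohort 4 (even): patient 7 keeps y5, patient 8 keeps x6
  expect_equal(r$y[7], r$y[5])
  expect_equal(r$x[8], r$x[6])
  # cohort 5 (odd): patient 9 keeps x7, patient 10 keeps y8
  expect_equal(r$x[9], r$x[7])
  expect_equal(r$y[10], r$y[8])
  # feasibility bounds recorded per cohort
  expect_equal(unique(r$alpha[r$cohort == 2]), 0.25)
  expect_equal(unique(r$alpha[r$cohort == 5]), 0.40)
  expect_equal(nrow(s1$cohort_log), 5)
})

test_that("point-mass posteriors make curve estimation and assignment exact", {
  p <- example_tox_params()
  draws <- tibble::tibble(rho00 = rep(p$rho00, 200), rho01 = p$rho01,
                          rho10 = p$rho10, alpha3 = p$alpha3)
  post <- fake_tox_posterior(draws)
  cfg <- design_config()
  cv <- estimate_mtd_curve(post, cfg)
  expect_equal(cv$params$rho00, p$rho00, tolerance = 1e-9)
  expect_equal(cv$params$alpha3, p$alpha3)
  # conditional percentile of a point mass is the deterministic inversion
  got <- conditional_mtd_percentile(post, 0.5, "Y", 0.25, 0.33)
  expect_equal(as.numeric(got), mtd_x_given_y(0.5, p, 0.33, "truncate"))
  got2 <- conditional_mtd_percentile(post, 0.4, "X", 0.5, 0.33)
  expect_equal(as.numeric(got2), mtd_y_given_x(0.4, p, 0.33, "truncate"))
})

test_that("curve estimation uses coordinatewise medians of the draws", {
  withr::with_seed(12, {
    draws <- tibble::tibble(rho00 = rbeta(501, 2, 30),
                            rho01 = rbeta(501, 4, 12),
                            rho10 = rbeta(501, 4, 12),
                            alpha3 = rgamma(501, 2, 0.5))
  })
  cv <- estimate_mtd_curve(fake_tox_posterior(draws), design_config())
  expect_equal(cv$params$rho01, sort(draws$rho01)[251])
  expect_equal(cv$params$alpha3, sort(draws$alpha3)[251])
})

test_that("standardized density normalizes and matches closed forms", {
  # constant efficacy curve -> uniform density over the domain
  dens <- standardized_density(function(x) rep(0.3, length(x)), c(0.2, 0.8))
  expect_equal(dens$fn(0.3), 1 / 0.6, tolerance = 1e-9)
  expect_equal(integrate(dens$fn, 0.2, 0.8, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  # linear ramp on [0, 1]: density 2x
  ramp <- standardized_density(function(x) x, c(0, 1))
  expect_equal(ramp$fn(0.5), 1, tolerance = 1e-9)
  expect_equal(ramp$fn(1), 2, tolerance = 1e-9)
  expect_equal(integrate(ramp$fn, 0, 1, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)
  expect_error(standardized_density(function(x) x - 0.5, c(0, 1)),
               "strictly positive")
})

test_that("rejection sampling reproduces the target density on the curve", {
  lc <- line_curve()
  set.seed(99)
  # uniform target
  dens_u <- standardized_density(function(x) rep(1, length(x)), c(0, 1))
  xu <- sample_doses_rejection(dens_u, lc, 4000)$x
  ks_u <- suppressWarnings(ks.test(xu, "punif"))
  expect_gt(ks_u$p.value, 0.01)
  # ramp target with analytic CDF x^2
  dens_r <- standardized_density(function(x) x, c(0, 1))
  pts <- sample_doses_rejection(dens_r, lc, 4000)
  ks_r <- suppressWarnings(ks.test(pts$x, function(q) q^2))
  expect_gt(ks_r$p.value, 0.01)
  # samples lie on the curve
  expect_true(all(abs(prob_dlt(pts$x, pts$y, lc$params) - 0.33) < 1e-8))
})

test_that("futility rule compares the best exceedance to delta_0", {
  cv <- example_curve()
  cfg <- design_config(sampler = fast_sampler)
  # hopeless posterior: efficacy essentially zero everywhere
  post_bad <- fake_eff_posterior(beta02 = rep(-12, 200), beta12 = -15,
                                 beta22 = -15, beta32 = 0)
  expect_true(futility_stop(post_bad, cv, cfg))
  # exceedance 0.5 at every dose defeats futility
  b0 <- c(rep(3, 100), rep(-12, 100))
  post_half <- fake_eff_posterior(beta02 = b0, beta12 = -15, beta22 = -15,
                                  beta32 = 0)
  expect_false(futility_stop(post_half, cv, cfg))
  # exceedance exactly 0.08 < 0.1 everywhere
  b08 <- c(rep(3, 8), rep(-12, 92))
  post_08 <- fake_eff_posterior(beta02 = b08, beta12 = -15, beta22 = -15,
                                beta32 = 0)
  expect_true(futility_stop(post_08, cv, cfg))
})

test_that("stage-II safety rule equals the closed-form Beta survival", {
  cfg <- design_config()
  mk <- function(k, n) tibble::tibble(
    stage = rep(2L, n), dlt = c(rep(1L, k), rep(0L, n - k)))
  expect_false(stage2_safety_stop(mk(0, 10), cfg))
  expect_true(stage2_safety_stop(mk(10, 10), cfg))
  # numeric-integration oracle for k = 20, n = 40
  surv_oracle <- integrate(function(t) dbeta(t, 20.5, 20.5), 0.43, 1,
                           rel.tol = 1e-13)$value
  surv_closed <- pbeta(0.43, 20.5, 20.5, lower.tail = FALSE)
  expect_equal(surv_closed, surv_oracle, tolerance = 1e-10)
  expect_equal(stage2_safety_stop(mk(20, 40), cfg), surv_closed > 0.9)
  # pooling switch: stage-1 DLTs count only when pooling
  rec <- tibble::tibble(stage = c(rep(1L, 15), rep(2L, 5)),
                        dlt = c(rep(1L, 15), rep(0L, 5)))
  cfg_pool <- design_config()
  cfg_s2 <- design_config(safety2_pool = FALSE)
  expect_true(stage2_safety_stop(rec, cfg_pool))
  expect_false(stage2_safety_stop(rec, cfg_s2))
})

test_that("final test rejects above delta_u and locates the argmax", {
  cv <- example_curve()
  cfg <- design_config(sampler = fast_sampler)
  # uniform exceedance 0.39 < 0.4: accept
  b39 <- c(rep(3, 39), rep(-12, 61))
  post39 <- fake_eff_posterior(beta02 = b39, beta12 = -15, beta22 = -15,
                               beta32 = 0)
  ft <- final_test(post39, cv, cfg)
  expect_false(ft$reject)
  # a dose-responsive posterior rejects and the argmax matches a fine grid
  withr::with_seed(23, {
    post_up <- fake_eff_posterior(beta02 = rnorm(400, -3, 0.7),
                                  beta12 = rnorm(400, 1.2, 0.2),
                                  beta22 = rnorm(400, -2, 0.5),
                                  beta32 = rexp(400, 2))
  })
  ft2 <- final_test(post_up, cv, cfg)
  expect_true(ft2$reject)
  fine <- equally_spaced_points(cv, 1001)
  fine$exceed <- prob_eff_exceeds(post_up, fine$x, fine$y, cfg$p0)
  step <- diff(range(ft2$grid$x)) / (cfg$grid_size - 1)
  expect_lt(abs(fine$x[which.max(fine$exceed)] - ft2$opt_x), 1.5 * step)
  # decision monotonicity in delta_u
  cfg_hi <- design_config(delta_u = 0.999, sampler = fast_sampler)
  expect_false(final_test(post_up, cv, cfg_hi)$reject)
})

test_that("a complete trial keeps its books straight", {
  sc <- default_scenario(2, 1, "H1", "CA")
  cfg <- small_design()
  res <- run_trial(cfg, outcome_source(sc), seed = 202)
  expect_s3_class(res, "trial_result")
  expect_true(res$decision %in%
                c("reject_H0", "accept_H0", "stopped_futility",
                  "stopped_safety_s1", "stopped_safety_s2",
                  "no_tolerable_set"))
  if (res$decision %in% c("reject_H0", "accept_H0")) {
    expect_equal(nrow(res$records), cfg$N1 + cfg$N2)
  } else {
    expect_lte(nrow(res$records), cfg$N1 + cfg$N2)
  }
  expect_equal(res$n_enrolled, nrow(res$records))
  expect_equal(res$dlt_count, sum(res$records$dlt))
  # all stage-II assignments lie on the estimated curve
  s2 <- res$records[res$records$stage == 2, ]
  if (nrow(s2) > 0) {
    expect_true(all(abs(prob_dlt(s2$x, s2$y, res$curve$params) -
                          cfg$theta_T) < 1e-8))
  }
  # glance() mirrors the result fields
  g <- glance(res)
  expect_equal(g$decision, res$decision)
  expect_equal(g$n_enrolled, res$n_enrolled)
})

test_that("a hopeless efficacy truth stops the trial for futility", {
  sc <- default_scenario(2, 1, "H1", "CA")
  # force stage-II efficacy to be essentially zero everywhere
  sc$eff_s1 <- eff_params(-12, -5, -5, 0)
  sc$eff_s2 <- eff_params(-12, -5, -5, 0)
  cfg <- small_design()
  res <- run_trial(cfg, outcome_source(sc), seed = 203)
  expect_equal(res$decision, "stopped_futility")
  # stopped during stage II, at or after the run-in
  expect_gte(nrow(res$records), cfg$N1 + cfg$n2)
  expect_lte(nrow(res$records), cfg$N1 + cfg$N2)
  expect_true(is.na(res$opt_x))
})

test_that("a uniformly intolerable truth triggers a safety stop", {
  sc <- default_scenario(2, 1, "H1", "CA")
  sc$tox <- tox_params(0.85, 0.9, 0.9, 0.5)
  cfg <- small_design()
  res <- run_trial(cfg, outcome_source(sc), seed = 204)
  # the informative prior concentrates rho00 at small values, so the
  # stage-I rule may resist a short all-DLT run; the pooled stage-II rule
  # (or an empty tolerable set) then catches it
  expect_true(res$decision %in% c("stopped_safety_s1", "stopped_safety_s2",
                                  "no_tolerable_set"))
  expect_lt(nrow(res$records), cfg$N1 + cfg$N2)
  expect_true(is.na(res$opt_x))
})
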