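#' Design configuration for the two-stage trial
#'
#' Collects every design constant: target DLT probability, standard-of-care
#' efficacy rate, decision and stopping thresholds, cohort bookkeeping, EWOC
#' feasibility-bound schedule, and sampler settings. Sample-size identities
#' `N1 = C1 * m1` and `N2 = n2 + C2 * m2` are enforced.
#'
#' @param theta_T Target DLT probability.
#' @param p0 Standard-of-care efficacy probability.
#' @param delta_u Decision threshold for rejecting the null at the end of
#'   stage II.
#' @param delta_0 Futility threshold on the maximum posterior exceedance
#'   probability along the curve (checked after the run-in).
#' @param delta_theta1,delta_theta2 Safety thresholds for stages I and II.
#' @param excess_tox_margin Margin added to `theta_T` in both safety rules.
#' @param C1,m1 Stage-I cohorts and cohort size (the alternating conditional
#'   EWOC assignment requires `m1 = 2`).
#' @param n2,C2,m2 Stage-II run-in size, adaptive cohorts, and cohort size.
#' @param ewoc_alpha_start,ewoc_alpha_step,ewoc_alpha_max Feasibility-bound
#'   schedule: `alpha = min(start + step * (c1 - 2), max)` from cohort 2 on.
#' @param start_dose Standardized starting combination for cohort 1.
#' @param grid_size Number of arc-length-spaced curve points used for the
#'   futility check and the final argmax.
#' @param spacing `"arc"` or `"x"`: what "equally spaced along the curve"
#'   means for the run-in and the decision grid.
#' @param safety2_pool Pool DLTs over both stages in the stage-II safety rule
#'   (default) or restrict to stage II (sensitivity switch).
#' @param sampler Named list of MCMC settings (`chains`, `warmup`, `n_draws`,
#'   `ess_floor`) applied to both model fits.
#' @return A `design_config` object (named list with derived `N1`, `N2`).
#' @export
design_config <- function(theta_T = 0.33, p0 = 0.15, delta_u = 0.4,
                          delta_0 = 0.1, delta_theta1 = 0.5,
                          delta_theta2 = 0.9, excess_tox_margin = 0.1,
                          C1 = 15, m1 = 2, n2 = 10, C2 = 4, m2 = 5,
                          ewoc_alpha_start = 0.25, ewoc_alpha_step = 0.05,
                          ewoc_alpha_max = 0.5,
                          start_dose = c(0.33, 0.5), grid_size = 101,
                          spacing = c("arc", "x"), safety2_pool = TRUE,
                          sampler = list(chains = 2, warmup = 500,
                                         n_draws = 500, ess_floor = 100)) {
  spacing <- match.arg(spacing)
  if (m1 != 2)
    stop("m1 must equal 2: stage-I cohorts alternate conditional MTD ",
         "assignments between the two agents")
  bad <- character()
  if (!(delta_0 < delta_u)) bad <- c(bad, "delta_0 must be < delta_u")
  for (nm in c("theta_T", "p0", "delta_u", "delta_0", "delta_theta1",
               "delta_theta2"))
    if (get(nm) <= 0 || get(nm) >= 1) bad <- c(bad, paste(nm, "not in (0,1)"))
  if (length(bad)) stop(paste(bad, collapse = "; "))
  structure(list(theta_T = theta_T, p0 = p0, delta_u = delta_u,
                 delta_0 = delta_0, delta_theta1 = delta_theta1,
                 delta_theta2 = delta_theta2,
                 excess_tox_margin = excess_tox_margin,
                 C1 = C1, m1 = m1, N1 = C1 * m1,
                 n2 = n2, C2 = C2, m2 = m2, N2 = n2 + C2 * m2,
                 ewoc_alpha_start = ewoc_alpha_start,
                 ewoc_alpha_step = ewoc_alpha_step,
                 ewoc_alpha_max = ewoc_alpha_max,
                 start_dose = start_dose, grid_size = grid_size,
                 spacing = spacing, safety2_pool = safety2_pool,
                 sampler = sampler),
            class = "design_config")
}

ewoc_alpha <- function(config, c1) {
  if (c1 <= 1) return(NA_real_)
  min(config$ewoc_alpha_start + config$ewoc_alpha_step * (c1 - 2),
      config$ewoc_alpha_max)
}

empty_records <- function() {
  tibble::tibble(patient_id = integer(), stage = integer(), cohort = integer(),
                 x = numeric(), y = numeric(), dlt = integer(),
                 eff = integer(), alpha = numeric(), truncated = logical())
}

fit_tox <- function(data, prior, config) {
  s <- config$sampler
  sample_tox_posterior(data, prior, n_draws = s$n_draws, chains = s$chains,
                       warmup = s$warmup, ess_floor = s$ess_floor)
}

#' Run stage I: conditional EWOC escalation
#'
#' Cohort 1 treats two patients at the starting combination. From cohort 2 on,
#' one patient keeps the previous dose of one agent and receives the
#' feasibility-bound percentile of the posterior conditional MTD of the other;
#' the roles alternate with cohort parity. The toxicity posterior is refit
#' after every cohort and the stage-I safety rule is checked each time.
#'
#' @param config A [design_config()].
#' @param outcome_source Function `(x, y, stage) -> list(dlt, eff)` supplying
#'   patient outcomes (e.g., [outcome_source()] for simulations).
#' @param tox_prior_spec A [tox_prior()].
#' @return List with `records` (patient tibble), `posterior` (final
#'   `tox_posterior`), `stopped` (logical safety stop), `cohort_log` tibble.
#' @export
run_stage1 <- function(config, outcome_source, tox_prior_spec = tox_prior()) {
  rec <- empty_records()
  log <- tibble::tibble(cohort = integer(), alpha = numeric(),
                        safety_stop = logical())
  observe <- function(x, y, cohort, alpha, truncated) {
    out <- outcome_source(x, y, 1L)
    rec <<- dplyr::bind_rows(rec, tibble::tibble(
      patient_id = nrow(rec) + 1L, stage = 1L, cohort = cohort,
      x = x, y = y, dlt = as.integer(out$dlt), eff = as.integer(out$eff),
      alpha = alpha, truncated = truncated))
  }
  post <- NULL
  for (c1 in seq_len(config$C1)) {
    if (c1 == 1) {
      observe(config$start_dose[1], config$start_dose[2], 1L, NA_real_, FALSE)
      observe(config$start_dose[1], config$start_dose[2], 1L, NA_real_, FALSE)
    } else {
      al <- ewoc_alpha(config, c1)
      n <- nrow(rec)
      if (c1 %% 2 == 0) {
        # first patient: new x given previous cohort's first-patient y
        y_fix <- rec$y[n - 1L]
        x_new <- conditional_mtd_percentile(post, y_fix, "Y", al, config$theta_T)
        observe(as.numeric(x_new), y_fix, c1, al, attr(x_new, "truncated"))
        x_fix <- rec$x[n]
        y_new <- conditional_mtd_percentile(post, x_fix, "X", al, config$theta_T)
        observe(x_fix, as.numeric(y_new), c1, al, attr(y_new, "truncated"))
      } else {
        x_fix <- rec$x[n - 1L]
        y_new <- conditional_mtd_percentile(post, x_fix, "X", al, config$theta_T)
        observe(x_fix, as.numeric(y_new), c1, al, attr(y_new, "truncated"))
        y_fix <- rec$y[n]
        x_new <- conditional_mtd_percentile(post, y_fix, "Y", al, config$theta_T)
        observe(as.numeric(x_new), y_fix, c1, al, attr(x_new, "truncated"))
      }
    }
    post <- fit_tox(rec, tox_prior_spec, config)
    stop_now <- stage1_safety_stop(post, config$theta_T, config$delta_theta1,
                                   config$excess_tox_margin)
    log <- dplyr::bind_rows(log, tibble::tibble(
      cohort = c1, alpha = ewoc_alpha(config, c1), safety_stop = stop_now))
    if (stop_now)
      return(list(records = rec, posterior = post, stopped = TRUE,
                  cohort_log = log))
  }
  list(records = rec, posterior = post, stopped = FALSE, cohort_log = log)
}

#' Estimate the MTD curve from the stage-I toxicity posterior
#'
#' Builds the curve from the coordinatewise posterior medians of
#' `(rho00, rho10, rho01, alpha3)`.
#'
#' @param post A `tox_posterior`.
#' @param config A [design_config()] (supplies `theta_T`).
#' @return An [mtd_curve()] (its domain may be empty).
#' @export
estimate_mtd_curve <- function(post, config) {
  d <- post$draws
  med <- lapply(d[c("rho00", "rho01", "rho10", "alpha3")], stats::median)
  # medians preserve rho00 <= min(rho01, rho10) for each draw but not jointly;
  # nudge inside the valid region if the joint medians land outside
  m00 <- min(med$rho00, min(med$rho01, med$rho10) * (1 - 1e-9))
  mtd_curve(tox_params(m00, med$rho01, med$rho10, med$alpha3), config$theta_T)
}

#' Standardized efficacy density along the MTD curve
#'
#' Normalizes a (strictly positive) plug-in efficacy curve over the curve's
#' `x` domain so it integrates to one; the result drives response-adaptive
#' randomization.
#'
#' @param eff_curve Function `x -> estimated efficacy` (from
#'   [plugin_eff_curve()]).
#' @param domain Length-2 numeric: the curve's `x` domain.
#' @return A `curve_density`: list with `fn` (density), `domain`, `norm_const`
#'   and `max_density`.
#' @export
standardized_density <- function(eff_curve, domain) {
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  grid <- seq(domain[1], domain[2], length.out = 512)
  vals <- eff_curve(grid)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals[-c(1L, length(vals))] <= 0))
    stop("efficacy curve must be strictly positive on the domain ",
         "(zeros are tolerated at the endpoints only)")
  Z <- stats::integrate(eff_curve, domain[1], domain[2],
                        rel.tol = 1e-10)$value
  fn <- function(x) eff_curve(x) / Z
  structure(list(fn = fn, domain = domain, norm_const = Z,
                 max_density = max(vals) / Z * 1.000001),
            class = "curve_density")
}

#' Rejection-sample dose combinations from the standardized density
#'
#' Uniform proposal over the curve's `x` domain with acceptance ratio
#' `density / max density`; accepted `x` values are mapped onto the curve.
#'
#' @param density A `curve_density` from [standardized_density()].
#' @param curve The [mtd_curve()] the density lives on.
#' @param m Number of combinations to draw.
#' @return Tibble with columns `x`, `y` of `m` on-curve combinations.
#' @export
sample_doses_rejection <- function(density, curve, m) {
  dom <- density$domain
  xs <- numeric(0)
  tries <- 0L
  while (length(xs) < m) {
    n_prop <- max(2L * (m - length(xs)), 16L)
    prop <- stats::runif(n_prop, dom[1], dom[2])
    acc <- stats::runif(n_prop) < density$fn(prop) / density$max_density
    xs <- c(xs, prop[acc])
    tries <- tries + n_prop
    if (tries > 1e6 && length(xs) / tries < 1e-3)
      stop("rejection sampler acceptance rate < 1e-3; ",
           "the proposal density looks inconsistent with its maximum")
  }
  curve_points(curve, xs[seq_len(m)])
}

#' Futility stopping rule
#'
#' Stop when even the best point on the estimated MTD curve has posterior
#' exceedance probability `P(pi_E2 > p0 | D)` below `delta_0`. Applies only
#' after the stage-II run-in.
#'
#' @param post An `eff_posterior`.
#' @param curve The estimated [mtd_curve()].
#' @param config A [design_config()].
#' @return Logical.
#' @export
futility_stop <- function(post, curve, config) {
  g <- decision_grid(post, curve, config)
  max(g$exceed) < config$delta_0
}

#' Stage-II safety stopping rule
#'
#' With `k` DLTs among `n` patients (pooled over both stages by default), the
#' DLT rate gets a Jeffreys `Beta(0.5, 0.5)` prior; stop when the posterior
#' probability that the rate exceeds `theta_T + margin` is above
#' `delta_theta2`.
#'
#' @param all_records Patient records (columns `stage`, `dlt`).
#' @param config A [design_config()].
#' @return Logical.
#' @export
stage2_safety_stop <- function(all_records, config) {
  rec <- if (config$safety2_pool) all_records
         else all_records[all_records$stage == 2L, , drop = FALSE]
  n <- nrow(rec); k <- sum(rec$dlt)
  if (n == 0) return(FALSE)
  surv <- stats::pbeta(config$theta_T + config$excess_tox_margin,
                       0.5 + k, 0.5 + n - k, lower.tail = FALSE)
  surv > config$delta_theta2
}

# exceedance probabilities on the decision grid along the curve
decision_grid <- function(post, curve, config) {
  pts <- equally_spaced_points(curve, config$grid_size,
                               spacing = config$spacing)
  pts$exceed <- prob_eff_exceeds(post, pts$x, pts$y, config$p0)
  pts
}

#' Final test and optimal dose recommendation
#'
#' Evaluates the posterior exceedance probability on the decision grid along
#' the estimated MTD curve; the null (no tolerable combination beats the
#' standard of care) is rejected when the maximum exceeds `delta_u`, and the
#' argmax combination is recommended. Ties break to the lowest `x`.
#'
#' @param post An `eff_posterior`.
#' @param curve The estimated [mtd_curve()].
#' @param config A [design_config()].
#' @return List with `reject` (logical), `opt_x`, `opt_y`, `max_exceed`, and
#'   the `grid` tibble.
#' @export
final_test <- function(post, curve, config) {
  g <- decision_grid(post, curve, config)
  i <- which(g$exceed == max(g$exceed))[1] # lowest x wins ties
  list(reject = max(g$exceed) > config$delta_u,
       opt_x = g$x[i], opt_y = g$y[i], max_exceed = max(g$exceed), grid = g)
}

fit_mac_cfg <- function(data_s1, data_s2, prior, config) {
  s <- config$sampler
  fit_mac(data_s1, data_s2, prior, n_draws = s$n_draws, chains = s$chains,
          warmup = s$warmup, ess_floor = s$ess_floor)
}

#' Run stage II: run-in, adaptive randomization, and final analysis
#'
#' Allocates the run-in cohort at equally spaced curve points, then `C2`
#' cohorts of `m2` patients drawn from the standardized plug-in efficacy
#' density, refitting the MAC efficacy model after every cohort. The stage-II
#' safety rule is checked after every cohort and the futility rule after
#' every post-run-in fit; otherwise the trial ends with the final test.
#'
#' @param config A [design_config()].
#' @param curve Estimated [mtd_curve()] from stage I.
#' @param data_s1 Stage-I patient records (their efficacy outcomes enter the
#'   MAC likelihood from the first stage-II fit on).
#' @param outcome_source Function `(x, y, stage) -> list(dlt, eff)`.
#' @param eff_prior_spec An [eff_prior()] (carries `omega`).
#' @return A `trial_result` (see [run_trial()]).
#' @export
run_stage2 <- function(config, curve, data_s1, outcome_source,
                       eff_prior_spec = eff_prior()) {
  if (!length(curve$x_domain))
    return(trial_result("no_tolerable_set", data_s1, curve, config))
  rec2 <- empty_records()
  observe <- function(pts, cohort) {
    for (i in seq_len(nrow(pts))) {
      out <- outcome_source(pts$x[i], pts$y[i], 2L)
      rec2 <<- dplyr::bind_rows(rec2, tibble::tibble(
        patient_id = nrow(data_s1) + nrow(rec2) + 1L, stage = 2L,
        cohort = cohort, x = pts$x[i], y = pts$y[i],
        dlt = as.integer(out$dlt), eff = as.integer(out$eff),
        alpha = NA_real_, truncated = FALSE))
    }
  }
  run_in <- equally_spaced_points(curve, config$n2, spacing = config$spacing)
  observe(run_in, 0L)
  all_rec <- function() dplyr::bind_rows(data_s1, rec2)
  if (stage2_safety_stop(all_rec(), config))
    return(trial_result("stopped_safety_s2", all_rec(), curve, config))
  post <- fit_mac_cfg(data_s1, rec2, eff_prior_spec, config)
  if (futility_stop(post, curve, config))
    return(trial_result("stopped_futility", all_rec(), curve, config,
                        eff_post = post))
  for (c2 in seq_len(config$C2)) {
    dens <- standardized_density(plugin_eff_curve(post, curve),
                                 curve$x_domain)
    pts <- sample_doses_rejection(dens, curve, config$m2)
    observe(pts, c2)
    if (stage2_safety_stop(all_rec(), config))
      return(trial_result("stopped_safety_s2", all_rec(), curve, config,
                          eff_post = post))
    post <- fit_mac_cfg(data_s1, rec2, eff_prior_spec, config)
    if (futility_stop(post, curve, config))
      return(trial_result("stopped_futility", all_rec(), curve, config,
                          eff_post = post))
  }
  ft <- final_test(post, curve, config)
  trial_result(if (ft$reject) "reject_H0" else "accept_H0",
               all_rec(), curve, config, eff_post = post, test = ft)
}

trial_result <- function(decision, records, curve, config, eff_post = NULL,
                         test = NULL, stage1_log = NULL) {
  structure(list(decision = decision, records = records, curve = curve,
                 config = config,
                 opt_x = if (!is.null(test) && test$reject) test$opt_x else NA_real_,
                 opt_y = if (!is.null(test) && test$reject) test$opt_y else NA_real_,
                 max_exceed = if (!is.null(test)) test$max_exceed else NA_real_,
                 exch_weight = if (!is.null(eff_post)) eff_post$exch_weight
                               else NA_real_,
                 grid = if (!is.null(test)) test$grid else NULL,
                 stage1_log = stage1_log,
                 n_enrolled = nrow(records),
                 dlt_count = sum(records$dlt)),
            class = "trial_result")
}

#' Run a complete two-stage trial
#'
#' Executes the full design: stage-I EWOC escalation, MTD-curve estimation
#' from the stage-I posterior medians, and stage-II response-adaptive
#' randomization with EXNEX borrowing, ending in one of six terminal
#' decisions: `reject_H0`, `accept_H0`, `stopped_futility`,
#' `stopped_safety_s1`, `stopped_safety_s2`, or `no_tolerable_set`.
#'
#' @param config A [design_config()].
#' @param outcome_source Function `(x, y, stage) -> list(dlt, eff)`; use
#'   [outcome_source()] to build one from a [scenario_truth()].
#' @param seed Integer master seed.
#' @param tox_prior_spec,eff_prior_spec Prior specifications.
#' @return A `trial_result`.
#' @export
run_trial <- function(config, outcome_source, seed = NULL,
                      tox_prior_spec = tox_prior(),
                      eff_prior_spec = eff_prior()) {
  if (!is.null(seed)) set.seed(derive_seed(seed, "stage1"))
  s1 <- run_stage1(config, outcome_source, tox_prior_spec)
  if (s1$stopped) {
    res <- trial_result("stopped_safety_s1", s1$records, NULL, config,
                        stage1_log = s1$cohort_log)
    return(res)
  }
  curve <- estimate_mtd_curve(s1$posterior, config)
  if (!is.null(seed)) set.seed(derive_seed(seed, "stage2"))
  res <- run_stage2(config, curve, s1$records, outcome_source,
                    eff_prior_spec)
  res$stage1_log <- s1$cohort_log
  res
}

# deterministic per-(master, label/index) seed derivation; stays < 2^31
derive_seed <- function(master, label) {
  h <- if (is.character(label)) sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
       else as.numeric(label) * 1000003
  as.integer((as.numeric(master) %% 2147483629 + h * 7919 + 12345) %% 2147483629)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Two-stage trial result:", x$decision, "\n")
  cat("  patients enrolled:", x$n_enrolled, " DLTs:", x$dlt_count, "\n")
  if (!is.na(x$opt_x))
    cat(sprintf("  recommended combination: (%.3f, %.3f), max exceedance %.3f\n",
                x$opt_x, x$opt_y, x$max_exceed))
  invisible(x)
}
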