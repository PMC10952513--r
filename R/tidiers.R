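#' Tidy posterior and result objects
#'
#' `tidy()` returns one row per parameter with posterior mean, median, SD and
#' central 95% interval; `glance()` returns a one-row summary with sampler
#' diagnostics.
#'
#' @param x A `tox_posterior`, `eff_posterior`, `trial_result` or
#'   `trial_sims`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

tidy_draws <- function(draws, pars) {
  purrr::map_dfr(pars, function(p) {
    v <- draws[[p]]
    tibble::tibble(parameter = p, mean = mean(v), median = stats::median(v),
                   sd = stats::sd(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)))
  })
}

#' @rdname tidiers
#' @export
tidy.tox_posterior <- function(x, ...) {
  tidy_draws(x$draws, c("rho00", "rho01", "rho10", "alpha3"))
}

#' @rdname tidiers
#' @export
glance.tox_posterior <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws), n_obs = x$n_obs,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE),
                 flagged = x$flagged)
}

#' @rdname tidiers
#' @export
tidy.eff_posterior <- function(x, ...) {
  tidy_draws(x$draws, c("beta01", "beta11", "beta21", "beta31",
                        "beta02", "beta12", "beta22", "beta32",
                        "mu1", "mu2", "tau1", "tau2", "xi", "zeta"))
}

#' @rdname tidiers
#' @export
glance.eff_posterior <- function(x, ...) {
  tibble::tibble(n_draws = nrow(x$draws), n_obs = x$n_obs,
                 omega = x$omega, exch_weight = x$exch_weight,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE),
                 flagged = x$flagged)
}

#' @rdname tidiers
#' @export
tidy.trial_result <- function(x, ...) x$records

#' @rdname tidiers
#' @export
glance.trial_result <- function(x, ...) {
  tibble::tibble(decision = x$decision, n_enrolled = x$n_enrolled,
                 dlt_count = x$dlt_count, opt_x = x$opt_x, opt_y = x$opt_y,
                 max_exceed = x$max_exceed, exch_weight = x$exch_weight)
}

#' @rdname tidiers
#' @export
tidy.trial_sims <- function(x, ...) x$summary

#' @rdname tidiers
#' @export
glance.trial_sims <- function(x, ...) {
  oc <- operating_characteristics(x)
  tibble::as_tibble(oc)
}

#' Plot the posterior MTD curve with uncertainty band
#'
#' Draws the curve at the posterior medians plus a pointwise 90% band from
#' the posterior draws.
#'
#' @param object A `tox_posterior`.
#' @param theta_T Target DLT probability.
#' @param n Grid size.
#' @param ... Unused.
#' @export
autoplot.tox_posterior <- function(object, theta_T = 0.33, n = 101, ...) {
  d <- object$draws
  xs <- seq(0, 1, length.out = n)
  ys <- vapply(seq_len(nrow(d)), function(i) {
    p <- tox_params(d$rho00[i], d$rho01[i], d$rho10[i], d$alpha3[i])
    mtd_y_given_x(xs, p, theta_T, outside = "raw")
  }, numeric(n))
  df <- tibble::tibble(
    x = xs,
    med = apply(ys, 1, stats::median),
    lo = apply(ys, 1, stats::quantile, 0.05),
    hi = apply(ys, 1, stats::quantile, 0.95))
  df <- df[df$med >= -0.2 & df$med <= 1.2, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$med)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$lo, 0),
                                      ymax = pmin(.data$hi, 1)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "standardized dose of agent X",
                  y = "standardized dose of agent Y",
                  title = "Posterior MTD curve (median and 90% band)")
}

#' Plot the exceedance profile along the estimated MTD curve
#'
#' @param object An `eff_posterior`.
#' @param curve The estimated [mtd_curve()].
#' @param p0 Reference efficacy rate.
#' @param n Grid size.
#' @param ... Unused.
#' @export
autoplot.eff_posterior <- function(object, curve, p0 = 0.15, n = 101, ...) {
  pts <- equally_spaced_points(curve, n)
  pts$exceed <- prob_eff_exceeds(object, pts$x, pts$y, p0)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$exceed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "standardized dose of agent X (along MTD curve)",
                  y = sprintf("P(stage-II efficacy > %.2f | data)", p0),
                  title = "Posterior exceedance along the MTD curve")
}
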