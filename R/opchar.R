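#' Simulate replicated trials
#'
#' Runs `J` independent trials of the full two-stage design under a scenario
#' truth. Per-trial seeds are derived deterministically from the master seed
#' and the trial index, so results are reproducible and independent of
#' execution order, and changing `J` does not reshuffle earlier trials.
#'
#' @param config A [design_config()].
#' @param truth A [scenario_truth()].
#' @param J Number of replicate trials.
#' @param seed Master seed.
#' @param tox_prior_spec,eff_prior_spec Prior specifications.
#' @return A `trial_sims` object: list with `results` (list of
#'   `trial_result`), `summary` (one row per trial), `truth`, `config`, `J`,
#'   `seed`.
#' @export
simulate_trials <- function(config, truth, J, seed = 1,
                            tox_prior_spec = tox_prior(),
                            eff_prior_spec = eff_prior()) {
  stopifnot(J >= 1)
  src <- outcome_source(truth)
  results <- vector("list", J)
  for (j in seq_len(J)) {
    res <- tryCatch(
      run_trial(config, src, seed = derive_seed(seed, j),
                tox_prior_spec = tox_prior_spec,
                eff_prior_spec = eff_prior_spec),
      error = function(e) structure(list(decision = "error",
                                         message = conditionMessage(e)),
                                    class = "trial_error"))
    results[[j]] <- res
  }
  structure(list(results = results, summary = summarize_trials(results),
                 truth = truth, config = config, J = J, seed = seed),
            class = "trial_sims")
}

summarize_trials <- function(results) {
  purrr::map_dfr(seq_along(results), function(j) {
    r <- results[[j]]
    if (inherits(r, "trial_error"))
      return(tibble::tibble(trial = j, decision = "error", opt_x = NA_real_,
                            opt_y = NA_real_, max_exceed = NA_real_,
                            exch_weight = NA_real_, n_enrolled = NA_integer_,
                            dlt_count = NA_integer_, n_stage2 = NA_integer_,
                            dlt_stage2 = NA_integer_))
    s2 <- r$records[r$records$stage == 2L, , drop = FALSE]
    tibble::tibble(trial = j, decision = r$decision, opt_x = r$opt_x,
                   opt_y = r$opt_y, max_exceed = r$max_exceed,
                   exch_weight = r$exch_weight,
                   n_enrolled = r$n_enrolled, dlt_count = r$dlt_count,
                   n_stage2 = nrow(s2), dlt_stage2 = sum(s2$dlt))
  })
}

#' Rejection rate (power / type-I error) over simulated trials
#'
#' Fraction of trials whose final test rejected the null. Trials stopped
#' early for futility or safety never reach the final test and count as
#' non-rejections; `conditional = TRUE` instead restricts the denominator to
#' trials that completed.
#'
#' @param sims A `trial_sims` (or its `summary` tibble).
#' @param conditional Condition on trial completion (default `FALSE`).
#' @return Proportion in \[0, 1\].
#' @export
estimate_power <- function(sims, conditional = FALSE) {
  s <- sims_summary(sims)
  if (conditional) {
    done <- s$decision %in% c("reject_H0", "accept_H0")
    if (!any(done)) return(NA_real_)
    mean(s$decision[done] == "reject_H0")
  } else mean(s$decision == "reject_H0")
}

sims_summary <- function(sims) {
  if (inherits(sims, "trial_sims")) sims$summary else sims
}

#' Proportion of correct recommendations
#'
#' Among rejecting trials, the fraction whose recommended combination has
#' TRUE stage-II efficacy probability above `p0`.
#'
#' @param sims A `trial_sims`.
#' @param truth A [scenario_truth()] (defaults to the one stored in `sims`).
#' @param p0 Reference rate (defaults to the design's).
#' @return Proportion, or `NA` when no trial made a recommendation.
#' @export
correct_recommendation_rate <- function(sims, truth = sims$truth,
                                        p0 = sims$config$p0) {
  s <- sims_summary(sims)
  rec <- s[s$decision == "reject_H0" & !is.na(s$opt_x), , drop = FALSE]
  if (!nrow(rec)) return(NA_real_)
  mean(prob_eff(rec$opt_x, rec$opt_y, truth$eff_s2) > p0)
}

#' Stage-II allocation to truly efficacious combinations
#'
#' Fraction of stage-II patients (pooled over trials) treated at combinations
#' whose true stage-II efficacy probability exceeds `p0`.
#'
#' @inheritParams correct_recommendation_rate
#' @return Proportion in \[0, 1\].
#' @export
allocation_above_p0 <- function(sims, truth = sims$truth,
                                p0 = sims$config$p0) {
  rec <- purrr::map_dfr(sims$results, function(r) {
    if (inherits(r, "trial_error")) return(NULL)
    r$records[r$records$stage == 2L, c("x", "y")]
  })
  if (!nrow(rec)) return(NA_real_)
  mean(prob_eff(rec$x, rec$y, truth$eff_s2) > p0)
}

#' Stopping, safety and sample-size summaries
#'
#' @param sims A `trial_sims`.
#' @param theta_T,margin Excess-DLT reporting threshold `theta_T + margin`.
#' @return A one-row tibble: futility / safety / no-tolerable-set stop rates,
#'   mean DLT rate overall and in stage II, fraction of trials with DLT rate
#'   above `theta_T + margin`, and mean realized sample size.
#' @export
stopping_and_safety_summaries <- function(sims,
                                          theta_T = sims$config$theta_T,
                                          margin = sims$config$excess_tox_margin) {
  s <- sims_summary(sims)
  ok <- s$decision != "error"
  dlt_rate <- s$dlt_count[ok] / s$n_enrolled[ok]
  s2rate <- ifelse(s$n_stage2[ok] > 0, s$dlt_stage2[ok] / s$n_stage2[ok], NA)
  tibble::tibble(
    futility_stop_rate = mean(s$decision == "stopped_futility"),
    safety_stop_rate = mean(s$decision %in%
                              c("stopped_safety_s1", "stopped_safety_s2")),
    no_tolerable_set_rate = mean(s$decision == "no_tolerable_set"),
    mean_dlt_rate = mean(dlt_rate),
    mean_dlt_rate_stage2 = mean(s2rate, na.rm = TRUE),
    frac_trials_excess_dlt = mean(dlt_rate > theta_T + margin),
    mean_sample_size = mean(s$n_enrolled[ok]))
}

#' Operating characteristics of the design under a scenario
#'
#' One-stop summary combining the rejection rate (unconditional and
#' conditional on completion), correct-recommendation rate, stage-II
#' allocation quality, stopping rates, and safety summaries.
#'
#' @param sims A `trial_sims`.
#' @return A `duocomb_oc` object (one-row tibble subclass).
#' @export
operating_characteristics <- function(sims) {
  out <- dplyr::bind_cols(
    tibble::tibble(
      label = sims$truth$label, hypothesis = sims$truth$hypothesis,
      J = sims$J,
      reject_rate = estimate_power(sims),
      reject_rate_completed = estimate_power(sims, conditional = TRUE),
      correct_recommendation_rate = correct_recommendation_rate(sims),
      allocation_above_p0 = allocation_above_p0(sims)),
    stopping_and_safety_summaries(sims))
  class(out) <- c("duocomb_oc", class(out))
  out
}

#' @export
autoplot.trial_sims <- function(object, ...) {
  s <- object$summary
  rec <- s[!is.na(s$opt_x), , drop = FALSE]
  curve <- NULL
  for (r in object$results)
    if (!inherits(r, "trial_error") && !is.null(r$curve)) { curve <- r$curve; break }
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$opt_x, y = .data$opt_y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "standardized dose of agent X",
                  y = "standardized dose of agent Y",
                  title = "Recommended optimal dose combinations")
  if (!is.null(curve) && length(curve$x_domain)) {
    dom <- curve$x_domain
    df <- curve_points(curve, seq(dom[1], dom[2], length.out = 200))
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                inherit.aes = FALSE, colour = "grey40")
  }
  p
}
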