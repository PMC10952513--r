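#' Scenario truth for simulation
#'
#' Bundles the true dose-toxicity parameters (shared by both stages), the
#' stage-specific true dose-efficacy parameters, and labels. Under the
#' alternative, stage-II efficacy profiles are calibrated so their maximum
#' over the true MTD curve equals `p0 + 0.25`; under the null it equals `p0`.
#'
#' @param tox A [tox_params()] object (same toxicity profile in both stages).
#' @param eff_s1,eff_s2 [eff_params()] for stages 1 and 2.
#' @param hypothesis `"H1"` or `"H0"`.
#' @param label Free-text scenario label.
#' @param provenance `"calibrated"` (default) or `"paper_supplement"` when
#'   parameter values are supplied verbatim from an external table (the
#'   calibration invariants are then not implied).
#' @return A `scenario_truth` object.
#' @export
scenario_truth <- function(tox, eff_s1, eff_s2, hypothesis = c("H1", "H0"),
                           label = "custom", provenance = "calibrated") {
  hypothesis <- match.arg(hypothesis)
  stopifnot(inherits(tox, "tox_params"), inherits(eff_s1, "eff_params"),
            inherits(eff_s2, "eff_params"))
  structure(list(tox = tox, eff_s1 = eff_s1, eff_s2 = eff_s2,
                 hypothesis = hypothesis, label = label,
                 provenance = provenance),
            class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("Scenario", x$label, sprintf("(%s, %s)\n", x$hypothesis, x$provenance))
  cat(sprintf("  tox: rho00=%.3g rho01=%.3g rho10=%.3g alpha3=%.3g\n",
              x$tox$rho00, x$tox$rho01, x$tox$rho10, x$tox$alpha3))
  for (s in 1:2) {
    p <- x[[paste0("eff_s", s)]]
    cat(sprintf("  eff stage %d: beta0=%.3g beta1=%.3g beta2=%.3g beta3=%.3g\n",
                s, p$beta0, p$beta1, p$beta2, p$beta3))
  }
  invisible(x)
}

# composite true efficacy along the curve, x -> pi_E(x, y(x))
composite_eff <- function(curve, params) {
  function(x) prob_eff(x, mtd_y_given_x(x, curve$params, curve$theta_T,
                                        outside = "raw"), params)
}

composite_argmax <- function(curve, params, n_grid = 1001) {
  dom <- curve$x_domain
  xs <- seq(dom[1], dom[2], length.out = n_grid)
  v <- composite_eff(curve, params)(xs)
  list(x = xs[which.max(v)], value = max(v), grid_x = xs, grid_v = v)
}

#' Calibrate a stage-II dose-efficacy profile on an MTD curve
#'
#' Solves for [eff_params()] such that the composite efficacy
#' `x -> pi_E(x, y(x))` along the curve attains its maximum `peak_prob` at
#' `peak_x`. The efficacy surface is monotone in each dose, so interior peaks
#' ("humped" profiles) only arise through the composition with the decreasing
#' curve `y(x)`. On the curve the identity
#' `alpha1 x + alpha2 y + alpha3 x y = const` makes the composite linear
#' predictor an element of the 3-dimensional space spanned by
#' `{1, x, y(x)}`; an interior hump corresponds to a negative effective
#' `y(x)` coefficient (the composite is then strictly concave), which is
#' always realizable with valid positive main effects by taking the
#' interaction `beta3` large enough. The calibration solves the linear system
#' pinning zero slope and level `peak_prob` at `peak_x` and level
#' `shape$floor_prob` at the domain end farther from the peak. At (or within
#' 2% of) a domain endpoint the profile is instead made monotone toward that
#' end with driving slope `shape$slope`.
#'
#' @param curve An [mtd_curve()] with non-empty domain.
#' @param peak_x Location of the composite maximum (in the curve's domain).
#' @param peak_prob Maximum efficacy probability on the curve.
#' @param shape Named list of shape controls: `floor_prob` (efficacy at the
#'   far end of the curve for interior peaks, default 0.05), `slope` (driving
#'   log-scale main effect for boundary peaks, default `log(3)`), `beta3`
#'   (interaction used by boundary peaks, default 0).
#' @param tol Calibration tolerance on the achieved maximum probability.
#' @return An [eff_params()] whose composite maximum is `peak_prob` at
#'   `peak_x` (checked on a 1001-point grid).
#' @export
calibrate_eff_profile <- function(curve, peak_x, peak_prob,
                                  shape = list(floor_prob = 0.05,
                                               slope = log(3), beta3 = 0),
                                  tol = 0.005) {
  dom <- curve$x_domain
  if (!length(dom)) stop("curve misses the unit square")
  if (peak_x < dom[1] - 1e-9 || peak_x > dom[2] + 1e-9)
    stop("peak_x outside the curve domain")
  slope <- shape$slope %||% log(3)
  beta3 <- shape$beta3 %||% 0
  floor_prob <- shape$floor_prob %||% 0.05
  edge <- 0.02 * diff(dom)
  y_at <- function(x) mtd_y_given_x(x, curve$params, curve$theta_T, "raw")
  if (peak_x >= dom[2] - edge) {
    # X-driven increasing profile peaking at the right end
    p <- eff_params(0, slope, -10, beta3)
    lin_peak <- exp(slope) * dom[2] + exp(-10) * y_at(dom[2]) +
      beta3 * dom[2] * y_at(dom[2])
    p$beta0 <- stats::qlogis(peak_prob) - lin_peak
  } else if (peak_x <= dom[1] + edge) {
    # Y-driven decreasing profile peaking at the left end
    p <- eff_params(0, -10, slope, beta3)
    lin_peak <- exp(-10) * dom[1] + exp(slope) * y_at(dom[1]) +
      beta3 * dom[1] * y_at(dom[1])
    p$beta0 <- stats::qlogis(peak_prob) - lin_peak
  } else {
    p <- calibrate_interior_hump(curve, peak_x, peak_prob, floor_prob)
  }
  chk <- composite_argmax(curve, p)
  if (abs(chk$value - peak_prob) > tol ||
      abs(chk$x - peak_x) > max(0.02 * diff(dom), 2 * diff(dom) / 1000))
    stop(sprintf(paste0("calibration failed: achieved max %.4f at x = %.3f ",
                        "(wanted %.3f at %.3f); adjust the shape controls"),
                 chk$value, chk$x, peak_prob, peak_x))
  p
}

# solve for a humped composite profile in the effective on-curve basis
# {1, x, y(x)} and lift back to valid (beta0, beta1, beta2, beta3)
calibrate_interior_hump <- function(curve, peak_x, peak_prob, floor_prob) {
  a <- tox_alphas(curve$params)
  if (a$a3 <= 0)
    stop("infeasible interior peak: with no toxicity interaction the curve ",
         "is a straight line and the composite efficacy of this monotone ",
         "surface cannot attain a strict interior maximum with a floor ",
         "constraint; move peak_x to a domain endpoint or use a curve with ",
         "alpha3 > 0")
  dom <- curve$x_domain
  y_at <- function(x) mtd_y_given_x(x, curve$params, curve$theta_T, "raw")
  far <- if (abs(peak_x - dom[1]) > abs(peak_x - dom[2])) dom[1] else dom[2]
  yp <- curve_dydx(curve, peak_x)
  # g(x) = u + b x + c y(x): g'(peak)=0, g(peak)=qlogis(peak_prob),
  # g(far)=qlogis(floor_prob)
  M <- rbind(c(0, 1, yp),
             c(1, peak_x, y_at(peak_x)),
             c(1, far, y_at(far)))
  sol <- solve(M, c(0, stats::qlogis(peak_prob), stats::qlogis(floor_prob)))
  u <- sol[1]; b <- sol[2]; cc <- sol[3]
  if (cc >= 0)
    stop("infeasible interior peak: the requested levels do not produce a ",
         "concave composite profile; lower floor_prob or move peak_x")
  # lift: e1 = b + beta3*alpha1/alpha3, e2 = cc + beta3*alpha2/alpha3 must be
  # positive; the on-curve identity absorbs the intercept shift
  A <- stats::qlogis(curve$theta_T) - a$a0
  beta3 <- 1.5 * max(1e-6, -b * a$a3 / a$a1, -cc * a$a3 / a$a2)
  e1 <- b + beta3 * a$a1 / a$a3
  e2 <- cc + beta3 * a$a2 / a$a3
  beta0 <- u - beta3 * A / a$a3
  eff_params(beta0, log(e1), log(e2), beta3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage-I efficacy profile at a chosen agreement level
#'
#' Builds the stage-1 true profile from the calibrated stage-2 profile:
#' complete agreement (`"CA"`) copies it; partial agreement (`"PA"`) keeps the
#' same location of the maximum but shifts the probabilities (via the
#' intercept) so the composite profiles differ by at least 0.05 somewhere;
#' complete disagreement (`"CD"`) recalibrates the peak at the opposite end of
#' the curve domain.
#'
#' @param eff_s2 Calibrated stage-2 [eff_params()].
#' @param curve The true [mtd_curve()].
#' @param level `"CA"`, `"PA"` or `"CD"`.
#' @param shift_prob Probability shift of the peak for `"PA"` (default 0.1,
#'   downward when the stage-2 peak is at least 0.25, upward otherwise).
#' @return An [eff_params()] for stage 1.
#' @export
make_agreement_variant <- function(eff_s2, curve, level = c("CA", "PA", "CD"),
                                   shift_prob = 0.1) {
  level <- match.arg(level)
  if (level == "CA") return(eff_s2)
  am <- composite_argmax(curve, eff_s2)
  if (level == "PA") {
    target <- if (am$value >= 0.25) am$value - shift_prob else am$value + shift_prob
    p <- eff_s2
    p$beta0 <- eff_s2$beta0 + stats::qlogis(target) - stats::qlogis(am$value)
    return(p)
  }
  # mirror the peak location across the middle of the curve domain
  dom <- curve$x_domain
  opposite <- dom[1] + dom[2] - am$x
  calibrate_eff_profile(curve, opposite, am$value)
}

#' Generate Bernoulli trial outcomes under a scenario truth
#'
#' DLT and efficacy outcomes are independent Bernoulli draws from the true
#' dose-toxicity model (common to both stages) and the stage-specific true
#' dose-efficacy model.
#'
#' @param truth A [scenario_truth()].
#' @param x,y Standardized doses.
#' @param stage 1 or 2.
#' @return List with integer `dlt` and `eff`.
#' @export
generate_outcomes <- function(truth, x, y, stage) {
  pe_params <- if (stage == 1L) truth$eff_s1 else truth$eff_s2
  list(dlt = stats::rbinom(1L, 1L, prob_dlt(x, y, truth$tox)),
       eff = stats::rbinom(1L, 1L, prob_eff(x, y, pe_params)))
}

#' Outcome source closure for the trial engine
#'
#' @param truth A [scenario_truth()].
#' @return A function `(x, y, stage) -> list(dlt, eff)` drawing from the
#'   current R random number stream.
#' @export
outcome_source <- function(truth) {
  function(x, y, stage) generate_outcomes(truth, x, y, stage)
}

#' Default simulation scenarios
#'
#' Two dose-toxicity profiles whose MTD curves pass through the standardized
#' anchor (0.33, 0.5) at `theta_T` (mirroring the 15/75 mg/m2 combination the
#' toxicity priors are centered on), each combined with two stage-II efficacy
#' profiles placing the most efficacious tolerable combination at opposite
#' ends of the curve. Profiles are calibrated so the maximum true stage-II
#' efficacy on the curve is `p0 + effect_size` under `"H1"` and `p0` under
#' `"H0"`.
#'
#' @param tox_profile 1 (wide curve spanning most of the square) or 2
#'   (curve confined to the lower-left region).
#' @param eff_profile 1 (peak at the high-x end) or 2 (peak at the low-x end).
#' @param hypothesis `"H1"` or `"H0"`.
#' @param agreement `"CA"`, `"PA"` or `"CD"` stage-I profile.
#' @param theta_T,p0,effect_size Design constants used in the calibration.
#' @return A [scenario_truth()].
#' @export
default_scenario <- function(tox_profile = 1, eff_profile = 1,
                             hypothesis = c("H1", "H0"),
                             agreement = c("CA", "PA", "CD"),
                             theta_T = 0.33, p0 = 0.15, effect_size = 0.25) {
  hypothesis <- match.arg(hypothesis)
  agreement <- match.arg(agreement)
  tox <- default_tox_profile(tox_profile, theta_T)
  curve <- mtd_curve(tox, theta_T)
  # humped profiles with the most efficacious tolerable combination near
  # opposite ends of the curve; the null variant is the same shape with the
  # intercept shifted so the on-curve maximum drops from p0 + effect_size
  # to p0
  dom <- curve$x_domain
  peak_x <- dom[1] + (if (eff_profile == 1) 0.8 else 0.2) * diff(dom)
  eff_s2 <- calibrate_eff_profile(curve, peak_x, p0 + effect_size)
  if (hypothesis == "H0")
    eff_s2$beta0 <- eff_s2$beta0 + stats::qlogis(p0) -
      stats::qlogis(p0 + effect_size)
  eff_s1 <- make_agreement_variant(eff_s2, curve, agreement)
  scenario_truth(tox, eff_s1, eff_s2, hypothesis,
                 label = sprintf("tox%d-eff%d-%s-%s", tox_profile,
                                 eff_profile, hypothesis, agreement))
}

# Default toxicity profiles, built by solving for the interaction so the MTD
# curve passes through a chosen point. Profile 1 is the harsher one: its true
# curve runs below the (0.33, 0.5) anchor the priors are centered on (the
# anchor combination is supratherapeutic), so safety stops are expected in a
# noticeable fraction of trials. Profile 2 passes through the anchor itself.
default_tox_profile <- function(profile, theta_T = 0.33) {
  # corner probabilities kept in the region the informative prior considers
  # plausible (low corner toxicity, substantial interaction), per the origin
  # of the prior and of the simulation truths in the same investigator team
  spec <- switch(as.character(profile),
                 "1" = list(corners = c(rho00 = 0.08, rho01 = 0.25,
                                        rho10 = 0.25),
                            through = c(0.33, 0.35)),
                 "2" = list(corners = c(rho00 = 0.05, rho01 = 0.20,
                                        rho10 = 0.20),
                            through = c(0.33, 0.50)),
                 stop("tox_profile must be 1 or 2"))
  corners <- spec$corners
  a0 <- stats::qlogis(corners["rho00"])
  a1 <- stats::qlogis(corners["rho10"]) - a0
  a2 <- stats::qlogis(corners["rho01"]) - a0
  x0 <- spec$through[1]; y0 <- spec$through[2]
  a3 <- (stats::qlogis(theta_T) - a0 - a1 * x0 - a2 * y0) / (x0 * y0)
  tox_params(corners["rho00"], corners["rho01"], corners["rho10"],
             unname(a3))
}

#' Serialize / deserialize a scenario as YAML
#'
#' @param truth A [scenario_truth()].
#' @param path File path.
#' @export
write_scenario <- function(truth, path) {
  yaml::write_yaml(list(
    tox = truth$tox[c("rho00", "rho01", "rho10", "alpha3")],
    eff_s1 = truth$eff_s1[c("beta0", "beta1", "beta2", "beta3")],
    eff_s2 = truth$eff_s2[c("beta0", "beta1", "beta2", "beta3")],
    hypothesis = truth$hypothesis, label = truth$label,
    provenance = truth$provenance), path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  o <- yaml::read_yaml(path)
  scenario_truth(do.call(tox_params, o$tox),
                 do.call(eff_params, o$eff_s1),
                 do.call(eff_params, o$eff_s2),
                 o$hypothesis, o$label, o$provenance %||% "calibrated")
}
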