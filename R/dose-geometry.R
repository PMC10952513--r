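#' Standardize a raw dose to the unit interval
#'
#' Doses of the two agents live on different raw scales (e.g., mg/m2), so all
#' modelling is done on standardized doses `(raw - lo) / (hi - lo)` in
#' \[0, 1\]. The combination (0, 0) is the lowest combination available in the
#' trial, not the absence of treatment.
#'
#' @param raw_dose Raw-scale dose (vectorized).
#' @param lo,hi Raw dose bounds, `lo < hi`.
#' @return Standardized dose(s) in \[0, 1\].
#' @examples
#' standardize_dose(15, 10, 25) # cisplatin-style bounds -> 1/3
#' @export
standardize_dose <- function(raw_dose, lo, hi) {
  stopifnot(is.numeric(raw_dose), length(lo) == 1, length(hi) == 1)
  if (!(lo < hi)) stop("dose bounds must satisfy lo < hi (got lo = ", lo,
                       ", hi = ", hi, ")")
  if (any(raw_dose < lo)) stop("raw_dose below lower bound lo = ", lo)
  if (any(raw_dose > hi)) stop("raw_dose above upper bound hi = ", hi)
  (raw_dose - lo) / (hi - lo)
}

#' @rdname standardize_dose
#' @param std_dose Standardized dose in \[0, 1\].
#' @export
destandardize_dose <- function(std_dose, lo, hi) {
  stopifnot(is.numeric(std_dose), lo < hi)
  lo + std_dose * (hi - lo)
}

#' Dose-toxicity parameters on the clinician scale
#'
#' The logistic dose-toxicity surface is parameterized by the DLT
#' probabilities at three corners of the standardized dose square --
#' `rho00` at (0,0), `rho10` at (1,0), `rho01` at (0,1) -- plus a
#' nonnegative logit-scale interaction `alpha3`. The induced slopes
#' `alpha1 = qlogis(rho10) - qlogis(rho00)` and
#' `alpha2 = qlogis(rho01) - qlogis(rho00)` must be positive (toxicity
#' increases with each agent), which is equivalent to
#' `0 < rho00 < min(rho01, rho10) < 1`.
#'
#' @param rho00,rho01,rho10 Corner DLT probabilities.
#' @param alpha3 Interaction on the logit scale, `>= 0`.
#' @return A `tox_params` object (named list).
#' @export
tox_params <- function(rho00, rho01, rho10, alpha3 = 0) {
  stopifnot(length(rho00) == 1, length(rho01) == 1, length(rho10) == 1,
            length(alpha3) == 1)
  if (!(rho00 > 0 && rho00 < 1 && rho01 > 0 && rho01 < 1 &&
        rho10 > 0 && rho10 < 1))
    stop("corner DLT probabilities must lie strictly inside (0, 1)")
  if (rho00 > min(rho01, rho10))
    stop("monotone toxicity requires rho00 <= min(rho01, rho10)")
  if (alpha3 < 0) stop("alpha3 must be nonnegative")
  structure(list(rho00 = unname(rho00), rho01 = unname(rho01),
                 rho10 = unname(rho10), alpha3 = unname(alpha3)),
            class = "tox_params")
}

# internal: natural (alpha) scale coefficients
tox_alphas <- function(params) {
  a0 <- stats::qlogis(params$rho00)
  list(a0 = a0,
       a1 = stats::qlogis(params$rho10) - a0,
       a2 = stats::qlogis(params$rho01) - a0,
       a3 = params$alpha3)
}

#' MTD curve: dose combination locus at the target DLT probability
#'
#' Solve the toxicity surface for the dose of one agent given the other at the
#' target DLT probability `theta_T`. The locus
#' `y(x) = (A - alpha1 x) / (alpha2 + alpha3 x)` with
#' `A = qlogis(theta_T) - qlogis(rho00)` is strictly decreasing in `x`
#' whenever `rho00 < theta_T`, so its intersection with the unit square is a
#' single closed interval of `x` values (possibly empty).
#'
#' @param x,y Standardized dose(s) of the fixed agent.
#' @param params A [tox_params()] object.
#' @param theta_T Target DLT probability.
#' @param outside How to report solutions outside \[0,1\]: `"na"` (default)
#'   returns `NA`, `"raw"` the unclamped solution, `"truncate"` clamps to the
#'   nearest bound (standard EWOC practice for continuous standardized doses).
#' @return Standardized dose(s) of the free agent.
#' @export
mtd_y_given_x <- function(x, params, theta_T,
                          outside = c("na", "raw", "truncate")) {
  outside <- match.arg(outside)
  a <- tox_alphas(params)
  if (a$a2 <= 0) stop("invalid parameters: toxicity not increasing in y")
  A <- stats::qlogis(theta_T) - a$a0
  y <- (A - a$a1 * x) / (a$a2 + a$a3 * x)
  finish_mtd_solution(y, outside)
}

#' @rdname mtd_y_given_x
#' @export
mtd_x_given_y <- function(y, params, theta_T,
                          outside = c("na", "raw", "truncate")) {
  outside <- match.arg(outside)
  a <- tox_alphas(params)
  if (a$a1 <= 0) stop("invalid parameters: toxicity not increasing in x")
  A <- stats::qlogis(theta_T) - a$a0
  x <- (A - a$a2 * y) / (a$a1 + a$a3 * y)
  finish_mtd_solution(x, outside)
}

finish_mtd_solution <- function(v, outside) {
  switch(outside,
         raw = v,
         na = ifelse(v >= 0 & v <= 1, v, NA_real_),
         truncate = pmin(pmax(v, 0), 1))
}

#' Interval of x for which the MTD curve lies inside the unit square
#'
#' @inheritParams mtd_y_given_x
#' @return Numeric vector `c(lo, hi)`, or `numeric(0)` when the curve misses
#'   the unit square (for instance when even the lowest combination is above
#'   the target DLT probability).
#' @export
curve_domain <- function(params, theta_T) {
  a <- tox_alphas(params)
  A <- stats::qlogis(theta_T) - a$a0
  if (A <= 0) return(numeric(0)) # rho00 >= theta_T: nothing tolerable
  # y(x) decreasing; y = 1 at x1, y = 0 at x0
  x_at_y1 <- (A - a$a2) / (a$a1 + a$a3)
  x_at_y0 <- A / a$a1
  lo <- max(0, x_at_y1)
  hi <- min(1, x_at_y0)
  if (lo > hi) return(numeric(0))
  c(lo, hi)
}

#' Construct an MTD curve object
#'
#' Bundles toxicity parameters, the target DLT probability, and the `x` domain
#' over which the curve crosses the unit dose square.
#'
#' @inheritParams mtd_y_given_x
#' @return An `mtd_curve` object with fields `params`, `theta_T`, `x_domain`.
#' @export
mtd_curve <- function(params, theta_T = 0.33) {
  stopifnot(inherits(params, "tox_params"))
  structure(list(params = params, theta_T = theta_T,
                 x_domain = curve_domain(params, theta_T)),
            class = "mtd_curve")
}

#' @export
print.mtd_curve <- function(x, ...) {
  cat("MTD curve at theta_T =", x$theta_T, "\n")
  p <- x$params
  cat(sprintf("  rho00 = %.4g, rho01 = %.4g, rho10 = %.4g, alpha3 = %.4g\n",
              p$rho00, p$rho01, p$rho10, p$alpha3))
  if (length(x$x_domain))
    cat(sprintf("  x domain: [%.4f, %.4f]\n", x$x_domain[1], x$x_domain[2]))
  else cat("  curve does not intersect the unit dose square\n")
  invisible(x)
}

#' Points on an MTD curve
#'
#' @param curve An [mtd_curve()] object.
#' @param x Standardized doses of agent X inside the curve domain.
#' @return A tibble with columns `x`, `y`.
#' @export
curve_points <- function(curve, x) {
  tibble::tibble(x = x,
                 y = mtd_y_given_x(x, curve$params, curve$theta_T,
                                   outside = "raw"))
}

# derivative dy/dx along the curve (constant-sign, negative on the domain)
curve_dydx <- function(curve, x) {
  a <- tox_alphas(curve$params)
  A <- stats::qlogis(curve$theta_T) - a$a0
  -(a$a1 * a$a2 + a$a3 * A) / (a$a2 + a$a3 * x)^2
}

# cumulative arc length table on a dense grid (composite Simpson), cached per
# call site; the integrand sqrt(1 + y'(x)^2) is smooth so 2049 panels give
# ~1e-10 accuracy on the unit square
arclength_table <- function(curve, n_grid = 2049) {
  dom <- curve$x_domain
  if (!length(dom)) stop("MTD curve does not intersect the unit dose square")
  xs <- seq(dom[1], dom[2], length.out = n_grid)
  h <- xs[2] - xs[1]
  f <- sqrt(1 + curve_dydx(curve, xs)^2)
  mid <- sqrt(1 + curve_dydx(curve, xs[-n_grid] + h / 2)^2)
  seg <- h / 6 * (f[-n_grid] + 4 * mid + f[-1]) # Simpson per panel
  list(x = xs, s = c(0, cumsum(seg)))
}

# arc length of the curve from x_domain[1] to x (vectorized)
curve_arclength <- function(curve, x, table = NULL) {
  tb <- if (is.null(table)) arclength_table(curve) else table
  stats::approx(tb$x, tb$s, xout = x, rule = 2)$y
}

#' Equally spaced dose combinations along an MTD curve
#'
#' "Equally spaced along the curve" is implemented as equal arc length by
#' default, treating the curve as the trial's one-dimensional dose set; equal
#' spacing in the `x` coordinate is available for sensitivity checks.
#'
#' @param curve An [mtd_curve()] object with non-empty domain.
#' @param n Number of points, `>= 2`; both domain endpoints are included.
#' @param spacing `"arc"` (default) or `"x"`.
#' @return Tibble with columns `x`, `y`.
#' @export
equally_spaced_points <- function(curve, n, spacing = c("arc", "x")) {
  spacing <- match.arg(spacing)
  stopifnot(n >= 2)
  dom <- curve$x_domain
  if (!length(dom))
    stop("no tolerable dose combinations: MTD curve misses the unit square")
  if (spacing == "x") return(curve_points(curve, seq(dom[1], dom[2], length.out = n)))
  tb <- arclength_table(curve)
  total <- tb$s[length(tb$s)]
  targets <- seq(0, total, length.out = n)
  # invert the monotone cumulative arc length by interpolation
  xs <- stats::approx(tb$s, tb$x, xout = targets, rule = 2)$y
  xs[1] <- dom[1]; xs[n] <- dom[2]
  curve_points(curve, xs)
}

#' Serialize / deserialize an MTD curve as JSON
#'
#' @param curve An [mtd_curve()] object.
#' @return `curve_to_json()` a JSON string; `curve_from_json()` an
#'   `mtd_curve`.
#' @export
curve_to_json <- function(curve) {
  jsonlite::toJSON(list(theta_T = curve$theta_T,
                        rho00 = curve$params$rho00,
                        rho01 = curve$params$rho01,
                        rho10 = curve$params$rho10,
                        alpha3 = curve$params$alpha3,
                        x_domain = curve$x_domain),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname curve_to_json
#' @param json JSON string produced by `curve_to_json()`.
#' @export
curve_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  mtd_curve(tox_params(o$rho00, o$rho01, o$rho10, o$alpha3), o$theta_T)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.mtd_curve <- function(object, n = 200, ...) {
  dom <- object$x_domain
  if (!length(dom)) stop("curve misses the unit square; nothing to plot")
  df <- curve_points(object, seq(dom[1], dom[2], length.out = n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "standardized dose of agent X",
                  y = "standardized dose of agent Y",
                  title = sprintf("MTD curve (theta_T = %.2f)", object$theta_T))
}
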