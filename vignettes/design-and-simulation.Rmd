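---
title: "A two-stage Bayesian dose-finding design for dual-agent combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage Bayesian dose-finding design for dual-agent combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duocomb)
```

## The design in one paragraph

`duocomb` implements a seamless phase I-II design for combinations of two
cytotoxic agents given at continuous doses. Stage I uses escalation with
overdose control (EWOC) to learn the *maximum tolerated dose (MTD) curve*:
the locus of standardized dose pairs $(x, y) \in [0,1]^2$ whose
dose-limiting-toxicity (DLT) probability equals a target $\theta_T$
(default 0.33). Stage II, typically run in a new but related patient
population, searches *along* the estimated curve for the most efficacious
tolerable combination, allocating patients by response-adaptive
randomization and testing at the end whether any point on the curve beats
the standard-of-care response rate $p_0$ (default 0.15). The novelty the
package centres on is robust borrowing of stage-I efficacy data through an
exchangeable/nonexchangeable (EXNEX) mixture: stage-I information sharpens
the stage-II analysis when the two populations respond similarly and is
discounted automatically when they conflict.

## Models

**Toxicity.** The marginal DLT probability is logistic in the standardized
doses with a nonnegative interaction,
$$\pi_T(x, y) = F(\alpha_0 + \alpha_1 x + \alpha_2 y + \alpha_3 x y),$$
with $F$ the standard logistic CDF and $\alpha_1, \alpha_2 > 0$ so that
toxicity increases with either agent. The package parameterizes the model by
clinician-interpretable corner probabilities: $\rho_{00}, \rho_{10},
\rho_{01}$ are the DLT probabilities at the standardized combinations
$(0,0), (1,0), (0,1)$, with $\alpha_0 = F^{-1}(\rho_{00})$,
$\alpha_1 = F^{-1}(\rho_{10}) - F^{-1}(\rho_{00})$ and
$\alpha_2 = F^{-1}(\rho_{01}) - F^{-1}(\rho_{00})$. Solving
$\pi_T(x,y) = \theta_T$ for $y$ gives the MTD curve in closed form; it is
strictly decreasing in $x$ and its intersection with the unit square is a
single closed $x$-interval (`mtd_curve()`, `curve_domain()`).

The default priors are the informative ones of the motivating
cisplatin-cabazitaxel programme: $\rho_{01}, \rho_{10} \sim
\mathrm{Beta}(1.4, 5.6)$, the ratio $\rho_{00}/\min(\rho_{01}, \rho_{10})
\sim \mathrm{Beta}(0.8, 7.2)$, and $\alpha_3 \sim \mathrm{Gamma}(0.8,\,
\text{rate } 0.0384)$. A caution for users: the accompanying design
documents describe these priors as placing a DLT probability of about
0.33 on the anchor combination (standardized $(0.33, 0.5)$, the previously
recommended single MTD). Direct Monte Carlo evaluation
(`sample_tox_prior()`) gives a prior-predictive *mean* of about 0.53 at
that combination (median about 0.49) — the heavy-tailed interaction prior
(mean $\approx 21$ on the logit scale) pushes the mean well above the
target. The package reproduces the priors exactly as specified; the 0.33
description appears to refer to a different summary than the
prior-predictive mean.

**Efficacy.** Each stage $S \in \{1, 2\}$ has its own monotone logistic
model
$$\pi_E^S(x, y) = F\!\big(\beta_{0S} + e^{\beta_{1S}} x + e^{\beta_{2S}} y +
\beta_{3S}\, x y\big), \qquad \beta_{3S} \ge 0,$$
the exponentials enforcing nondecreasing efficacy in each dose. The
stagewise main-effect pairs $\Psi_S = (\beta_{1S}, \beta_{2S})$ are tied
together by a meta-analytic-combined (MAC) hierarchy:
$\Psi_1 \sim \mathrm{BVN}(\mu, \Phi)$ always, while
$$\Psi_2 \sim \begin{cases}
\mathrm{BVN}(\mu, \Phi) & \text{with probability } \omega\\
\mathrm{BVN}(0, R_0) & \text{with probability } 1 - \omega,
\end{cases}$$
with $\Phi$ built from heterogeneity SDs $\tau_1, \tau_2 \sim
\mathrm{HalfNormal}(0.5)$ and correlation $\xi \sim U(0, 0.5)$, and the
weakly informative own prior $R_0 = 100 \begin{pmatrix} 1 & \zeta \\
\zeta & 1\end{pmatrix}$, $\zeta \sim U(0, 0.5)$. Intercepts get
$N(-1.8, 3.16^2)$ priors and interactions $\mathrm{Gamma}(0.1, 0.1)$. The
prior exchangeability probability $\omega$ is fixed by design, not
estimated; $\omega = 0$ discards stage-I efficacy data entirely and
$\omega = 1$ enforces full exchangeability of the main effects.

Only $\Psi_2$ carries the mixture: intercepts and interactions are always
stage-specific, so "agreement" between stages is judged on the main
effects alone. $\zeta$ parameterizes only the nonexchangeable covariance;
when $\omega = 1$ it is still sampled but the data never update it.

## Posterior computation

Both posteriors are sampled by an adaptive Metropolis scheme written in
C++ (`src/mcmc.cpp`): each iteration performs a component-wise
random-walk sweep (per-component steps tuned to 0.44 acceptance during
warmup) followed by one joint random-walk update whose proposal covariance
is the running warmup covariance of the chain, Haario-style, with a scalar
factor tuned to 0.25 acceptance. Adaptation freezes at the end of warmup.
The EXNEX mixture is marginalized inside the target density by
log-sum-exp — no trans-dimensional moves — and the posterior
exchangeability weight is recovered as the average of the per-draw
responsibilities $\omega f_{\mathrm{ex}} / (\omega f_{\mathrm{ex}} +
(1-\omega) f_{\mathrm{nex}})$.

Sampling is done on unconstrained scales (logits of probabilities and of
the ratio parameterization, logs of $\alpha_3$, $\beta_{3S}$, $\tau_k$,
scaled logits of $\xi, \zeta$) with Jacobian corrections, so no proposals
are wasted outside the support. Heterogeneity draws are floored at
$10^{-6}$ to keep $\Phi$ nonsingular. Split-$\widehat R$ and a crude
autocorrelation ESS are attached to every fit; a fit is flagged (never
silently discarded) when $\widehat R > 1.05$ or the ESS falls below the
configured floor.

One honest caveat: the log-scale main effects $\beta_{1S}$ have a flat
ridge toward $-\infty$ (where $e^{\beta_1} \approx 0$), so their raw
traces mix slowly in small samples. The decision-relevant functionals —
efficacy probabilities and exceedance probabilities along the curve — are
bounded functions of $e^{\beta_1}$ and mix an order of magnitude better;
the test suite validates the sampler against importance-sampling and
grid-integration oracles on those functionals.

## The trial algorithm

*Stage I* enrolls $C_1 = 15$ cohorts of $m_1 = 2$. Cohort 1 treats both
patients at the standardized starting combination $(0.33, 0.5)$. In later
cohorts one patient keeps the previous dose of one agent and receives the
EWOC dose of the other — the $\alpha$-th percentile of the posterior
conditional MTD distribution, truncated to $[0, 1]$ — and the roles
alternate with cohort parity. The feasibility bound escalates as $\alpha =
\min\{0.25 + 0.05 (c_1 - 2),\, 0.5\}$ per cohort (the escalation cadence
is a design choice; the bound, start, step and cap are config fields). The
toxicity posterior is refit after every cohort, and the trial stops if
$P(\rho_{00} > \theta_T + 0.1 \mid D_1) > \delta_{\theta_1} = 0.5$ — the
lowest combination is already too toxic. We evaluate this rule after every
cohort; the design documents do not state a cadence, and per-cohort
checking matches the sequential character of the stage.

*Stage II* starts from the curve built at the coordinatewise posterior
medians of $(\rho_{00}, \rho_{10}, \rho_{01}, \alpha_3)$. If that curve
misses the unit square the trial ends with the distinct outcome
`no_tolerable_set`. Otherwise $n_2 = 10$ run-in patients are allocated at
equally spaced curve points, then $C_2 = 4$ cohorts of $m_2 = 5$ are drawn
by rejection sampling from the *standardized density* along the curve —
the plug-in stage-II efficacy curve (posterior medians of the stage-2
parameters, evaluated through the one-to-one $x \mapsto (x, y(x))$ map)
normalized to integrate to 1. The MAC model is refit after the run-in and
after every cohort; stage-I efficacy outcomes enter the likelihood from
the first stage-II fit onward, reflecting their delayed observability.

"Equally spaced along the curve" is implemented as equal *arc length*
(invariant to which agent is called $x$), with equal-$x$ spacing available
as `spacing = "x"` for sensitivity checks. Arc length is computed by
composite Simpson quadrature on a 2049-point grid and inverted by
monotone interpolation; the suite checks both against adaptive quadrature
to $10^{-6}$.

Stopping rules:

* **Futility** (after the run-in and every later fit): stop when even the
  best curve point has $P(\pi_E^2 > p_0 \mid D) < \delta_0 = 0.1$.
* **Stage-II safety** (after every stage-II cohort): with $k$ DLTs among
  $n$ patients pooled over both stages, stop when the
  $\mathrm{Beta}(0.5 + k,\, 0.5 + n - k)$ posterior puts more than
  $\delta_{\theta_2} = 0.9$ of its mass above $\theta_T + 0.1$. The
  pooling follows the rule's definition of the DLT rate as covering both
  stages; a config switch restricts it to stage II for sensitivity
  analyses.

At the planned end the design rejects the null hypothesis (no tolerable
combination beats $p_0$) when $\max P(\pi_E^2 > p_0 \mid D) > \delta_u =
0.4$ over a 101-point arc-length grid on the curve, recommending the
argmax point (ties break to the lower $x$ — deterministic and
conservative for agent X).

```{r one-trial, eval = FALSE}
sc <- default_scenario(tox_profile = 2, eff_profile = 1,
                       hypothesis = "H1", agreement = "CA")
res <- run_trial(design_config(), outcome_source(sc), seed = 7)
res
glance(res)
autoplot(res$curve)
```

## What the synthetic scenarios emulate

The simulation truths are *calibrated stand-ins*: the published scenario
tables for the motivating trial are not redistributed here, so
`default_scenario()` reconstructs scenarios from the printed constraints.

* Two toxicity profiles with low corner probabilities and substantial
  interaction — the region the informative prior itself considers
  plausible, consistent with the priors and truths sharing a provenance.
  Profile 2's curve passes through the anchor $(0.33, 0.5)$; profile 1's
  runs below it (the anchor is supratherapeutic there).
* Humped stage-II efficacy profiles along the curve, peaking at 20% or
  80% of the curve domain with a floor of 0.05 at the far end. The
  surface itself is monotone in each dose; an interior peak arises only
  through composition with the decreasing curve $y(x)$. On the curve the
  identity $\alpha_1 x + \alpha_2 y + \alpha_3 x y = \text{const}$ makes
  the composite predictor an element of $\mathrm{span}\{1, x, y(x)\}$, so
  calibration reduces to a 3x3 linear solve (zero slope and level at the
  peak, level at the far end) lifted back to valid positive coefficients;
  `calibrate_eff_profile()` errors informatively when a hump is requested
  on a straight-line curve, where the lift does not exist.
* Under the alternative the on-curve maximum of the true stage-II
  efficacy is $p_0 + 0.25 = 0.40$ (grid-checked to $\pm 0.005$); the null
  variant shifts the intercept so the same shape peaks at $p_0 = 0.15$.
* Stage-I profiles at three agreement levels: complete agreement (CA,
  identical), partial agreement (PA, same peak location, probabilities
  shifted by 0.1 — our operationalization of "slightly different"), and
  complete disagreement (CD, peak mirrored across the curve domain).

DLT and response outcomes are independent Bernoulli draws from the true
models, toxicity shared across stages. What passing simulation checks do
*not* show: robustness to non-monotone efficacy (molecularly targeted
agents), toxicity-efficacy dependence, patient heterogeneity, or truths
far outside the informative prior's support — none of which the design
models.

## Numerical and design choices worth knowing

* Conditional-MTD solutions outside $[0, 1]$ are truncated to the nearest
  bound before assignment (standard practice for continuous standardized
  doses); truncation is recorded per patient.
* Algebraic curve inversions are exact to $10^{-10}$; arc-length numerics
  to $10^{-6}$; the stage-II safety rule uses the closed-form incomplete
  Beta, exact to machine precision.
* The futility display compares the *maximum posterior exceedance
  probability* to $\delta_0$ — the only reading consistent with the final
  test and $\delta_0 < \delta_u$.
* Early stops count as non-rejections in the power estimator (the final
  test never runs); `estimate_power(..., conditional = TRUE)` reports the
  completed-trials variant alongside.
* Per-trial seeds are derived deterministically from the master seed and
  trial index, so replicate sets are reproducible and extendable without
  reshuffling earlier trials.
* The `m1 = 2` cohort size is structural: the alternating
  conditional-assignment pattern needs exactly two patients per cohort.

## Problem sizes used by the shipped checks

The simulation-based checks in the test suite and `scripts/acceptance.R`
run the full design (N1 = N2 = 30) at J = 100 and J = 80 replicates per
arm respectively, with the per-fit sampler at 2 chains x 500 kept draws —
sizes chosen so the whole suite runs at a desk in well under half an hour
while keeping Monte Carlo standard errors near 0.05 on the reported
rates. Standalone analyses default to 4 chains x 1000 draws. Under the
calibrated stand-in scenarios the rejection rate under the alternative,
the correct-recommendation rate, the futility-stop rate under the null
and the stage-II allocation quality land inside the published ranges; the
unconditional type-I error and the futility-stop rate under the
alternative are sensitive to the exact profile shapes (the null is a
knife-edge: the truth touches $p_0$ exactly, so any upward drift of the
estimated curve crosses it), and with our stand-ins both land above their
published bands. All measured values are printed by the acceptance
machinery so the comparison is transparent.

## Limitations

Two agents only; binary endpoints; no toxicity attribution; no
dose insertion off the estimated curve; toxicity data are not borrowed
across stages (the toxicity model is fit on stage-I data only, matching
the design's assumption of a common dose-toxicity profile).
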