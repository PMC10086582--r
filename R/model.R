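#' Right-hand side of the two-compartment NSC model
#'
#' The population model tracks quiescent (`qNSC`) and active (`aNSC`) neural
#' stem cells:
#' \deqn{dq/dt = -r(t) q + 2 b ps a, \qquad da/dt = r(t) q - ps a,}
#' where `r(t)` is the activation rate, `ps` the cell-cycle progression rate,
#' and `b` the self-renewal probability (evaluated per variant, using
#' `N = q + a` for the population-feedback law). Active cells divide at rate
#' `ps`; a division self-renews with probability `b` (both daughters return
#' to quiescence) or produces two progenitors otherwise, so the total obeys
#' `d(q+a)/dt = (2b - 1) ps a`.
#'
#' @param q,a Quiescent and active NSC counts (finite).
#' @param t Age in days, >= 0.
#' @param params A [model_params()] object.
#' @param variant A [model_variant()] object.
#'
#' @return Numeric vector `c(dq, da)` of time derivatives (cells per day).
#' @export
#' @examples
#' p <- model_params(r0 = 0.01, b0 = 0.3, NSC0 = 100)
#' nsc_rhs(q = 100, a = 0, t = 0, p, model_variant("constant", "constant"))
nsc_rhs <- function(q, a, t, params, variant) {
  if (!is.finite(q) || !is.finite(a)) stop("'q' and 'a' must be finite")
  r <- activation_rate(params, variant, t)
  b <- selfrenewal_prob(params, variant, t, total_nsc = q + a)
  c(-r * q + 2 * b * params$ps * a,
    r * q - params$ps * a)
}

#' Steady-state split of an initial total into compartments
#'
#' Distributes a total NSC count between the quiescent and active compartments
#' at the ratio that makes the active compartment stationary
#' (`da/dt = 0`, i.e. `a/q = r/ps`), so that a simulation does not start with
#' a transient in the activity fraction.
#'
#' @param NSC0 Total NSC count (> 0).
#' @param r Activation rate at the starting age (per day, >= 0).
#' @param ps Cell-cycle progression rate (per day, > 0).
#'
#' @return Named numeric vector `c(q = , a = )` summing to `NSC0`.
#' @export
#' @examples
#' steady_state_split(100, r = 0.9506, ps = 0.9506)
steady_state_split <- function(NSC0, r, ps) {
  if (!is.finite(NSC0) || NSC0 <= 0) stop("'NSC0' must be > 0")
  if (!is.finite(ps) || ps <= 0) stop("'ps' must be > 0")
  if (!is.finite(r) || r < 0) stop("'r' must be >= 0")
  c(q = NSC0 * ps / (ps + r), a = NSC0 * r / (ps + r))
}

# Internal: pack parameters and law codes for the compiled RHS (src/nsc_ode.c).
.ode_parms <- function(params, variant) {
  v <- c(params$r0, params$beta_r, params$b0, params$beta_b, params$ps,
         params$kb, params$nb,
         match(variant$activation, .activation_laws) - 1,
         match(variant$selfrenewal, .selfrenewal_laws) - 1)
  v[is.na(v)] <- 0  # placeholders for parameters the selected laws ignore
  v
}

# Internal: integrate the model from an explicit initial state using the
# compiled right-hand side (its agreement with nsc_rhs() is asserted in the
# test suite). Negative solver state is never clipped here; derived outputs
# clip instead.
.simulate_from_state <- function(y0, params, variant, times,
                                 rtol = 1e-8, atol = 1e-10) {
  sol <- tryCatch(
    deSolve::ode(y = c(q = unname(y0[[1]]), a = unname(y0[[2]])),
                 times = times, func = "nsc_derivs", parms = .ode_parms(params, variant),
                 dllname = "nscdyn", initfunc = "nsc_init",
                 rtol = rtol, atol = atol),
    error = function(e) stop("integration failure: ", conditionMessage(e)),
    warning = function(w) stop("integration failure: ", conditionMessage(w))
  )
  sol <- as.data.frame(sol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    stop(sprintf(
      "integration failure: solver returned %d of %d requested points (t last = %g)",
      sum(stats::complete.cases(sol)), length(times), max(sol$time, na.rm = TRUE)))
  }
  traj <- data.frame(time_days = sol$time, qNSC = sol$q, aNSC = sol$a)
  structure(traj, class = c("nsc_trajectory", "data.frame"),
            params = params, variant = variant)
}

#' Simulate the NSC population model
#'
#' Integrates the two-compartment model over an age grid with an adaptive
#' solver (relative tolerance `1e-8`, absolute `1e-10`). The initial state at
#' the first grid age is obtained by [steady_state_split()] of `NSC0` using
#' the activation rate evaluated at that age.
#'
#' @inheritParams nsc_rhs
#' @param times Strictly increasing age grid in days, first element >= 0.
#' @param rtol,atol Solver tolerances.
#'
#' @return An `nsc_trajectory`: a data frame with columns `time_days`, `qNSC`,
#'   `aNSC`, carrying the parameters and variant as attributes. Use
#'   [fraction_active()] and [progenitor_flux()] for derived series and
#'   [as_trajectory_table()] for a tidy export.
#' @export
#' @examples
#' p <- model_params(r0 = 0.04, beta_r = 0.006, b0 = 0.35, beta_b = 0.004,
#'                   NSC0 = 2800)
#' v <- model_variant("exponential_decay", "time_logistic")
#' traj <- simulate_nsc(p, v, times = seq(0, 700, by = 7))
#' head(traj)
simulate_nsc <- function(params, variant, times, rtol = 1e-8, atol = 1e-10) {
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("'times' must be a strictly increasing grid of length >= 2")
  }
  if (times[1] < 0) stop("'times' must start at age >= 0")
  .check_variant_params(params, variant)
  if (is.na(params$NSC0)) stop("'NSC0' is required to simulate")
  r_init <- activation_rate(params, variant, times[1])
  y0 <- steady_state_split(params$NSC0, r_init, params$ps)
  .simulate_from_state(y0, params, variant, times, rtol = rtol, atol = atol)
}

#' Fraction of active NSCs along a trajectory
#'
#' @param traj An `nsc_trajectory` from [simulate_nsc()].
#'
#' @return Numeric vector `aNSC / (qNSC + aNSC)` in `[0, 1]`; tiny negative
#'   solver excursions are clipped to zero before forming the ratio.
#' @export
fraction_active <- function(traj) {
  q <- pmax(traj$qNSC, 0)
  a <- pmax(traj$aNSC, 0)
  tot <- q + a
  if (any(tot == 0)) stop("fraction undefined: total NSC count is zero")
  a / tot
}

#' Progenitor production flux along a trajectory
#'
#' The instantaneous rate at which progenitors leave the stem-cell pool:
#' `2 * ps * (1 - b) * aNSC`, with the self-renewal probability `b` evaluated
#' at each trajectory point under the given laws (using the current total for
#' the population-feedback law).
#'
#' @param traj An `nsc_trajectory`.
#' @param params,variant Parameter set and variant; default to those stored
#'   on the trajectory.
#'
#' @return Numeric vector of fluxes (cells per day), non-negative.
#' @export
progenitor_flux <- function(traj, params = attr(traj, "params"),
                            variant = attr(traj, "variant")) {
  a <- pmax(traj$aNSC, 0)
  tot <- pmax(traj$qNSC, 0) + a
  b <- selfrenewal_prob(params, variant, traj$time_days, total_nsc = tot)
  pmax(2 * params$ps * (1 - b) * a, 0)
}

#' Tidy table of a trajectory with derived series
#'
#' @param traj An `nsc_trajectory`.
#' @inheritParams progenitor_flux
#'
#' @return A data frame with columns `time_days`, `qNSC`, `aNSC`, `total`,
#'   `fraction_active`, `progenitor_flux`.
#' @export
as_trajectory_table <- function(traj, params = attr(traj, "params"),
                                variant = attr(traj, "variant")) {
  data.frame(time_days = traj$time_days,
             qNSC = traj$qNSC,
             aNSC = traj$aNSC,
             total = traj$qNSC + traj$aNSC,
             fraction_active = fraction_active(traj),
             progenitor_flux = progenitor_flux(traj, params, variant))
}
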