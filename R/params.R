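#' Default cell-cycle progression rate
#'
#' The per-day rate at which active NSCs complete the cell cycle, fixed from a
#' literature cell-cycle length of 17.5 hours: `log(2) / (17.5 / 24)` per day.
#' This parameter is held constant during fitting, not estimated.
#'
#' @return A single numeric, approximately 0.9506 per day.
#' @export
#' @examples
#' ps_default()
ps_default <- function() {
  log(2) / (17.5 / 24)
}

#' Kinetic parameter set for the two-compartment NSC model
#'
#' Bundles the kinetic parameters of the quiescent/active NSC model for one
#' genotype. Which parameters are actually used depends on the
#' [model_variant()]: `beta_r` only matters for the exponentially decaying
#' activation law, `b0`/`beta_b` for the constant and time-logistic
#' self-renewal laws, and `kb`/`nb` for the population-feedback (Hill) law.
#'
#' @param r0 Activation rate at age 0 (per day, >= 0).
#' @param beta_r Exponential decay rate of the activation rate (per day, >= 0).
#' @param b0 Self-renewal probability at age 0 (dimensionless; must lie in
#'   `[0, 1/2]` for the time-dependent laws).
#' @param beta_b Rate at which the self-renewal probability approaches 1/2
#'   (per day, >= 0).
#' @param ps Cell-cycle progression rate of active NSCs (per day, > 0).
#'   Defaults to [ps_default()].
#' @param NSC0 Total NSC count at age 0 (cells, > 0).
#' @param kb Inverse half-saturation scale of the Hill self-renewal law
#'   (per cell, > 0); the law crosses 1/2 exactly at `N = 1/kb`.
#' @param nb Hill exponent (dimensionless, any nonzero sign; negative values
#'   give self-stabilising feedback where self-renewal falls as the
#'   population grows).
#'
#' @return An object of class `nsc_params` (a named list).
#' @export
#' @examples
#' model_params(r0 = 0.04, beta_r = 0.006, b0 = 0.35, beta_b = 0.004,
#'              NSC0 = 2800)
model_params <- function(r0, beta_r = 0, b0 = NA_real_, beta_b = 0,
                         ps = ps_default(), NSC0 = NA_real_,
                         kb = NA_real_, nb = NA_real_) {
  p <- list(r0 = as.numeric(r0), beta_r = as.numeric(beta_r),
            b0 = as.numeric(b0), beta_b = as.numeric(beta_b),
            ps = as.numeric(ps), NSC0 = as.numeric(NSC0),
            kb = as.numeric(kb), nb = as.numeric(nb))
  if (!is.finite(p$r0) || p$r0 < 0) stop("'r0' must be finite and >= 0")
  if (!is.finite(p$beta_r) || p$beta_r < 0) stop("'beta_r' must be finite and >= 0")
  if (!is.finite(p$ps) || p$ps <= 0) stop("'ps' must be finite and > 0")
  if (!is.finite(p$beta_b) || p$beta_b < 0) stop("'beta_b' must be finite and >= 0")
  if (!is.na(p$NSC0) && p$NSC0 <= 0) stop("'NSC0' must be > 0")
  class(p) <- "nsc_params"
  p
}

#' @export
print.nsc_params <- function(x, ...) {
  cat("NSC model parameters:\n")
  vals <- unlist(x)
  for (nm in names(vals)) {
    cat(sprintf("  %-7s %s\n", nm, format(vals[[nm]], digits = 6)))
  }
  invisible(x)
}

.activation_laws <- c("constant", "exponential_decay")
.selfrenewal_laws <- c("constant", "time_logistic", "hill_population")

#' Declare a candidate model variant
#'
#' A model variant is the declarative choice of which functional law governs
#' the activation rate and which governs the self-renewal probability. The
#' kinetic constants themselves live in [model_params()].
#'
#' @param activation One of `"constant"` (rate is `r0` at every age) or
#'   `"exponential_decay"` (rate is `r0 * exp(-beta_r * t)`).
#' @param selfrenewal One of `"constant"` (probability `b0`),
#'   `"time_logistic"` (starts at `b0`, approaches 1/2 with rate `beta_b`),
#'   or `"hill_population"` (depends on the current total population through
#'   a Hill function with constants `kb`, `nb`).
#'
#' @return An object of class `nsc_variant`.
#' @export
#' @examples
#' model_variant("exponential_decay", "time_logistic")
model_variant <- function(activation = c("exponential_decay", "constant"),
                          selfrenewal = c("time_logistic", "constant",
                                          "hill_population")) {
  activation <- match.arg(activation, .activation_laws)
  selfrenewal <- match.arg(selfrenewal, .selfrenewal_laws)
  structure(list(activation = activation, selfrenewal = selfrenewal),
            class = "nsc_variant")
}

#' @export
print.nsc_variant <- function(x, ...) {
  cat(sprintf("NSC model variant: activation = %s, selfrenewal = %s\n",
              x$activation, x$selfrenewal))
  invisible(x)
}

.check_variant_params <- function(params, variant) {
  if (variant$selfrenewal %in% c("constant", "time_logistic")) {
    if (is.na(params$b0)) stop("selected self-renewal law requires 'b0'")
    if (params$b0 < 0 || params$b0 > 0.5) {
      stop("'b0' must lie in [0, 1/2] for the time-dependent self-renewal laws")
    }
  }
  if (variant$selfrenewal == "hill_population") {
    if (is.na(params$kb) || params$kb <= 0) {
      stop("hill_population law requires 'kb' > 0")
    }
    if (is.na(params$nb)) stop("hill_population law requires 'nb'")
    if (params$nb == 0) {
      stop("degenerate Hill law: 'nb' must be nonzero")
    }
  }
  invisible(TRUE)
}

#' Activation rate at a given age
#'
#' Evaluates the per-day rate at which quiescent NSCs activate, under the
#' activation law selected by the variant: either a constant `r0` or an
#' exponential decline `r0 * exp(-beta_r * t)` capturing the deepening of
#' quiescence with age.
#'
#' @param params A [model_params()] object.
#' @param variant A [model_variant()] object.
#' @param t Age(s) in days, >= 0. Vectorised.
#'
#' @return Numeric vector of activation rates (per day), non-negative.
#' @export
#' @examples
#' p <- model_params(r0 = 0.02, beta_r = 0.001, NSC0 = 1000, b0 = 0.3)
#' activation_rate(p, model_variant("exponential_decay"), t = c(0, 693.147))
activation_rate <- function(params, variant, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  switch(variant$activation,
         constant = rep_len(params$r0, length(t)),
         exponential_decay = params$r0 * exp(-params$beta_r * t))
}

#' Self-renewal probability at a given age or population size
#'
#' Evaluates the probability `b` that a dividing active NSC self-renews
#' (returning two NSCs to the pool) rather than producing two progenitors.
#' Three laws are supported:
#' \describe{
#'   \item{constant}{`b = b0` at every age.}
#'   \item{time_logistic}{`b(t) = (1 + exp(-beta_b * t) * (2 * b0 - 1)) / 2`,
#'     which starts at `b0` and relaxes monotonically towards 1/2, encoding
#'     the assumption that self-renewal never exceeds 1/2 and may increase
#'     with age.}
#'   \item{hill_population}{`b(N) = 1 - 1 / (1 + (kb * N)^nb)` with `N` the
#'     current total NSC count; with `nb < 0` this is a self-stabilising
#'     feedback that crosses 1/2 exactly at `N = 1/kb`. At `N = 0` with
#'     `nb < 0` the limit value 1 is returned.}
#' }
#'
#' @inheritParams activation_rate
#' @param t Age(s) in days, >= 0 (used by the time-dependent laws).
#' @param total_nsc Current total NSC count(s); required for the
#'   `hill_population` law, ignored otherwise.
#'
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
#' @examples
#' p <- model_params(r0 = 0.02, b0 = 0.3, beta_b = 0.01, NSC0 = 1000)
#' selfrenewal_prob(p, model_variant(selfrenewal = "time_logistic"), t = 0)
selfrenewal_prob <- function(params, variant, t, total_nsc = NULL) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  .check_variant_params(params, variant)
  switch(variant$selfrenewal,
         constant = rep_len(params$b0, length(t)),
         time_logistic = 0.5 * (1 + exp(-params$beta_b * t) * (2 * params$b0 - 1)),
         hill_population = {
           if (is.null(total_nsc)) {
             stop("hill_population law requires 'total_nsc'")
           }
           if (any(total_nsc < 0)) stop("'total_nsc' must be >= 0")
           .hill_b(total_nsc, params$kb, params$nb)
         })
}

# b(N) = 1 - 1/(1 + (kb*N)^nb) = x/(1+x); at N = 0 the power is 0 (nb > 0,
# b = 0) or Inf (nb < 0, b = 1); Inf is also handled for huge (kb*N)^nb.
.hill_b <- function(N, kb, nb) {
  x <- (kb * N)^nb
  b <- ifelse(is.infinite(x), 1, x / (1 + x))
  as.numeric(b)
}
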