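# Pointwise constitutive functions of the Langevin-Bikerman electric double
# layer: net ionic charge density with steric saturation, and the field- and
# potential-dependent relative permittivity from orientational ordering of
# water dipoles. Shared by the planar and arc solvers.

# Switch-point for the small-argument series of L(x) and sinh(x)/x. Below
# u = 0.01 the direct expressions lose digits to cancellation (relative
# error ~1e-12 at the switch, growing as 1/u^2 below it) while the
# three-term series are accurate to ~6e-16 relative there, so the profiles
# they enter stay smooth and monotone across the switch.
.series_switch <- 1e-2

#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the mean alignment of a freely rotating dipole in
#' a field of `x` thermal units. Odd in `x`, bounded by 1 in magnitude. For
#' `|x| < 0.01` the series `x/3 - x^3/45 + 2x^5/945` is used to avoid
#' catastrophic cancellation; the switch keeps the relative error below
#' 1e-12 everywhere.
#'
#' @param x Numeric vector, finite.
#' @return `coth(x) - 1/x`, with `L(0) = 0`.
#' @examples
#' langevin_L(1) # 1/tanh(1) - 1
#' @export
langevin_L <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  out <- numeric(length(x))
  small <- abs(x) < .series_switch
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45 + 2 * xs^5 / 945
  xb <- x[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  out
}

# sinh(u)/u with series guard; used by H and F.
.sinhc <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < .series_switch
  us <- u[small]
  out[small] <- 1 + us^2 / 6 + us^4 / 120
  out[!small] <- sinh(u[!small]) / u[!small]
  out
}

#' Dipole ordering factor
#'
#' `F(x) = L(x) sinh(x)/x`, the combination entering the Langevin-Bikerman
#' permittivity. `F(0) = 0` by the limit `F(x) ~ x/3`; strictly increasing
#' for `x > 0`. Below the series switch-point both factors are evaluated by
#' series; for `x > 600`, `sinh(x)` would overflow and the function is
#' evaluated in the log domain as `exp(log L(x) + x - log(2x))`.
#'
#' @param x Numeric vector, non-negative and finite.
#' @return `F(x)`, dimensionless.
#' @examples
#' dipole_factor_F(1) # equals exp(-1)
#' @export
dipole_factor_F <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)), all(x >= 0))
  out <- numeric(length(x))
  small <- x < .series_switch
  out[small] <- langevin_L(x[small]) * .sinhc(x[small])
  big <- x > 600
  mid <- !small & !big
  out[mid] <- langevin_L(x[mid]) * sinh(x[mid]) / x[mid]
  # log-domain: sinh(x) ~ exp(x)/2 to machine precision for x > 600
  out[big] <- exp(log(langevin_L(x[big])) + x[big] - log(2 * x[big]))
  out
}

#' Steric denominator of the Langevin-Bikerman model
#'
#' `H(phi, E) = 2 n0 cosh(e0 phi beta) + n0w sinh(p0 E beta)/(p0 E beta)`,
#' the local lattice normalisation that caps ion and water densities at the
#' density of lattice sites. At `phi = 0`, `E -> 0` it equals `n_s` exactly.
#'
#' @param model An [electrolyte_model()].
#' @param phi Electric potential (V), vectorised.
#' @param E Electric field magnitude (V/m), non-negative, vectorised.
#' @return `H` in 1/m^3, always `> 0`.
#' @examples
#' m <- electrolyte_model(0.15)
#' h_denominator(m, 0, 0) == m$ns
#' @export
h_denominator <- function(model, phi, E) {
  stopifnot(inherits(model, "electrolyte_model"), all(E >= 0))
  u <- model$p0 * E * model$beta
  2 * model$n0 * cosh(.consts$e0 * phi * model$beta) + model$n0w * .sinhc(u)
}

#' Field- and potential-dependent relative permittivity
#'
#' The Langevin-Bikerman permittivity
#' `eps_r = 1 + n_s n0w p0 F(p0 E beta) / (eps0 E H(phi, E))`.
#' Orientational ordering of the water dipoles in strong fields (dielectric
#' saturation) and their depletion near a charged surface both lower `eps_r`
#' below its bulk value. The `E -> 0` limit is taken analytically
#' (`F(u)/u -> 1/3`), so the function is continuous at `E = 0`; it is even in
#' `phi` and non-increasing in `E`.
#'
#' @inheritParams h_denominator
#' @return Relative permittivity, `>= 1`, dimensionless.
#' @examples
#' m <- electrolyte_model(0.15)
#' relative_permittivity(m, 0, 0)    # bulk value
#' relative_permittivity(m, 0, 1e9)  # saturated, much lower
#' @export
relative_permittivity <- function(model, phi, E) {
  stopifnot(inherits(model, "electrolyte_model"), all(E >= 0))
  n <- max(length(phi), length(E))
  phi <- rep_len(phi, n); E <- rep_len(E, n)
  if (model$p0 == 0) return(rep(1, n))
  u <- model$p0 * E * model$beta
  H <- h_denominator(model, phi, E)
  out <- numeric(n)
  small <- u < .series_switch
  # small-field branch: F(u)/E = p0 beta * (L(u)/u) * sinhc(u), with the
  # removable singularity of L(u)/u handled by its series
  us <- u[small]
  L_over_u <- 1 / 3 - us^2 / 45 + 2 * us^4 / 945
  out[small] <- 1 + model$ns * model$n0w * model$p0^2 * model$beta *
    L_over_u * .sinhc(us) / (.consts$eps0 * H[small])
  out[!small] <- 1 + model$ns * model$n0w * model$p0 *
    dipole_factor_F(u[!small]) / (.consts$eps0 * E[!small] * H[!small])
  out
}

#' Net (free) volume charge density of the ions
#'
#' `rho_free = -2 e0 n_s n0 sinh(e0 phi beta) / H(phi, E)`. Odd in `phi`,
#' opposite in sign to `phi`, and bounded in magnitude by `e0 n_s` (steric
#' saturation: counterions cannot pack beyond one per lattice site). When
#' `H -> n_s` it reduces to the point-ion Boltzmann form
#' `-2 e0 n0 sinh(e0 phi beta)`.
#'
#' @inheritParams h_denominator
#' @return Charge density in C/m^3.
#' @examples
#' m <- electrolyte_model(0.15)
#' free_charge_density(m, 0.025, 0)
#' @export
free_charge_density <- function(model, phi, E) {
  stopifnot(inherits(model, "electrolyte_model"), all(E >= 0))
  H <- h_denominator(model, phi, E)
  -2 * .consts$e0 * model$ns * model$n0 *
    sinh(.consts$e0 * phi * model$beta) / H
}

# d rho_free / d phi at lagged E; analytic Jacobian for the Newton solvers.
.d_free_charge_density <- function(model, phi, E) {
  e0 <- .consts$e0; b <- model$beta
  H <- h_denominator(model, phi, E)
  sh <- sinh(e0 * phi * b); ch <- cosh(e0 * phi * b)
  dH <- 2 * model$n0 * sh * e0 * b
  -2 * e0 * model$ns * model$n0 * (ch * e0 * b * H - sh * dH) / H^2
}

#' Bulk relative permittivity
#'
#' Closed-form zero-field, zero-potential limit of
#' [relative_permittivity()]: `1 + n0w p0^2 beta / (3 eps0)` (the `n_s`
#' prefactor cancels against `H -> n_s`). With the default water parameters
#' (55 mol/l, 4.79 D, 298 K) this evaluates to 78.4, the bulk permittivity
#' of the electrolyte.
#'
#' @param model An [electrolyte_model()].
#' @return Dimensionless bulk relative permittivity.
#' @examples
#' bulk_permittivity(electrolyte_model(0.15))
#' @export
bulk_permittivity <- function(model) {
  stopifnot(inherits(model, "electrolyte_model"))
  1 + model$n0w * model$p0^2 * model$beta / (3 * .consts$eps0)
}

#' Debye screening length
#'
#' `lambda_D = sqrt(eps0 eps_r k T / (2 n0 e0^2))` for a monovalent salt.
#'
#' @param model An [electrolyte_model()].
#' @param eps_r Relative permittivity to use (default: the model's bulk
#'   value).
#' @return Length in metres; `Inf` (with a warning) when the model has no
#'   salt, i.e. no screening.
#' @examples
#' m_to_nm(debye_length(electrolyte_model(0.15), 78.5))
#' @export
debye_length <- function(model, eps_r = bulk_permittivity(model)) {
  stopifnot(inherits(model, "electrolyte_model"), eps_r >= 1)
  if (model$n0 == 0) {
    rlang::warn("no salt: no screening, Debye length is infinite")
    return(Inf)
  }
  sqrt(.consts$eps0 * eps_r / (model$beta * 2 * model$n0 * .consts$e0^2))
}
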