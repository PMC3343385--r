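# Shared fixtures. The "standard electrolyte" is the reference composition
# used throughout: 0.15 mol/l monovalent salt, 55 mol/l water with an
# effective dipole moment of 4.79 D, at 298 K.
std_model <- function() electrolyte_model(salt_mol_l = 0.15)

# Analytic Gouy-Chapman potential for a planar surface with point ions and
# fixed permittivity: the independent oracle for the planar solver.
gouy_chapman_phi <- function(x, sigma, model, eps_r) {
  e0 <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  kT <- 1 / model$beta
  lam <- sqrt(eps0 * eps_r * kT / (2 * model$n0 * e0^2))
  phi0 <- (2 * kT / e0) * asinh(sigma / sqrt(8 * model$n0 * eps0 * eps_r * kT))
  gam <- tanh(e0 * phi0 / (4 * kT))
  (4 * kT / e0) * atanh(gam * exp(-x / lam))
}

# Hand-built planar profile object for testing pure profile utilities.
fake_profile <- function(x_nm, eps_r, sigma = 0.1) {
  structure(
    list(
      profile = tibble::tibble(
        x_nm = x_nm, phi_mV = 0 * x_nm, E_V_per_m = 0 * x_nm,
        eps_r = eps_r, rho_C_per_m3 = 0 * x_nm
      ),
      x = x_nm * 1e-9, sigma = sigma, model = std_model(),
      convergence = list(outer_iterations = 0L, residual = 0, eps_update = 0)
    ),
    class = "edl_profile"
  )
}
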