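#' Electrolyte model for the Langevin-Bikerman double layer
#'
#' Describes a monovalent salt solution on a lattice of density `n_s`
#' shared by ions and orientable water dipoles. The lattice-site density is
#' always derived as `n_s = n0w + 2 n0` (water plus both ion species) and is
#' never user-set, so the lattice bookkeeping stays consistent.
#'
#' User-facing units are mol/l for concentrations and debye for the water
#' dipole moment; everything is stored in SI internally.
#'
#' @param salt_mol_l Bulk salt concentration (mol/l), monovalent, `>= 0`.
#' @param water_mol_l Bulk water concentration (mol/l), default 55.
#' @param dipole_debye Magnitude of the water (or small water cluster) dipole
#'   moment in debye, default 4.79. This effective value, larger than the
#'   bare molecular 1.85 D, absorbs short-range dipole correlations so that
#'   the zero-field limit reproduces the measured bulk permittivity.
#' @param temperature_K Temperature in kelvin, default 298.
#' @return An object of class `electrolyte_model`: a list with fields
#'   `n0`, `n0w`, `ns` (number densities, 1/m^3), `p0` (C m), `T` (K),
#'   `beta` (1/J) and the original user inputs.
#' @examples
#' m <- electrolyte_model(salt_mol_l = 0.15)
#' m$ns == m$n0w + 2 * m$n0
#' @seealso [bulk_permittivity()], [solve_planar()]
#' @export
electrolyte_model <- function(salt_mol_l = 0.15, water_mol_l = 55,
                              dipole_debye = 4.79, temperature_K = 298) {
  if (!is.numeric(salt_mol_l) || length(salt_mol_l) != 1 || salt_mol_l < 0)
    rlang::abort("`salt_mol_l` must be a single non-negative number.")
  if (!is.numeric(water_mol_l) || length(water_mol_l) != 1 || water_mol_l <= 0)
    rlang::abort("`water_mol_l` must be a single positive number.")
  if (!is.numeric(dipole_debye) || length(dipole_debye) != 1 || dipole_debye < 0)
    rlang::abort("`dipole_debye` must be a single non-negative number.")
  if (!is.numeric(temperature_K) || length(temperature_K) != 1 || temperature_K <= 0)
    rlang::abort("`temperature_K` must be a single positive number.")

  n0  <- mol_l_to_per_m3(salt_mol_l)
  n0w <- mol_l_to_per_m3(water_mol_l)
  structure(
    list(
      n0 = n0, n0w = n0w, ns = n0w + 2 * n0,
      p0 = debye_to_Cm(dipole_debye),
      T = temperature_K,
      beta = 1 / thermal_energy(temperature_K),
      salt_mol_l = salt_mol_l, water_mol_l = water_mol_l,
      dipole_debye = dipole_debye
    ),
    class = "electrolyte_model"
  )
}

#' @export
print.electrolyte_model <- function(x, ...) {
  cat("<electrolyte_model>\n")
  cat(sprintf("  salt     %g mol/l  (n0  = %.4g 1/m^3)\n", x$salt_mol_l, x$n0))
  cat(sprintf("  water    %g mol/l  (n0w = %.4g 1/m^3)\n", x$water_mol_l, x$n0w))
  cat(sprintf("  lattice  n_s = n0w + 2 n0 = %.4g 1/m^3\n", x$ns))
  cat(sprintf("  dipole   %g D, T = %g K\n", x$dipole_debye, x$T))
  cat(sprintf("  bulk permittivity %.2f, Debye length %.3f nm\n",
              bulk_permittivity(x),
              m_to_nm(debye_length(x, bulk_permittivity(x)))))
  invisible(x)
}

#' @method tidy electrolyte_model
#' @export
tidy.electrolyte_model <- function(x, ...) {
  tibble::tibble(
    salt_mol_l = x$salt_mol_l, water_mol_l = x$water_mol_l,
    dipole_debye = x$dipole_debye, temperature_K = x$T,
    n0 = x$n0, n0w = x$n0w, ns = x$ns, p0 = x$p0, beta = x$beta,
    eps_bulk = bulk_permittivity(x),
    debye_length_nm = m_to_nm(debye_length(x, bulk_permittivity(x)))
  )
}
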