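# CODATA 2018 values, fixed at build time. Not user-editable: every routine in
# the package reads from this list so a single source of truth exists.
.consts <- list(
  e0    = 1.602176634e-19,  # elementary charge, C (exact)
  eps0  = 8.8541878128e-12, # vacuum permittivity, As/Vm
  k     = 1.380649e-23,     # Boltzmann constant, J/K (exact)
  N_A   = 6.02214076e23,    # Avogadro number, 1/mol (exact)
  debye = 3.33564e-30       # 1 debye in C m
)

#' Physical constants used throughout the package
#'
#' CODATA values of the elementary charge, vacuum permittivity, Boltzmann
#' constant, Avogadro number and the debye-to-SI dipole conversion. These are
#' fixed at build time; all internal computation is in SI units.
#'
#' @return A tibble with columns `constant`, `symbol`, `value`, `unit`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function() {
  tibble::tibble(
    constant = c("elementary charge", "vacuum permittivity",
                 "Boltzmann constant", "Avogadro number", "debye"),
    symbol   = c("e0", "eps0", "k", "N_A", "D"),
    value    = unlist(.consts, use.names = FALSE),
    unit     = c("C", "As/Vm", "J/K", "1/mol", "C m")
  )
}

#' Unit converters
#'
#' Pure converters between the user-facing units of the package
#' (concentrations in mol/l, dipole moments in debye, distances in nm) and the
#' SI units used internally. Each pair round-trips to machine precision.
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' per_m3_to_mol_l(mol_l_to_per_m3(0.15))
#' @name unit-converters
NULL

#' @rdname unit-converters
#' @export
mol_l_to_per_m3 <- function(x) x * 1000 * .consts$N_A

#' @rdname unit-converters
#' @export
per_m3_to_mol_l <- function(x) x / (1000 * .consts$N_A)

#' @rdname unit-converters
#' @export
debye_to_Cm <- function(x) x * .consts$debye

#' @rdname unit-converters
#' @export
Cm_to_debye <- function(x) x / .consts$debye

#' @rdname unit-converters
#' @export
nm_to_m <- function(x) x * 1e-9

#' @rdname unit-converters
#' @export
m_to_nm <- function(x) x * 1e9

#' Thermal energy
#'
#' @param temperature_K Temperature in kelvin.
#' @return kT in joules.
#' @examples
#' thermal_energy(298)
#' @export
thermal_energy <- function(temperature_K) .consts$k * temperature_K
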