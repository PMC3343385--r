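# Membrane-tube equilibria under protein decoration, and stylised packing
# scenarios for rod-like proteins on tubes. Units as in bending.R (nm, kT).

#' Equilibrium radius of a protein-decorated membrane tube
#'
#' Minimises the per-area free energy of a cylindrical membrane,
#' `f(R) = k_c / (2 R^2) - 2 m0 ln(2 cosh(l2 d_eff / 2R))
#'         + coverage * min_omega E_p(omega; R)`,
#' over the tube radius: bilayer bending plus the lipid deviatoric ordering
#' term plus the orientationally optimised bending energy of the adsorbed
#' rods at areal density `coverage`. A bracketed logarithmic grid scan is
#' followed by local refinement with [stats::optimize()]. Proteins with
#' larger intrinsic curvature pull the equilibrium towards thinner tubes;
#' under strong coupling the tube tracks `1/C_p`, which is how a
#' low-curvature protein (such as beta2-GPI on a giant-vesicle nanotube)
#' widens the tubes it decorates.
#'
#' @param material A [membrane_material()].
#' @param protein A [rod_protein()].
#' @param coverage Proteins per nm^2 of membrane, `>= 0`.
#' @param r_range_nm Search bracket for the radius (nm).
#' @param n_grid Number of logarithmic grid points for the coarse scan.
#' @return Object of class `tube_equilibrium`: list with `r_opt_nm`,
#'   `f_opt`, the scan tibble (`R_nm`, `f_per_area_kT_nm2`) and the inputs.
#'   Supports [tidy()], [glance()], [ggplot2::autoplot()].
#' @examples
#' eq <- equilibrium_tube_radius(membrane_material(), rod_protein(0.05),
#'                               coverage = 0.01)
#' glance(eq)
#' @export
equilibrium_tube_radius <- function(material, protein, coverage,
                                    r_range_nm = c(0.5, 500), n_grid = 400) {
  stopifnot(inherits(material, "membrane_material"),
            inherits(protein, "rod_protein"))
  if (coverage < 0) rlang::abort("`coverage` must be non-negative")
  if (coverage == 0 && material$d_eff == 0)
    rlang::abort(paste("no finite equilibrium: with no adsorbed proteins and",
                       "no deviatoric ordering the bending energy decreases",
                       "monotonically with radius"),
                 class = "barmem_no_minimum_error")

  f <- function(R) {
    patch <- membrane_patch(1 / R, 0)
    .tube_energy_per_area(R, material) +
      coverage * optimal_orientation(protein, patch)$E_min_kT
  }
  Rs <- exp(seq(log(r_range_nm[1]), log(r_range_nm[2]), length.out = n_grid))
  fs <- purrr::map_dbl(Rs, f)
  scan <- tibble::tibble(R_nm = Rs, f_per_area_kT_nm2 = fs)
  i <- which.min(fs)
  if (i == 1L || i == n_grid) {
    rlang::abort(
      c("no interior minimum of the tube energy in the search bracket",
        sprintf("minimum found at the %s edge (R = %.3g nm)",
                if (i == 1L) "lower" else "upper", Rs[i])),
      class = "barmem_no_minimum_error",
      scan = scan
    )
  }
  ref <- stats::optimize(f, lower = Rs[i - 1], upper = Rs[i + 1],
                         tol = 1e-10)
  structure(
    list(r_opt_nm = ref$minimum, f_opt = ref$objective, scan = scan,
         material = material, protein = protein, coverage = coverage),
    class = "tube_equilibrium"
  )
}

#' @export
print.tube_equilibrium <- function(x, ...) {
  cat("<tube_equilibrium>\n")
  cat(sprintf("  R* = %.3f nm (1/R* = %.4g 1/nm; protein c_p = %g 1/nm)\n",
              x$r_opt_nm, 1 / x$r_opt_nm, x$protein$c_p))
  cat(sprintf("  f(R*) = %.5g kT/nm^2 at coverage %g /nm^2\n",
              x$f_opt, x$coverage))
  invisible(x)
}

#' @method tidy tube_equilibrium
#' @export
tidy.tube_equilibrium <- function(x, ...) x$scan

#' @method glance tube_equilibrium
#' @export
glance.tube_equilibrium <- function(x, ...) {
  tibble::tibble(r_opt_nm = x$r_opt_nm, f_opt_kT_nm2 = x$f_opt,
                 coverage = x$coverage, c_p = x$protein$c_p,
                 k_c = x$material$k_c, d_eff = x$material$d_eff)
}

#' Plot a tube-radius energy scan
#'
#' @param object A `tube_equilibrium`.
#' @param ... Unused.
#' @return A ggplot object with the minimiser marked.
#' @method autoplot tube_equilibrium
#' @export
autoplot.tube_equilibrium <- function(object, ...) {
  ggplot(object$scan, aes(x = .data$R_nm, y = .data$f_per_area_kT_nm2)) +
    geom_line() +
    geom_vline(xintercept = object$r_opt_nm, linetype = 2) +
    scale_x_log10() +
    labs(x = "tube radius R (nm)", y = "free energy per area (kT/nm^2)") +
    theme_minimal()
}

#' Stylised packing scenarios of rigid rods on a membrane tube
#'
#' Compares, at each protein surface density, three stylised arrangements of
#' rigid rod-like proteins on a tube whose radius adapts to them:
#' * `dispersed` -- isolated proteins at their optimal orientation on a tube
#'   of radius `1/C_p`; no protein-protein contacts;
#' * `ring` -- circumferential rings (`omega = 0`) on the same tube; one
#'   end-to-end contact per protein;
#' * `spiral` -- a spiral aggregate at `omega = pi/4`, which by the rigid-rod
#'   relation [rigid_tube_c1()] tightens the tube to curvature `2 C_p`; two
#'   contacts per protein (end-to-end plus lateral).
#'
#' In the rigid limit the membrane adapts exactly, so the protein strain is
#' zero in all three cases and the competition is between the bilayer energy
#' of the (possibly tighter) tube -- counted as the excess over a flat
#' membrane and paid over the membrane area per protein `1/density` -- and
#' the contact energy gained. The contact bookkeeping
#' (0/1/2 per protein) is a deliberate stylisation; configurational entropy
#' of mixing is not modelled. Ties are resolved in the order dispersed,
#' ring, spiral (the entropically favoured order).
#'
#' @param protein A [rod_protein()].
#' @param material A [membrane_material()].
#' @param interaction_energy Direct protein-protein interaction energy per
#'   contact (kT); negative = attractive.
#' @param densities Protein surface densities (1/nm^2), non-negative.
#' @return Tibble with one row per density and configuration: energy
#'   components per protein (`membrane_kT`, `contacts_kT`, `total_kT`), a
#'   `tube_c1` column, and logical `minimal` marking the winning
#'   configuration at each density.
#' @examples
#' packing_scenarios(rod_protein(0.05), membrane_material(),
#'                   interaction_energy = -5, densities = c(1e-4, 0.01))
#' @export
packing_scenarios <- function(protein, material, interaction_energy,
                              densities) {
  stopifnot(inherits(protein, "rod_protein"),
            inherits(material, "membrane_material"))
  if (any(densities < 0)) rlang::abort("`densities` must be non-negative")
  configs <- tibble::tibble(
    config = factor(c("dispersed", "ring", "spiral"),
                    levels = c("dispersed", "ring", "spiral")),
    omega = c(NA, 0, pi / 4),
    contacts = c(0, 1, 2),
    tube_c1 = c(protein$c_p, protein$c_p, rigid_tube_c1(protein$c_p, pi / 4))
  )
  rows <- purrr::map(densities, function(dens) {
    area_per_protein <- if (dens > 0) 1 / dens else Inf
    out <- dplyr::mutate(
      configs,
      density = dens,
      membrane_kT = purrr::map_dbl(.data$tube_c1, function(c1) {
        f_flat <- -2 * material$m0 * log(2)        # D = 0 reference
        f <- if (c1 == 0) f_flat else .tube_energy_per_area(1 / c1, material)
        if (f == f_flat) 0 else (f - f_flat) * area_per_protein
      }),
      contacts_kT = .data$contacts * interaction_energy,
      total_kT = .data$membrane_kT + .data$contacts_kT
    )
    # ties (including density = 0, where all membrane terms are +/- Inf of
    # the same sign) resolve to the first-listed, most dispersed config
    best <- which(out$total_kT == min(out$total_kT))[1]
    out$minimal <- seq_len(3) == best
    out
  })
  dplyr::select(dplyr::bind_rows(rows), "density", "config", "omega",
                "contacts", "tube_c1", "membrane_kT", "contacts_kT",
                "total_kT", "minimal")
}
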