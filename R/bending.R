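# Orientation-dependent bending energetics of rod-like membrane inclusions.
# Working units throughout this module: lengths in nm, curvatures in 1/nm,
# energies in kT (flexural rigidity in kT nm, bending moduli in kT, lipid
# area density in 1/nm^2). Joule values are reported alongside where a
# temperature is available.

#' Rod-like membrane protein
#'
#' A BAR-type inclusion characterised by its intrinsic (preferred) curvature
#' `c_p`, flexural rigidity `k_p`, contour length `l0` and in-plane
#' orientation `omega`. The orientation enters the energetics only through
#' `cos(2 omega)`, so it is reduced modulo pi.
#'
#' The default magnitudes (`k_p` = 10 kT nm, `l0` = 20 nm) are
#' representative fixtures for an F-BAR-scale dimer, not measured values.
#'
#' @param c_p Intrinsic curvature (1/nm).
#' @param k_p Flexural rigidity (kT nm), `>= 0`.
#' @param l0 Protein length (nm), `> 0`.
#' @param omega Orientation angle (rad) between the protein's normal plane
#'   and the first principal direction.
#' @return Object of class `rod_protein`.
#' @examples
#' rod_protein(c_p = 0.05)
#' @export
rod_protein <- function(c_p, k_p = 10, l0 = 20, omega = 0) {
  if (k_p < 0) rlang::abort("`k_p` must be non-negative")
  if (l0 <= 0) rlang::abort("`l0` must be positive")
  structure(list(c_p = c_p, k_p = k_p, l0 = l0, omega = omega %% pi),
            class = "rod_protein")
}

#' @export
print.rod_protein <- function(x, ...) {
  cat(sprintf("<rod_protein> c_p = %g 1/nm, K_p = %g kT nm, L0 = %g nm, omega = %.3g rad\n",
              x$c_p, x$k_p, x$l0, x$omega))
  invisible(x)
}

#' Local membrane patch
#'
#' A point on the membrane described by its two principal curvatures, with
#' the derived mean curvature `H = (c1 + c2)/2` and curvature deviator
#' `D = |c1 - c2|/2`.
#'
#' @param c1,c2 Principal curvatures (1/nm).
#' @return Object of class `membrane_patch` with fields `c1`, `c2`, `H`, `D`.
#' @examples
#' membrane_patch(c1 = 0.1, c2 = 0) # cylinder of radius 10 nm
#' @export
membrane_patch <- function(c1, c2) {
  structure(list(c1 = c1, c2 = c2, H = (c1 + c2) / 2, D = abs(c1 - c2) / 2),
            class = "membrane_patch")
}

#' Bilayer elastic material
#'
#' Elastic description of a symmetric bilayer: local bending constant
#' `k_c`, Gaussian (saddle-splay) constant `k_g`, lipid area density `m0`,
#' effective intrinsic curvature deviator of the lipids `d_eff`, and the
#' coupling area `l2` that makes the deviatoric ordering argument
#' `l2 * d_eff * D` dimensionless. None of these moduli come from
#' measurement; the defaults are field-typical fixtures (`k_c` = 20 kT,
#' one lipid per 0.6 nm^2).
#'
#' @param k_c Local bending constant (kT), `> 0`.
#' @param k_g Gaussian constant (kT).
#' @param m0 Lipid area density (1/nm^2), `> 0`.
#' @param d_eff Effective lipid curvature deviator (1/nm), `>= 0`.
#' @param l2 Deviator coupling area (nm^2), `> 0`; the published variants of
#'   the orientational-ordering free energy carry such a constant and all
#'   equilibrium properties below are invariant to it up to a rescaling of
#'   `d_eff`.
#' @param temperature_K Temperature (K), used only to express energies in
#'   joules.
#' @return Object of class `membrane_material`.
#' @examples
#' membrane_material()
#' @export
membrane_material <- function(k_c = 20, k_g = -16, m0 = 1.67, d_eff = 1,
                              l2 = 1, temperature_K = 298) {
  if (k_c <= 0) rlang::abort("`k_c` must be positive")
  if (m0 <= 0) rlang::abort("`m0` must be positive")
  if (l2 <= 0) rlang::abort("`l2` must be positive")
  if (d_eff < 0) rlang::abort("`d_eff` must be non-negative")
  structure(list(k_c = k_c, k_g = k_g, m0 = m0, d_eff = d_eff, l2 = l2,
                 T = temperature_K),
            class = "membrane_material")
}

#' Parametric membrane shape
#'
#' Cylinders (`c1 = 1/radius`, `c2 = 0`) and spheres (`c1 = c2 = 1/radius`)
#' with their areas, for closed-form bilayer energies.
#'
#' @param kind `"cylinder"` or `"sphere"`.
#' @param radius_nm Radius (nm), `> 0`.
#' @param length_nm Length (nm), cylinders only.
#' @return Object of class `parametric_shape` with derived `c1`, `c2`,
#'   `area` (nm^2).
#' @examples
#' parametric_shape("cylinder", radius_nm = 10, length_nm = 100)
#' @export
parametric_shape <- function(kind = c("cylinder", "sphere"), radius_nm,
                             length_nm = NULL) {
  kind <- match.arg(kind)
  if (radius_nm <= 0) rlang::abort("`radius_nm` must be positive")
  if (kind == "cylinder") {
    if (is.null(length_nm) || length_nm <= 0)
      rlang::abort("cylinders need a positive `length_nm`")
    out <- list(kind = kind, radius = radius_nm, length = length_nm,
                c1 = 1 / radius_nm, c2 = 0,
                area = 2 * pi * radius_nm * length_nm)
  } else {
    out <- list(kind = kind, radius = radius_nm, length = NA_real_,
                c1 = 1 / radius_nm, c2 = 1 / radius_nm,
                area = 4 * pi * radius_nm^2)
  }
  structure(out, class = "parametric_shape")
}

#' Curvature seen by a rotated rod
#'
#' A rod lying on the membrane at orientation `omega` to the first principal
#' direction samples the normal curvature `C = H + D cos(2 omega)`, which is
#' always within `[H - D, H + D]`.
#'
#' @param patch A [membrane_patch()].
#' @param omega Orientation angle(s), rad.
#' @return Normal curvature (1/nm), vectorised over `omega`.
#' @examples
#' curvature_seen(membrane_patch(0.1, 0), pi / 2) # rod along the axis: 0
#' @export
curvature_seen <- function(patch, omega) {
  stopifnot(inherits(patch, "membrane_patch"))
  patch$H + patch$D * cos(2 * omega)
}

#' Bending energy of a flexible rod at a given curvature
#'
#' `E_p = (K_p L0 / 2) (C - C_p)^2`: the harmonic cost, under strong
#' adhesion, of bending the rod from its intrinsic curvature `C_p` to the
#' membrane curvature `C` it lies along.
#'
#' @param protein A [rod_protein()].
#' @param C Membrane curvature(s) sampled by the rod (1/nm).
#' @return Energy in kT, `>= 0`, zero iff `C = C_p`.
#' @examples
#' protein_energy(rod_protein(0.05, k_p = 10, l0 = 20), C = 0.1)
#' @export
protein_energy <- function(protein, C) {
  stopifnot(inherits(protein, "rod_protein"))
  protein$k_p * protein$l0 / 2 * (C - protein$c_p)^2
}

#' Orientation-dependent bending energy of a rod on a patch
#'
#' `E_p(omega) = (K_p L0 / 2) (H - C_p + D cos(2 omega))^2`; identically the
#' composition of [protein_energy()] with [curvature_seen()].
#'
#' @param protein A [rod_protein()].
#' @param patch A [membrane_patch()].
#' @param omega Orientation(s), rad; defaults to the protein's own.
#' @return Energy in kT, vectorised over `omega`.
#' @examples
#' p <- rod_protein(0.05)
#' protein_energy_orient(p, membrane_patch(0.1, 0), omega = pi / 4)
#' @export
protein_energy_orient <- function(protein, patch, omega = protein$omega) {
  stopifnot(inherits(protein, "rod_protein"), inherits(patch, "membrane_patch"))
  protein$k_p * protein$l0 / 2 *
    (patch$H - protein$c_p + patch$D * cos(2 * omega))^2
}

#' Energy landscape over orientations
#'
#' Convenience scan of `E_p(omega)` for plotting and for the `bend-orient`
#' command-line tool.
#'
#' @inheritParams protein_energy_orient
#' @param n Number of orientations over `[0, pi/2]`.
#' @return Tibble with `omega_rad`, `E_kT`.
#' @export
orientation_energy_scan <- function(protein, patch, n = 181) {
  omega <- seq(0, pi / 2, length.out = n)
  tibble::tibble(omega_rad = omega,
                 E_kT = protein_energy_orient(protein, patch, omega))
}

#' Optimal in-plane orientation of a rod on a patch
#'
#' Minimises the quadratic `E_p(omega)` analytically. If
#' `H - D <= C_p <= H + D` the rod can match its intrinsic curvature
#' exactly: `cos(2 omega*) = (C_p - H)/D` and the minimum energy is zero.
#' Otherwise the minimum sits at the boundary: `omega* = 0` when
#' `C_p > H + D`, `omega* = pi/2` when `C_p < H - D`. Of the two symmetric
#' interior minima `+/- omega*`, the non-negative smaller angle is returned;
#' for an isotropic patch (`D = 0`) the convention `omega* = 0` is used.
#'
#' @inheritParams protein_energy_orient
#' @return One-row tibble with `omega_opt` (rad, in `[0, pi/2]`) and
#'   `E_min_kT`.
#' @examples
#' optimal_orientation(rod_protein(0.05), membrane_patch(0.1, 0))
#' @export
optimal_orientation <- function(protein, patch) {
  stopifnot(inherits(protein, "rod_protein"), inherits(patch, "membrane_patch"))
  H <- patch$H; D <- patch$D; cp <- protein$c_p
  if (D == 0) {
    omega <- 0
  } else if (cp > H + D) {
    omega <- 0
  } else if (cp < H - D) {
    omega <- pi / 2
  } else {
    omega <- acos((cp - H) / D) / 2
  }
  tibble::tibble(omega_opt = omega,
                 E_min_kT = protein_energy_orient(protein, patch, omega))
}

#' Tube curvature imposed by a rigid rod at orientation omega
#'
#' In the rigid (stiff) limit the membrane tube adapts to the protein:
#' `C_p = C1 cos^2(omega)` inverts to `C1 = C_p / cos^2(omega)`. Rotating
#' the rod away from the tube's circumference therefore tightens the tube;
#' at `omega = pi/4` the tube curvature is exactly `2 C_p`.
#'
#' @param c_p Intrinsic curvature (1/nm), vectorised.
#' @param omega Orientation in `[0, pi/2)`, rad.
#' @return Tube principal curvature `C1` (1/nm), `>= c_p`.
#' @examples
#' rigid_tube_c1(0.05, pi / 4) # 0.1
#' @export
rigid_tube_c1 <- function(c_p, omega) {
  if (any(omega < 0 | omega >= pi / 2)) {
    rlang::abort(paste("`omega` must lie in [0, pi/2);",
                       "at pi/2 the protein lies along the tube axis",
                       "and the tube curvature is unconstrained"))
  }
  c_p / cos(omega)^2
}

#' Bilayer free energy of a parametric shape
#'
#' Closed-form evaluation of the symmetric-bilayer energy
#' `W_b = (k_c/2) int (2H)^2 dA + k_g int C1 C2 dA
#'        - 2 m0 kT int ln(2 cosh(l2 d_eff D)) dA`
#' on cylinders and spheres. The last term is the orientational-ordering
#' (deviatoric) free energy of the anisotropic lipids; it favours saddle or
#' cylindrical geometry (`D > 0`) and equals `-2 m0 kT ln 2 * Area` when
#' either `d_eff` or `D` vanishes.
#'
#' @param shape A [parametric_shape()].
#' @param material A [membrane_material()].
#' @return Tibble with one row per term (`bending`, `gaussian`,
#'   `deviatoric`, `total`) and columns `energy_kT`, `energy_J`.
#' @examples
#' membrane_energy(parametric_shape("sphere", 50), membrane_material())
#' @export
membrane_energy <- function(shape, material) {
  stopifnot(inherits(shape, "parametric_shape"),
            inherits(material, "membrane_material"))
  H <- (shape$c1 + shape$c2) / 2
  D <- abs(shape$c1 - shape$c2) / 2
  A <- shape$area
  bend <- material$k_c / 2 * (2 * H)^2 * A
  gauss <- material$k_g * shape$c1 * shape$c2 * A
  dev <- -2 * material$m0 * log(2 * cosh(material$l2 * material$d_eff * D)) * A
  kT <- thermal_energy(material$T)
  tibble::tibble(
    term = c("bending", "gaussian", "deviatoric", "total"),
    energy_kT = c(bend, gauss, dev, bend + gauss + dev),
    energy_J = kT * c(bend, gauss, dev, bend + gauss + dev)
  )
}

# Per-area bilayer free energy of a tube of radius R (nm), in kT/nm^2.
.tube_energy_per_area <- function(R, material) {
  D <- 1 / (2 * R)
  material$k_c / 2 * (1 / R)^2 -
    2 * material$m0 * log(2 * cosh(material$l2 * material$d_eff * D))
}
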