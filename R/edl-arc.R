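# 2-D double layer around the charged concave arc of a BAR domain.
# Finite-volume discretisation on a graded tensor-product grid; the arc's
# surface charge enters as a line-charge deposit on the control volumes it
# crosses (the discrete form of the interface flux-jump condition), and the
# permittivity is a step function: eps_ord within the ordered-water layer of
# thickness a on the concave side of the arc, eps_b elsewhere.

#' Geometry of a charged BAR-domain arc
#'
#' The concave charged face of a BAR domain is modelled as a circular arc of
#' curvature radius `R` and fixed arc length `L0` in a 2-D cross-section,
#' symmetric about the y-axis, with the concave side facing the membrane.
#' The field is evaluated at "point 1" on the symmetry axis at distance `d`
#' beyond the plane through the arc's tips, on the concave side -- the
#' position of the membrane surface beneath the bound protein. Its distance
#' from the arc's concave midpoint is therefore `sagitta + d`, where the
#' sagitta `R (1 - cos(L0 / 2R))` shrinks as the arc flattens, which is what
#' makes a flatter BAR domain (larger `R`) field stronger at the membrane.
#'
#' @param radius_nm Curvature radius `R` of the arc (nm).
#' @param arc_length_nm Arc length `L0` (nm), held fixed across radius
#'   scans; must satisfy `L0 <= pi R` (at most a half-circle).
#' @param layer_nm Ordered-water layer thickness `a` (nm), default 0.32.
#' @param sigma Uniform surface charge density of the concave face (As/m^2),
#'   default 0.2.
#' @param point_distance_nm Distance `d` of point 1 beyond the tip plane
#'   (nm), default 0.5.
#' @param body_nm Thickness of the impermeable protein body behind the
#'   charged face (nm), default 2 (the scale of a BAR-domain cross-section).
#'   The body region is excluded from the electrolyte domain with a no-flux
#'   condition, so the surface charge drives flux only through the concave
#'   face, as the surface boundary condition prescribes; `body_nm = 0`
#'   degenerates to a permeable charged sheet screened from both sides.
#' @return An object of class `arc_geometry` (all lengths stored in m).
#' @examples
#' g <- arc_geometry(radius_nm = 10, arc_length_nm = 20)
#' g$theta # subtended angle, L0/R = 2 rad
#' @export
arc_geometry <- function(radius_nm, arc_length_nm, layer_nm = 0.32,
                         sigma = 0.2, point_distance_nm = 0.5, body_nm = 2) {
  if (radius_nm <= 0 || arc_length_nm <= 0 || layer_nm <= 0)
    rlang::abort("`radius_nm`, `arc_length_nm` and `layer_nm` must be positive")
  if (arc_length_nm > pi * radius_nm + 1e-9)
    rlang::abort("arc length exceeds pi * R: the arc may subtend at most a half-circle")
  if (point_distance_nm < 0)
    rlang::abort("`point_distance_nm` must be non-negative")
  if (body_nm < 0)
    rlang::abort("`body_nm` must be non-negative")
  R <- nm_to_m(radius_nm); L0 <- nm_to_m(arc_length_nm)
  theta <- L0 / R
  structure(
    list(
      R = R, L0 = L0, a = nm_to_m(layer_nm), sigma = sigma,
      d = nm_to_m(point_distance_nm), body = nm_to_m(body_nm), theta = theta,
      sagitta = R * (1 - cos(theta / 2))
    ),
    class = "arc_geometry"
  )
}

#' @export
print.arc_geometry <- function(x, ...) {
  cat("<arc_geometry>\n")
  cat(sprintf("  R = %.3g nm, L0 = %.3g nm (subtends %.3g rad), a = %.3g nm\n",
              m_to_nm(x$R), m_to_nm(x$L0), x$theta, m_to_nm(x$a)))
  cat(sprintf("  sigma = %g As/m^2; point 1 at d = %.3g nm beyond the tip plane\n",
              x$sigma, m_to_nm(x$d)))
  cat(sprintf("  sagitta = %.3g nm -> point 1 is %.3g nm from the concave midpoint\n",
              m_to_nm(x$sagitta), m_to_nm(x$sagitta + x$d)))
  invisible(x)
}

# One coordinate axis: uniform fine step over [flo, fhi], geometric
# coarsening to [lo, hi].
.graded_axis <- function(lo, hi, flo, fhi, hf, hmax, grow = 1.35) {
  g <- seq(flo, fhi, by = hf)
  if (tail(g, 1) < fhi - 1e-15) g <- c(g, fhi)
  left <- c(); h <- hf; pos <- flo
  while (pos > lo) { h <- min(h * grow, hmax); pos <- pos - h; left <- c(pos, left) }
  if (length(left)) left[1] <- lo
  right <- c(); h <- hf; pos <- fhi
  while (pos < hi) { h <- min(h * grow, hmax); pos <- pos + h; right <- c(right, pos) }
  if (length(right)) right[length(right)] <- hi
  sort(unique(c(left, g, right)))
}

#' Solve the double layer around a charged BAR arc
#'
#' Solves `div(eps0 eps_r grad phi) = -rho_free` on a 2-D box around the
#' arc, with the arc's surface charge imposed as a flux jump (discretised as
#' a line-charge deposit conserving `sigma L0` exactly), a step-function
#' permittivity (`eps_ord` within distance `a` of the concave face,
#' `eps_b` elsewhere) and `phi = 0` on the outer boundary, which lies at
#' least 10 Debye lengths from the arc in every direction.
#'
#' In `mode = "full"` the charge density is the full Langevin-Bikerman
#' expression, solved by damped Newton with the field magnitude in the
#' steric denominator lagged one Picard sweep. In `mode = "linearized"` the
#' hyperbolic sine is linearised and the denominator replaced by `n_s`,
#' giving a single Debye-Hueckel solve.
#'
#' @param model An [electrolyte_model()].
#' @param geom An [arc_geometry()].
#' @param eps_ord Ordered-layer relative permittivity (default 54.5, the
#'   near-surface plateau of the planar profile at `sigma` = 0.2 As/m^2).
#' @param eps_b Bulk relative permittivity; defaults to the model's
#'   closed-form bulk value.
#' @param mode `"full"` (default) or `"linearized"`.
#' @param h_fine_nm Fine mesh step (nm) in the region containing the arc and
#'   point 1; must not exceed `a/4` so the ordered layer is resolved.
#' @param tol Relative convergence tolerance of the outer lagged-field
#'   iteration; the default sits just above the inner Newton noise floor and
#'   three orders below the mesh discretisation error.
#' @param max_picard,max_newton Iteration caps for the full mode.
#' @return An object of class `arc_field`: list with `field_at_point1`
#'   (V/m), `phi_at_point1` (V), the solution matrices (`phi`, `E`), grid
#'   vectors `x`, `y` (m), the geometry, and a `convergence` report.
#'   Supports [tidy()] (long tibble of the field map), [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' m <- electrolyte_model(0.15)
#' g <- arc_geometry(radius_nm = 4, arc_length_nm = 6)
#' sol <- solve_arc(m, g, mode = "linearized")
#' sol$field_at_point1
#' }
#' @export
solve_arc <- function(model, geom, eps_ord = 54.5, eps_b = NULL,
                      mode = c("full", "linearized"), h_fine_nm = 0.08,
                      tol = 1e-5, max_picard = 40, max_newton = 40) {
  stopifnot(inherits(model, "electrolyte_model"), inherits(geom, "arc_geometry"))
  mode <- match.arg(mode)
  if (is.null(eps_b)) eps_b <- bulk_permittivity(model)
  if (eps_ord < 1 || eps_b < 1)
    rlang::abort("permittivities must be >= 1")
  hf <- nm_to_m(h_fine_nm)
  if (hf > geom$a / 4 + 1e-15)
    rlang::abort("mesh too coarse: fine step must be <= a/4 in the ordered layer")

  R <- geom$R; th <- geom$theta; a <- geom$a; d <- geom$d; sigma <- geom$sigma
  lam <- debye_length(model, eps_b)
  M <- 10 * lam
  xe <- R * sin(th / 2)              # tip half-spacing
  ye <- -R * cos(th / 2)             # tip height (centre of curvature at origin)
  ypt <- ye + d                      # point 1 (concave side of the tip plane)
  pad <- 4 * hf

  xg <- .graded_axis(-(xe + M), xe + M, -(xe + a + pad), xe + a + pad, hf, lam / 2)
  xp <- xg[xg >= 0]
  xg <- sort(unique(c(-xp, xp)))     # enforce mirror symmetry, includes x = 0
  # anchor the uniform fine lattice on the arc's bottom surface (y = -R) so
  # the discrete charge row coincides with the physical surface at the
  # midpoint without creating degenerate thin cells
  flo <- -R - hf * ceiling((a + pad) / hf)
  fhi <- -R + hf * ceiling((max(ypt, ye) + pad + R) / hf)
  yg <- .graded_axis(-R - M, fhi + M, flo, fhi, hf, lam / 2)
  # place a grid line exactly at point 1, displacing any line closer than
  # half a cell so no degenerate thin cell is created
  yg <- sort(c(yg[abs(yg - ypt) > hf / 2], ypt))
  nx <- length(xg); ny <- length(yg)

  # protein body: impermeable region on the convex side of the charged face
  is_solid <- function(X, Y) {
    r <- sqrt(X^2 + Y^2)
    ang <- atan2(X, -Y)              # angle from the downward symmetry axis
    # strictly behind the surface: nodes on the charged face itself stay fluid
    geom$body > 0 & r > R + 1e-6 * hf & r <= R + geom$body & abs(ang) <= th / 2
  }
  XY <- expand.grid(X = xg, Y = yg)
  solid <- matrix(is_solid(XY$X, XY$Y), nx, ny)
  idx <- matrix(0L, nx, ny)
  interior <- which(outer(seq_len(nx), seq_len(ny),
                          function(i, j) i > 1 & i < nx & j > 1 & j < ny) &
                      !solid)
  idx[interior] <- seq_along(interior)
  nun <- length(interior)

  eps_at <- function(X, Y) {
    r <- sqrt(X^2 + Y^2)
    ang <- atan2(X, -Y)
    inlayer <- r < R & r > R - a & abs(ang) <= th / 2
    ifelse(inlayer, eps_ord, eps_b)
  }

  hx <- diff(xg); hy <- diff(yg)
  wx <- c(hx[1] / 2, (hx[-1] + hx[-length(hx)]) / 2, hx[length(hx)] / 2)
  wy <- c(hy[1] / 2, (hy[-1] + hy[-length(hy)]) / 2, hy[length(hy)] / 2)

  ij <- expand.grid(i = 2:(nx - 1), j = 2:(ny - 1))
  keep <- idx[cbind(ij$i, ij$j)] > 0     # skip protein-body nodes
  i <- ij$i[keep]; j <- ij$j[keep]
  k <- idx[cbind(i, j)]
  eps0 <- .consts$eps0
  aE <- eps0 * eps_at((xg[i] + xg[i + 1]) / 2, yg[j]) * wy[j] / hx[i]
  aW <- eps0 * eps_at((xg[i - 1] + xg[i]) / 2, yg[j]) * wy[j] / hx[i - 1]
  aN <- eps0 * eps_at(xg[i], (yg[j] + yg[j + 1]) / 2) * wx[i] / hy[j]
  aS <- eps0 * eps_at(xg[i], (yg[j - 1] + yg[j]) / 2) * wx[i] / hy[j - 1]
  # faces into the protein body carry no flux
  aE[solid[cbind(i + 1, j)]] <- 0
  aW[solid[cbind(i - 1, j)]] <- 0
  aN[solid[cbind(i, j + 1)]] <- 0
  aS[solid[cbind(i, j - 1)]] <- 0
  kE <- idx[cbind(i + 1, j)]; kW <- idx[cbind(i - 1, j)]
  kN <- idx[cbind(i, j + 1)]; kS <- idx[cbind(i, j - 1)]
  sE <- kE > 0; sW <- kW > 0; sN <- kN > 0; sS <- kS > 0
  Lap <- Matrix::sparseMatrix(
    i = c(k, k[sE], k[sW], k[sN], k[sS]),
    j = c(k, kE[sE], kW[sW], kN[sN], kS[sS]),
    x = c(-(aE + aW + aN + aS), aE[sE], aW[sW], aN[sN], aS[sS]),
    dims = c(nun, nun)
  )
  area <- wx[i] * wy[j]

  # surface charge: deposit sigma * ds of each arc segment on the control
  # volume of the nearest electrolyte node (the concave-face side when a
  # protein body is present); conserves the total line charge sigma * L0
  nseg <- max(200L, ceiling(geom$L0 / (hf / 4)))
  alph <- ((seq_len(nseg) - 0.5) / nseg - 0.5) * th
  ds <- geom$L0 / nseg
  sx <- R * sin(alph); sy <- -R * cos(alph)
  fi <- findInterval(sx, xg, rightmost.closed = TRUE)
  fj <- findInterval(sy, yg, rightmost.closed = TRUE)
  bsurf <- numeric(nun)
  for (s in seq_len(nseg)) {
    ci <- c(fi[s], fi[s] + 1L, fi[s], fi[s] + 1L)
    cj <- c(fj[s], fj[s], fj[s] + 1L, fj[s] + 1L)
    kc <- idx[cbind(ci, cj)]
    ok <- kc > 0
    if (!any(ok)) next
    d2 <- (xg[ci] - sx[s])^2 + (yg[cj] - sy[s])^2
    pick <- which(ok)[which.min(d2[ok])]
    bsurf[kc[pick]] <- bsurf[kc[pick]] + sigma * ds
  }

  # surface-field estimate at the charge-carrying nodes: all deposited flux
  # leaves through the concave face, so E ~ (line charge / cell width) /
  # (eps0 eps_ord); used for the lagged field there because the potential
  # spike of the regularised line charge corrupts finite differences
  dep <- bsurf > 0
  wx_of_k <- (wx[i])[match(seq_len(nun), k)]
  E_dep <- (bsurf / wx_of_k) / (eps0 * eps_ord)

  grad_mag <- function(phi_vec) {
    Phi <- matrix(0, nx, ny); Phi[interior] <- phi_vec
    Ex <- matrix(0, nx, ny); Ey <- matrix(0, nx, ny)
    Ex[2:(nx - 1), ] <- (Phi[3:nx, ] - Phi[1:(nx - 2), ]) /
      (xg[3:nx] - xg[1:(nx - 2)])
    Ey[, 2:(ny - 1)] <- t(t(Phi[, 3:ny] - Phi[, 1:(ny - 2)]) /
                            (yg[3:ny] - yg[1:(ny - 2)]))
    out <- sqrt(Ex^2 + Ey^2)[interior]
    out[dep] <- E_dep[dep]
    out
  }

  conv <- list(mode = mode, unknowns = nun, picard = 0L, newton = 0L,
               residual = 0, converged = TRUE)
  if (sigma == 0) {
    phi <- numeric(nun)
  } else if (mode == "linearized") {
    kap2 <- 2 * .consts$e0^2 * model$n0 * model$beta   # rho = -kap2 * phi
    A <- Lap - Matrix::Diagonal(nun, x = kap2 * area)
    phi <- as.numeric(Matrix::solve(A, -bsurf))
  } else {
    phi <- numeric(nun); E_lag <- numeric(nun)
    scale <- max(bsurf)
    done <- FALSE
    relax_E <- 0.5   # damp the lagged-field update of the steric denominator
    for (out in seq_len(max_picard)) {
      phi_old <- phi
      for (nit in seq_len(max_newton)) {
        res <- as.numeric(Lap %*% phi) +
          free_charge_density(model, phi, E_lag) * area + bsurf
        conv$newton <- conv$newton + 1L
        if (max(abs(res)) < 1e-8 * scale) break
        J <- Lap + Matrix::Diagonal(
          nun, x = .d_free_charge_density(model, phi, E_lag) * area)
        dphi <- as.numeric(Matrix::solve(J, -res))
        t <- 1; r0 <- max(abs(res))
        repeat {
          cand <- phi + t * dphi
          rc <- max(abs(as.numeric(Lap %*% cand) +
                          free_charge_density(model, cand, E_lag) * area + bsurf))
          if (rc < r0 || t < 1e-4) break
          t <- t / 2
        }
        phi <- cand
      }
      E_lag <- (1 - relax_E) * E_lag + relax_E * grad_mag(phi)
      conv$picard <- out
      conv$history <- c(conv$history,
                        max(abs(phi - phi_old)) / max(max(abs(phi)), 1e-15))
      if (tail(conv$history, 1) < tol) {
        done <- TRUE; break
      }
    }
    conv$residual <- max(abs(as.numeric(Lap %*% phi) +
                               free_charge_density(model, phi, E_lag) * area +
                               bsurf)) / scale
    if (!done)
      rlang::abort("arc solver: Picard iteration on the lagged field failed to converge",
                   class = "barmem_convergence_error",
                   history = conv$history)
  }

  Phi <- matrix(0, nx, ny); Phi[interior] <- phi
  Ex <- matrix(0, nx, ny); Ey <- matrix(0, nx, ny)
  Ex[2:(nx - 1), ] <- (Phi[3:nx, ] - Phi[1:(nx - 2), ]) / (xg[3:nx] - xg[1:(nx - 2)])
  Ey[, 2:(ny - 1)] <- t(t(Phi[, 3:ny] - Phi[, 1:(ny - 2)]) / (yg[3:ny] - yg[1:(ny - 2)]))
  Emag <- sqrt(Ex^2 + Ey^2)
  i0 <- which.min(abs(xg)); j0 <- which.min(abs(yg - ypt))
  # second-order three-point derivatives at point 1 (its grid line has
  # unequal neighbour spacing; the wide central difference is biased there)
  d3p <- function(fm, f0, fp, dm, dp)
    (dm^2 * fp - dp^2 * fm + (dp^2 - dm^2) * f0) / (dm * dp * (dm + dp))
  Ey_pt <- d3p(Phi[i0, j0 - 1], Phi[i0, j0], Phi[i0, j0 + 1],
               yg[j0] - yg[j0 - 1], yg[j0 + 1] - yg[j0])
  Ex_pt <- d3p(Phi[i0 - 1, j0], Phi[i0, j0], Phi[i0 + 1, j0],
               xg[i0] - xg[i0 - 1], xg[i0 + 1] - xg[i0])
  Emag[i0, j0] <- sqrt(Ex_pt^2 + Ey_pt^2)

  structure(
    list(
      field_at_point1 = Emag[i0, j0],
      phi_at_point1 = Phi[i0, j0],
      point1 = c(x = 0, y = ypt),
      phi = Phi, E = Emag, x = xg, y = yg,
      geom = geom, eps_ord = eps_ord, eps_b = eps_b, mode = mode,
      convergence = conv
    ),
    class = "arc_field"
  )
}

#' @export
print.arc_field <- function(x, ...) {
  cat("<arc_field>\n")
  cat(sprintf("  R = %.3g nm, L0 = %.3g nm, sigma = %g As/m^2, mode = %s\n",
              m_to_nm(x$geom$R), m_to_nm(x$geom$L0), x$geom$sigma, x$mode))
  cat(sprintf("  %d unknowns; |E| at point 1 = %.4g V/m (phi = %.3g mV)\n",
              x$convergence$unknowns, x$field_at_point1, 1e3 * x$phi_at_point1))
  invisible(x)
}

#' @method tidy arc_field
#' @export
tidy.arc_field <- function(x, ...) {
  tibble::tibble(
    x_nm = rep(m_to_nm(x$x), times = length(x$y)),
    y_nm = rep(m_to_nm(x$y), each = length(x$x)),
    phi_mV = as.vector(x$phi) * 1e3,
    E_V_per_m = as.vector(x$E)
  )
}

#' @method glance arc_field
#' @export
glance.arc_field <- function(x, ...) {
  tibble::tibble(
    R_nm = m_to_nm(x$geom$R), L0_nm = m_to_nm(x$geom$L0),
    sigma = x$geom$sigma, mode = x$mode,
    E_point1_V_per_m = x$field_at_point1,
    phi_point1_mV = 1e3 * x$phi_at_point1,
    unknowns = x$convergence$unknowns,
    picard_iterations = x$convergence$picard
  )
}

#' Plot the potential map around a charged arc
#'
#' @param object An `arc_field` from [solve_arc()].
#' @param ... Unused.
#' @return A ggplot raster of the potential with point 1 marked.
#' @method autoplot arc_field
#' @export
autoplot.arc_field <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_nm, y = .data$y_nm, fill = .data$phi_mV)) +
    geom_raster(interpolate = TRUE) +
    annotate("point", x = 0, y = m_to_nm(object$point1[["y"]]),
             shape = 4, size = 2) +
    scale_fill_viridis_c(name = "phi (mV)") +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)") +
    theme_minimal()
}

#' Field at point 1 as a function of the arc's curvature radius
#'
#' Runs [solve_arc()] for each radius at fixed arc length, layer thickness
#' and mesh resolution, and reports the field magnitude at point 1. The
#' headline physics: at fixed `L0` the field grows strongly and
#' monotonically with `R`, because the flatter arc brings its charged
#' concave face closer to the membrane plane through its tips.
#'
#' @param model An [electrolyte_model()].
#' @param radii_nm Strictly increasing vector of curvature radii (nm).
#' @param arc_length_nm Fixed arc length `L0` (nm).
#' @param layer_nm,sigma,point_distance_nm Passed to [arc_geometry()].
#' @param eps_ord,eps_b,mode,h_fine_nm Passed to [solve_arc()].
#' @return A tibble of class `field_scan` with columns `R_nm`,
#'   `E_point1_V_per_m`, `phi_point1_mV`; attribute `monotone_increasing`
#'   flags whether the field column increases strictly.
#' @examples
#' \donttest{
#' m <- electrolyte_model(0.15)
#' field_vs_radius(m, radii_nm = c(3, 6, 12), arc_length_nm = 6,
#'                 mode = "linearized")
#' }
#' @export
field_vs_radius <- function(model, radii_nm, arc_length_nm, layer_nm = 0.32,
                            sigma = 0.2, point_distance_nm = 0.5,
                            eps_ord = 54.5, eps_b = NULL,
                            mode = c("full", "linearized"), h_fine_nm = 0.08) {
  mode <- match.arg(mode)
  if (anyDuplicated(radii_nm))
    rlang::abort("`radii_nm` contains duplicated radii")
  if (is.unsorted(radii_nm, strictly = TRUE))
    rlang::abort("`radii_nm` must be strictly increasing")
  rows <- purrr::map(radii_nm, function(R) {
    sol <- tryCatch({
      g <- arc_geometry(R, arc_length_nm, layer_nm, sigma, point_distance_nm)
      solve_arc(model, g, eps_ord = eps_ord, eps_b = eps_b, mode = mode,
                h_fine_nm = h_fine_nm)
    }, error = function(e) rlang::abort(
      sprintf("arc solve failed at R = %g nm", R), parent = e)
    )
    tibble::tibble(R_nm = R, E_point1_V_per_m = sol$field_at_point1,
                   phi_point1_mV = 1e3 * sol$phi_at_point1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "monotone_increasing") <- all(diff(out$E_point1_V_per_m) > 0)
  class(out) <- c("field_scan", class(out))
  out
}

#' Plot a field-versus-radius scan
#'
#' @param object A `field_scan` from [field_vs_radius()].
#' @param ... Unused.
#' @return A ggplot object (log-scaled field axis).
#' @method autoplot field_scan
#' @export
autoplot.field_scan <- function(object, ...) {
  ggplot(object, aes(x = .data$R_nm, y = .data$E_point1_V_per_m)) +
    geom_line() + geom_point() +
    scale_y_log10() +
    labs(x = "curvature radius R (nm)",
         y = "|E| at point 1 (V/m)") +
    theme_minimal()
}
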