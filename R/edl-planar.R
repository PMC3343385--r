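# 1-D planar Langevin-Bikerman solver. Finite differences in conservative
# form on a graded grid; damped Newton for the nonlinear Poisson problem;
# outer fixed-point iteration on the permittivity profile, started from the
# constant bulk value, with under-relaxation.

#' Graded 1-D grid for the planar double-layer solver
#'
#' Node positions start at the charged surface (`x = 0`) with fine spacing
#' and grow geometrically into the bulk. The domain must span at least 10
#' Debye lengths of the configured electrolyte so that the far Dirichlet
#' boundary (`phi = 0`) is a faithful stand-in for the decay condition at
#' infinity, and the spacing at the surface must be at most 0.01 nm to
#' resolve the ordered-water layer.
#'
#' @param model An [electrolyte_model()], used to size the domain in Debye
#'   lengths.
#' @param h0_nm Node spacing at the surface (nm), `<= 0.01`.
#' @param growth Geometric growth factor of the spacing.
#' @param n_debye Domain length in bulk Debye lengths, `>= 10`.
#' @return An object of class `planar_grid` with field `x` (m, increasing,
#'   `x[1] = 0`).
#' @examples
#' g <- planar_grid(electrolyte_model(0.15))
#' length(g$x)
#' @export
planar_grid <- function(model, h0_nm = 0.01, growth = 1.05, n_debye = 12) {
  stopifnot(inherits(model, "electrolyte_model"))
  if (h0_nm > 0.01 + 1e-12)
    rlang::abort("surface node spacing `h0_nm` must be <= 0.01 nm")
  if (n_debye < 10)
    rlang::abort("domain must span at least 10 Debye lengths (`n_debye` >= 10)")
  lam <- debye_length(model, bulk_permittivity(model))
  L <- n_debye * lam
  h0 <- nm_to_m(h0_nm)
  n_max <- ceiling(log(1 + L * (growth - 1) / h0) / log(growth)) + 2
  x <- c(0, cumsum(h0 * growth^(0:n_max)))
  x <- x[x < L]
  x <- c(x, L)
  structure(list(x = x, domain_length = L, h0 = h0, growth = growth),
            class = "planar_grid")
}

# Assemble and solve one damped-Newton pass for the planar problem at fixed
# face permittivities and lagged field magnitude in the steric denominator.
# Unknowns are phi at nodes 1..N-1 (R indexing; node N is Dirichlet phi = 0).
.planar_newton <- function(x, phi, eps_face, sigma, rho_fun, drho_fun, E_lag,
                           tol, max_iter) {
  eps0 <- .consts$eps0
  N <- length(x)
  h <- diff(x)                       # N-1 segment lengths
  w <- c(h[1] / 2, (h[-1] + h[-(N - 1)]) / 2)  # control-volume widths, 1..N-1
  a <- eps0 * eps_face / h           # face conductances, N-1 values
  resid <- function(p) {
    Fl <- a * diff(p)                # flux at faces 1..N-1
    r <- numeric(N - 1)
    r[1] <- Fl[1] + sigma + rho_fun(p[1], E_lag[1]) * w[1]
    i <- 2:(N - 1)
    r[i] <- Fl[i] - Fl[i - 1] + rho_fun(p[i], E_lag[i]) * w[i]
    r
  }
  scale <- max(abs(sigma), 1e-12)
  r <- resid(phi)
  iter <- 0L
  while (max(abs(r)) > tol * scale && iter < max_iter) {
    iter <- iter + 1L
    n <- N - 1
    dr <- drho_fun(phi[1:n], E_lag[1:n]) * w
    dd <- c(-a[1] + dr[1], -a[2:n] - a[1:(n - 1)] + dr[2:n])
    lo <- a[1:(n - 1)]
    up <- c(a[1:(n - 1)], 0)[1:(n - 1)]
    # Thomas algorithm on the tridiagonal Jacobian
    b <- -r
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- up[1] / dd[1]; dp[1] <- b[1] / dd[1]
    for (i in 2:n) {
      m <- dd[i] - lo[i - 1] * cp[i - 1]
      if (i < n) cp[i] <- up[i] / m
      dp[i] <- (b[i] - lo[i - 1] * dp[i - 1]) / m
    }
    dphi <- numeric(n); dphi[n] <- dp[n]
    for (i in (n - 1):1) dphi[i] <- dp[i] - cp[i] * dphi[i + 1]
    # damping: halve the step until the residual norm decreases
    t <- 1; r0 <- max(abs(r))
    repeat {
      cand <- phi
      cand[1:n] <- phi[1:n] + t * dphi
      rc <- resid(cand)
      if (max(abs(rc)) < r0 || t < 1e-6) break
      t <- t / 2
    }
    phi <- cand; r <- rc
  }
  list(phi = phi, residual = max(abs(r)) / scale, iterations = iter)
}

# |d phi/dx| at the nodes: central differences inside, one-sided at the ends.
.grad_mag_1d <- function(x, phi) {
  N <- length(x)
  E <- numeric(N)
  E[1] <- abs((phi[2] - phi[1]) / (x[2] - x[1]))
  E[N] <- abs((phi[N] - phi[N - 1]) / (x[N] - x[N - 1]))
  i <- 2:(N - 1)
  E[i] <- abs((phi[i + 1] - phi[i - 1]) / (x[i + 1] - x[i - 1]))
  E
}

#' Solve the planar Langevin-Bikerman double layer
#'
#' Solves `d/dx (eps0 eps_r(x) dphi/dx) = -rho_free(phi, E)` on a graded 1-D
#' grid with a surface-charge Neumann condition at `x = 0`
#' (`eps0 eps_r(0) phi'(0) = -sigma`, with `eps_r(0)` taken self-consistently
#' from the current iterate) and `phi = 0` at the far boundary. The spatial
#' permittivity profile is obtained iteratively: starting from the constant
#' bulk value, `eps_r(x)` is recomputed from the latest `(phi, E)` via
#' [relative_permittivity()], under-relaxed, and the nonlinear Poisson
#' problem is re-solved until the relative sup-norm change of the profile
#' falls below `outer_tol`. The inner problem is solved by damped Newton with
#' an analytic tridiagonal Jacobian; the field magnitude inside the steric
#' denominator `H` is lagged one outer iteration.
#'
#' @param model An [electrolyte_model()].
#' @param sigma Surface charge density in As/m^2; `|sigma| <= 1` (documented
#'   validity range of the mean-field model).
#' @param grid A [planar_grid()]; defaults to `planar_grid(model)`.
#' @param permittivity `"iterative"` (default) for the self-consistent
#'   profile, `"bulk"` to freeze `eps_r` at the bulk value, or `"frozen"` to
#'   impose the fixed profile `eps_profile(x)`.
#' @param eps_profile Function of position (m) returning `eps_r`, used only
#'   with `permittivity = "frozen"`.
#' @param steric If `FALSE`, the steric denominator is replaced by `n_s`,
#'   giving the point-ion (Gouy-Chapman) charge density; useful for
#'   validation against the classical closed form.
#' @param outer_tol Sup-norm tolerance on the relative permittivity update.
#' @param newton_tol Relative residual tolerance of the inner Newton loop.
#' @param relax Under-relaxation factor for the permittivity update.
#' @param max_outer,max_newton Iteration caps.
#' @return An object of class `edl_profile`: list with `profile` (a tibble
#'   with columns `x_nm`, `phi_mV`, `E_V_per_m`, `eps_r`, `rho_C_per_m3`),
#'   `sigma`, `model`, and `convergence` (iterations, final residual, final
#'   permittivity-update norm). Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' prof <- solve_planar(electrolyte_model(0.15), sigma = 0.2)
#' glance(prof)
#' }
#' @export
solve_planar <- function(model, sigma, grid = NULL,
                         permittivity = c("iterative", "bulk", "frozen"),
                         eps_profile = NULL, steric = TRUE,
                         outer_tol = 1e-6, newton_tol = 1e-10, relax = 0.5,
                         max_outer = 400, max_newton = 80) {
  stopifnot(inherits(model, "electrolyte_model"))
  permittivity <- match.arg(permittivity)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma))
    rlang::abort("`sigma` must be a single finite number (As/m^2)")
  if (abs(sigma) > 1)
    rlang::abort("|sigma| > 1 As/m^2 is outside the documented validity range")
  if (permittivity == "frozen" && !is.function(eps_profile))
    rlang::abort("`eps_profile` must be a function of x when permittivity = \"frozen\"")
  if (is.null(grid)) grid <- planar_grid(model)
  stopifnot(inherits(grid, "planar_grid"))

  x <- grid$x
  N <- length(x)
  eb <- bulk_permittivity(model)

  if (steric) {
    rho_fun  <- function(p, E) free_charge_density(model, p, E)
    drho_fun <- function(p, E) .d_free_charge_density(model, p, E)
  } else {
    rho_fun  <- function(p, E)
      -2 * .consts$e0 * model$n0 * sinh(.consts$e0 * p * model$beta)
    drho_fun <- function(p, E)
      -2 * .consts$e0^2 * model$beta * model$n0 *
        cosh(.consts$e0 * p * model$beta)
  }

  eps_now <- switch(permittivity,
    iterative = rep(eb, N),
    bulk      = rep(eb, N),
    frozen    = eps_profile(x)
  )
  phi <- rep(0, N)
  E_lag <- rep(0, N)
  eps_change <- NA_real_
  history <- numeric(0)
  newt <- list(residual = 0, iterations = 0L)
  outer <- 0L
  repeat {
    outer <- outer + 1L
    eps_face <- 2 * eps_now[-N] * eps_now[-1] / (eps_now[-N] + eps_now[-1])
    phi_old <- phi
    newt <- .planar_newton(x, phi, eps_face, sigma, rho_fun, drho_fun, E_lag,
                           newton_tol, max_newton)
    phi <- newt$phi
    E <- .grad_mag_1d(x, phi)
    E[1] <- abs(sigma) / (.consts$eps0 * eps_now[1])  # boundary condition value
    if (permittivity == "iterative") {
      eps_new <- relative_permittivity(model, phi, E)
      eps_change <- max(abs(eps_new - eps_now) / eps_now)
      eps_now <- (1 - relax) * eps_now + relax * eps_new
    } else {
      eps_change <- 0
    }
    phi_change <- max(abs(phi - phi_old)) / max(max(abs(phi)), 1e-15)
    history <- c(history, eps_change)
    done <- eps_change < outer_tol && phi_change < outer_tol
    if (done || outer >= max_outer) break
    E_lag <- E
  }
  # boundary-condition field value with the final (post-update) permittivity
  E[1] <- abs(sigma) / (.consts$eps0 * eps_now[1])
  if (!done) {
    rlang::abort(
      c("planar solver failed to converge",
        sprintf("outer iterations: %d, last permittivity update: %.3g",
                outer, eps_change)),
      class = "barmem_convergence_error",
      history = history
    )
  }
  rho <- rho_fun(phi, E)
  structure(
    list(
      profile = tibble::tibble(
        x_nm = m_to_nm(x), phi_mV = phi * 1e3, E_V_per_m = E,
        eps_r = eps_now, rho_C_per_m3 = rho
      ),
      x = x, sigma = sigma, model = model,
      options = list(permittivity = permittivity, steric = steric,
                     outer_tol = outer_tol, newton_tol = newton_tol,
                     relax = relax),
      convergence = list(
        outer_iterations = outer,
        newton_iterations_last = newt$iterations,
        residual = newt$residual,
        eps_update = eps_change,
        converged = done
      )
    ),
    class = "edl_profile"
  )
}

#' @export
print.edl_profile <- function(x, ...) {
  cat("<edl_profile>\n")
  cat(sprintf("  sigma = %g As/m^2, %d nodes over %.2f nm\n",
              x$sigma, nrow(x$profile), max(x$profile$x_nm)))
  cat(sprintf("  phi(0) = %.2f mV, E(0) = %.3g V/m, eps_r(0) = %.2f\n",
              x$profile$phi_mV[1], x$profile$E_V_per_m[1], x$profile$eps_r[1]))
  cat(sprintf("  converged in %d outer iterations (eps update %.2g)\n",
              x$convergence$outer_iterations, x$convergence$eps_update))
  invisible(x)
}

#' @method tidy edl_profile
#' @export
tidy.edl_profile <- function(x, ...) x$profile

#' @method glance edl_profile
#' @export
glance.edl_profile <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma,
    phi0_mV = x$profile$phi_mV[1],
    E0_V_per_m = x$profile$E_V_per_m[1],
    eps_r0 = x$profile$eps_r[1],
    eps_r_bulk = bulk_permittivity(x$model),
    outer_iterations = x$convergence$outer_iterations,
    residual = x$convergence$residual,
    eps_update = x$convergence$eps_update,
    electroneutrality = electroneutrality(x)
  )
}

#' Plot a planar double-layer profile
#'
#' @param object An `edl_profile` from [solve_planar()].
#' @param what Which quantity to plot against distance: `"eps_r"`,
#'   `"phi_mV"`, `"E_V_per_m"` or `"rho_C_per_m3"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edl_profile
#' @export
autoplot.edl_profile <- function(object, what = "eps_r", ...) {
  stopifnot(what %in% c("eps_r", "phi_mV", "E_V_per_m", "rho_C_per_m3"))
  lab <- c(eps_r = "relative permittivity",
           phi_mV = "electric potential (mV)",
           E_V_per_m = "field magnitude (V/m)",
           rho_C_per_m3 = "net charge density (C/m^3)")[[what]]
  ggplot(object$profile, aes(x = .data$x_nm, y = .data[[what]])) +
    geom_line(linewidth = 0.7) +
    labs(x = "distance from charged surface (nm)", y = lab) +
    theme_minimal()
}

#' Permittivity of the ordered surface layer
#'
#' Reports the relative permittivity at the charged surface and its
#' arithmetic average over the first `a_nm` nanometres, so that the
#' step-function value used by the arc solver is reproducible from a
#' converged planar profile. Both readings are returned because either could
#' serve as the ordered-layer value.
#'
#' @param profile An `edl_profile` from [solve_planar()].
#' @param a_nm Ordered-layer thickness in nm (default 0.32).
#' @return One-row tibble with `at_surface` and `layer_average`.
#' @examples
#' \donttest{
#' prof <- solve_planar(electrolyte_model(0.15), sigma = 0.2)
#' surface_layer_permittivity(prof, a_nm = 0.32)
#' }
#' @export
surface_layer_permittivity <- function(profile, a_nm = 0.32) {
  stopifnot(inherits(profile, "edl_profile"))
  p <- profile$profile
  if (a_nm <= 0 || a_nm > max(p$x_nm))
    rlang::abort("`a_nm` must lie within the grid extent")
  xs <- seq(0, a_nm, length.out = 401)
  es <- stats::approx(p$x_nm, p$eps_r, xout = xs)$y
  tibble::tibble(
    at_surface = p$eps_r[1],
    # trapezoidal mean over [0, a]
    layer_average = sum((es[-1] + es[-length(es)]) / 2 * diff(xs)) / a_nm
  )
}

#' Electroneutrality check of a converged profile
#'
#' Integrates the net space charge of the diffuse layer and compares it with
#' the surface charge; Gauss's law requires the ratio
#' `integral(rho) / (-sigma)` to equal 1.
#'
#' @param profile An `edl_profile`.
#' @return The ratio; `NA` for an uncharged surface.
#' @export
electroneutrality <- function(profile) {
  stopifnot(inherits(profile, "edl_profile"))
  if (profile$sigma == 0) return(NA_real_)
  x <- profile$x
  r <- profile$profile$rho_C_per_m3
  Q <- sum((r[-1] + r[-length(r)]) / 2 * diff(x))
  Q / (-profile$sigma)
}
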