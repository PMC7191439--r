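#' Fluid properties
#'
#' Constant-property Newtonian air under mechanical ventilation. Defaults are
#' air at body-humidified conditions: density 1.161 kg/m^3 and dynamic
#' viscosity 1.864e-5 kg/(m s). Body forces are omitted (steady horizontal
#' duct flow at negligible Froude-number relevance).
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (kg/(m s)).
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho = 1.161, mu = 1.864e-5) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu, body_force = 0), class = "fluid_properties")
}

#' Boundary conditions
#'
#' Constant volume-controlled inspiratory flow at the inlet (default 3 L/min),
#' zero static gauge pressure at the outlet, rigid no-slip walls. Inlet
#' turbulence is prescribed by an intensity and a length scale expressed as a
#' fraction of the local diameter.
#'
#' @param inlet_flow volumetric flow rate (L/min).
#' @param outlet_pressure outlet gauge pressure (Pa); fixed at 0.
#' @param turbulence_intensity inlet turbulence intensity (fraction of mean
#'   speed).
#' @param turbulence_length_frac inlet turbulence length scale as a fraction
#'   of the inlet diameter.
#' @param inlet_profile `"uniform"` plug (a long upstream extension develops
#'   it) or `"parabolic"` (fully developed laminar inflow, used by analytic
#'   validation cases).
#' @return object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_flow = 3, outlet_pressure = 0,
                                turbulence_intensity = 0.05,
                                turbulence_length_frac = 0.1,
                                inlet_profile = c("uniform", "parabolic")) {
  stopifnot(inlet_flow >= 0, turbulence_intensity >= 0,
            turbulence_length_frac > 0)
  if (outlet_pressure != 0)
    stop("outlet gauge pressure is the datum and must be 0")
  structure(list(inlet_flow = inlet_flow, outlet_pressure = 0,
                 turbulence_intensity = turbulence_intensity,
                 turbulence_length_frac = turbulence_length_frac,
                 inlet_profile = match.arg(inlet_profile)),
            class = "boundary_conditions")
}

#' Wilcox k-omega closure coefficients
#'
#' The standard two-equation closure constants: `alpha = 5/9`, `beta = 3/40`,
#' `beta_star = 9/100`, `sigma = 1/2`, `sigma_star = 1/2`.
#'
#' @return named list of the five exact rational coefficients.
#' @export
kw_closure <- function() {
  list(alpha = 5 / 9, beta = 3 / 40, beta_star = 9 / 100,
       sigma = 1 / 2, sigma_star = 1 / 2)
}

#' Solver settings
#'
#' @param convergence_tol relative inter-iteration variation below which the
#'   solution is declared steady (applied to every transported field).
#' @param max_iterations outer SIMPLE iteration cap.
#' @param relax_u,relax_p,relax_kw under-relaxation factors for momentum,
#'   pressure, and the turbulence scalars.
#' @param convection_scheme `"second_order_upwind"` (deferred correction) or
#'   `"upwind"`.
#' @param laminar_mode disable the turbulence model (molecular viscosity only).
#' @param quadratic_wall use a second-order one-sided wall gradient for the
#'   viscous wall flux (deferred correction).
#' @param n_sweeps inner line-relaxation sweeps per transport equation.
#' @param min_iterations iterations before the convergence test may fire.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(convergence_tol = 1e-5, max_iterations = 20000L,
                            relax_u = 0.7, relax_p = 0.3, relax_kw = 0.8,
                            convection_scheme = c("second_order_upwind", "upwind"),
                            laminar_mode = FALSE, quadratic_wall = TRUE,
                            n_sweeps = 2L, min_iterations = 20L) {
  stopifnot(convergence_tol > 0, convergence_tol < 1, max_iterations >= 1,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1,
            relax_kw > 0, relax_kw <= 1, n_sweeps >= 1)
  structure(list(convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 relax_u = relax_u, relax_p = relax_p, relax_kw = relax_kw,
                 convection_scheme = match.arg(convection_scheme),
                 laminar_mode = isTRUE(laminar_mode),
                 quadratic_wall = isTRUE(quadratic_wall),
                 n_sweeps = as.integer(n_sweeps),
                 min_iterations = as.integer(min_iterations)),
            class = "solver_settings")
}

#' Eddy viscosity of the k-omega closure
#'
#' `mu_t = rho * k / omega`.
#'
#' @param rho density (kg/m^3).
#' @param k turbulence kinetic energy (m^2/s^2), `>= 0`.
#' @param omega specific dissipation rate (1/s), `> 0`.
#' @return eddy viscosity (kg/(m s)).
#' @export
eddy_viscosity <- function(rho, k, omega) {
  if (any(omega <= 0)) stop("omega must be positive")
  if (any(k < 0)) stop("k must be nonnegative")
  rho * k / omega
}

#' Reynolds number
#'
#' `Re = rho * U * D / mu`, the ratio of inertial to viscous forces.
#'
#' @param fluid a [fluid_properties()].
#' @param U characteristic speed (m/s), `>= 0`.
#' @param D characteristic length (m), `> 0`.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, U, D) {
  stopifnot(all(U >= 0), all(D > 0))
  fluid$rho * U * D / fluid$mu
}

#' Solve steady incompressible RANS flow on a structured mesh
#'
#' SIMPLE pressure-velocity coupling on the collocated axisymmetric grid with
#' Rhie-Chow momentum-interpolated face fluxes, second-order upwind convection
#' (deferred correction), and the Wilcox k-omega closure integrated to the
#' wall. Iterates until the relative variation of every field between two
#' successive iterations falls below `convergence_tol`, then performs one
#' tightly converged pressure-correction pass so the returned face fluxes are
#' discretely conservative in every cell.
#'
#' @param mesh a [build_mesh()] result.
#' @param bc a [boundary_conditions()].
#' @param fluid a [fluid_properties()].
#' @param settings a [solver_settings()].
#' @param closure closure coefficients, see [kw_closure()].
#' @return object of class `flow_state` with cell-centered fields `u`, `v`,
#'   `p`, `k`, `omega`, `mu_t`, conservative face mass fluxes `me`/`mn`, the
#'   per-field residual history, and convergence diagnostics.
#' @export
solve_flow <- function(mesh, bc, fluid, settings = solver_settings(),
                       closure = kw_closure()) {
  stopifnot(inherits(mesh, "structured_mesh"),
            inherits(bc, "boundary_conditions"),
            inherits(fluid, "fluid_properties"),
            inherits(settings, "solver_settings"))
  nj <- mesh$nj
  A_in <- sum(mesh$Se_x[1, ])
  Q <- bc$inlet_flow / 60000            # L/min -> m^3/s
  U <- Q / A_in                         # bulk speed through the discrete inlet
  r_in <- mesh$rfe[1, ]
  R_in <- mesh$rn[1, nj + 1]
  u_in <- switch(bc$inlet_profile,
    uniform = rep(U, nj),
    parabolic = 2 * U * (1 - (r_in / R_in)^2))
  flux <- sum(fluid$rho * u_in * mesh$Se_x[1, ])
  target <- fluid$rho * Q
  if (flux > 0) u_in <- u_in * target / flux

  if (settings$laminar_mode || U == 0) {
    k_in <- 0; omega_in <- 1
  } else {
    k_in <- max(1.5 * (bc$turbulence_intensity * U)^2, 1e-10 * U^2)
    lt <- bc$turbulence_length_frac * 2 * R_in
    omega_in <- sqrt(k_in) / (0.09^0.25 * lt)
  }

  csett <- list(tol = settings$convergence_tol,
                max_iter = settings$max_iterations,
                min_iter = settings$min_iterations,
                relax_u = settings$relax_u, relax_p = settings$relax_p,
                relax_kw = settings$relax_kw,
                laminar = settings$laminar_mode || U == 0,
                sou = settings$convection_scheme == "second_order_upwind",
                quad_wall = settings$quadratic_wall,
                n_sweeps = settings$n_sweeps,
                alpha = closure$alpha, beta = closure$beta,
                beta_star = closure$beta_star, sigma = closure$sigma,
                sigma_star = closure$sigma_star)
  cbc <- list(u_in = u_in, k_in = k_in, omega_in = omega_in)
  out <- cpp_simple_solve(mesh, cbc, fluid, csett)
  colnames(out$history) <- c("u", "v", "p", "k", "omega", "continuity")

  state <- structure(c(out, list(bc = bc, fluid = fluid, settings = settings,
                                 u_in = u_in, k_in = k_in, omega_in = omega_in,
                                 U_in = U, Q = Q)),
                     class = "flow_state")
  if (!state$converged)
    warning(sprintf("solver stopped at %d iterations without meeting tol %g",
                    state$iterations, settings$convergence_tol))
  state
}

#' @export
print.flow_state <- function(x, ...) {
  cat("Converged flow state\n")
  cat(sprintf("  iterations: %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  inlet flux %.4g kg/s, outlet flux %.4g kg/s\n",
              x$inlet_flux, x$outlet_flux))
  cat(sprintf("  max cell mass imbalance: %.3g kg/s\n", x$max_cell_imbalance))
  cat(sprintf("  max |u| = %.3f m/s, p range [%.3f, %.3f] Pa\n",
              max(abs(x$u)), min(x$p), max(x$p)))
  invisible(x)
}

#' Relative inter-iteration change between two flow states
#'
#' For each transported field, the L1 norm of the change normalized by the L1
#' norm of the previous state (the convergence monitor of the steady solver:
#' iteration stops when every field's relative variation drops below the
#' preassigned tolerance).
#'
#' @param prev,curr `flow_state` objects on the same mesh.
#' @return named numeric vector of relative changes for u, v, p, k, omega.
#' @export
flow_residual <- function(prev, curr) {
  fields <- c("u", "v", "p", "k", "omega")
  if (!all(vapply(fields, function(f)
    identical(dim(prev[[f]]), dim(curr[[f]])), logical(1))))
    stop("flow states are not on the same mesh")
  vapply(fields, function(f) {
    d <- sum(abs(curr[[f]] - prev[[f]]))
    n <- sum(abs(prev[[f]]))
    if (d == 0) 0 else d / max(n, .Machine$double.xmin)
  }, numeric(1))
}

#' Reynolds stress tensor field
#'
#' `tau_ij = 2 mu_t S_ij - (2/3) rho k delta_ij`, with `S_ij` the mean
#' strain-rate tensor of the axisymmetric velocity field (components xx, rr,
#' theta-theta and xr; the azimuthal normal strain is `v/r`).
#'
#' @param state a [solve_flow()] result (or a synthetic `flow_state`-like list
#'   with `u`, `v`, `mu_t`, `k` matrices and `u_in` inlet values).
#' @param mesh the mesh the state lives on.
#' @param fluid a [fluid_properties()]; defaults to the one stored in `state`.
#' @return list of matrices `txx`, `trr`, `ttt`, `txr` (Pa) plus the strain
#'   components `Sxx`, `Srr`, `Stt`, `Sxr` (1/s).
#' @export
reynolds_stress <- function(state, mesh, fluid = state$fluid) {
  u_in <- if (!is.null(state$u_in)) state$u_in else rep(0, mesh$nj)
  gu <- cpp_cell_gradient(mesh, state$u, 1L, u_in, 0L, 0, 1L, 0)
  gv <- cpp_cell_gradient(mesh, state$v, 1L, rep(0, mesh$nj), 0L, 0, 1L, 0)
  Sxx <- gu$gx
  Srr <- gv$gr
  Stt <- state$v / mesh$rc
  Sxr <- 0.5 * (gu$gr + gv$gx)
  rho <- fluid$rho
  iso <- (2 / 3) * rho * state$k
  list(txx = 2 * state$mu_t * Sxx - iso,
       trr = 2 * state$mu_t * Srr - iso,
       ttt = 2 * state$mu_t * Stt - iso,
       txr = 2 * state$mu_t * Sxr,
       Sxx = Sxx, Srr = Srr, Stt = Stt, Sxr = Sxr)
}

#' Kronecker delta
#'
#' @param i,j integer indices.
#' @return 1 if `i == j`, else 0.
#' @export
kronecker_delta <- function(i, j) as.numeric(i == j)
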