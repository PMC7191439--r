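# shared, memoised heavy runs so validation solves happen once per test session

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .case_cache))
    assign(key, force(expr), envir = .case_cache)
  get(key, envir = .case_cache)
}

# laminar Poiseuille pipe at three refinement levels (parabolic inflow)
poiseuille_study <- function() cached("poiseuille", {
  fl <- fluid_properties()
  R <- 0.0015; L <- 0.1; Q <- 1 / 60000; U <- Q / (pi * R^2)
  out <- list(fluid = fl, R = R, L = L, Q = Q, U = U,
              dp_exact = 8 * fl$mu * L * Q / (pi * R^4), levels = list())
  for (lev in 0:2) {
    f <- 2^lev
    mesh <- build_mesh(axi_profile(length = L, radius = R),
                       mesh_params(n_axial = 40 * f, n_radial = 16 * f,
                                   first_layer_height = 2e-5 / f))
    st <- solve_flow(mesh,
                     boundary_conditions(inlet_flow = 1,
                                         inlet_profile = "parabolic"),
                     fl, solver_settings(laminar_mode = TRUE,
                                         convergence_tol = 1e-8))
    i <- which.min(abs(mesh$xc[, 1] - L / 2))
    uex <- 2 * U * (1 - (mesh$rc[i, ] / R)^2)
    w <- mesh$vol[i, ]
    l2 <- sqrt(sum(w * (st$u[i, ] - uex)^2) / sum(w)) / U
    # fully developed flow: scale the interior-station drop to the full length
    dp <- pressure_drop(st, mesh, 0.01, 0.09) * L / 0.08
    out$levels[[lev + 1]] <- list(mesh = mesh, state = st, l2 = l2, dp = dp)
  }
  out
})

# straight pipe at bulk Reynolds number 1e4
turbulent_pipe_run <- function() cached("turbulent_pipe", {
  case <- make_validation_suite()$turbulent_pipe
  res <- run_case(case)
  fl <- case$fluid
  D <- 2 * case$R0
  U <- res$state$Q / (pi * case$R0^2)
  mesh <- res$mesh; st <- res$state
  colavg <- function(i) sum(st$p[i, ] * mesh$vol[i, ]) / sum(mesh$vol[i, ])
  x <- mesh$xc[, 1]
  i1 <- which.min(abs(x - 40 * D)); i2 <- which.min(abs(x - 55 * D))
  dpdx <- (colavg(i1) - colavg(i2)) / (x[i2] - x[i1])
  f_dp <- dpdx * D / (0.5 * fl$rho * U^2)
  wss <- wall_shear_stress(st, mesh)
  tau <- mean(wss$tau[x >= 40 * D & x <= 55 * D])
  list(res = res, U = U, D = D, f_dp = f_dp,
       f_tau = 8 * tau / (fl$rho * U^2),
       f_blasius = 0.316 * 1e4^(-0.25))
})

# single-stenosis severity sweep at the study flow rate
severity_sweep <- function() cached("sweep", {
  suite <- make_validation_suite()
  sw <- suite[grep("^sweep_", names(suite))]
  lapply(sw, run_case)
})

# the four-variant patient-like comparison
patient_comparison <- function() cached("patient", {
  run_comparison(make_patient_like_suite(), keep_states = TRUE)
})

# every converged (state, mesh) pair collected from the cached runs, for
# conservation and energy bookkeeping properties
all_cached_runs <- function() {
  out <- list()
  for (l in poiseuille_study()$levels)
    out[[length(out) + 1]] <- list(state = l$state, mesh = l$mesh)
  tr <- turbulent_pipe_run()$res
  out[[length(out) + 1]] <- list(state = tr$state, mesh = tr$mesh)
  for (r in severity_sweep())
    out[[length(out) + 1]] <- list(state = r$state, mesh = r$mesh)
  for (r in patient_comparison()$runs)
    out[[length(out) + 1]] <- list(state = r$state, mesh = r$mesh)
  out
}
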