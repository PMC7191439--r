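test_that("eddy viscosity is rho k / omega with domain checks", {
  expect_equal(eddy_viscosity(1.161, 0, 50), 0)
  expect_equal(eddy_viscosity(1.161, 0.01, 100), 1.161e-4)
  expect_equal(eddy_viscosity(1.161, 0.02, 100),
               2 * eddy_viscosity(1.161, 0.01, 100))
  expect_error(eddy_viscosity(1.161, 0.01, 0), "omega")
  expect_error(eddy_viscosity(1.161, -1, 10), "k must")
})

test_that("Reynolds number follows rho U D / mu", {
  fl <- fluid_properties()
  expect_equal(reynolds_number(fl, 0, 0.003), 0)
  # Q = 3 L/min through D = 3 mm: Re = 4 rho Q / (pi D mu)
  Q <- 3 / 60000; D <- 0.003
  U <- 4 * Q / (pi * D^2)
  expect_equal(reynolds_number(fl, U, D), 4 * fl$rho * Q / (pi * D * fl$mu))
  expect_equal(reynolds_number(fl, U, D), 1.32e3, tolerance = 0.005)
})

test_that("closure coefficients carry the exact standard rationals", {
  cc <- kw_closure()
  expect_identical(cc$alpha, 5 / 9)
  expect_identical(cc$beta, 3 / 40)
  expect_identical(cc$beta_star, 9 / 100)
  expect_identical(cc$sigma, 1 / 2)
  expect_identical(cc$sigma_star, 1 / 2)
})

test_that("Kronecker delta behaves as an identity indicator", {
  expect_equal(kronecker_delta(1, 1), 1)
  expect_equal(kronecker_delta(1, 2), 0)
})

test_that("Reynolds stress reduces to its analytic limits", {
  mesh <- build_mesh(axi_profile(length = 0.02, radius = 0.003),
                     mesh_params(n_axial = 12, n_radial = 24,
                                 first_layer_height = 1.25e-4,
                                 growth_ratio = 1, n_bl_layers = 1))
  fl <- fluid_properties()
  nj <- mesh$nj
  # uniform flow, zero gradients: tau_ij = -(2/3) rho k delta_ij
  k0 <- 0.5
  st_unif <- list(u = matrix(2, mesh$ni, nj), v = matrix(0, mesh$ni, nj),
                  k = matrix(k0, mesh$ni, nj),
                  mu_t = matrix(3e-4, mesh$ni, nj),
                  u_in = rep(2, nj), fluid = fl)
  tau <- reynolds_stress(st_unif, mesh)
  mid <- cbind(6, 5:18)
  expect_equal(max(abs(tau$txx[mid] + 2 / 3 * fl$rho * k0)), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(tau$txr[mid])), 0, tolerance = 1e-10)

  # pure shear du/dr = -gamma with k = 0: |tau_xr| = mu_t gamma
  gam <- 100
  u_sh <- matrix(rep(gam * (0.003 - mesh$rc[1, ]), each = mesh$ni), mesh$ni, nj)
  st_sh <- list(u = u_sh, v = matrix(0, mesh$ni, nj),
                k = matrix(0, mesh$ni, nj),
                mu_t = matrix(3e-4, mesh$ni, nj),
                u_in = gam * (0.003 - mesh$rfe[1, ]), fluid = fl)
  tau2 <- reynolds_stress(st_sh, mesh)
  expect_equal(mean(abs(tau2$txr[mid])), 3e-4 * gam, tolerance = 0.02)
})

test_that("inter-iteration residual reports normalized per-field change", {
  mesh <- build_mesh(axi_profile(length = 0.05, radius = 0.0015),
                     mesh_params(n_axial = 10, n_radial = 8,
                                 first_layer_height = 5e-5))
  st <- solve_flow(mesh, boundary_conditions(inlet_flow = 0.2,
                                             inlet_profile = "parabolic"),
                   fluid_properties(),
                   solver_settings(laminar_mode = TRUE))
  expect_equal(unname(flow_residual(st, st)), rep(0, 5))
  st2 <- st
  st2$u <- st$u * (1 + 1e-3)
  r <- flow_residual(st, st2)
  expect_equal(unname(r["u"]), 1e-3, tolerance = 1e-10)
  expect_equal(unname(r["p"]), 0)
  # convex combination toward prev shrinks the residual monotonically
  st3 <- st2
  st3$u <- 0.5 * st$u + 0.5 * st2$u
  expect_lt(flow_residual(st, st3)["u"], r["u"])
  st_bad <- st
  st_bad$u <- st$u[1:5, ]
  expect_error(flow_residual(st, st_bad), "same mesh")
})

test_that("zero inflow relaxes to rest with uniform pressure", {
  mesh <- build_mesh(axi_profile(length = 0.03, radius = 0.002),
                     mesh_params(n_axial = 10, n_radial = 8,
                                 first_layer_height = 5e-5))
  st <- solve_flow(mesh, boundary_conditions(inlet_flow = 0),
                   fluid_properties(), solver_settings(laminar_mode = TRUE))
  expect_true(st$converged)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
  expect_equal(max(st$p) - min(st$p), 0)
})

test_that("laminar solution recovers Poiseuille flow on the finest grid", {
  ps <- poiseuille_study()
  fin <- ps$levels[[3]]
  expect_true(fin$state$converged)
  expect_lt(fin$l2, 0.01)
  expect_equal(fin$dp, ps$dp_exact, tolerance = 0.02)
  # pressure drop via Hagen-Poiseuille: about 15.6 Pa for these conditions
  expect_equal(ps$dp_exact, 15.6, tolerance = 0.005)
})

test_that("Stokes-regime pressure drop scales linearly with flow rate", {
  fl <- fluid_properties()
  mesh <- build_mesh(axi_profile(length = 0.05, radius = 0.0015),
                     mesh_params(n_axial = 30, n_radial = 14,
                                 first_layer_height = 2e-5))
  dp <- sapply(c(0.05, 0.1), function(q) {
    st <- solve_flow(mesh, boundary_conditions(inlet_flow = q,
                                               inlet_profile = "parabolic"),
                     fl, solver_settings(laminar_mode = TRUE,
                                         convergence_tol = 1e-8))
    pressure_drop(st, mesh, 0.005, 0.045)
  })
  expect_equal(dp[2] / dp[1], 2, tolerance = 0.01)
})

test_that("turbulence fields stay positive with the stored eddy viscosity", {
  tr <- turbulent_pipe_run()$res
  st <- tr$state
  expect_true(all(st$k >= 0))
  expect_true(all(st$omega > 0))
  expect_true(all(st$mu_t >= 0))
  expect_equal(st$mu_t, st$fluid$rho * st$k / st$omega, tolerance = 1e-12)
})
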