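test_that("laminar wall shear stress matches the analytic 8 mu U / D", {
  ps <- poiseuille_study()
  fin <- ps$levels[[3]]
  wss <- wall_shear_stress(fin$state, fin$mesh)
  mid <- wss$s > 0.02 & wss$s < 0.08
  tau_exact <- 8 * ps$fluid$mu * ps$U / (2 * ps$R)
  expect_equal(mean(wss$tau[mid]), tau_exact, tolerance = 0.03)
  expect_equal(tau_exact, 0.117, tolerance = 0.005)
  expect_true(all(wss$tau >= 0))
})

test_that("wall shear stress vanishes at rest and warns when unconverged", {
  mesh <- build_mesh(axi_profile(length = 0.03, radius = 0.002),
                     mesh_params(n_axial = 10, n_radial = 8,
                                 first_layer_height = 5e-5))
  st <- solve_flow(mesh, boundary_conditions(inlet_flow = 0),
                   fluid_properties(), solver_settings(laminar_mode = TRUE))
  expect_equal(max(wall_shear_stress(st, mesh)$tau), 0)
  st$converged <- FALSE
  expect_warning(wall_shear_stress(st, mesh), "unconverged")
})

test_that("pressure drop recovers Hagen-Poiseuille and validates stations", {
  ps <- poiseuille_study()
  fin <- ps$levels[[3]]
  dp <- pressure_drop(fin$state, fin$mesh, 0.01, 0.09) * 0.1 / 0.08
  expect_equal(dp, ps$dp_exact, tolerance = 0.02)
  expect_error(pressure_drop(fin$state, fin$mesh, 0.09, 0.01), "upstream")
  expect_error(pressure_drop(fin$state, fin$mesh, 0.01, 0.2), "anatomical")
})

test_that("energy flux reduces to the plug-flow closed form", {
  # uniform plug over a constant section: E = (P + 1/2 rho U^2) U A
  mesh <- build_mesh(axi_profile(length = 0.03, radius = 0.002),
                     mesh_params(n_axial = 12, n_radial = 10,
                                 first_layer_height = 5e-5))
  fl <- fluid_properties()
  U <- 1.5; P <- 40
  st <- list(p = matrix(P, mesh$ni, mesh$nj),
             u = matrix(U, mesh$ni, mesh$nj),
             v = matrix(0, mesh$ni, mesh$nj),
             me = fl$rho * U * mesh$Se_x,
             u_in = rep(U, mesh$nj), fluid = fl,
             Q = U * pi * 0.002^2, converged = TRUE)
  A_disc <- sum(mesh$Se_x[6, ])
  expect_equal(energy_flux(st, mesh, 0.015),
               (P + 0.5 * fl$rho * U^2) * U * A_disc, tolerance = 1e-10)
  expect_error(energy_flux(st, mesh, 1), "outside")
})

test_that("energy-loss rate is the normalized inlet/outlet energy difference", {
  expect_equal(energy_loss_rate(1, 1), 0)
  expect_equal(energy_loss_rate(1.000, 0.851), 0.149)
  expect_error(energy_loss_rate(0, 1), "positive")
})

test_that("metric identities hold on every converged case", {
  for (r in all_cached_runs()) {
    m <- flow_metrics(r$state, r$mesh)
    expect_identical(m$lambda, 1 - m$E_outlet / m$E_inlet)
    expect_gte(m$lambda, 0)
    expect_lt(m$lambda, 1)
    expect_gte(m$EL, 0)
  }
})

test_that("energy loss equals total-pressure drop times flow for a single duct", {
  ps <- poiseuille_study()
  fin <- ps$levels[[2]]
  m <- flow_metrics(fin$state, fin$mesh)
  dp_tot <- pressure_drop(fin$state, fin$mesh, fin$mesh$profile$anat[1],
                          fin$mesh$profile$anat[2], type = "total")
  expect_equal(m$EL, dp_tot * fin$state$Q, tolerance = 1e-12)
})

test_that("stenotic WSS ordering follows severity within a case", {
  cmp <- patient_comparison()
  m1 <- cmp$table[cmp$table$case == "M1", ]
  expect_gt(m1$wss_max_S2_Pa, m1$wss_max_S1_Pa)
})
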