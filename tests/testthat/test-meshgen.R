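test_that("boundary-layer stack follows the first-layer/growth-ratio law", {
  mesh <- build_mesh(axi_profile(length = 0.02, radius = 0.003),
                     mesh_params(n_axial = 10, n_radial = 12,
                                 first_layer_height = 1e-4,
                                 growth_ratio = 1.2, n_bl_layers = 3))
  dr <- rev(diff(mesh$rn[1, ]))  # spacings from the wall inward
  expect_equal(dr[1], 1e-4, tolerance = 1e-12)
  expect_equal(dr[2] / dr[1], 1.2, tolerance = 1e-10)
  expect_equal(dr[3] / dr[2], 1.2, tolerance = 1e-10)
  # three-layer wall stack thickness: h (1 + 1.2 + 1.44) = 3.64 h
  expect_equal(sum(dr[1:3]), 3.64e-4, tolerance = 1e-10)
  # identical stations for a straight tube
  expect_equal(mesh$rn[3, ], mesh$rn[8, ])
})

test_that("cell volumes reproduce the revolved solid exactly and positively", {
  prof <- apply_stenosis(axi_profile(length = 0.045, radius = 0.003),
                         stenosis_spec("S", 0.02, 0.01, 0.7))
  mesh <- build_mesh(prof, mesh_params(n_axial = 60, n_radial = 20,
                                       first_layer_height = 2e-5))
  expect_true(all(mesh$vol > 0))
  # mesh volume equals the revolved volume of its own piecewise-linear wall
  node_prof <- axi_profile(length = 0.045, radius = 0.003)
  node_prof$s <- mesh$xn[, 1]
  node_prof$R <- mesh$rn[, mesh$nj + 1]
  expect_equal(sum(mesh$vol), revolved_volume(node_prof), tolerance = 1e-12)
})

test_that("mesh volume converges to the profile's revolved volume at 2nd order", {
  prof <- apply_stenosis(axi_profile(length = 0.045, radius = 0.003),
                         stenosis_spec("S", 0.02, 0.012, 0.6))
  vex <- revolved_volume(prof)
  errs <- sapply(c(1, 2, 4), function(f) {
    mp <- mesh_params(n_axial = 20 * f, n_radial = 8 * f,
                      first_layer_height = 2e-4 / f, n_bl_layers = 2)
    abs(sum(build_mesh(prof, mp)$vol) - vex)
  })
  expect_lt(errs[2] / errs[1], 0.35)   # at least ~1.5th order per halving
  expect_lt(errs[3] / errs[2], 0.35)
})

test_that("refinement composes and divides the wall spacing", {
  mp <- mesh_params(n_axial = 10, n_radial = 8, first_layer_height = 1e-4)
  r2 <- refine_mesh(mp, 2)
  expect_equal(r2$n_axial, 20L)
  expect_equal(r2$n_radial, 16L)
  expect_equal(r2$first_layer_height, 5e-5)
  expect_equal(refine_mesh(r2, 2), refine_mesh(mp, 4))
  expect_error(refine_mesh(mp, 1), "factor")
  mesh <- build_mesh(axi_profile(length = 0.02, radius = 0.003), r2)
  expect_true(all(mesh$vol > 0))
})

test_that("an overgrown wall stack raises an infeasible-mesh error naming the station", {
  prof <- apply_stenosis(axi_profile(length = 0.045, radius = 0.003),
                         stenosis_spec("S", 0.02, 0.01, 0.99))
  err <- tryCatch(
    build_mesh(prof, mesh_params(n_axial = 40, n_radial = 12,
                                 first_layer_height = 1e-4, n_bl_layers = 3)),
    error = function(e) conditionMessage(e))
  expect_match(err, "axial station")
})

test_that("mesh quality reports no degenerate cells for the scenario suite", {
  for (case in make_patient_like_suite()) {
    mesh <- build_mesh(case_profile(case), mesh_params(n_axial = 40,
                                                       n_radial = 16,
                                                       first_layer_height = 2e-5))
    q <- mesh_quality(mesh)
    expect_gt(q$min_volume, 0)
    expect_equal(q$flags$nonpositive_volume, 0)
    expect_lt(q$max_jump, 10)
  }
})
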