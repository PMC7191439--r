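test_that("branch resistance combines Poiseuille and minor-loss terms", {
  fl <- fluid_properties()
  b <- airway_branch("b", length = 0.01, diameter = 0.003, K = 0)
  # K = 0 at any flow is exactly the Poiseuille resistance
  R_pois <- 128 * fl$mu * 0.01 / (pi * 0.003^4)
  expect_equal(branch_resistance(b, 0, fl), R_pois)
  expect_equal(branch_resistance(b, 1e-4, fl), R_pois)
  # doubling the diameter divides the laminar resistance by 16
  b2 <- airway_branch("b2", length = 0.01, diameter = 0.006, K = 0)
  expect_equal(branch_resistance(b, 0, fl) / branch_resistance(b2, 0, fl), 16)
  # hand evaluation with a minor loss
  bk <- airway_branch("bk", length = 0.008, diameter = 0.0025, K = 1.5)
  Q <- 2e-5; A <- pi * 0.0025^2 / 4
  expect_equal(branch_resistance(bk, Q, fl),
               128 * fl$mu * 0.008 / (pi * 0.0025^4) +
                 1.5 * fl$rho * Q / (2 * A^2))
})

test_that("a mirror-symmetric tree splits exactly 50:50", {
  sol <- solve_network(symmetric_bronchial_tree(), 3)
  expect_equal(unname(sol$split["right"]), 50, tolerance = 1e-12)
  expect_equal(unname(sol$split["left"]), 50, tolerance = 1e-12)
})

test_that("two parallel laminar branches split inversely to resistance", {
  fl <- fluid_properties()
  branches <- list(airway_branch("root", 0.005, 0.006, 0),
                   airway_branch("L1", 0.01, 0.002, 0),
                   airway_branch("R1", 0.01, 0.0025, 0))
  tree <- airway_tree(branches, c(root = NA, L1 = "root", R1 = "root"))
  sol <- solve_network(tree, 2, fl)
  R_L <- branch_resistance(tree$branches$L1, 0, fl)
  R_R <- branch_resistance(tree$branches$R1, 0, fl)
  expect_equal(unname(sol$flow_L_min["L1"] / sol$flow_L_min["R1"]),
               R_R / R_L, tolerance = 1e-12)
})

test_that("junction conservation and outlet sum hold to machine precision", {
  for (preset in c("right_dominant", "healthy")) {
    tree <- default_bronchial_tree(preset)
    sol <- solve_network(tree, 3)
    fl <- sol$flow_L_min
    expect_equal(sum(fl[tree$outlets]), 3, tolerance = 1e-14)
    for (id in names(tree$children)) {
      ch <- tree$children[[id]]
      if (length(ch))
        expect_equal(unname(fl[id]), sum(fl[ch]), tolerance = 1e-14)
    }
    expect_equal(sum(sol$share_percent), 100, tolerance = 1e-12)
  }
})

test_that("the split is invariant to uniform scaling of all resistances", {
  tree <- default_bronchial_tree()
  # scale all laminar resistances by 8 via mu; K terms scale with rho
  s1 <- solve_network(tree, 3, fluid_properties())
  s2 <- solve_network(tree, 3, fluid_properties(rho = 8 * 1.161,
                                                mu = 8 * 1.864e-5))
  expect_equal(s1$split, s2$split, tolerance = 1e-10)
})

test_that("the right-dominant preset favors the right lung near 7:3", {
  sol <- solve_network(default_bronchial_tree(), 3)
  expect_gt(sol$split[["right"]], sol$split[["left"]])
  expect_equal(sol$split[["right"]], 70, tolerance = 0.05)
  healthy <- solve_network(default_bronchial_tree("healthy"), 3)
  expect_equal(healthy$split[["right"]], 56.57, tolerance = 0.02)
})

test_that("tree construction rejects malformed connectivity", {
  b <- list(airway_branch("a", 0.01, 0.003), airway_branch("b", 0.01, 0.003))
  expect_error(airway_tree(b, c(a = "b", b = "a")), "root")
  expect_error(airway_tree(list(b[[1]], b[[1]]), c(a = NA)), "unique")
})
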