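test_that("cross-section area follows pi R^2", {
  prof <- axi_profile(length = 0.1, radius = 1)
  expect_equal(cross_section_area(prof, 0.05), pi)
  prof2 <- axi_profile(length = 0.1, radius = 0.003)
  expect_equal(cross_section_area(prof2, 0.02), 2.827433e-5, tolerance = 1e-6)
  # constant radius -> constant area along the profile
  areas <- cross_section_area(prof2, seq(0, 0.1, by = 0.01))
  expect_equal(max(areas) - min(areas), 0)
  expect_error(cross_section_area(prof2, 0.2), "outside")
})

test_that("stenosis ratio matches the entrance/throat area definition", {
  # hand arithmetic: S_TE = 28.27 mm^2 (R = 3 mm), S_SP = 8.85 mm^2
  prof <- axi_profile(length = 0.045, radius = 0.003)
  sev <- 1 - 8.85e-6 / (pi * 0.003^2)
  prof <- apply_stenosis(prof, stenosis_spec("S1", 0.02, 0.009, sev))
  expect_equal(stenosis_ratio(prof, "S1"), 68.7, tolerance = 1e-3)
  expect_error(stenosis_ratio(prof, "nope"), "no stenosis")
})

test_that("severity round-trips through the constructor across the range", {
  for (r in seq(0.1, 0.9, by = 0.1)) {
    prof <- apply_stenosis(axi_profile(), stenosis_spec("S", 0.02, 0.009, r))
    expect_equal(stenosis_ratio(prof, "S"), 100 * r, tolerance = 1e-6)
  }
  # zero severity leaves the lumen unchanged
  p0 <- axi_profile()
  p1 <- apply_stenosis(p0, stenosis_spec("S", 0.02, 0.009, 0))
  expect_equal(p1$R, p0$R)
  expect_equal(stenosis_ratio(p1, "S"), 0)
})

test_that("severity 0.5 narrows the throat radius to R0 sqrt(0.5)", {
  prof <- apply_stenosis(axi_profile(radius = 0.003),
                         stenosis_spec("S", 0.02, 0.009, 0.5))
  expect_equal(min(prof$R), 0.003 * sqrt(0.5), tolerance = 1e-9)
})

test_that("two stenoses are independent and protected against overlap", {
  prof <- axi_profile(length = 0.045, radius = 0.003)
  prof <- apply_stenosis(prof, stenosis_spec("S1", 0.015, 0.009, 0.687))
  prof <- apply_stenosis(prof, stenosis_spec("S2", 0.030, 0.009, 0.865))
  expect_equal(stenosis_ratio(prof, "S1"), 68.7, tolerance = 1e-4)
  expect_equal(stenosis_ratio(prof, "S2"), 86.5, tolerance = 1e-4)
  expect_error(apply_stenosis(prof, stenosis_spec("S3", 0.017, 0.01, 0.3)),
               "overlap")
  expect_error(apply_stenosis(prof, stenosis_spec("X", 0.044, 0.009, 0.3)),
               "outside")
})

test_that("correction restores the reference lumen locally and reversibly", {
  prof0 <- axi_profile(length = 0.045, radius = 0.003)
  s1 <- stenosis_spec("S1", 0.015, 0.009, 0.687)
  s2 <- stenosis_spec("S2", 0.030, 0.009, 0.865)
  prof <- apply_stenosis(apply_stenosis(prof0, s1), s2)

  # correcting S1 leaves S2 untouched
  p_m2 <- correct_stenosis(prof, "S1")
  expect_equal(stenosis_ratio(p_m2, "S2"), 86.5, tolerance = 1e-4)
  expect_equal(max(abs(profile_radius(p_m2, seq(0.0105, 0.0195, by = 1e-4)) -
                         0.003)), 0, tolerance = 1e-12)

  # correcting both recovers the stenosis-free lumen everywhere
  p_m4 <- correct_stenosis(p_m2, "S2")
  expect_equal(max(abs(p_m4$R - 0.003)), 0, tolerance = 1e-12)
  expect_length(p_m4$stenoses, 0)

  # corrections commute
  p_ba <- correct_stenosis(correct_stenosis(prof, "S2"), "S1")
  expect_equal(p_m4$R, p_ba$R)

  # correct then re-apply recovers the stenotic profile
  p_re <- apply_stenosis(correct_stenosis(prof, "S1"), s1)
  expect_equal(max(abs(p_re$R - prof$R)), 0, tolerance = 1e-12)
  expect_error(correct_stenosis(prof, "S9"), "no stenosis")
})

test_that("domain extensions prepend/append straight ducts of factor x D", {
  prof <- axi_profile(length = 0.045, radius = 0.003)
  expect_identical(extend_domain(prof, 0, 0), prof)
  ext <- extend_domain(prof, 20, 40)
  expect_equal(unname(ext$extension["inlet"]), 20 * 0.006)
  expect_equal(unname(ext$extension["outlet"]), 40 * 0.006)
  expect_equal(min(ext$s), -0.12)
  expect_equal(max(ext$s), 0.045 + 0.24)
  expect_equal(ext$anat, c(0, 0.045))
  expect_true(all(diff(ext$s) > 0))
  expect_true(all(ext$R > 0))
  expect_error(extend_domain(prof, -1, 0), "nonnegative")
})

test_that("surgical schemes map one-to-one onto model labels", {
  expect_equal(scheme_label(surgical_scheme()), "M1")
  expect_equal(scheme_label(surgical_scheme("S1")), "M2")
  expect_equal(scheme_label(surgical_scheme("S2")), "M3")
  expect_equal(scheme_label(surgical_scheme(c("S2", "S1"))), "M4")
  expect_equal(scheme_label(surgical_scheme("S3")), "custom")
})
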