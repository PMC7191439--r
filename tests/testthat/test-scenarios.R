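test_that("the patient-like suite encodes the four surgical variants", {
  suite <- make_patient_like_suite()
  expect_named(suite, c("M1", "M2", "M3", "M4"))
  expect_equal(lapply(suite, function(x) sort(x$scheme$corrected)),
               list(M1 = character(0), M2 = "S1", M3 = "S2",
                    M4 = c("S1", "S2")))
  # study conditions
  m1 <- suite$M1
  expect_equal(m1$bc$inlet_flow, 3)
  expect_equal(m1$fluid$rho, 1.161)
  expect_equal(m1$fluid$mu, 1.864e-5)
  sev <- sapply(m1$stenoses, `[[`, "severity")
  expect_equal(sev, c(0.687, 0.865))
  # stenotic extents jointly exceed 30% of the tracheal length
  tot <- sum(sapply(m1$stenoses, `[[`, "length"))
  expect_gt(tot / m1$length, 0.3)
})

test_that("case profiles realize the requested severities and corrections", {
  suite <- make_patient_like_suite()
  p1 <- case_profile(suite$M1)
  expect_equal(stenosis_ratio(p1, "S1"), 68.7, tolerance = 1e-4)
  expect_equal(stenosis_ratio(p1, "S2"), 86.5, tolerance = 1e-4)
  # M2 retains S2 untouched
  p2 <- case_profile(suite$M2)
  expect_equal(stenosis_ratio(p2, "S2"), 86.5, tolerance = 1e-4)
  expect_false("S1" %in% sapply(p2$stenoses, `[[`, "id"))
  # M4 equals the stenosis-free lumen
  p4 <- case_profile(suite$M4)
  expect_equal(max(abs(p4$R - suite$M4$R0)), 0, tolerance = 1e-12)
})

test_that("suite overrides are validated and applied", {
  s <- make_patient_like_suite(list(inlet_flow = 5, R0 = 0.004))
  expect_equal(s$M1$bc$inlet_flow, 5)
  expect_equal(s$M1$R0, 0.004)
  expect_error(make_patient_like_suite(list(nonsense = 1)), "unknown")
  expect_error(make_patient_like_suite(list(s2_severity = 1.2)), "severities")
  expect_error(case_spec("M2", scheme = surgical_scheme("S1")), "not present")
})

test_that("validation suite cases pass their own type invariants", {
  suite <- make_validation_suite()
  for (case in suite) {
    expect_s3_class(case, "case_spec")
    prof <- case_profile(case)
    expect_true(all(prof$R > 0))
    expect_true(all(diff(prof$s) > 0))
  }
  # severity sweep: throat speed at fixed Q rises as 1/(1-r)
  sw <- suite[grep("^sweep_", names(suite))]
  r <- as.numeric(sub("sweep_r", "", names(sw)))
  a_throat <- sapply(sw, function(cs) {
    prof <- case_profile(cs)
    min(cross_section_area(prof, prof$s))
  })
  u_throat <- (3 / 60000) / a_throat
  expect_true(all(diff(u_throat) > 0))
  expect_equal(u_throat / u_throat[1], (1 - r[1]) / (1 - r),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("configs round-trip and are byte-identical for identical specs", {
  suite <- make_patient_like_suite()
  f1 <- tempfile(fileext = ".yaml"); f2 <- tempfile(fileext = ".yaml")
  write_case_config(suite$M2, f1)
  write_case_config(make_patient_like_suite()$M2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_case_config(f1)
  expect_equal(back$R0, suite$M2$R0)
  expect_equal(back$scheme$corrected, "S1")
  expect_equal(back$bc$inlet_flow, 3)
  expect_equal(back$mesh, suite$M2$mesh)
  expect_equal(back$settings, suite$M2$settings)
  # provenance flags mark synthetic defaults
  expect_match(paste(readLines(f1), collapse = "\n"), "not[\n ]+patient")
})
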