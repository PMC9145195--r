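test_that("a flat isotropic Biot sheet stretches exactly linearly with slope E", {
  sh <- flat_sheet_template(width = 40, height = 20, spacing = 4,
                            thickness = 1)
  mod <- fem_model(sh, material_params(E_long = 100, E_trans = 100))
  cv <- stretch(mod, NULL,
                stretch_protocol("longitudinal", total_strain = 0.2,
                                 steps = 10, pressure = 0))
  ss <- to_stress_strain(cv)
  # nominal stress (MPa) = E * strain: with E = 100, stress == strain%
  expect_equal(ss$stress, ss$strain, tolerance = 1e-9)
  expect_false(attr(cv, "truncated"))
})

test_that("zero prescribed displacement gives zero net reaction", {
  sh <- flat_sheet_template(width = 40, height = 20, spacing = 4)
  mod <- fem_model(sh, material_params())
  cv <- stretch(mod, NULL,
                stretch_protocol("longitudinal", total_strain = 1e-9,
                                 steps = 10, pressure = 0))
  expect_lt(max(abs(cv$force)), 1e-3)
})

test_that("stretch of a pressurized tissue starts near zero force and stiffens", {
  tm <- small_tissue_template()
  pr <- pressurize(tm, 0.5, material_params())
  expect_true(pr$state$converged)
  expect_gt(pr$volume_change, 0.02)
  cv <- stretch(pr$model, pr$state,
                stretch_protocol("longitudinal", total_strain = 0.2,
                                 steps = 10, pressure = 0.5))
  expect_equal(cv$displacement[1], 0)
  expect_lt(abs(cv$force[1]), 0.05 * max(cv$force))
  expect_true(all(diff(cv$force) > 0))
  ss <- to_stress_strain(cv)
  expect_equal(max(ss$strain), 20, tolerance = 1e-6)
})

test_that("reaction-force curve is step-count independent within 2% at 20% strain", {
  tm <- small_tissue_template()
  pr <- pressurize(tm, 0.5, material_params())
  s10 <- to_stress_strain(stretch(pr$model, pr$state,
    stretch_protocol("longitudinal", 0.2, 10, 0.5)))
  s20 <- to_stress_strain(stretch(pr$model, pr$state,
    stretch_protocol("longitudinal", 0.2, 20, 0.5)))
  a <- stress_at_strain(s10, 20)
  b <- stress_at_strain(s20, 20)
  expect_lt(abs(a - b) / b, 0.02)
})

test_that("run_experiment_grid collects runs and tolerates failures", {
  expect_equal(length(run_experiment_grid(list())$curves), 0)
  sp <- template_spec(aspect_ratio = 2, staggered = TRUE,
                      template_extent = c(80, 40), vertex_spacing = 4)
  grid <- run_experiment_grid(list(
    list(spec = sp,
         protocol = stretch_protocol("longitudinal", 0.2, 10, 0.5),
         label = "ok"),
    list(spec = sp,
         protocol = stretch_protocol("longitudinal", 0.2, 10, 0.5),
         materials = "not a material", label = "bad")))
  expect_equal(nrow(grid$summary), 2)
  expect_true(is.na(grid$summary$stress_at_ref[2]))
  expect_false(is.na(grid$summary$stress_at_ref[1]))
  expect_s3_class(grid$curves[["ok"]], "stress_strain_curve")
})
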