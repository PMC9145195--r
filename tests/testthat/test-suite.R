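test_that("staggering statistics aggregate a panel summary correctly", {
  s <- data.frame(
    aspect_ratio = rep(c(2, 5), each = 4),
    staggered = rep(c(TRUE, TRUE, FALSE, FALSE), 2),
    pressure = 0.5,
    direction = rep(c("longitudinal", "transverse"), 4),
    stress20 = c(4, 1, 4.2, 1.4,   5, 1, 5.1, 1.2))
  agg <- staggering_statistics(s)
  br <- agg$by_ratio
  expect_equal(br$ratio_staggered, c(4, 5))
  expect_equal(br$ratio_nonstaggered, c(3, 4.25))
  expect_equal(br$ratio_difference_pct, 100 * c(1 / 3, 0.75 / 4.25))
  expect_equal(br$transverse_reduction_pct,
               100 * c(0.4 / 1.4, 0.2 / 1.2))
  expect_equal(agg$mean_transverse_reduction,
               mean(100 * c(0.4 / 1.4, 0.2 / 1.2)))
  # rows without stress values or at other pressures are ignored
  s2 <- rbind(s, data.frame(aspect_ratio = 2, staggered = TRUE,
                            pressure = 0.01, direction = "transverse",
                            stress20 = 99))
  expect_equal(staggering_statistics(s2)$by_ratio, br)
})

test_that("the coarsened spec halves extents and doubles spacing", {
  sp <- template_spec(aspect_ratio = 5, staggered = TRUE)
  cs <- coarsen_spec(sp)
  expect_equal(cs$vertex_spacing, 4)
  expect_equal(cs$template_extent, c(152, 152))  # snapped to the lattice
  expect_equal(cs$aspect_ratio, 5)
  sp20 <- template_spec(aspect_ratio = 20)
  expect_equal(coarsen_spec(sp20)$template_extent, c(300, 300))
})
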