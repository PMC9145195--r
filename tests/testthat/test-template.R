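test_that("the 2D grid tiles the extent with the requested cells", {
  # 300/20 per side: 225 square cells
  g1 <- make_cell_grid(template_spec(aspect_ratio = 1, staggered = FALSE,
                                     template_extent = c(300, 300)))
  expect_equal(nrow(g1$cells), 225)
  expect_true(all(g1$cells$x1 - g1$cells$x0 == 20))
  expect_false(any(g1$cells$clipped))

  # staggered 5:1: 100 x 20 um cells, alternate files offset by half a
  # cell length
  g2 <- make_cell_grid(template_spec(aspect_ratio = 5, staggered = TRUE,
                                     template_extent = c(300, 300),
                                     vertex_spacing = 2))
  expect_equal(g2$stagger_offset, 50)
  full <- g2$cells[!g2$cells$clipped, ]
  expect_true(all(full$x1 - full$x0 == 100))
  expect_true(all(full$y1 - full$y0 == 20))
  file2 <- g2$cells[g2$cells$y0 == 20, ]
  expect_true(50 %in% file2$x0)

  # non-staggered: all files share transverse wall lines
  g3 <- make_cell_grid(template_spec(aspect_ratio = 5, staggered = FALSE,
                                     template_extent = c(300, 300)))
  expect_equal(sort(unique(g3$cells$x0)), c(0, 100, 200))

  expect_error(template_spec(template_extent = c(10, 10)),
               "smaller than one cell")
})

test_that("extrusion produces closed boxes with the exact connection band", {
  tm <- tiny_one_cell_template()
  expect_equal(tm$cells$V0, 8000, tolerance = 1e-12)  # 20^3 box

  tm2 <- tiny_two_cell_template()
  expect_equal(tm2$cells$V0, c(8000, 8000), tolerance = 1e-12)
  # exactly one shared band strip of height ~ depth/3 between the cells
  sb <- tm2$wall_type == "shared-band"
  expect_gt(sum(sb), 0)
  zb <- range(tm2$vertices[unique(as.vector(tm2$triangles[sb, ])), 3])
  expect_equal(zb, c(20 / 3, 40 / 3), tolerance = 1e-9)
  xb <- unique(tm2$vertices[unique(as.vector(tm2$triangles[sb, ])), 1])
  expect_equal(xb, 20)  # single strip on the shared wall plane
})

test_that("per-cell surfaces agree with the signed-tetrahedron volume oracle", {
  tm <- small_tissue_template()
  v_pkg <- cell_volumes(tm)
  v_orc <- oracle_cell_volumes(tm)
  expect_equal(v_pkg, v_orc, tolerance = 1e-10)
  expect_true(all(v_pkg > 0))

  # also at a random displaced configuration
  set.seed(21)
  coords <- tm$vertices + matrix(rnorm(length(tm$vertices), sd = 0.3),
                                 ncol = 3)
  expect_equal(cell_volumes(tm, coords), oracle_cell_volumes(tm, coords),
               tolerance = 1e-10)
})

test_that("unsmoothed template volume equals the tiled box volume", {
  sp <- template_spec(aspect_ratio = 2, staggered = TRUE,
                      template_extent = c(80, 60), vertex_spacing = 4,
                      smoothing_iterations = 0)
  tm <- extrude_template(make_cell_grid(sp))
  expect_equal(sum(tm$cells$V0), 80 * 60 * 20, tolerance = 1e-3 * 80 * 60 * 20)
})

test_that("staggering preserves total volume and wall area within 5%", {
  mk <- function(stag) {
    extrude_template(make_cell_grid(template_spec(
      aspect_ratio = 5, staggered = stag, template_extent = c(152, 152),
      vertex_spacing = 4, smoothing_iterations = 0)))
  }
  st <- mk(TRUE); ns <- mk(FALSE)
  expect_equal(sum(st$cells$V0), sum(ns$cells$V0), tolerance = 1e-3)
  expect_lt(abs(wall_area(st) / wall_area(ns) - 1), 0.05)
})

test_that("smoothing rounds the mesh but pins the central segment", {
  tm <- tiny_two_cell_template()
  sm0 <- smooth_template(tm, iterations = 0)
  expect_identical(sm0$vertices, tm$vertices)

  sm <- smooth_template(tm, iterations = 10)
  central <- tm$vertices[, 3] > tm$central[1] - 1e-9 &
    tm$vertices[, 3] < tm$central[2] + 1e-9 &
    tm$vertices[, 3] > 1e-9 & tm$vertices[, 3] < 20 - 1e-9
  expect_equal(sm$vertices[central, ], tm$vertices[central, ])
  expect_false(isTRUE(all.equal(sm$vertices, tm$vertices)))
  # volumes change by less than 20%
  expect_true(all(abs(sm$cells$V0 / tm$cells$V0 - 1) < 0.2))

  # smoothed elongated cells with interior sides: enclosed volume strictly
  # below the box volume (rounding removes the corners)
  sp <- template_spec(aspect_ratio = 5, staggered = FALSE,
                      template_extent = c(200, 60), vertex_spacing = 4)
  tm5 <- extrude_template(make_cell_grid(sp))
  sm5 <- smooth_template(tm5)
  mid <- which(tm5$cells$y0 == 20)
  expect_true(all(sm5$cells$V0[mid] < tm5$cells$V0[mid]))
})

test_that("template generation is deterministic", {
  sp <- template_spec(aspect_ratio = 2, staggered = TRUE,
                      template_extent = c(80, 40), vertex_spacing = 4)
  t1 <- build_template(sp)
  t2 <- build_template(sp)
  expect_identical(t1$vertices, t2$vertices)
  expect_identical(t1$triangles, t2$triangles)
})

test_that("template spec invariants are enforced", {
  expect_error(template_spec(extrusion_segments = 4, anticlinal_depth = 20),
               "must equal anticlinal_depth")
  expect_error(template_spec(aspect_ratio = 0.5), "aspect_ratio")
  expect_error(template_spec(vertex_spacing = 25), "vertex_spacing")
  expect_error(template_spec(connection_band_fraction = 0), "band")
})
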