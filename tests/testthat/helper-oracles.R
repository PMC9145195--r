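# Independent oracles and shared fixtures for the test suite.

# Signed-tetrahedron volume oracle: decompose each cell surface into
# tetrahedra against the cell's own centroid (a different decomposition
# from the origin-based divergence-theorem sum used by the package).
oracle_cell_volumes <- function(template, coords = template$vertices) {
  nc <- length(template$cellptr) - 1L
  vols <- numeric(nc)
  for (c in seq_len(nc)) {
    idx <- (template$cellptr[c] + 1L):template$cellptr[c + 1L]
    f <- template$faces[idx, , drop = FALSE]
    ctr <- colMeans(coords[unique(as.vector(f)), , drop = FALSE])
    a <- sweep(coords[f[, 1], , drop = FALSE], 2, ctr)
    b <- sweep(coords[f[, 2], , drop = FALSE], 2, ctr)
    d <- sweep(coords[f[, 3], , drop = FALSE], 2, ctr)
    cx <- b[, 2] * d[, 3] - b[, 3] * d[, 2]
    cy <- b[, 3] * d[, 1] - b[, 1] * d[, 3]
    cz <- b[, 1] * d[, 2] - b[, 2] * d[, 1]
    vols[c] <- sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
  }
  vols
}

# random 3D rotation matrix (QR-based, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# polar decomposition oracle for a 3x2 or 2x2 deformation gradient
oracle_polar_U <- function(F) {
  e <- eigen(crossprod(F), symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)
}

# small cached templates (built once per test session)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

tiny_two_cell_template <- function() {
  fixture("two_cell", function() {
    extrude_template(make_cell_grid(template_spec(
      aspect_ratio = 1, staggered = FALSE, template_extent = c(40, 20),
      vertex_spacing = 4, smoothing_iterations = 0)))
  })
}

tiny_one_cell_template <- function() {
  fixture("one_cell", function() {
    extrude_template(make_cell_grid(template_spec(
      aspect_ratio = 1, staggered = FALSE, template_extent = c(20, 20),
      vertex_spacing = 4, smoothing_iterations = 0)))
  })
}

# small pressurizable multi-cell template for solver-level tests
small_tissue_template <- function() {
  fixture("small_tissue", function() {
    build_template(template_spec(aspect_ratio = 2, staggered = TRUE,
                                 template_extent = c(80, 40),
                                 vertex_spacing = 4))
  })
}

# --- anisotropy-fit round trips (shared by the fit and acceptance suites)

fit_fixture_template <- function() {
  fixture("fit_template", function() {
    build_template(template_spec(aspect_ratio = 1, staggered = FALSE,
                                 template_extent = c(40, 40),
                                 vertex_spacing = 4))
  })
}

fit_protocol <- function() {
  stretch_protocol(total_strain = 0.2, steps = 10, pressure = 0.01)
}

# tissue stiffness ratio simulated at a planted wall modulus fraction,
# with the Green-strain linearization applied as in the fit itself
planted_fit_ratio <- function(f) {
  fixture(sprintf("planted_%g", f), function() {
    tmpl <- fit_fixture_template()
    proto <- fit_protocol()
    mat <- material_params(E_long = f * 100, E_trans = 100,
                           strain_measure = "green")
    pr <- pressurize(tmpl, proto$pressure, mat)
    corr <- 1 + 0.2 / 2
    sl <- stress_at_strain(to_stress_strain(stretch(
      pr$model, pr$state,
      stretch_protocol("longitudinal", 0.2, 10, proto$pressure))),
      20) / corr
    st <- stress_at_strain(to_stress_strain(stretch(
      pr$model, pr$state,
      stretch_protocol("transverse", 0.2, 10, proto$pressure))),
      20) / corr
    sl / st
  })
}

fit_roundtrip <- function(f_star) {
  fixture(sprintf("fit_rt_%g", f_star), function() {
    target <- planted_fit_ratio(f_star)
    fit <- fit_longitudinal_fraction(fit_fixture_template(), target,
                                     protocol = fit_protocol())
    list(f_star = f_star, target = target, fit = fit)
  })
}
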