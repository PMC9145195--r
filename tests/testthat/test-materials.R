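test_that("Lame conversions invert the printed modulus relations", {
  expect_equal(unname(lame_from_elastic(100, 0)), c(0, 50))
  lm <- lame_from_elastic(90, 0.25)
  expect_equal(unname(lm["lambda"]), unname(lm["mu"]))
  # round trip on random positive pairs against the algebraic oracle
  set.seed(42)
  for (i in 1:20) {
    lambda <- runif(1, 0, 200); mu <- runif(1, 1, 200)
    en <- elastic_from_lame(lambda, mu)
    lm2 <- lame_from_elastic(en["E"], en["nu"])
    expect_equal(unname(lm2["lambda"]), lambda, tolerance = 1e-12)
    expect_equal(unname(lm2["mu"]), mu, tolerance = 1e-12)
  }
  expect_error(lame_from_elastic(100, 0.5), "incompressible")
})

test_that("strain measures from the deformation gradient are correct", {
  s0 <- strain_from_F(diag(2))
  expect_equal(s0$E_biot, matrix(0, 2, 2))
  expect_equal(s0$E_green, matrix(0, 2, 2))
  expect_equal(s0$J, 1)

  s <- strain_from_F(diag(c(1.2, 1)))
  expect_equal(s$E_biot, diag(c(0.2, 0)), tolerance = 1e-12)
  expect_equal(s$E_green, diag(c(0.22, 0)), tolerance = 1e-12)

  # Biot strain is invariant under a pre-rotation of F (polar oracle)
  set.seed(7)
  for (i in 1:25) {
    F <- matrix(rnorm(6, sd = 0.2), 3, 2) + rbind(diag(2), 0)
    R3 <- random_rotation()
    s1 <- strain_from_F(F)
    s2 <- strain_from_F(R3 %*% F)
    expect_equal(s1$E_biot, s2$E_biot, tolerance = 1e-10)
    expect_equal(s1$U, oracle_polar_U(F), tolerance = 1e-10)
  }
  expect_error(strain_from_F(diag(c(-1, 1))), "inverted")
})

test_that("SVK energy density follows the quadratic form and is convex", {
  expect_equal(svk_energy_density(matrix(0, 2, 2), 30, 50), 0)
  expect_equal(svk_energy_density(diag(c(0.2, 0)), 0, 50), 2)
  # strict convexity near 0: random second differences are positive
  set.seed(11)
  for (i in 1:20) {
    E0 <- matrix(rnorm(4, sd = 0.05), 2); E0 <- (E0 + t(E0)) / 2
    D <- matrix(rnorm(4, sd = 1), 2); D <- (D + t(D)) / 2
    h <- 1e-3
    w0 <- svk_energy_density(E0, 3, 5)
    wp <- svk_energy_density(E0 + h * D, 3, 5)
    wm <- svk_energy_density(E0 - h * D, 3, 5)
    expect_gt(wp + wm - 2 * w0, 0)
  }
})

test_that("transversely isotropic energy reduces to isotropic and has the stated moduli", {
  iso <- material_params(E_long = 100, E_trans = 100,
                         strain_measure = "green")
  aniso <- material_params(E_long = 30, E_trans = 100)
  set.seed(3)
  for (i in 1:20) {
    E <- matrix(rnorm(4, sd = 0.05), 2); E <- (E + t(E)) / 2
    expect_equal(transversely_isotropic_energy(E, iso),
                 svk_energy_density(E, iso$lambda, iso$mu),
                 tolerance = 1e-12)
  }
  # uniaxial small-strain tangent along each material axis
  slope_along <- function(params, axis) {
    eps <- 1e-5
    stretch <- function(e) {
      F <- diag(c(1, 1)); F[axis, axis] <- 1 + e
      EG <- (crossprod(F) - diag(2)) / 2
      transversely_isotropic_energy(EG, params)
    }
    (stretch(eps) + stretch(-eps) - 2 * stretch(0)) / eps^2
  }
  expect_equal(slope_along(aniso, 1), 30, tolerance = 1e-3)
  expect_equal(slope_along(aniso, 2), 100, tolerance = 1e-3)
  # swapping the frame axes swaps the two tangent moduli
  swap <- matrix(c(0, 1, 1, 0), 2)
  E <- diag(c(0.1, 0))
  expect_equal(transversely_isotropic_energy(E, aniso, frame = swap),
               transversely_isotropic_energy(diag(c(0, 0.1)), aniso),
               tolerance = 1e-12)
})

test_that("Cauchy stress recovery matches the linear Biot response", {
  iso <- material_params()
  s0 <- cauchy_stress(strain_from_F(diag(2)), iso)
  expect_equal(s0$trace, 0)
  # nu = 0, Biot, 20% uniaxial stretch: nominal stress = E * 0.2 = 20 MPa;
  # Cauchy sigma_11 = nominal / (width change) = 20 (no lateral change)
  st <- strain_from_F(diag(c(1.2, 1)))
  cs <- cauchy_stress(st, iso)
  expect_equal(cs$sigma[1, 1], 100 * 0.2 / 1, tolerance = 1e-12)
  # symmetry of sigma for random F (direct tensor-algebra oracle)
  set.seed(5)
  for (i in 1:20) {
    F <- diag(2) + matrix(rnorm(4, sd = 0.15), 2)
    if (det(F) <= 0.1) next
    cs <- cauchy_stress(strain_from_F(F), iso)
    expect_equal(cs$sigma, t(cs$sigma), tolerance = 1e-10)
  }
})

test_that("material parameter invariants are enforced", {
  expect_error(material_params(poisson = 0.6))
  expect_error(material_params(E_long = -1))
  expect_error(material_params(E_long = 30, E_trans = 100,
                               strain_measure = "biot"),
               "Green")
  m <- material_params(E_long = 30, E_trans = 100)
  expect_equal(m$strain_measure, "green")
  expect_equal(m$shear, sqrt(30 * 100) / 2)
})
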