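make_loaded_model <- function() {
  tm <- tiny_two_cell_template()
  list(model = fem_model(tm, material_params()),
       load = load_case(pressure = 0.3))
}

test_that("analytic gradient matches finite differences of the energy", {
  ml <- make_loaded_model()
  mod <- ml$model; ld <- ml$load
  set.seed(1)
  u <- matrix(rnorm(mod$n_nodes * 3, sd = 0.05), ncol = 3)
  g <- generalized_forces(mod, u, ld)
  h <- 1e-6
  idx <- sample(mod$ndof, 80)
  gfd <- vapply(idx, function(d) {
    n <- (d - 1) %/% 3 + 1; a <- (d - 1) %% 3 + 1
    up <- u; up[n, a] <- up[n, a] + h
    um <- u; um[n, a] <- um[n, a] - h
    (total_energy(mod, up, ld) - total_energy(mod, um, ld)) / (2 * h)
  }, 0)
  gan <- g[cbind((idx - 1) %/% 3 + 1, (idx - 1) %% 3 + 1)]
  expect_lt(max(abs(gan - gfd)) / max(abs(gfd)), 1e-5)
})

test_that("energy and gradient vanish at rest and under rigid motion", {
  ml <- make_loaded_model()
  mod <- ml$model
  u0 <- matrix(0, mod$n_nodes, 3)
  expect_equal(total_energy(mod, u0), 0)
  expect_equal(max(abs(generalized_forces(mod, u0))), 0)

  # rigid translation of an unpressurized body: zero energy and gradient
  ut <- matrix(rep(c(3, -2, 5), each = mod$n_nodes), ncol = 3)
  expect_equal(total_energy(mod, ut), 0, tolerance = 1e-10)
  expect_lt(max(abs(generalized_forces(mod, ut))), 1e-8)

  # pressure term of a unit-volume closed cell: -P * (V - V0) with V0
  # offset, so zero at rest but -P * dV under expansion
  ld <- load_case(pressure = 0.5)
  expect_equal(total_energy(mod, u0, ld), 0)
  usc <- 0.1 * (mod$X0 - matrix(colMeans(mod$X0), mod$n_nodes, 3,
                                byrow = TRUE))
  V1 <- sum(cell_volumes(mod$template, mod$X0 + usc))
  en <- total_energy(mod, usc, ld)
  el <- total_energy(mod, usc, load_case(pressure = 0))
  expect_equal(en - el, -0.5 * (V1 - sum(mod$V0)), tolerance = 1e-8)
})

test_that("energies are invariant under rotation of the deformed body", {
  tm <- tiny_two_cell_template()
  for (mat in list(material_params(),
                   material_params(strain_measure = "green"),
                   material_params(E_long = 30, E_trans = 100))) {
    mod <- fem_model(tm, mat)
    set.seed(9)
    u <- matrix(rnorm(mod$n_nodes * 3, sd = 0.05), ncol = 3)
    e0 <- total_energy(mod, u, load_case(pressure = 0.2))
    for (i in 1:8) {
      R3 <- random_rotation()
      u2 <- (mod$X0 + u) %*% t(R3) - mod$X0
      e1 <- total_energy(mod, u2, load_case(pressure = 0.2))
      expect_equal(e1, e0, tolerance = 1e-10)
    }
  }
})

test_that("the assembled Hessian is symmetric, local, and consistent with the gradient", {
  ml <- make_loaded_model()
  mod <- ml$model; ld <- ml$load
  set.seed(2)
  u <- matrix(rnorm(mod$n_nodes * 3, sd = 0.03), ncol = 3)
  H <- fem_hessian(mod, u, ld)
  expect_s4_class(H, "dsCMatrix")  # symmetric storage by construction

  # FD consistency: random Hessian columns against central differences of
  # the analytic gradient
  h <- 1e-6
  for (d in sample(mod$ndof, 6)) {
    n <- (d - 1) %/% 3 + 1; a <- (d - 1) %% 3 + 1
    up <- u; up[n, a] <- up[n, a] + h
    um <- u; um[n, a] <- um[n, a] - h
    cfd <- (as.vector(t(generalized_forces(mod, up, ld))) -
            as.vector(t(generalized_forces(mod, um, ld)))) / (2 * h)
    expect_lt(max(abs(H[, d] - cfd)) / max(abs(cfd)), 1e-3)
  }

  # sparsity pattern within the node adjacency of elements and cell faces
  Hg <- as(H, "generalMatrix")
  nz <- Matrix::which(Hg != 0, arr.ind = TRUE)
  n1 <- (nz[, 1] - 1) %/% 3 + 1
  n2 <- (nz[, 2] - 1) %/% 3 + 1
  adj <- unique(rbind(
    do.call(rbind, lapply(1:3, function(i) lapply(1:3, function(j)
      cbind(mod$tri[, i], mod$tri[, j]))[[1]])),
    do.call(rbind, lapply(1:3, function(i) lapply(1:3, function(j)
      cbind(mod$faces[, i], mod$faces[, j]))[[1]]))))
  adjkey <- c(outer(0, 0, "+"))
  key_edge <- function(a, b) paste(pmin(a, b), pmax(a, b))
  allowed <- unique(unlist(lapply(1:3, function(i) unlist(lapply(1:3,
    function(j) c(key_edge(mod$tri[, i], mod$tri[, j]),
                  key_edge(mod$faces[, i], mod$faces[, j])))))))
  expect_true(all(key_edge(n1, n2) %in% allowed))
})

test_that("equilibrate returns immediately at equilibrium and inflates under pressure", {
  tm <- tiny_one_cell_template()
  mod <- fem_model(tm, material_params())
  pins <- cellstretch:::.rigid_body_pins(mod$X0)

  # no load: u = 0 is an equilibrium; 0 iterations beyond the check
  st0 <- equilibrate(mod, load_case(pressure = 0, dirichlet = pins))
  expect_true(st0$converged)
  expect_equal(st0$iterations, 0)
  expect_equal(max(abs(st0$u)), 0)

  # small pressure: final volume exceeds the reference volume
  pr <- pressurize(tm, 0.1, material_params())
  expect_true(pr$state$converged)
  expect_gt(pr$volume_change, 0)

  # volume change increases monotonically with pressure
  dv <- vapply(c(0.01, 0.1, 0.5),
               function(P) pressurize(tm, P, material_params())$volume_change,
               0)
  expect_true(all(diff(dv) > 0))

  # restarting at the pressurized equilibrium converges without iterations
  mod2 <- pr$model
  ld <- load_case(pressure = 0.1, dirichlet = pins)
  st2 <- equilibrate(mod2, ld, u0 = pr$state$u)
  expect_true(st2$converged)
  expect_equal(st2$iterations, 0)

  # energy is non-increasing across accepted pseudo-time steps
  expect_true(all(diff(pr$state$energy_history) <= 1e-9 *
                    (abs(pr$state$energy_history[-1]) + 1)))
})

test_that("equilibrium is invariant under rigid translation of the start guess", {
  tm <- tiny_one_cell_template()
  mod <- fem_model(tm, material_params())
  pins <- cellstretch:::.rigid_body_pins(mod$X0)
  ld <- load_case(pressure = 0.2, dirichlet = pins)
  st1 <- equilibrate(mod, ld)
  u0 <- matrix(rep(c(1, -1, 0.5), each = mod$n_nodes), ncol = 3)
  u0 <- apply_dirichlet(u0, mod, ld)
  st2 <- equilibrate(mod, ld, u0 = u0)
  expect_true(st1$converged && st2$converged)
  expect_equal(sum(st1$volumes), sum(st2$volumes), tolerance = 1e-6)
})

test_that("with no load, random small perturbations relax back to rest", {
  tm <- tiny_one_cell_template()
  mod <- fem_model(tm, material_params())
  pins <- cellstretch:::.rigid_body_pins(mod$X0)
  ld <- load_case(pressure = 0, dirichlet = pins)
  set.seed(12)
  u0 <- apply_dirichlet(matrix(rnorm(mod$n_nodes * 3, sd = 0.01), ncol = 3),
                        mod, ld)
  st <- equilibrate(mod, ld, u0 = u0)
  expect_true(st$converged)
  expect_lt(max(abs(st$u)), 0.05)
  expect_lt(abs(st$energy), 1e-6)
})

test_that("Dirichlet handling: prescriptions, conflicts, reactions", {
  tm <- tiny_two_cell_template()
  mod <- fem_model(tm, material_params())
  expect_error(load_case(dirichlet = data.frame(node = c(1, 1),
                                                axis = c(1, 1),
                                                value = c(0, 1))),
               "conflicting")

  # prescribed displacement d on the right end, 0 on the left:
  # end-node x-coordinates differ by exactly extent + d along x
  b <- tm$boundary
  d <- 2.5
  dir <- rbind(
    data.frame(node = b$left, axis = 1L, value = 0),
    data.frame(node = b$right, axis = 1L, value = d),
    data.frame(node = rep(order(rowSums(sweep(mod$X0, 2,
      colMeans(mod$X0))^2))[1], 2), axis = c(2L, 3L), value = 0))
  ld <- load_case(pressure = 0, dirichlet = dir)
  st <- equilibrate(mod, ld)
  expect_true(st$converged)
  x <- mod$X0 + st$u
  expect_equal(unique(round(x[b$right, 1] - 40, 9)), d)

  # reactions on the two ends are equal and opposite (global balance,
  # free lateral edges)
  Fr <- sum(st$grad[b$right, 1])
  Fl <- sum(st$grad[b$left, 1])
  expect_gt(Fr, 0)
  expect_equal(Fl, -Fr, tolerance = 1e-6 * abs(Fr))
})
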