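#' Convert Young's modulus and Poisson ratio to Lame coefficients
#'
#' Inverts the classical relations `E = mu (3 lambda + 2 mu) / (lambda + mu)`
#' and `nu = lambda / (2 (lambda + mu))`.
#'
#' @param E Young's modulus (MPa), positive.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return Named numeric vector `c(lambda = , mu = )` in MPa.
#' @examples
#' lame_from_elastic(100, 0)     # lambda = 0, mu = 50
#' lame_from_elastic(90, 0.25)   # lambda == mu
#' @export
lame_from_elastic <- function(E, nu) {
  E <- as.numeric(E)
  nu <- as.numeric(nu)
  stopifnot(is.numeric(E), length(E) == 1L, E > 0,
            is.numeric(nu), length(nu) == 1L, nu >= 0)
  if (nu >= 0.5) {
    stop("nu must be < 0.5 (incompressible limit is not representable)")
  }
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  c(lambda = lambda, mu = mu)
}

#' Convert Lame coefficients to Young's modulus and Poisson ratio
#'
#' @param lambda,mu Lame coefficients (MPa); `mu > 0`, `lambda >= 0`.
#' @return Named numeric vector `c(E = , nu = )`.
#' @export
elastic_from_lame <- function(lambda, mu) {
  lambda <- as.numeric(lambda)
  mu <- as.numeric(mu)
  stopifnot(mu > 0, lambda >= 0)
  E <- mu * (3 * lambda + 2 * mu) / (lambda + mu)
  nu <- lambda / (2 * (lambda + mu))
  c(E = E, nu = nu)
}

#' Cell-wall material parameters
#'
#' Bundles directional Young's moduli, Poisson ratio and the strain measure
#' used by the Saint Venant-Kirchhoff wall model. The isotropic wall uses
#' Biot (engineering) strain by default, which yields an exactly linear
#' uniaxial nominal-stress response of slope `E` when `nu = 0`; the
#' transversely isotropic wall uses Green-Lagrange strain.
#'
#' @param E_long Young's modulus along the cell long axis (MPa).
#' @param E_trans Young's modulus along the transverse in-plane axis (MPa).
#' @param E_normal Modulus normal to the wall (MPa). A membrane element
#'   cannot strain normally, so this is inert metadata kept for reporting.
#' @param poisson Poisson ratio (default 0, which removes all coupling terms).
#' @param strain_measure `"biot"` or `"green"`. Defaults to `"biot"` for
#'   isotropic parameters and `"green"` when `E_long != E_trans`.
#' @return Object of class `material_params`.
#' @examples
#' material_params()                       # isotropic 100 MPa walls
#' material_params(E_long = 30, E_trans = 100)  # anisotropic walls
#' @export
material_params <- function(E_long = 100, E_trans = 100, E_normal = E_trans,
                            poisson = 0, strain_measure = NULL) {
  stopifnot(E_long > 0, E_trans > 0, E_normal > 0,
            poisson >= 0, poisson < 0.5)
  iso <- isTRUE(all.equal(E_long, E_trans))
  if (is.null(strain_measure)) strain_measure <- if (iso) "biot" else "green"
  strain_measure <- match.arg(strain_measure, c("biot", "green"))
  if (!iso && strain_measure == "biot") {
    stop("the transversely isotropic wall model is formulated on Green strain")
  }
  if (!iso && poisson != 0) {
    stop("the transversely isotropic wall model assumes poisson = 0")
  }
  lm_iso <- lame_from_elastic(E_trans, poisson)
  structure(list(
    E_long = E_long, E_trans = E_trans, E_normal = E_normal,
    poisson = poisson, strain_measure = strain_measure,
    lambda = unname(lm_iso["lambda"]), mu = unname(lm_iso["mu"]),
    # in-plane shear modulus of the orthotropic law; reduces to E/2 (nu = 0)
    # in the isotropic limit
    shear = sqrt(E_long * E_trans) / 2,
    isotropic = iso
  ), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  if (x$isotropic) {
    cat(sprintf("Isotropic SVK wall material (%s strain): E = %g MPa, nu = %g\n",
                x$strain_measure, x$E_trans, x$poisson))
    cat(sprintf("  Lame coefficients: lambda = %g, mu = %g MPa\n",
                x$lambda, x$mu))
  } else {
    cat(sprintf(paste0("Transversely isotropic SVK wall material (%s strain):\n",
                       "  E_long = %g, E_trans = %g, E_normal = %g MPa, nu = %g\n",
                       "  in-plane shear modulus = %g MPa\n"),
                x$strain_measure, x$E_long, x$E_trans, x$E_normal,
                x$poisson, x$shear))
  }
  invisible(x)
}

#' Strain measures from a deformation gradient
#'
#' Computes the right stretch tensor `U` by polar decomposition (via SVD),
#' the Biot strain `U - I`, the Green-Lagrange strain `(F'F - I)/2` and the
#' area Jacobian `J = det(U)`.
#'
#' @param F Deformation gradient: a 2x2 matrix, or a 3x2 in-plane tangent
#'   map of a membrane element.
#' @param measure Which strain to mark as active, `"biot"` or `"green"`
#'   (both are always computed).
#' @return Object of class `strain_state` with components `F`, `R`, `U`,
#'   `J`, `E_biot`, `E_green`, `measure`.
#' @examples
#' s <- strain_from_F(diag(c(1.2, 1)))
#' s$E_biot   # diag(0.2, 0)
#' s$E_green  # diag(0.22, 0)
#' @export
strain_from_F <- function(F, measure = c("biot", "green")) {
  measure <- match.arg(measure)
  F <- as.matrix(F)
  stopifnot(ncol(F) == 2L, nrow(F) %in% c(2L, 3L))
  sv <- svd(F)
  J <- prod(sv$d)
  if (nrow(F) == 2L) {
    # orientation sign for square F
    J <- det(F)
  }
  if (J <= 0) stop("inverted element: det(F) <= 0")
  U <- sv$v %*% diag(sv$d, 2) %*% t(sv$v)
  R <- sv$u %*% t(sv$v)
  C <- crossprod(F)
  structure(list(
    F = F, R = R, U = U, J = J,
    E_biot = U - diag(2),
    E_green = (C - diag(2)) / 2,
    measure = measure
  ), class = "strain_state")
}

#' Saint Venant-Kirchhoff strain-energy density
#'
#' `W = (lambda/2) Tr(E)^2 + mu Tr(E^2)` for a symmetric strain tensor `E`
#' (either Biot or Green-Lagrange, per the material's strain measure).
#'
#' @param E Symmetric strain matrix.
#' @param lambda,mu Lame coefficients (MPa).
#' @return Energy per unit reference volume (MPa).
#' @export
svk_energy_density <- function(E, lambda, mu) {
  E <- as.matrix(E)
  stopifnot(nrow(E) == ncol(E), isTRUE(all.equal(E, t(E), tolerance = 1e-8)))
  lambda / 2 * sum(diag(E))^2 + mu * sum(E * E)
}

#' Transversely isotropic SVK energy density
#'
#' Orthotropic quadratic energy in the Green-Lagrange strain expressed in
#' the wall's material frame: with `nu = 0` there are no coupling terms and
#' `W = Ea/2 E11^2 + Eb/2 E22^2 + 2 G E12^2`, where `Ea`/`Eb` are the moduli
#' along the frame's longitudinal/transverse axes and
#' `G = sqrt(Ea Eb) / 2` is the in-plane shear modulus (so the form reduces
#' exactly to the isotropic SVK when `Ea = Eb`).
#'
#' @param E_green Symmetric 2x2 Green-Lagrange strain in some in-plane basis.
#' @param params A [material_params()] object (Green measure).
#' @param frame 2x2 matrix whose columns are the material longitudinal and
#'   transverse axes in the basis of `E_green` (default identity).
#' @return Energy per unit reference volume (MPa).
#' @export
transversely_isotropic_energy <- function(E_green, params,
                                          frame = diag(2)) {
  stopifnot(inherits(params, "material_params"))
  if (is.null(frame)) stop("material frame is required")
  Em <- t(frame) %*% E_green %*% frame
  params$E_long / 2 * Em[1, 1]^2 + params$E_trans / 2 * Em[2, 2]^2 +
    2 * params$shear * Em[1, 2]^2
}

#' Cauchy stress from a strain state
#'
#' Recovers the stress work-conjugate to the material's strain measure and
#' pushes it forward to Cauchy stress. For the Green measure
#' `S = lambda Tr(E) I + 2 mu E` and `sigma = (1/J) F S F'`; for the Biot
#' measure the conjugate stress is `T = lambda Tr(E) I + 2 mu E` and the
#' first Piola-Kirchhoff stress is `P = R T`, with `sigma = (1/J) P F'`.
#'
#' @param state A [strain_from_F()] result.
#' @param params A [material_params()] object (isotropic).
#' @return List with `sigma` (in-plane Cauchy stress pushed forward to the
#'   row space of `F`) and `trace` (MPa).
#' @export
cauchy_stress <- function(state, params) {
  stopifnot(inherits(state, "strain_state"), inherits(params, "material_params"))
  lam <- params$lambda
  mu <- params$mu
  if (params$strain_measure == "biot") {
    E <- state$E_biot
    T <- lam * sum(diag(E)) * diag(2) + 2 * mu * E
    P <- state$R %*% T
  } else {
    E <- state$E_green
    S <- lam * sum(diag(E)) * diag(2) + 2 * mu * E
    P <- state$F %*% S
  }
  sigma <- P %*% t(state$F) / state$J
  list(sigma = sigma, trace = sum(diag(sigma)))
}
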