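#' Assemble a finite-element model of a tissue template
#'
#' Precomputes per-element reference quantities (local tangent basis,
#' inverse reference shape matrix, area, material frame) for the membrane
#' wall elements and the per-cell closed face sets used by the follower
#' pressure load. For anisotropic materials the element frame's first axis
#' is the projection of the global longitudinal (x) axis onto the element
#' plane; elements whose plane is nearly perpendicular to x (transverse end
#' walls) carry the transverse modulus isotropically.
#'
#' @param template A `tissue_template`.
#' @param materials A [material_params()] object.
#' @param wall_overrides Optional named list of [material_params()] objects
#'   keyed by wall type (`"outer-periclinal"`, `"inner-periclinal"`,
#'   `"anticlinal"`, `"shared-band"`), overriding `materials` for those
#'   elements.
#' @return Object of class `fem_model`.
#' @export
fem_model <- function(template, materials = material_params(),
                      wall_overrides = NULL) {
  stopifnot(inherits(template, "tissue_template"),
            inherits(materials, "material_params"))
  v <- template$vertices
  tr <- template$triangles
  m <- nrow(tr)
  E1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  E2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cr <- cbind(E1[, 2] * E2[, 3] - E1[, 3] * E2[, 2],
              E1[, 3] * E2[, 1] - E1[, 1] * E2[, 3],
              E1[, 1] * E2[, 2] - E1[, 2] * E2[, 1])
  nlen <- sqrt(rowSums(cr^2))
  if (any(nlen < 2e-6)) stop("degenerate reference triangle in template")
  A0 <- nlen / 2
  nhat <- cr / nlen

  elem_mat <- function(mat, idx) {
    mcode <- integer(length(idx))
    mp <- matrix(0, length(idx), 3)
    e1 <- matrix(0, length(idx), 3)
    if (mat$isotropic) {
      mcode[] <- if (mat$strain_measure == "biot") 0L else 1L
      mp[, 1] <- mat$lambda
      mp[, 2] <- mat$mu
      el <- E1[idx, , drop = FALSE]
      e1 <- el / sqrt(rowSums(el^2))
    } else {
      mcode[] <- 2L
      nh <- nhat[idx, , drop = FALSE]
      # project global x onto each element plane
      px <- cbind(1 - nh[, 1] * nh[, 1], -nh[, 1] * nh[, 2], -nh[, 1] * nh[, 3])
      plen <- sqrt(rowSums(px^2))
      endwall <- plen < 0.3
      mp[, 1] <- ifelse(endwall, mat$E_trans, mat$E_long)
      mp[, 2] <- mat$E_trans
      mp[, 3] <- ifelse(endwall, mat$E_trans / 2, mat$shear)
      if (any(endwall)) {
        py <- cbind(-nh[, 2] * nh[, 1], 1 - nh[, 2] * nh[, 2],
                    -nh[, 2] * nh[, 3])
        px[endwall, ] <- py[endwall, , drop = FALSE]
        plen[endwall] <- sqrt(rowSums(px[endwall, , drop = FALSE]^2))
      }
      e1 <- px / plen
    }
    list(mcode = mcode, mp = mp, e1 = e1)
  }

  base <- elem_mat(materials, seq_len(m))
  mcode <- base$mcode; mp <- base$mp; e1 <- base$e1
  if (!is.null(wall_overrides)) {
    for (wt in names(wall_overrides)) {
      idx <- which(as.character(template$wall_type) == wt)
      if (!length(idx)) next
      ov <- elem_mat(wall_overrides[[wt]], idx)
      mcode[idx] <- ov$mcode; mp[idx, ] <- ov$mp; e1[idx, ] <- ov$e1
    }
  }
  e2 <- cbind(nhat[, 2] * e1[, 3] - nhat[, 3] * e1[, 2],
              nhat[, 3] * e1[, 1] - nhat[, 1] * e1[, 3],
              nhat[, 1] * e1[, 2] - nhat[, 2] * e1[, 1])
  d11 <- rowSums(E1 * e1); d21 <- rowSums(E1 * e2)
  d12 <- rowSums(E2 * e1); d22 <- rowSums(E2 * e2)
  det <- d11 * d22 - d21 * d12
  if (any(det <= 0)) stop("internal error: non-positive reference Jacobian")
  binv <- cbind(d22 / det, -d21 / det, -d12 / det, d11 / det)

  structure(list(
    template = template, materials = materials,
    X0 = v, tri = tr, binv = binv, a0t = A0 * template$thickness,
    area0 = A0, mcode = mcode, mp = mp,
    faces = template$faces, face_cell = template$face_cell,
    cellptr = template$cellptr, V0 = template$cells$V0,
    n_nodes = nrow(v), ndof = 3L * nrow(v),
    cache = new.env(parent = emptyenv())
  ), class = "fem_model")
}

#' @export
print.fem_model <- function(x, ...) {
  cat(sprintf("FEM model: %d nodes, %d membrane elements, %d cells\n",
              x$n_nodes, nrow(x$tri), length(x$V0)))
  print(x$materials)
  invisible(x)
}

#' Pressure and displacement loads
#'
#' @param pressure Turgor pressure in MPa applied to the interior faces of
#'   the pressurized cells (follower load via the enclosed-volume term).
#' @param cells Integer ids of pressurized cells (default: all).
#' @param dirichlet Data frame with columns `node`, `axis` (1 = x, 2 = y,
#'   3 = z) and `value` (prescribed displacement, um).
#' @return Object of class `load_case`.
#' @export
load_case <- function(pressure = 0, cells = NULL, dirichlet = NULL) {
  stopifnot(pressure >= 0)
  if (is.null(dirichlet)) {
    dirichlet <- data.frame(node = integer(), axis = integer(),
                            value = numeric())
  }
  stopifnot(all(c("node", "axis", "value") %in% names(dirichlet)))
  key <- paste(dirichlet$node, dirichlet$axis)
  if (anyDuplicated(key)) {
    dup <- dirichlet[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    agg <- stats::aggregate(value ~ node + axis, dup,
                            function(v) length(unique(v)))
    if (any(agg$value > 1)) {
      stop("conflicting Dirichlet prescriptions on one (node, axis) pair")
    }
    dirichlet <- dirichlet[!duplicated(key), ]
  }
  structure(list(pressure = pressure, cells = cells, dirichlet = dirichlet),
            class = "load_case")
}

# per-face pressure vector for the model under a load case
.face_pressure <- function(model, load) {
  P <- rep(0, nrow(model$faces))
  if (load$pressure > 0) {
    cells <- load$cells
    if (is.null(cells)) cells <- model$template$cells$id
    P[model$face_cell %in% cells] <- load$pressure
  }
  P
}

#' Apply Dirichlet constraints to a displacement field
#'
#' Sets the constrained entries of the displacement matrix to their
#' prescribed values and attaches the free-DOF mask. The reaction forces at
#' the constrained entries are the entries of [generalized_forces()] there.
#'
#' @param u n x 3 displacement matrix (um), or `NULL` for zeros.
#' @param model A [fem_model()].
#' @param load A [load_case()] whose `dirichlet` table defines the
#'   constraints.
#' @return The displacement matrix with prescribed entries set and a
#'   logical attribute `"free"` (length 3n, TRUE for unconstrained DOFs in
#'   row-major node/axis order).
#' @export
apply_dirichlet <- function(u, model, load) {
  if (is.null(u)) u <- matrix(0, model$n_nodes, 3)
  d <- load$dirichlet
  free <- rep(TRUE, model$ndof)
  if (nrow(d)) {
    u[cbind(d$node, d$axis)] <- d$value
    free[3L * (d$node - 1L) + d$axis] <- FALSE
  }
  attr(u, "free") <- free
  u
}

#' Total potential energy of a displaced tissue
#'
#' `Pi(u) = sum_elements W(E(F)) area0 thickness - sum_cells P (V(u) - V0)`,
#' with per-cell volumes from the divergence theorem over each closed
#' deformed cell surface.
#'
#' @param model A [fem_model()].
#' @param u n x 3 nodal displacement matrix (um).
#' @param load A [load_case()].
#' @return Energy in uN um.
#' @export
total_energy <- function(model, u, load = load_case()) {
  x <- model$X0 + u
  el <- .cs_elastic(x, model$tri, model$binv, model$a0t, model$mcode,
                    model$mp, grad = FALSE)
  if (el$bad > 0) stop(sprintf("inverted element %d", el$bad))
  en <- el$energy
  if (load$pressure > 0) {
    V <- .cs_cellvol(x, model$faces, model$cellptr)
    P <- rep(0, length(V))
    cells <- if (is.null(load$cells)) model$template$cells$id else load$cells
    P[match(cells, model$template$cells$id)] <- load$pressure
    en <- en - sum(P * (V - model$V0))
  }
  en
}

#' Generalized forces (gradient of the total potential energy)
#'
#' Analytic first derivatives of [total_energy()] with respect to the nodal
#' displacements.
#'
#' @inheritParams total_energy
#' @return n x 3 gradient matrix (uN).
#' @export
generalized_forces <- function(model, u, load = load_case()) {
  x <- model$X0 + u
  el <- .cs_elastic(x, model$tri, model$binv, model$a0t, model$mcode,
                    model$mp, grad = TRUE)
  if (el$bad > 0) stop(sprintf("inverted element %d", el$bad))
  g <- el$grad
  if (load$pressure > 0) {
    g <- g + .cs_pressure_grad(x, model$faces, .face_pressure(model, load))
  }
  g
}

#' Hessian of the total potential energy
#'
#' Assembled from per-element finite differences of the analytic gradient
#' (forward differences, symmetrized), exploiting element locality for
#' sparsity.
#'
#' @inheritParams total_energy
#' @param fd_step Finite-difference step (um).
#' @return Sparse symmetric `ndof x ndof` matrix (`Matrix::dsCMatrix`), DOF
#'   order `3 (node - 1) + axis`.
#' @export
fem_hessian <- function(model, u, load = load_case(), fd_step = 1e-6) {
  x <- model$X0 + u
  t1 <- .cs_elastic_hess(x, model$tri, model$binv, model$a0t, model$mcode,
                         model$mp, fd_step)
  i <- t1$i; j <- t1$j; vv <- t1$v
  if (load$pressure > 0) {
    t2 <- .cs_pressure_hess(x, model$faces, .face_pressure(model, load),
                            fd_step)
    i <- c(i, t2$i); j <- c(j, t2$j); vv <- c(vv, t2$v)
  }
  H <- Matrix::sparseMatrix(i = i, j = j, x = vv,
                            dims = c(model$ndof, model$ndof))
  Matrix::forceSymmetric((H + Matrix::t(H)) / 2, uplo = "U")
}

#' Solver control parameters
#'
#' @param tol Convergence tolerance: infinity norm of the free-DOF residual
#'   (uN), default `1e-4`.
#' @param dt0 Initial pseudo-time step (default 0.1).
#' @param dt_max Pseudo-time step cap (default 1e6; at large `dt` one update
#'   approaches a full Newton step).
#' @param max_iter Maximum accepted updates per equilibration (default 600).
#' @param fd_step Finite-difference step for the element Hessians (um).
#' @param hessian_lag Recompute the Hessian every `hessian_lag` accepted
#'   iterations (default 1, i.e. every iteration; 2 roughly halves
#'   assembly cost on hard runs at some cost in step quality).
#' @param verbose Print per-iteration diagnostics?
#' @return List of class `solver_control`.
#' @export
solver_control <- function(tol = 1e-4, dt0 = 0.1, dt_max = 1e6,
                           max_iter = 600, fd_step = 1e-6,
                           hessian_lag = 1L, verbose = FALSE) {
  structure(list(tol = tol, dt0 = dt0, dt_max = dt_max,
                 max_iter = max_iter, fd_step = fd_step,
                 hessian_lag = as.integer(hessian_lag), verbose = verbose),
            class = "solver_control")
}

# Precompute the sparse machinery for repeated equilibrations under a fixed
# constraint pattern: Hessian slot maps, the upper-triangular symmetric
# template of I + dt H on the free DOFs, and the symbolic Cholesky analysis.
# The Hessian sparsity pattern depends only on the mesh (and on whether
# pressure faces contribute), so it is cached on the model.
.solver_ctx <- function(model, load, control = solver_control()) {
  nd <- model$ndof
  x0 <- model$X0
  faceP <- .face_pressure(model, load)
  has_p <- any(faceP > 0)
  active <- faceP > 0
  pkey <- sprintf("pattern_%d_%.0f", sum(active), sum(which(active)))
  pat <- model$cache[[pkey]]
  if (is.null(pat)) {
    t1 <- .cs_elastic_hess(x0, model$tri, model$binv, model$a0t, model$mcode,
                           model$mp, control$fd_step)
    ti <- t1$i; tj <- t1$j
    if (has_p) {
      t2 <- .cs_pressure_hess(x0, model$faces, as.numeric(active),
                              control$fd_step)
      ti <- c(ti, t2$i); tj <- c(tj, t2$j)
    }
    Pid <- Matrix::sparseMatrix(i = ti, j = tj, x = 1, dims = c(nd, nd))
    nnz <- length(Pid@x)
    colP <- rep(seq_len(nd), diff(Pid@p))
    kp <- (colP - 1) * nd + (Pid@i + 1)
    map <- match((as.numeric(tj) - 1) * nd + ti, kp)
    Pid@x <- as.numeric(seq_len(nnz))
    pat <- list(Pid = Pid, nnz = nnz, map = map)
    model$cache[[pkey]] <- pat
  }

  d <- load$dirichlet
  free <- rep(TRUE, nd)
  if (nrow(d)) free[3L * (d$node - 1L) + d$axis] <- FALSE
  freedofs <- which(free)
  nf <- length(freedofs)

  Sub <- pat$Pid[freedofs, freedofs, drop = FALSE]
  submap <- as.integer(Sub@x)
  colS <- rep(seq_len(nf), diff(Sub@p))
  rowS <- Sub@i + 1L
  upper_sel <- which(rowS <= colS)
  diag_in_upper <- which(rowS[upper_sel] == colS[upper_sel])
  stopifnot(length(diag_in_upper) == nf)

  Asym <- Sub
  Asym@x <- rep(0, length(Asym@x))
  Asym <- Matrix::forceSymmetric(Asym, uplo = "U")
  stopifnot(length(Asym@x) == length(upper_sel))
  ax0 <- numeric(length(upper_sel))
  ax0[diag_in_upper] <- 1
  Asym@x <- ax0
  chol0 <- Matrix::Cholesky(Asym, LDL = FALSE, super = TRUE)
  # simplicial LDL fallback: factors indefinite shifted Hessians without
  # erroring (the supernodal LL error path leaks CHOLMOD memory, so it is
  # abandoned after its first failure within an equilibration)
  chol0_ldl <- Matrix::Cholesky(Asym, LDL = TRUE, super = FALSE)

  list(model = model, load = load, control = control, faceP = faceP,
       has_p = has_p, map = pat$map, nnz = pat$nnz, free = free,
       freedofs = freedofs, submap = submap, upper_sel = upper_sel,
       diag_in_upper = diag_in_upper, Asym = Asym, chol0 = chol0,
       chol0_ldl = chol0_ldl,
       state = local({e <- new.env(parent = emptyenv())
                      e$n_super_fail <- 0L
                      e}))
}

# One full equilibration given a context and a start displacement whose
# constrained entries are already set to their prescribed values.
.equilibrate_ctx <- function(ctx, u, dt0 = ctx$control$dt0) {
  model <- ctx$model; control <- ctx$control
  tol <- control$tol
  dt <- dt0
  uvec <- as.vector(t(u))
  res_hist <- numeric(0)
  en_hist <- numeric(0)
  Pcell <- rep(0, length(model$V0))
  if (ctx$has_p) {
    cells <- if (is.null(ctx$load$cells)) model$template$cells$id else ctx$load$cells
    Pcell[match(cells, model$template$cells$id)] <- ctx$load$pressure
  }

  eval_eg <- function(uvec, grad = TRUE) {
    x <- model$X0 + matrix(uvec, ncol = 3, byrow = TRUE)
    el <- .cs_elastic(x, model$tri, model$binv, model$a0t, model$mcode,
                      model$mp, grad = grad)
    if (el$bad > 0) return(NULL)
    en <- el$energy
    g <- el$grad
    if (ctx$has_p) {
      V <- .cs_cellvol(x, model$faces, model$cellptr)
      en <- en - sum(Pcell * (V - model$V0))
      if (grad) g <- g + .cs_pressure_grad(x, model$faces, ctx$faceP)
    }
    list(energy = en, g = g, x = x)
  }

  cur <- eval_eg(uvec)
  if (is.null(cur)) stop("inverted element at the solver start state")
  iters <- 0L
  converged <- FALSE
  warned_energy <- FALSE
  # supernodal failures leak CHOLMOD workspace (Matrix error path), so
  # the budget of allowed failures is shared across all equilibrations
  # using this context
  use_super <- ctx$state$n_super_fail < 2L
  n_accepts <- 0L
  xup_cache <- NULL

  repeat {
    gvec <- as.vector(t(cur$g))
    gf <- gvec[ctx$freedofs]
    res <- max(abs(gf))
    res_hist <- c(res_hist, res)
    en_hist <- c(en_hist, cur$energy)
    if (control$verbose) {
      message(sprintf("  iter %3d  dt %-10.3g res %-12.4g energy %.8g",
                      iters, dt, res, cur$energy))
    }
    if (res <= tol) { converged <- TRUE; break }
    if (iters >= control$max_iter) break

    # assemble Hessian values at the current state (optionally lagged:
    # reuse the previous values every other iteration)
    if (iters %% control$hessian_lag == 0L || is.null(xup_cache)) {
      x <- cur$x
      hv <- .cs_elastic_hess_v(x, model$tri, model$binv, model$a0t,
                               model$mcode, model$mp, control$fd_step)
      pv <- if (ctx$has_p) {
        .cs_pressure_hess_v(x, model$faces, ctx$faceP, control$fd_step)
      } else numeric(0)
      xfull <- .cs_accum(ctx$map, hv, pv, ctx$nnz)
      xup_cache <- xfull[ctx$submap][ctx$upper_sel]
    }
    xup <- xup_cache

    accepted <- FALSE
    while (!accepted) {
      ax <- dt * xup
      ax[ctx$diag_in_upper] <- ax[ctx$diag_in_upper] + 1
      A <- ctx$Asym
      A@x <- ax
      # suppressWarnings (not a warning handler): unwinding out of CHOLMOD
      # mid-factorization corrupts its workspace; the terminal error is
      # raised after CHOLMOD returns and is safe to catch
      ch <- tryCatch(
        suppressWarnings(Matrix::update(
          if (use_super) ctx$chol0 else ctx$chol0_ldl, A)),
        error = function(e) NULL)
      if (is.null(ch) && use_super) {
        # supernodal LL failed (indefinite): switch to simplicial LDL and
        # retry at the same dt
        ctx$state$n_super_fail <- ctx$state$n_super_fail + 1L
        use_super <- FALSE
        ch <- tryCatch(
          suppressWarnings(Matrix::update(ctx$chol0_ldl, A)),
          error = function(e) NULL)
      }
      trial <- NULL
      full_step <- TRUE
      if (!is.null(ch)) {
        du <- tryCatch(-dt * as.numeric(Matrix::solve(ch, gf)),
                       error = function(e) NULL)
        if (!is.null(du) && all(is.finite(du))) {
          # backtracking on the computed direction: damping the step is
          # far cheaper than refactorizing at a smaller dt
          for (s in c(1, 0.5, 0.25, 0.125)) {
            uv2 <- uvec
            uv2[ctx$freedofs] <- uv2[ctx$freedofs] + s * du
            trial <- eval_eg(uv2)
            if (!is.null(trial) &&
                trial$energy <= cur$energy +
                  1e-9 * (abs(cur$energy) + 1)) {
              full_step <- s == 1
              break
            }
            trial <- NULL
          }
        }
      }
      if (!is.null(trial)) {
        if (trial$energy > cur$energy && !warned_energy) {
          warned_energy <- TRUE
        }
        uvec <- uv2
        cur <- trial
        if (full_step) dt <- min(dt * 2, control$dt_max)
        accepted <- TRUE
        n_accepts <- n_accepts + 1L
        if (!use_super && ctx$state$n_super_fail < 2L &&
            n_accepts %% 8L == 0L) {
          # the matrix may have become definite again; probe supernodal
          # on the next iteration
          use_super <- TRUE
        }
      } else {
        if (control$verbose) {
          message(sprintf("    reject at dt %.3g (%s)", dt,
                          if (is.null(ch)) "not PD"
                          else if (is.null(trial)) "bad trial"
                          else sprintf("dE=%.3g", trial$energy - cur$energy)))
        }
        dt <- dt / 2
        if (dt < 1e-12) {
          warning("pseudo-time step collapsed; returning best state")
          break
        }
      }
    }
    if (!accepted) break
    iters <- iters + 1L
  }

  if (!converged && iters >= control$max_iter) {
    warning(sprintf(
      "equilibration did not converge in %d iterations (residual %.3g uN)",
      control$max_iter, res_hist[length(res_hist)]))
  }
  u <- matrix(uvec, ncol = 3, byrow = TRUE)
  x <- model$X0 + u
  V <- .cs_cellvol(x, model$faces, model$cellptr)
  structure(list(
    u = u, converged = converged, iterations = iters,
    residual = res_hist[length(res_hist)], residual_history = res_hist,
    energy = cur$energy, energy_history = en_hist, dt = dt,
    grad = cur$g, volumes = V, free = ctx$free
  ), class = "solver_state")
}

#' Equilibrate a tissue model under loads
#'
#' Minimizes the total potential energy with the pseudo-time-stepping
#' implicit backward Euler scheme: each accepted update is
#' `u <- u - dt (I + dt H)^{-1} grad(Pi)` on the free DOFs, where `H` is the
#' Hessian of the total potential. The step `dt` doubles after an
#' energy-decreasing update and halves when the update fails (energy
#' increase or an indefinite linear system), so large `dt` approaches full
#' Newton steps near the minimum.
#'
#' @param model A [fem_model()].
#' @param load A [load_case()]; its Dirichlet table defines the constrained
#'   DOFs, whose displacement entries are held at their prescribed values.
#' @param u0 Optional n x 3 starting displacement (free entries only are
#'   used; constrained entries are overwritten with prescribed values).
#' @param control A [solver_control()].
#' @return Object of class `solver_state`: displacement `u`, `converged`
#'   flag, `iterations`, `residual_history`, `energy`, the full gradient
#'   `grad` (reaction forces at constrained DOFs), and per-cell `volumes`.
#' @export
equilibrate <- function(model, load = load_case(), u0 = NULL,
                        control = solver_control()) {
  ctx <- .solver_ctx(model, load, control)
  u <- apply_dirichlet(u0, model, load)
  .equilibrate_ctx(ctx, u)
}

#' @export
print.solver_state <- function(x, ...) {
  cat(sprintf(
    "Solver state: %s after %d iterations, residual %.3g uN, energy %.6g uN um\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$residual, x$energy))
  invisible(x)
}

#' Write a solver convergence log as CSV
#'
#' One row per pseudo-time iteration: residual (uN, infinity norm over
#' free DOFs) and total potential energy (uN um).
#'
#' @param state A `solver_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_solver_log <- function(state, path) {
  stopifnot(inherits(state, "solver_state"))
  utils::write.csv(data.frame(
    iteration = seq_along(state$residual_history) - 1L,
    residual = state$residual_history,
    energy = state$energy_history), path, row.names = FALSE)
  invisible(path)
}

#' Per-element stress field of a displaced model
#'
#' Recovers, per membrane element, the area Jacobian `J`, the strain-energy
#' density `W` (MPa) and the trace of the Cauchy stress tensor (MPa, the
#' quantity used for tissue stress heatmaps).
#'
#' @param model A [fem_model()].
#' @param u n x 3 displacement matrix.
#' @return `data.frame` with columns `J`, `W`, `cauchy_trace`, `wall_type`.
#' @export
stress_field <- function(model, u) {
  x <- model$X0 + u
  s <- .cs_stress(x, model$tri, model$binv, model$a0t, model$mcode, model$mp)
  out <- as.data.frame(s)
  out$wall_type <- model$template$wall_type
  out
}
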