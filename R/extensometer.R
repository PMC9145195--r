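#' Stretch protocol for the virtual extensometer
#'
#' @param direction `"longitudinal"` (along the cell long axis, x) or
#'   `"transverse"` (y).
#' @param total_strain Total applied strain as a fraction of the reference
#'   length (default 0.5 for full curve sweeps; quantitative reference
#'   stresses are read at 20 percent).
#' @param steps Number of displacement increments (>= 10).
#' @param pressure Turgor pressure in MPa (0.5 for turgid tissue, 0.01 for
#'   plasmolyzed).
#' @return Object of class `stretch_protocol`.
#' @export
stretch_protocol <- function(direction = c("longitudinal", "transverse"),
                             total_strain = 0.5, steps = 25,
                             pressure = 0.5) {
  direction <- match.arg(direction)
  stopifnot(total_strain > 0, steps >= 10, pressure >= 0)
  structure(list(direction = direction, total_strain = total_strain,
                 steps = as.integer(steps), pressure = pressure),
            class = "stretch_protocol")
}

# Minimal statically determinate rigid-body fixture (3-2-1): full pin at
# the lexicographically smallest node, y+z at an extreme-x node, z at an
# extreme-y node. Pressure loading is self-equilibrated, so reactions at
# these pins vanish and the deformation is unconstrained.
.rigid_body_pins <- function(X0) {
  lex <- order(X0[, 1], X0[, 2], X0[, 3])
  a <- lex[1]
  ox <- order(-X0[, 1], X0[, 2], X0[, 3])
  b <- ox[1]
  oy <- order(-X0[, 2], X0[, 1], X0[, 3])
  c3 <- oy[1]
  data.frame(node = c(a, a, a, b, b, c3),
             axis = c(1L, 2L, 3L, 2L, 3L, 3L),
             value = 0)
}

#' Pressurize a tissue template
#'
#' Finds the equilibrium of the tissue under turgor pressure alone (no end
#' constraints beyond a statically determinate rigid-body fixture) and
#' reports the relative increase of the total enclosed cell volume.
#'
#' @param model A [fem_model()], or a `tissue_template` (then `materials`
#'   is used to build the model).
#' @param pressure Turgor pressure (MPa).
#' @param materials Materials used when `model` is a template.
#' @param control A [solver_control()].
#' @return List with `state` (a `solver_state`), `volume_change`
#'   (fractional), and `model`.
#' @export
pressurize <- function(model, pressure = 0.5,
                       materials = material_params(),
                       control = solver_control()) {
  if (inherits(model, "tissue_template")) {
    model <- fem_model(model, materials)
  }
  stopifnot(inherits(model, "fem_model"))
  load <- load_case(pressure = pressure,
                    dirichlet = .rigid_body_pins(model$X0))
  st <- equilibrate(model, load, control = control)
  if (!st$converged) {
    warning("pressurization did not fully converge; volume change may be off")
  }
  vc <- (sum(st$volumes) - sum(model$V0)) / sum(model$V0)
  list(state = st, volume_change = vc, model = model)
}

#' Stretch a pressurized tissue with the virtual extensometer
#'
#' Applies the extensometer protocol: the stretch-axis coordinates of one
#' template end are held at their pressurized positions while the other
#' end is displaced in equal increments; after each increment the
#' equilibrium is recomputed and the reaction force along the displacement
#' axis is summed over the displaced nodes. Displacement and force are
#' logged relative to the pressurized pre-stretch equilibrium. Lateral
#' edges are free, as in the physical instrument.
#'
#' @param model A [fem_model()].
#' @param state A `solver_state` from [pressurize()] (or `NULL` to start
#'   from the reference configuration).
#' @param protocol A [stretch_protocol()]. Its `pressure` is kept during
#'   stretching.
#' @param control A [solver_control()].
#' @param keep_stress Record the per-element stress field at the final
#'   step?
#' @return A `force_displacement_curve`: data frame with columns
#'   `displacement` (um) and `force` (uN), with protocol and template
#'   metadata attached as attributes (`width`, `thickness`, `length0` for
#'   normalization; `stress_field` if requested).
#' @export
stretch <- function(model, state = NULL, protocol = stretch_protocol(),
                    control = solver_control(), keep_stress = FALSE) {
  stopifnot(inherits(model, "fem_model"))
  tmpl <- model$template
  axis <- if (protocol$direction == "longitudinal") 1L else 2L
  ends <- if (axis == 1L) {
    list(fixed = tmpl$boundary$left, moving = tmpl$boundary$right)
  } else {
    list(fixed = tmpl$boundary$bottom, moving = tmpl$boundary$top)
  }
  if (!length(ends$fixed) || !length(ends$moving)) {
    stop("template has no boundary nodes on the stretch axis")
  }
  u <- if (is.null(state)) matrix(0, model$n_nodes, 3) else state$u
  x <- model$X0 + u
  L0 <- max(x[, axis]) - min(x[, axis])
  width <- diff(range(model$X0[, if (axis == 1L) 2L else 1L]))
  depth <- tmpl$spec$anticlinal_depth
  inc <- protocol$total_strain * L0 / protocol$steps

  # interior pin (two orthogonal axes) to remove in-plane rigid modes
  ctr <- colMeans(model$X0)
  dist <- rowSums(sweep(model$X0, 2, ctr)^2)
  pin <- order(dist)[1]
  oth <- setdiff(1:3, axis)
  dir0 <- data.frame(
    node = c(ends$fixed, ends$moving, pin, pin),
    axis = c(rep(axis, length(ends$fixed) + length(ends$moving)), oth),
    value = 0)
  load <- load_case(pressure = protocol$pressure, dirichlet = dir0)
  ctx <- .solver_ctx(model, load, control)

  # prescribed displacements are held at the pressurized values, then the
  # moving end is incremented
  base_fix <- u[ends$fixed, axis]
  base_mov <- u[ends$moving, axis]
  pin_val <- u[pin, oth]

  frac <- (model$X0[, axis] - min(model$X0[, axis])) /
    diff(range(model$X0[, axis]))

  disp <- numeric(protocol$steps + 1)
  force <- numeric(protocol$steps + 1)
  states <- NULL
  truncated <- FALSE

  set_constraints <- function(u, d) {
    u[ends$fixed, axis] <- base_fix
    u[ends$moving, axis] <- base_mov + d
    u[pin, oth] <- pin_val
    u
  }

  u <- set_constraints(u, 0)
  st <- .equilibrate_ctx(ctx, u)
  disp[1] <- 0
  force[1] <- sum(st$grad[ends$moving, axis])
  u <- st$u
  u_prev <- NULL

  for (k in seq_len(protocol$steps)) {
    d <- k * inc
    if (is.null(u_prev)) {
      # first increment: affine extrapolation along the stretch axis
      guess <- u
      guess[, axis] <- guess[, axis] + inc * pmin(pmax(frac, 0), 1)
    } else {
      # subsequent increments: second-order extrapolation of the full
      # displacement field (captures the evolving wall-unfolding pattern
      # far better than an affine guess)
      guess <- 2 * u - u_prev
    }
    guess <- set_constraints(guess, d)
    dt_warm <- min(max(st$dt, control$dt0), 100)
    st_k <- tryCatch(.equilibrate_ctx(ctx, guess, dt0 = dt_warm),
                     error = function(e) e)
    if (inherits(st_k, "error") || !st_k$converged) {
      warning(sprintf(
        "stretch truncated at step %d/%d (%s)", k - 1L, protocol$steps,
        if (inherits(st_k, "error")) conditionMessage(st_k)
        else "no convergence"))
      truncated <- TRUE
      break
    }
    st <- st_k
    u_prev <- u
    u <- st$u
    disp[k + 1] <- d
    force[k + 1] <- sum(st$grad[ends$moving, axis])
  }
  nkeep <- if (truncated) k else protocol$steps + 1
  curve <- data.frame(displacement = disp[seq_len(nkeep)],
                      force = force[seq_len(nkeep)])
  class(curve) <- c("force_displacement_curve", "data.frame")
  attr(curve, "direction") <- protocol$direction
  attr(curve, "pressure") <- protocol$pressure
  attr(curve, "width") <- width
  attr(curve, "thickness") <- depth
  attr(curve, "length0") <- L0
  attr(curve, "material") <- model$materials
  attr(curve, "truncated") <- truncated
  if (keep_stress) attr(curve, "stress_field") <- stress_field(model, u)
  attr(curve, "final_state") <- st
  curve
}

#' @export
print.force_displacement_curve <- function(x, ...) {
  cat(sprintf(
    "Force-displacement curve (%s, P = %g MPa): %d samples, max force %.4g uN\n",
    attr(x, "direction"), attr(x, "pressure"), nrow(x), max(x$force)))
  cat(sprintf("  sample: width %g um, depth %g um, reference length %g um\n",
              attr(x, "width"), attr(x, "thickness"), attr(x, "length0")))
  invisible(x)
}

#' @export
plot.force_displacement_curve <- function(x, ...) {
  plot(x$displacement, x$force, type = "l",
       xlab = "displacement (um)", ylab = "force (uN)", ...)
  invisible(x)
}

#' Run a grid of extensometer simulations
#'
#' Executes one pressurize + stretch pipeline per entry and collects the
#' curves and their 20 percent reference stresses. Individual failures are
#' caught and reported in the summary so the grid continues.
#'
#' @param specs A list of entries, each a list with components `spec` (a
#'   [template_spec()]) and `protocol` (a [stretch_protocol()]), plus
#'   optional `materials` and `label`.
#' @param control A [solver_control()].
#' @param ref_strain Reference strain (percent) for the summary stresses.
#' @return List with `curves` (list of stress-strain curves, `NULL` on
#'   failure) and `summary` (data frame: label, direction, aspect ratio,
#'   staggered, pressure, stress at the reference strain, error message).
#' @export
run_experiment_grid <- function(specs, control = solver_control(),
                                ref_strain = 20) {
  curves <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  tmpl_cache <- new.env(parent = emptyenv())
  for (k in seq_along(specs)) {
    ent <- specs[[k]]
    lab <- if (!is.null(ent$label)) ent$label else sprintf("run%02d", k)
    res <- tryCatch({
      key <- paste(ent$spec$aspect_ratio, ent$spec$staggered,
                   paste(ent$spec$template_extent, collapse = "x"),
                   ent$spec$vertex_spacing)
      if (is.null(tmpl_cache[[key]])) {
        tmpl_cache[[key]] <- build_template(ent$spec)
      }
      mat <- if (!is.null(ent$materials)) ent$materials else material_params()
      pr <- pressurize(tmpl_cache[[key]], ent$protocol$pressure, mat,
                       control = control)
      fd <- stretch(pr$model, pr$state, ent$protocol, control = control)
      ss <- to_stress_strain(fd)
      list(curve = ss,
           stress = stress_at_strain(ss, ref_strain),
           volume_change = pr$volume_change, err = NA_character_)
    }, error = function(e) {
      list(curve = NULL, stress = NA_real_, volume_change = NA_real_,
           err = conditionMessage(e))
    })
    curves[k] <- list(res$curve)
    rows[[k]] <- data.frame(
      label = lab, direction = ent$protocol$direction,
      aspect_ratio = ent$spec$aspect_ratio, staggered = ent$spec$staggered,
      pressure = ent$protocol$pressure,
      stress_at_ref = res$stress, volume_change = res$volume_change,
      error = res$err, stringsAsFactors = FALSE)
  }
  list(curves = stats::setNames(curves, vapply(rows, `[[`, "", "label")),
       summary = do.call(rbind, rows))
}
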