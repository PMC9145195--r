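#' Calibrate the uniform wall thickness
#'
#' The wall thickness is the only free scale of the model (membrane
#' stiffness is linear in it). It is fixed by requiring that pressurizing
#' the staggered 5:1 template to 0.5 MPa with isotropic 100 MPa walls
#' expands the total cell volume by a target fraction (15 percent).
#' Monotone bisection on the thickness.
#'
#' @param target Target fractional volume increase (default 0.15).
#' @param spec Template spec of the calibration template (default: the
#'   staggered 5:1 template at the given resolution).
#' @param pressure Calibration pressure (MPa).
#' @param materials Wall material.
#' @param bracket Thickness search bracket in um.
#' @param tol Absolute tolerance on the achieved volume fraction.
#' @param control Solver control.
#' @return List: `thickness` (um), `achieved` volume fraction, and the
#'   search `trace`.
#' @export
calibrate_wall_thickness <- function(target = 0.15,
                                     spec = template_spec(),
                                     pressure = 0.5,
                                     materials = material_params(),
                                     bracket = c(0.2, 4),
                                     tol = 0.005,
                                     control = solver_control()) {
  tmpl0 <- build_template(spec)
  dv_at <- function(th) {
    tm <- tmpl0
    tm$thickness[] <- th
    tm$spec$wall_thickness <- th
    pressurize(tm, pressure, materials, control = control)$volume_change
  }
  trace <- data.frame(thickness = numeric(), volume_change = numeric())
  lo <- bracket[1]; hi <- bracket[2]
  dlo <- dv_at(lo); dhi <- dv_at(hi)
  trace[1:2, ] <- cbind(c(lo, hi), c(dlo, dhi))
  if (!(dlo >= target && dhi <= target)) {
    stop(sprintf(
      "target volume change %.3f not bracketed: dV(%g um) = %.3f, dV(%g um) = %.3f",
      target, lo, dlo, hi, dhi))
  }
  repeat {
    mid <- sqrt(lo * hi)
    dmid <- dv_at(mid)
    trace[nrow(trace) + 1L, ] <- c(mid, dmid)
    if (abs(dmid - target) <= tol || hi / lo < 1.02) break
    if (dmid > target) lo <- mid else hi <- mid
  }
  list(thickness = mid, achieved = dmid, trace = trace)
}

#' Coarsen a template spec
#'
#' The reduced-resolution variant used for desk-scale runs: vertex spacing
#' doubled and template extent halved.
#'
#' @param spec A [template_spec()].
#' @return The coarsened spec.
#' @export
coarsen_spec <- function(spec) {
  template_spec(
    cell_width = spec$cell_width, aspect_ratio = spec$aspect_ratio,
    staggered = spec$staggered,
    template_extent = spec$template_extent / 2,
    vertex_spacing = spec$vertex_spacing * 2,
    extrusion_segments = spec$extrusion_segments,
    segment_length = spec$segment_length,
    anticlinal_depth = spec$anticlinal_depth,
    connection_band_fraction = spec$connection_band_fraction,
    wall_thickness = spec$wall_thickness,
    smoothing_iterations = spec$smoothing_iterations,
    rng_seed = spec$rng_seed)
}

# build + pressurize + stretch one template in both directions, reusing the
# pressurized state; returns stress-strain curves and summary scalars
.panel_run <- function(spec, pressure, materials, directions, steps,
                       total_strain, control, ref_strain = 20,
                       template = NULL) {
  tmpl <- if (is.null(template)) build_template(spec) else template
  pr <- pressurize(tmpl, pressure, materials, control = control)
  out <- list(volume_change = pr$volume_change, curves = list(),
              stress = c())
  for (dir in directions) {
    fd <- stretch(pr$model, pr$state,
                  stretch_protocol(dir, total_strain, steps, pressure),
                  control = control)
    ss <- to_stress_strain(fd)
    out$curves[[dir]] <- ss
    out$stress[dir] <- stress_at_strain(ss, ref_strain)
  }
  out
}

#' Run the packaged simulation panels
#'
#' Reproduces the idealized-template simulation suite: the 5:1
#' staggered/non-staggered comparison in both stretch directions at turgid
#' pressure, the plasmolyzed staggered 5:1 runs, and an aspect-ratio sweep.
#' Writes curves (CSV), a summary table and the resolved configuration to
#' `outdir` when given.
#'
#' @param outdir Output directory, or `NULL` to skip writing.
#' @param coarse Run at the reduced desk-scale resolution (vertex spacing
#'   4 um, halved extents; default TRUE)? Full resolution is substantially
#'   slower.
#' @param aspect_ratios Aspect ratios of the sweep.
#' @param sweep_directions Stretch directions simulated in the sweep.
#' @param steps Displacement increments per stretch.
#' @param total_strain Total applied strain (default 0.2; the reference
#'   stresses are read at 20 percent).
#' @param materials Wall material for all runs.
#' @param realistic_mesh Optional path to a VTK template with realistic
#'   cell shapes; when absent the corresponding entry is marked skipped.
#' @param control Solver control.
#' @return List with `summary` (per-run stresses at 20 percent strain),
#'   `aggregates` (staggering statistics) and `curves`.
#' @export
run_paper_suite <- function(outdir = NULL, coarse = TRUE,
                            aspect_ratios = c(1, 2, 5, 10, 20),
                            sweep_directions = c("longitudinal",
                                                 "transverse"),
                            steps = 10, total_strain = 0.2,
                            materials = material_params(),
                            realistic_mesh = NULL,
                            control = solver_control()) {
  mkspec <- function(ar, stag) {
    sp <- template_spec(aspect_ratio = ar, staggered = stag)
    if (coarse) coarsen_spec(sp) else sp
  }
  rows <- list(); curves <- list()
  add_row <- function(label, ar, stag, P, dir, stress, dv, err = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, aspect_ratio = ar, staggered = stag, pressure = P,
      direction = dir, stress20 = stress, volume_change = dv, error = err,
      stringsAsFactors = FALSE)
  }

  runs <- list()
  for (ar in aspect_ratios) {
    for (stag in c(TRUE, FALSE)) {
      dirs <- unique(c(
        if (ar == 5) c("longitudinal", "transverse"),
        if (ar == 2) c("longitudinal", "transverse"),
        sweep_directions))
      key <- sprintf("ar%g_%s", ar, if (stag) "st" else "ns")
      res <- tryCatch(
        .panel_run(mkspec(ar, stag), 0.5, materials, dirs, steps,
                   total_strain, control),
        error = function(e) e)
      if (inherits(res, "error")) {
        add_row(key, ar, stag, 0.5, paste(dirs, collapse = "+"),
                NA_real_, NA_real_, conditionMessage(res))
        next
      }
      runs[[key]] <- res
      for (dir in names(res$stress)) {
        add_row(paste0(key, "_", substr(dir, 1, 1)), ar, stag, 0.5, dir,
                res$stress[[dir]], res$volume_change)
        curves[[paste0(key, "_", substr(dir, 1, 1))]] <- res$curves[[dir]]
      }
    }
  }
  # plasmolyzed staggered 5:1
  resp <- tryCatch(
    .panel_run(mkspec(5, TRUE), 0.01, materials,
               c("longitudinal", "transverse"), steps, total_strain,
               control),
    error = function(e) e)
  if (inherits(resp, "error")) {
    add_row("ar5_st_plasmolyzed", 5, TRUE, 0.01, "longitudinal+transverse",
            NA_real_, NA_real_, conditionMessage(resp))
  } else {
    runs[["ar5_st_p001"]] <- resp
    for (dir in names(resp$stress)) {
      add_row(paste0("ar5_st_p001_", substr(dir, 1, 1)), 5, TRUE, 0.01,
              dir, resp$stress[[dir]], resp$volume_change)
      curves[[paste0("ar5_st_p001_", substr(dir, 1, 1))]] <-
        resp$curves[[dir]]
    }
  }
  # realistic template, if supplied
  if (!is.null(realistic_mesh) && file.exists(realistic_mesh)) {
    resr <- tryCatch({
      tmpl <- read_vtk_template(realistic_mesh)
      .panel_run(NULL, 0.5, materials, c("longitudinal", "transverse"),
                 steps, total_strain, control, template = tmpl)
    }, error = function(e) e)
    if (inherits(resr, "error")) {
      add_row("realistic", NA, NA, 0.5, "longitudinal+transverse",
              NA_real_, NA_real_, conditionMessage(resr))
    } else {
      for (dir in names(resr$stress)) {
        add_row(paste0("realistic_", substr(dir, 1, 1)), NA, NA, 0.5, dir,
                resr$stress[[dir]], resr$volume_change)
        curves[[paste0("realistic_", substr(dir, 1, 1))]] <-
          resr$curves[[dir]]
      }
    }
  } else {
    add_row("realistic", NA, NA, 0.5, "longitudinal+transverse",
            NA_real_, NA_real_, "skipped: no realistic mesh supplied")
  }

  summary <- do.call(rbind, rows)
  aggregates <- staggering_statistics(summary)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(outdir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregates$by_ratio,
                     file.path(outdir, "staggering_by_ratio.csv"),
                     row.names = FALSE)
    for (nm in names(curves)) {
      write_curve_csv(curves[[nm]],
                      file.path(outdir, paste0("curve_", nm, ".csv")))
    }
    yaml::write_yaml(list(coarse = coarse, aspect_ratios = aspect_ratios,
                          steps = steps, total_strain = total_strain,
                          defaults = default_config()),
                     file.path(outdir, "resolved_config.yaml"),
                     precision = 15)
  }
  list(summary = summary, aggregates = aggregates, curves = curves)
}

#' Staggering statistics from a panel summary
#'
#' Computes, per aspect ratio: the longitudinal/transverse stiffness ratio
#' for staggered and non-staggered arrangements, the relative difference
#' between the two arrangements' ratios (percent), and the relative
#' reduction of transverse stress due to staggering (percent), plus the
#' mean transverse reduction across ratios.
#'
#' @param summary The `summary` data frame from [run_paper_suite()] (or any
#'   data frame with columns `aspect_ratio`, `staggered`, `pressure`,
#'   `direction`, `stress20`).
#' @return List with `by_ratio` (data frame) and
#'   `mean_transverse_reduction` (percent).
#' @export
staggering_statistics <- function(summary) {
  s <- summary[!is.na(summary$stress20) & summary$pressure == 0.5, ]
  get <- function(ar, stag, dir) {
    v <- s$stress20[s$aspect_ratio == ar & s$staggered == stag &
                    s$direction == dir]
    if (length(v)) v[1] else NA_real_
  }
  ars <- sort(unique(s$aspect_ratio))
  by_ratio <- do.call(rbind, lapply(ars, function(ar) {
    lt_st <- get(ar, TRUE, "longitudinal") / get(ar, TRUE, "transverse")
    lt_ns <- get(ar, FALSE, "longitudinal") / get(ar, FALSE, "transverse")
    trans_red <- 100 * (get(ar, FALSE, "transverse") -
                        get(ar, TRUE, "transverse")) /
      get(ar, FALSE, "transverse")
    data.frame(aspect_ratio = ar, ratio_staggered = lt_st,
               ratio_nonstaggered = lt_ns,
               ratio_difference_pct = 100 * abs(lt_st - lt_ns) /
                 pmin(lt_st, lt_ns),
               transverse_reduction_pct = trans_red)
  }))
  list(by_ratio = by_ratio,
       mean_transverse_reduction =
         mean(by_ratio$transverse_reduction_pct, na.rm = TRUE))
}
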