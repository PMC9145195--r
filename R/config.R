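#' Default run configuration
#'
#' Nested list mirroring the YAML schema: `template` ([template_spec()]
#' fields), `material` (directional moduli in MPa, Poisson ratio, strain
#' measure), `load` (turgor pressure in MPa), `protocol`
#' ([stretch_protocol()] fields), `solver` ([solver_control()] fields),
#' `output` and `rng_seed`. Defaults are the standard simulation
#' conditions: isotropic 100 MPa walls, Poisson ratio 0, 0.5 MPa turgor.
#'
#' @return Named list of class `run_config_defaults`.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    template = list(
      cell_width = 20, aspect_ratio = 5, staggered = TRUE,
      template_extent = c(300, 300), vertex_spacing = 2,
      extrusion_segments = 5L, segment_length = 4, anticlinal_depth = 20,
      connection_band_fraction = 1 / 3,
      wall_thickness = cs_default_wall_thickness(),
      smoothing_iterations = 10L
    ),
    material = list(
      E_long = 100, E_trans = 100, E_normal = 100, poisson = 0,
      strain_measure = "auto"
    ),
    load = list(pressure = 0.5),
    protocol = list(direction = "longitudinal", total_strain = 0.5,
                    steps = 25L),
    solver = list(tol = 1e-4, dt0 = 0.1, dt_max = 1e6, max_iter = 600L,
                  fd_step = 1e-6),
    output = list(dir = "."),
    rng_seed = 1L
  )
}

.check_known_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref)) {
      stop(sprintf("unknown configuration key: %s%s", path, nm))
    }
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]]))) {
      .check_known_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys, merges over [default_config()],
#' and instantiates the validated objects ([template_spec()],
#' [material_params()], [stretch_protocol()], [solver_control()]), so any
#' invariant violation (e.g. a Poisson ratio of 0.6) fails with a
#' descriptive error.
#'
#' @param path Path to a YAML file (may set any subset of keys).
#' @return Object of class `run_config`: the resolved configuration list
#'   plus instantiated `template_spec`, `materials`, `protocol`,
#'   `control` and `pressure`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  def <- default_config()
  .check_known_keys(raw, def)
  cfg <- utils::modifyList(def, raw)
  resolve_config(cfg)
}

#' Resolve a configuration list into validated objects
#'
#' @param cfg A full configuration list (shape of [default_config()]).
#' @return A `run_config` object.
#' @export
resolve_config <- function(cfg) {
  tmpl_args <- cfg$template
  tmpl_args$template_extent <- as.numeric(unlist(tmpl_args$template_extent))
  spec <- do.call(template_spec, c(tmpl_args, list(rng_seed = cfg$rng_seed)))
  sm <- cfg$material$strain_measure
  if (is.null(sm) || identical(sm, "auto")) sm <- NULL
  mat <- material_params(E_long = cfg$material$E_long,
                         E_trans = cfg$material$E_trans,
                         E_normal = cfg$material$E_normal,
                         poisson = cfg$material$poisson,
                         strain_measure = sm)
  proto <- stretch_protocol(direction = cfg$protocol$direction,
                            total_strain = cfg$protocol$total_strain,
                            steps = cfg$protocol$steps,
                            pressure = cfg$load$pressure)
  ctrl <- solver_control(tol = cfg$solver$tol, dt0 = cfg$solver$dt0,
                         dt_max = cfg$solver$dt_max,
                         max_iter = cfg$solver$max_iter,
                         fd_step = cfg$solver$fd_step)
  structure(list(config = cfg, template_spec = spec, materials = mat,
                 protocol = proto, control = ctrl,
                 pressure = cfg$load$pressure,
                 output_dir = cfg$output$dir),
            class = "run_config")
}

#' Write a resolved configuration as YAML
#'
#' Every run directory gets a copy of its resolved configuration, so runs
#' can be reproduced exactly; [load_config()] on the written file
#' round-trips to the same configuration.
#'
#' @param rc A `run_config` (or plain configuration list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(rc, path) {
  cfg <- if (inherits(rc, "run_config")) rc$config else rc
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  print(x$template_spec)
  print(x$materials)
  cat(sprintf("  pressure %g MPa, %s stretch to %g%% in %d steps\n",
              x$pressure, x$protocol$direction,
              100 * x$protocol$total_strain, x$protocol$steps))
  invisible(x)
}
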