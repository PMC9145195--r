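#' Specification of a synthetic extensometer trace
#'
#' Describes an idealized raw microextensometer force-displacement record:
#' a toe region where the sample straightens at near-zero force, followed
#' by a linear elastic rise of slope `apparent_modulus * width * thickness
#' / length`, with additive Gaussian force noise.
#'
#' @param length,width,thickness Sample dimensions (um), positive.
#' @param apparent_modulus Apparent tissue modulus (MPa).
#' @param toe_displacement Displacement consumed by the toe region (um).
#' @param noise Standard deviation of the force noise (uN), >= 0.
#' @param max_strain Largest strain simulated (fraction of `length`).
#' @param n_samples Number of displacement samples.
#' @param rng_seed Integer seed making the trace reproducible.
#' @return Object of class `trace_spec`.
#' @export
trace_spec <- function(length = 3600, width = 4000, thickness = 20,
                       apparent_modulus = 5, toe_displacement = 100,
                       noise = 0, max_strain = 0.5, n_samples = 200,
                       rng_seed = 1L) {
  stopifnot(length > 0, width > 0, thickness > 0, apparent_modulus > 0,
            toe_displacement >= 0, noise >= 0, max_strain > 0,
            n_samples >= 2)
  structure(list(length = length, width = width, thickness = thickness,
                 apparent_modulus = apparent_modulus,
                 toe_displacement = toe_displacement, noise = noise,
                 max_strain = max_strain, n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "trace_spec")
}

#' Generate a synthetic extensometer trace
#'
#' Produces a reproducible raw force-displacement curve per a
#' [trace_spec()]: zero force (plus noise) over the toe displacement, then
#' `force = apparent_modulus * width * thickness * (d - toe) / length`.
#' Used as a stand-in for raw microextensometer records when exercising
#' the curve-analysis functions.
#'
#' @param spec A [trace_spec()].
#' @return A `force_displacement_curve` with metadata set so that
#'   [to_stress_strain()] recovers the planted apparent modulus.
#' @examples
#' tr <- synth_extensometer_trace(trace_spec(noise = 0, toe_displacement = 0))
#' ss <- to_stress_strain(remove_toe(tr, 0))
#' @export
synth_extensometer_trace <- function(spec = trace_spec()) {
  stopifnot(inherits(spec, "trace_spec"))
  dmax <- spec$toe_displacement + spec$max_strain * spec$length
  d <- seq(0, dmax, length.out = spec$n_samples)
  A <- spec$width * spec$thickness
  f <- ifelse(d <= spec$toe_displacement, 0,
              spec$apparent_modulus * A * (d - spec$toe_displacement) /
                spec$length)
  if (spec$noise > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(spec$rng_seed)
    f <- f + stats::rnorm(length(f), sd = spec$noise)
  }
  out <- data.frame(displacement = d, force = f)
  class(out) <- c("force_displacement_curve", "data.frame")
  attr(out, "direction") <- "synthetic"
  attr(out, "pressure") <- NA_real_
  attr(out, "width") <- spec$width
  attr(out, "thickness") <- spec$thickness
  attr(out, "length0") <- spec$length
  attr(out, "toe") <- spec$toe_displacement
  out
}
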