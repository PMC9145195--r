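#' Normalize a force-displacement curve to stress-strain
#'
#' Tissue stress is the force normalized over the sample cross-sectional
#' area (width times thickness); strain is the displacement as a percentage
#' of the original sample length.
#'
#' @param curve A `force_displacement_curve` (data frame with
#'   `displacement` in um and `force` in uN).
#' @param width,thickness Sample cross-section (um); default from the
#'   curve's metadata.
#' @param length0 Original sample length (um); default from metadata.
#' @return A `stress_strain_curve`: data frame with `strain` (percent) and
#'   `stress` (MPa), metadata preserved.
#' @examples
#' fd <- data.frame(displacement = c(0, 60), force = c(0, 1200))
#' to_stress_strain(fd, width = 300, thickness = 20, length0 = 300)
#' @export
to_stress_strain <- function(curve, width = attr(curve, "width"),
                             thickness = attr(curve, "thickness"),
                             length0 = attr(curve, "length0")) {
  stopifnot(is.data.frame(curve),
            all(c("displacement", "force") %in% names(curve)))
  if (is.null(width) || is.null(thickness) || is.null(length0)) {
    stop("width, thickness and length0 are required (no metadata on curve)")
  }
  if (width <= 0 || thickness <= 0 || length0 <= 0) {
    stop("sample dimensions must be positive")
  }
  out <- data.frame(strain = 100 * curve$displacement / length0,
                    stress = curve$force / (width * thickness))
  class(out) <- c("stress_strain_curve", "data.frame")
  for (a in c("direction", "pressure", "width", "thickness", "length0",
              "material")) {
    attr(out, a) <- attr(curve, a)
  }
  out
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve (%s): %d samples, strain %g..%g%%, max stress %.4g MPa\n",
              if (is.null(attr(x, "direction"))) "?" else attr(x, "direction"),
              nrow(x), min(x$strain), max(x$strain), max(x$stress)))
  invisible(x)
}

#' @export
plot.stress_strain_curve <- function(x, ...) {
  plot(x$strain, x$stress, type = "l",
       xlab = "strain (% of original length)", ylab = "stress (MPa)", ...)
  invisible(x)
}

#' Remove the toe region of a raw extensometer curve
#'
#' Raw experimental curves begin with a flat region where displacement
#' accumulates at near-zero force while the sample straightens; this region
#' does not reflect sample stiffness. Leading samples with force below the
#' floor are dropped and the displacement is re-zeroed at the first
#' retained sample.
#'
#' @param curve A force-displacement data frame.
#' @param force_floor Force threshold (uN).
#' @return The trimmed curve (same class and metadata).
#' @export
remove_toe <- function(curve, force_floor) {
  stopifnot(is.data.frame(curve), force_floor >= 0)
  keep <- which(curve$force >= force_floor)
  if (!length(keep)) stop("entire curve is below the force floor")
  first <- keep[1]
  out <- curve[first:nrow(curve), , drop = FALSE]
  out$displacement <- out$displacement - out$displacement[1]
  rownames(out) <- NULL
  out
}

#' Stress at a reference strain
#'
#' Linear interpolation of the stress-strain curve at the reference strain
#' (20 percent by default, the comparison point used throughout).
#'
#' @param curve A `stress_strain_curve`.
#' @param ref_strain Reference strain in percent (default 20).
#' @return Stress in MPa.
#' @export
stress_at_strain <- function(curve, ref_strain = 20) {
  stopifnot(is.data.frame(curve),
            all(c("strain", "stress") %in% names(curve)))
  tol <- 1e-6 * max(abs(curve$strain), 1)
  if (ref_strain < min(curve$strain) - tol ||
      ref_strain > max(curve$strain) + tol) {
    stop(sprintf("curve does not span the reference strain %g%% (range %g..%g)",
                 ref_strain, min(curve$strain), max(curve$strain)))
  }
  xq <- min(max(ref_strain, min(curve$strain)), max(curve$strain))
  stats::approx(curve$strain, curve$stress, xout = xq, ties = "ordered")$y
}

#' Tissue stiffness anisotropy ratio
#'
#' Ratio of the longitudinal to the transverse stress at the reference
#' strain; the cross-section normalization cancels, so this equals the
#' force ratio for identically sized samples.
#'
#' @param long_curve,trans_curve `stress_strain_curve`s for the two
#'   directions.
#' @param ref_strain Reference strain in percent (default 20).
#' @return Dimensionless ratio.
#' @export
stiffness_ratio <- function(long_curve, trans_curve, ref_strain = 20) {
  s_l <- stress_at_strain(long_curve, ref_strain)
  s_t <- stress_at_strain(trans_curve, ref_strain)
  if (s_t == 0) stop("transverse stress at the reference strain is zero")
  s_l / s_t
}
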