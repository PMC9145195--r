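.wall_type_levels <- c("outer-periclinal", "inner-periclinal",
                       "anticlinal", "shared-band")

#' Export a tissue template as legacy ASCII VTK
#'
#' Writes the per-cell oriented face sets (shared-band walls appear once
#' per adjacent cell, so every cell's closed surface is recoverable) as an
#' unstructured grid of triangles with cell data arrays `cell_label`,
#' `wall_type` (integer codes 1-4 in the order outer-periclinal,
#' inner-periclinal, anticlinal, shared-band) and `thickness`. The same
#' layout is read back by [read_vtk_template()], so externally segmented
#' templates can be supplied in this format.
#'
#' @param template A `tissue_template`.
#' @param path Output file path (`.vtk`).
#' @param coords Optional deformed coordinates to write instead of the
#'   reference vertices.
#' @return `path`, invisibly.
#' @export
write_vtk_template <- function(template, path, coords = template$vertices) {
  v <- coords
  f <- template$faces
  # wall type per per-cell face: look up via sorted-triple key of the
  # unique triangle table
  K <- nrow(v) + 1
  key <- function(m) {
    s <- t(apply(m, 1, sort))
    (s[, 1] * K + s[, 2]) * K + s[, 3]
  }
  wt_map <- stats::setNames(as.integer(template$wall_type),
                            as.character(key(template$triangles)))
  th_map <- stats::setNames(template$thickness,
                            as.character(key(template$triangles)))
  fk <- as.character(key(f))
  wt <- unname(wt_map[fk])
  th <- unname(th_map[fk])

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cellstretch tissue template", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(format(v, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(f), 4L * nrow(f)), con)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(f)), con)
  writeLines(as.character(rep(5L, nrow(f))), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(f)),
               "SCALARS cell_label int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(template$face_cell), con)
  writeLines(c("SCALARS wall_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(wt), con)
  writeLines(c("SCALARS thickness double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(th, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

# minimal legacy-ASCII VTK tokenizer
.vtk_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[-(1:2)]  # header comment + title
  scan(text = paste(lines, collapse = "\n"), what = "character",
       quiet = TRUE)
}

#' Import a tissue template from legacy ASCII VTK
#'
#' Reads the layout written by [write_vtk_template()]: triangles with
#' `cell_label` (face owner), `wall_type` and `thickness` cell data. Faces
#' must be outward-oriented per owning cell; shared-band faces appear once
#' per adjacent cell and are deduplicated into single wall elements.
#' Boundary node sets are taken from the x/y extremes and the anticlinal
#' depth from the z range, so imported templates plug directly into
#' [fem_model()], [pressurize()] and [stretch()].
#'
#' @param path Path to a `.vtk` file.
#' @return A `tissue_template`.
#' @export
read_vtk_template <- function(path) {
  tk <- .vtk_tokens(path)
  expect <- function(i, what) {
    if (toupper(tk[i]) != what) {
      stop(sprintf("unsupported VTK layout: expected %s at token %d, got %s",
                   what, i, tk[i]))
    }
  }
  i <- 1
  expect(i, "ASCII"); i <- i + 1
  expect(i, "DATASET"); expect(i + 1, "UNSTRUCTURED_GRID"); i <- i + 2
  expect(i, "POINTS")
  np <- as.integer(tk[i + 1]); i <- i + 3
  v <- matrix(as.numeric(tk[i:(i + 3 * np - 1)]), np, 3, byrow = TRUE)
  colnames(v) <- c("x", "y", "z")
  i <- i + 3 * np
  expect(i, "CELLS")
  nf <- as.integer(tk[i + 1]); ntok <- as.integer(tk[i + 2]); i <- i + 3
  cc <- matrix(as.integer(tk[i:(i + ntok - 1)]), nf, ntok / nf, byrow = TRUE)
  if (ncol(cc) != 4 || any(cc[, 1] != 3L)) {
    stop("unsupported VTK layout: triangles expected")
  }
  faces <- cc[, 2:4, drop = FALSE] + 1L
  i <- i + ntok
  expect(i, "CELL_TYPES"); i <- i + 2
  i <- i + nf
  arrays <- list()
  while (i <= length(tk)) {
    if (toupper(tk[i]) == "CELL_DATA") { i <- i + 2; next }
    if (toupper(tk[i]) == "SCALARS") {
      nm <- tk[i + 1]
      i <- i + 4  # SCALARS name type ncomp + LOOKUP_TABLE default
      i <- i + 2
      arrays[[nm]] <- as.numeric(tk[i:(i + nf - 1)])
      i <- i + nf
      next
    }
    break
  }
  for (need in c("cell_label", "wall_type", "thickness")) {
    if (is.null(arrays[[need]])) {
      stop(sprintf("VTK template is missing the %s cell array", need))
    }
  }
  face_cell <- as.integer(arrays$cell_label)
  wt <- as.integer(arrays$wall_type)
  th <- arrays$thickness

  ord <- order(face_cell)
  faces <- faces[ord, , drop = FALSE]
  face_cell <- face_cell[ord]
  wt <- wt[ord]; th <- th[ord]
  ids <- sort(unique(face_cell))
  cellptr <- c(0L, cumsum(as.integer(table(factor(face_cell, levels = ids)))))

  srt <- t(apply(faces, 1, sort))
  K <- np + 1
  key3 <- (srt[, 1] * K + srt[, 2]) * K + srt[, 3]
  first <- !duplicated(key3)
  triangles <- faces[first, , drop = FALSE]
  wall_type <- factor(.wall_type_levels[wt[first]],
                      levels = .wall_type_levels)
  thickness <- th[first]

  ext <- c(max(v[, 1]) - min(v[, 1]), max(v[, 2]) - min(v[, 2]))
  depth <- max(v[, 3]) - min(v[, 3])
  tolb <- 1e-6 * max(ext)
  spec <- list(cell_width = NA_real_, aspect_ratio = NA_real_,
               staggered = NA, template_extent = ext,
               vertex_spacing = NA_real_, extrusion_segments = NA_integer_,
               segment_length = NA_real_, anticlinal_depth = depth,
               connection_band_fraction = NA_real_,
               wall_thickness = stats::median(thickness),
               smoothing_iterations = 0L, rng_seed = 0L)
  class(spec) <- "template_spec"
  tmpl <- structure(list(
    vertices = v, triangles = triangles, wall_type = wall_type,
    cell_label = ifelse(wall_type == "shared-band", NA_integer_,
                        face_cell[first]),
    thickness = thickness, faces = faces, face_cell = face_cell,
    cellptr = cellptr,
    cells = data.frame(id = ids),
    boundary = list(left = which(v[, 1] < min(v[, 1]) + tolb),
                    right = which(v[, 1] > max(v[, 1]) - tolb),
                    bottom = which(v[, 2] < min(v[, 2]) + tolb),
                    top = which(v[, 2] > max(v[, 2]) - tolb)),
    spec = spec, h = NA_real_, levels_z = sort(unique(v[, 3])),
    band = c(NA_real_, NA_real_), central = c(NA_real_, NA_real_),
    smoothed = TRUE
  ), class = "tissue_template")
  tmpl$cells$V0 <- cell_volumes(tmpl)
  if (any(tmpl$cells$V0 <= 0)) {
    stop("imported template has a non-closed or inward-oriented cell surface")
  }
  tmpl
}

#' Export a stress field as legacy ASCII VTK
#'
#' Writes the unique wall elements at displaced coordinates with per-element
#' `cauchy_trace` (MPa), `wall_type` and `cell_label` arrays — the layout
#' used for tissue stress heatmaps.
#'
#' @param model A [fem_model()].
#' @param u n x 3 displacement matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_field <- function(model, u, path) {
  v <- model$X0 + u
  tr <- model$tri
  sf <- stress_field(model, u)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cellstretch stress field", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(format(v, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(tr), 4L * nrow(tr)), con)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(tr)), con)
  writeLines(as.character(rep(5L, nrow(tr))), con)
  writeLines(c(sprintf("CELL_DATA %d", nrow(tr)),
               "SCALARS cauchy_trace double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(sf$cauchy_trace, scientific = FALSE, trim = TRUE), con)
  writeLines(c("SCALARS wall_type int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(model$template$wall_type)), con)
  writeLines(c("SCALARS cell_label int 1", "LOOKUP_TABLE default"), con)
  lab <- model$template$cell_label
  lab[is.na(lab)] <- 0L
  writeLines(as.character(lab), con)
  invisible(path)
}

#' Export a template surface as ASCII PLY
#'
#' Unique wall triangles only (no per-cell duplication); a lightweight
#' format for generic mesh viewers.
#'
#' @param template A `tissue_template`.
#' @param path Output file path (`.ply`).
#' @return `path`, invisibly.
#' @export
write_ply <- function(template, path) {
  v <- template$vertices
  tr <- template$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, scientific = FALSE, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, tr - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a force-displacement or stress-strain curve as CSV
#'
#' @param curve The curve data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a force-displacement curve from CSV
#'
#' Expects columns `displacement` (um) and `force` (uN) — the shape
#' produced by a microextensometer logger — or a previously written
#' stress-strain curve with `strain`/`stress` columns.
#'
#' @param path CSV path.
#' @param width,thickness,length0 Optional sample dimensions attached as
#'   metadata for [to_stress_strain()].
#' @return A `force_displacement_curve` or `stress_strain_curve`.
#' @export
read_curve_csv <- function(path, width = NULL, thickness = NULL,
                           length0 = NULL) {
  d <- utils::read.csv(path)
  if (all(c("displacement", "force") %in% names(d))) {
    class(d) <- c("force_displacement_curve", "data.frame")
  } else if (all(c("strain", "stress") %in% names(d))) {
    class(d) <- c("stress_strain_curve", "data.frame")
  } else {
    stop("CSV must have displacement/force or strain/stress columns")
  }
  if (!is.null(width)) attr(d, "width") <- width
  if (!is.null(thickness)) attr(d, "thickness") <- thickness
  if (!is.null(length0)) attr(d, "length0") <- length0
  d
}
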