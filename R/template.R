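#' Default wall thickness (um)
#'
#' Uniform cell-wall thickness used when a [template_spec()] does not set
#' one. The value is calibrated with [calibrate_wall_thickness()] so that
#' pressurizing the staggered 5:1 template to 0.5 MPa with isotropic
#' 100 MPa walls expands the enclosed cell volume by approximately
#' 15 percent (see the package vignette).
#' @export
cs_default_wall_thickness <- function() 1.71

#' Specification of an idealized cell template
#'
#' Parameters of the synthetic tissue generator: a rectangular monolayer of
#' rounded-cuboid cells emulating an onion epidermal peel. Cells are
#' `cell_width` um wide (transverse, y) and `cell_width * aspect_ratio` um
#' long (longitudinal, x), extruded to `anticlinal_depth` um (z) in
#' `extrusion_segments` rings of `segment_length` um. Adjacent cells share a
#' single common wall only within a central band of the anticlinal depth
#' (`connection_band_fraction` of the depth); outside the band they have
#' separate, coincident walls.
#'
#' @param cell_width Cell width in um (default 20).
#' @param aspect_ratio Cell length / width, >= 1 (typical values 1, 2, 5,
#'   10, 20).
#' @param staggered Offset alternate cell files by half a cell length
#'   (brick-like onion pattern)?
#' @param template_extent Numeric length 2, template width and height in um.
#'   Defaults to 300 x 300 um, or 600 x 600 um for aspect ratio >= 20.
#' @param vertex_spacing Target spacing of generated vertices in um
#'   (default 2). Cell dimensions and extents must be multiples of it.
#' @param extrusion_segments Number of extrusion segments (default 5).
#' @param segment_length Segment length in um (default 4);
#'   `extrusion_segments * segment_length` must equal `anticlinal_depth`.
#' @param anticlinal_depth Depth of the anticlinal walls in um (default 20).
#' @param connection_band_fraction Fraction of the depth over which adjacent
#'   cells share a wall (default 1/3).
#' @param wall_thickness Uniform wall thickness in um; default
#'   [cs_default_wall_thickness()].
#' @param smoothing_iterations Laplacian smoothing iterations applied by
#'   [smooth_template()] (default 10).
#' @param rng_seed Integer seed recorded with the spec (template generation
#'   itself is deterministic).
#' @return Object of class `template_spec`.
#' @examples
#' template_spec(aspect_ratio = 5, staggered = TRUE)
#' @export
template_spec <- function(cell_width = 20, aspect_ratio = 5, staggered = TRUE,
                          template_extent = NULL, vertex_spacing = 2,
                          extrusion_segments = 5, segment_length = 4,
                          anticlinal_depth = extrusion_segments * segment_length,
                          connection_band_fraction = 1 / 3,
                          wall_thickness = cs_default_wall_thickness(),
                          smoothing_iterations = 10, rng_seed = 1L) {
  if (is.null(template_extent)) {
    template_extent <- if (aspect_ratio >= 20) c(600, 600) else c(300, 300)
  }
  stopifnot(length(template_extent) == 2L, all(template_extent > 0),
            cell_width > 0, vertex_spacing > 0)
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (vertex_spacing >= cell_width) {
    stop("vertex_spacing must be smaller than cell_width")
  }
  if (abs(extrusion_segments * segment_length - anticlinal_depth) > 1e-9) {
    stop("extrusion_segments * segment_length must equal anticlinal_depth")
  }
  if (connection_band_fraction <= 0 || connection_band_fraction >= 1) {
    stop("connection_band_fraction must be in (0, 1)")
  }
  if (wall_thickness <= 0) stop("wall_thickness must be positive")
  if (any(template_extent < cell_width)) {
    stop("template_extent is smaller than one cell")
  }
  h <- vertex_spacing
  divisible <- function(a) abs(a / h - round(a / h)) < 1e-9
  if (!divisible(cell_width) || !any(divisible(template_extent))) {
    # be strict: everything meshes on an h-grid
  }
  if (!divisible(cell_width)) {
    stop("cell_width must be a multiple of vertex_spacing")
  }
  # extents are snapped to the vertex lattice
  template_extent <- round(template_extent / h) * h
  if (!divisible(cell_width * aspect_ratio)) {
    stop("cell length (cell_width * aspect_ratio) must be a multiple of vertex_spacing")
  }
  structure(list(
    cell_width = cell_width, aspect_ratio = aspect_ratio,
    staggered = isTRUE(staggered), template_extent = template_extent,
    vertex_spacing = vertex_spacing, extrusion_segments = extrusion_segments,
    segment_length = segment_length, anticlinal_depth = anticlinal_depth,
    connection_band_fraction = connection_band_fraction,
    wall_thickness = wall_thickness,
    smoothing_iterations = smoothing_iterations,
    rng_seed = as.integer(rng_seed)
  ), class = "template_spec")
}

#' @export
print.template_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "Template spec: %g x %g um cells (%s), extent %g x %g um,\n",
    "  vertex spacing %g um, depth %g um (%d x %g um segments),\n",
    "  connection band %.3g of depth, wall thickness %g um\n"),
    x$cell_width * x$aspect_ratio, x$cell_width,
    if (x$staggered) "staggered" else "non-staggered",
    x$template_extent[1], x$template_extent[2], x$vertex_spacing,
    x$anticlinal_depth, x$extrusion_segments, x$segment_length,
    x$connection_band_fraction, x$wall_thickness))
  invisible(x)
}

#' Generate the 2D cell grid of a template
#'
#' Tiles the template extent with `cell_width x (cell_width * aspect_ratio)`
#' rectangular cells on the vertex-spacing lattice, optionally staggering
#' alternate cell files by half a cell length, and truncating cells at the
#' template borders. The stagger offset is snapped to the vertex lattice.
#'
#' @param spec A [template_spec()].
#' @return Object of class `cell_grid` with a per-lattice-square cell label
#'   matrix and a table of cell rectangles.
#' @examples
#' g <- make_cell_grid(template_spec(aspect_ratio = 1, staggered = FALSE))
#' nrow(g$cells)  # 225 square cells on a 300 x 300 um extent
#' @export
make_cell_grid <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  h <- spec$vertex_spacing
  nxs <- as.integer(round(spec$template_extent[1] / h))
  nys <- as.integer(round(spec$template_extent[2] / h))
  Lh <- as.integer(round(spec$cell_width * spec$aspect_ratio / h))
  wh <- as.integer(round(spec$cell_width / h))
  offh <- if (spec$staggered) as.integer(round(Lh / 2)) else 0L

  # border-straddling cells are truncated to the extent; truncated slivers
  # narrower than two lattice units are merged into their neighbor so no
  # degenerate cells arise
  min_units <- 2L
  iy <- 0:(nys - 1L)
  file_of_iy <- iy %/% wh
  if (nys %% wh > 0L && nys %% wh < min_units) {
    file_of_iy[file_of_iy == max(file_of_iy)] <- max(file_of_iy) - 1L
  }
  off_of_iy <- ifelse(file_of_iy %% 2L == 1L, offh, 0L)
  ix <- 0:(nxs - 1L)
  colmat <- outer(ix, off_of_iy, function(a, b) (a + b) %/% Lh)
  # merge x slivers at either border (per file, since offsets differ)
  for (j in seq_len(nys)) {
    cm <- colmat[, j]
    lead <- sum(cm == cm[1])
    if (lead > 0L && lead < min_units && length(unique(cm)) > 1L) {
      cm[cm == cm[1]] <- cm[lead + 1L]
    }
    tail_n <- sum(cm == cm[nxs])
    if (tail_n > 0L && tail_n < min_units && length(unique(cm)) > 1L) {
      cm[cm == cm[nxs]] <- cm[nxs - tail_n]
    }
    colmat[, j] <- cm
  }
  filemat <- matrix(rep(file_of_iy, each = nxs), nxs, nys)
  key <- filemat * (max(colmat) + 2L) + colmat
  lab <- matrix(match(key, sort(unique(as.vector(key)))), nxs, nys)

  ids <- sort(unique(as.vector(lab)))
  axv <- bxv <- ayv <- byv <- integer(length(ids))
  for (k in seq_along(ids)) {
    w <- which(lab == ids[k], arr.ind = TRUE)
    axv[k] <- min(w[, 1]) - 1L; bxv[k] <- max(w[, 1])
    ayv[k] <- min(w[, 2]) - 1L; byv[k] <- max(w[, 2])
  }
  cells <- data.frame(
    id = ids,
    x0 = axv * h, x1 = bxv * h, y0 = ayv * h, y1 = byv * h,
    ax = axv, bx = bxv, ay = ayv, by = byv,
    clipped = (bxv - axv) < Lh | (byv - ayv) < wh
  )
  structure(list(spec = spec, h = h, nxs = nxs, nys = nys,
                 label = lab, cells = cells,
                 stagger_offset = offh * h),
            class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("2D cell grid: %d cells (%d truncated at borders) on %g x %g um\n",
              nrow(x$cells), sum(x$cells$clipped),
              x$nxs * x$h, x$nys * x$h))
  invisible(x)
}

# encode/decode lattice node codes: (ix, iy, lev) with ix in 0..nxs,
# iy in 0..nys, lev in 1..nz
.node_code <- function(ix, iy, lev, nxs, nys) {
  ((lev - 1) * (nys + 1) + iy) * (nxs + 1) + ix + 1
}

#' Extrude a 2D cell grid into a 3D tissue template
#'
#' Builds, for every cell, a closed triangulated surface: top and bottom
#' periclinal faces, and anticlinal walls extruded through the segment
#' rings. Adjacent cells share a single common wall (welded nodes, one set
#' of triangles) only within the central connection band of the depth; the
#' remaining portions of facing walls are coincident but topologically
#' separate, so cells can detach there. Two extra ring lines are inserted
#' at the exact band edges so the band height equals
#' `connection_band_fraction * anticlinal_depth`.
#'
#' @param grid A [make_cell_grid()] result.
#' @param spec Template spec; defaults to the one stored in `grid`.
#' @return Object of class `tissue_template`. Components include `vertices`
#'   (reference coordinates, um), `triangles` (unique wall elements),
#'   `wall_type` (outer-periclinal / inner-periclinal / anticlinal /
#'   shared-band), `thickness` (per triangle, um), `faces`/`face_cell`/
#'   `cellptr` (per-cell closed oriented face sets for enclosed volumes),
#'   `cells` (with reference volumes `V0`), and `boundary` node sets.
#' @export
extrude_template <- function(grid, spec = grid$spec) {
  stopifnot(inherits(grid, "cell_grid"))
  h <- grid$h; nxs <- grid$nxs; nys <- grid$nys
  depth <- spec$anticlinal_depth
  zb <- seq(0, depth, by = spec$segment_length)
  f <- spec$connection_band_fraction
  z_lo <- depth * (1 - f) / 2
  z_hi <- depth * (1 + f) / 2
  levels_z <- sort(unique(round(c(zb, z_lo, z_hi), 9)))
  nz <- length(levels_z)
  band_lev <- which(levels_z >= z_lo - 1e-9 & levels_z <= z_hi + 1e-9)
  ncode <- nz * (nxs + 1) * (nys + 1)
  BIG <- ncode + 1

  lab <- grid$label
  cells <- grid$cells
  nc <- nrow(cells)

  face_list <- vector("list", nc)
  type_list <- vector("list", nc)

  lev_of_code <- function(code) (code - 1) %/% ((nxs + 1) * (nys + 1)) + 1

  for (k in seq_len(nc)) {
    ax <- cells$ax[k]; bx <- cells$bx[k]; ay <- cells$ay[k]; by <- cells$by[k]
    sq <- expand.grid(ix = ax:(bx - 1L), iy = ay:(by - 1L))
    par <- (sq$ix + sq$iy) %% 2L
    code <- function(ix, iy, lev) .node_code(ix, iy, lev, nxs, nys)

    # top surface (outward +z), lev = nz
    ll <- code(sq$ix, sq$iy, nz); lr <- code(sq$ix + 1L, sq$iy, nz)
    ur <- code(sq$ix + 1L, sq$iy + 1L, nz); ul <- code(sq$ix, sq$iy + 1L, nz)
    topf <- rbind(
      cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, lr, ur),
            ifelse(par == 0, ur, ul)),
      cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, ur, ul),
            ifelse(par == 0, ul, ll)))
    # bottom surface (outward -z), lev = 1: reverse orientation
    ll <- code(sq$ix, sq$iy, 1L); lr <- code(sq$ix + 1L, sq$iy, 1L)
    ur <- code(sq$ix + 1L, sq$iy + 1L, 1L); ul <- code(sq$ix, sq$iy + 1L, 1L)
    botf <- rbind(
      cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, ur, ul),
            ifelse(par == 0, lr, ur)),
      cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, ul, ll),
            ifelse(par == 0, ur, ul)))

    # wall edges: (pmin, pmax, flip, interior)
    edges <- NULL
    if (bx > ax) {
      exs <- ax:(bx - 1L)
      south <- cbind(exs, ay, exs + 1L, ay, 0L,
                     ifelse(ay > 0L, lab[exs + 1L, ay], 0L))
      north <- cbind(exs, by, exs + 1L, by, 1L,
                     ifelse(by < nys, lab[exs + 1L, by + 1L], 0L))
      edges <- rbind(edges, south, north)
    }
    if (by > ay) {
      eys <- ay:(by - 1L)
      west <- cbind(ax, eys, ax, eys + 1L, 1L,
                    ifelse(ax > 0L, lab[ax, eys + 1L], 0L))
      east <- cbind(bx, eys, bx, eys + 1L, 0L,
                    ifelse(bx < nxs, lab[bx + 1L, eys + 1L], 0L))
      edges <- rbind(edges, west, east)
    }
    interior <- edges[, 6] != 0L & edges[, 6] != cells$id[k]

    wallf <- NULL; walltype <- NULL
    for (j in seq_len(nz - 1L)) {
      A <- code(edges[, 1], edges[, 2], j)
      B <- code(edges[, 3], edges[, 4], j)
      C <- code(edges[, 3], edges[, 4], j + 1L)
      D <- code(edges[, 1], edges[, 2], j + 1L)
      parw <- (edges[, 1] + edges[, 2] + edges[, 3] + edges[, 4] + j) %% 2L
      t1 <- cbind(ifelse(parw == 0, A, B), ifelse(parw == 0, B, C),
                  ifelse(parw == 0, C, D))
      t2 <- cbind(ifelse(parw == 0, A, B), ifelse(parw == 0, C, D),
                  ifelse(parw == 0, D, A))
      flip <- edges[, 5] == 1L
      t1f <- t1; t1f[flip, 2:3] <- t1[flip, 3:2]
      t2f <- t2; t2f[flip, 2:3] <- t2[flip, 3:2]
      in_band <- levels_z[j] >= z_lo - 1e-9 && levels_z[j + 1L] <= z_hi + 1e-9
      ty <- ifelse(interior & in_band, "shared-band", "anticlinal")
      wallf <- rbind(wallf, t1f, t2f)
      walltype <- c(walltype, ty, ty)
    }

    fk <- rbind(topf, botf, wallf)
    tk <- c(rep("outer-periclinal", nrow(topf)),
            rep("inner-periclinal", nrow(botf)), walltype)
    # scope node codes: global for band levels, cell-local otherwise
    lev <- lev_of_code(fk)
    scoped <- ifelse(matrix(lev %in% band_lev, nrow(fk), 3), fk,
                     cells$id[k] * BIG + fk)
    face_list[[k]] <- scoped
    type_list[[k]] <- tk
  }

  faces_all <- do.call(rbind, face_list)
  type_all <- unlist(type_list)
  face_cell <- rep(cells$id, vapply(face_list, nrow, 1L))

  keys <- sort(unique(as.vector(faces_all)))
  Fm <- matrix(match(faces_all, keys), nrow(faces_all), 3)

  cid <- keys %/% BIG
  code <- keys - cid * BIG
  lev <- lev_of_code(code)
  rem <- code - 1 - (lev - 1) * (nxs + 1) * (nys + 1)
  iy <- rem %/% (nxs + 1)
  ix <- rem %% (nxs + 1)
  vertices <- cbind(x = ix * h, y = iy * h, z = levels_z[lev])

  # unique elastic elements: shared-band faces are generated by both
  # adjacent cells and must appear exactly twice; all others exactly once
  srt <- t(apply(Fm, 1, sort))
  K <- nrow(vertices) + 1
  key3 <- (srt[, 1] * K + srt[, 2]) * K + srt[, 3]
  first <- !duplicated(key3)
  counts <- table(key3)
  cnt <- as.integer(counts[as.character(key3[first])])
  ty_first <- type_all[first]
  if (any(cnt > 2L) || any((cnt == 2L) != (ty_first == "shared-band"))) {
    stop("non-manifold template topology: wall faces do not pair up as expected")
  }
  triangles <- Fm[first, , drop = FALSE]
  wall_type <- factor(ty_first, levels = c("outer-periclinal",
                                           "inner-periclinal",
                                           "anticlinal", "shared-band"))
  owner <- face_cell[first]
  owner[wall_type == "shared-band"] <- NA_integer_

  ord <- order(face_cell)
  faces <- Fm[ord, , drop = FALSE]
  fc <- face_cell[ord]
  cellptr <- c(0L, cumsum(as.integer(table(factor(fc, levels = cells$id)))))

  ext <- c(nxs * h, nys * h)
  tolb <- h * 1e-6
  boundary <- list(
    left = which(vertices[, 1] < tolb),
    right = which(vertices[, 1] > ext[1] - tolb),
    bottom = which(vertices[, 2] < tolb),
    top = which(vertices[, 2] > ext[2] - tolb)
  )

  tmpl <- structure(list(
    vertices = vertices, triangles = triangles, wall_type = wall_type,
    cell_label = owner, thickness = rep(spec$wall_thickness, nrow(triangles)),
    faces = faces, face_cell = fc, cellptr = cellptr, cells = cells,
    boundary = boundary, spec = spec, h = h, levels_z = levels_z,
    band = c(z_lo, z_hi),
    central = c(depth / 2 - spec$segment_length / 2,
                depth / 2 + spec$segment_length / 2),
    smoothed = FALSE
  ), class = "tissue_template")
  tmpl$cells$V0 <- cell_volumes(tmpl)
  if (any(tmpl$cells$V0 <= 0)) {
    stop("template topology error: non-positive enclosed cell volume")
  }
  tmpl
}

#' Enclosed cell volumes of a template
#'
#' Divergence-theorem volume of every cell's closed oriented surface,
#' optionally at displaced coordinates.
#'
#' @param template A `tissue_template`.
#' @param coords Optional n x 3 coordinate matrix (defaults to the reference
#'   vertices).
#' @return Numeric vector of volumes (um^3), one per cell.
#' @export
cell_volumes <- function(template, coords = template$vertices) {
  .cs_cellvol(coords, template$faces, template$cellptr)
}

#' Total wall area of a template
#'
#' Sum of the reference areas of the unique wall triangles (um^2).
#' @param template A `tissue_template`.
#' @export
wall_area <- function(template) {
  v <- template$vertices
  tr <- template$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @export
print.tissue_template <- function(x, ...) {
  cat(sprintf(paste0(
    "Tissue template: %d cells, %d vertices, %d wall triangles%s\n",
    "  extent %g x %g um, depth %g um, total cell volume %.4g um^3\n"),
    nrow(x$cells), nrow(x$vertices), nrow(x$triangles),
    if (x$smoothed) " (smoothed)" else "",
    x$spec$template_extent[1], x$spec$template_extent[2],
    x$spec$anticlinal_depth, sum(x$cells$V0)))
  tab <- table(x$wall_type)
  cat("  wall triangles by type: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.tissue_template <- function(x, ...) {
  v <- x$vertices
  top <- x$wall_type == "outer-periclinal"
  tr <- x$triangles[top, , drop = FALSE]
  plot(NA, xlim = range(v[, 1]), ylim = range(v[, 2]), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = "Template (outer periclinal surface)", ...)
  for (j in 1:3) {
    a <- tr[, j]; b <- tr[, if (j == 3) 1 else j + 1]
    graphics::segments(v[a, 1], v[a, 2], v[b, 1], v[b, 2], col = "grey60")
  }
  invisible(x)
}

# Deterministic profile rounding: cells become rounded cuboids. Outside
# the connection band the anticlinal walls curve inward along an elliptic
# arc toward the (shrunken) periclinal faces, so adjacent cells separate
# everywhere except the welded band, as in the idealized templates the
# mesh emulates. Nodes on the template borders and in the band keep their
# positions; truncated cells only round their interior sides.
.round_cell_profiles <- function(template, corner_radius) {
  v <- template$vertices
  if (corner_radius <= 0) return(v)
  depth <- template$spec$anticlinal_depth
  z_lo <- template$band[1]; z_hi <- template$band[2]
  ext <- template$spec$template_extent
  tolb <- 1e-6

  # inward offset as a function of depth position
  d_of_z <- function(z) {
    d <- numeric(length(z))
    up <- z > z_hi
    if (any(up)) {
      f <- pmin((z[up] - z_hi) / (depth - z_hi), 1)
      d[up] <- corner_radius * (1 - sqrt(pmax(0, 1 - f^2)))
    }
    dn <- z < z_lo
    if (any(dn)) {
      f <- pmin((z_lo - z[dn]) / z_lo, 1)
      d[dn] <- corner_radius * (1 - sqrt(pmax(0, 1 - f^2)))
    }
    d
  }

  # owning cell per node (band nodes are shared but have zero offset)
  node_cell <- integer(nrow(v))
  f <- template$faces
  fc <- template$face_cell
  node_cell[as.vector(f)] <- rep(fc, 3)

  d <- d_of_z(v[, 3])
  move <- d > tolb & node_cell > 0
  if (!any(move)) return(v)
  cells <- template$cells
  row_of <- match(node_cell[move], cells$id)
  # per-cell radius cap: 0.15 of the smaller cell dimension, so the
  # rounding keeps every cell's volume change within the smoothing bound
  mind <- pmin(cells$x1 - cells$x0, cells$y1 - cells$y0)[row_of]
  dcap <- pmin(d[move], 0.15 * mind)
  for (axis in 1:2) {
    lo <- if (axis == 1) cells$x0[row_of] else cells$y0[row_of]
    hi <- if (axis == 1) cells$x1[row_of] else cells$y1[row_of]
    dlo <- dcap * (lo > tolb)
    dhi <- dcap * (hi < ext[axis] - tolb)
    x <- v[move, axis]
    frac <- pmin(pmax((x - lo) / pmax(hi - lo, tolb), 0), 1)
    v[move, axis] <- x + dlo * (1 - frac) - dhi * frac
  }
  v
}

#' Smooth a tissue template
#'
#' Two-stage rounding of the cell sides and ends, emulating the rounded
#' cuboid cell shapes of the idealized templates: first a deterministic
#' profile rounding (anticlinal walls curve inward outside the connection
#' band with an elliptic corner profile of radius `corner_radius`, so
#' adjacent cells separate except at the welded band), then
#' shrink-compensated uniform-weight Laplacian sweeps that relax the
#' remaining corners. Vertices of the central extrusion segment are pinned
#' (the welded connection-band topology is unchanged by construction), as
#' are vertices on the template borders, so clamped template ends stay
#' planar.
#'
#' @param template An extruded `tissue_template`.
#' @param iterations Number of smoothing sweeps; defaults to the spec's
#'   `smoothing_iterations`. `0` returns the template unchanged.
#' @param lambda Relaxation factor of the forward pass in (0, 1]
#'   (default 0.5).
#' @param mu Relaxation factor of the shrink-compensating backward pass
#'   (default -0.53, slightly exceeding `lambda` in magnitude as in Taubin
#'   smoothing, which rounds corners while approximately preserving cell
#'   volumes). Set `mu = 0` for plain shrinking Laplacian smoothing.
#' @param corner_radius Radius (um) of the elliptic profile rounding of
#'   cell sides and ends (default 5, about a quarter of the default cell
#'   width); `0` disables the profile stage.
#' @return The smoothed `tissue_template` (reference volumes `V0` updated).
#' @export
smooth_template <- function(template,
                            iterations = template$spec$smoothing_iterations,
                            lambda = 0.5, mu = -0.53,
                            corner_radius = 5) {
  stopifnot(inherits(template, "tissue_template"))
  if (iterations == 0) return(template)
  v <- .round_cell_profiles(template, corner_radius)
  n <- nrow(v)
  tr <- template$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  ed <- unique(ed)
  ord <- order(ed[, 1], ed[, 2])
  ed <- ed[ord, , drop = FALSE]
  nbrptr <- c(0L, cumsum(tabulate(ed[, 1], nbins = n)))
  nbr <- ed[, 2]

  tolb <- 1e-6
  border <- v[, 1] < tolb | v[, 1] > template$spec$template_extent[1] - tolb |
    v[, 2] < tolb | v[, 2] > template$spec$template_extent[2] - tolb
  central <- v[, 3] >= template$central[1] - 1e-9 &
    v[, 3] <= template$central[2] + 1e-9 &
    v[, 3] > 1e-9 & v[, 3] < template$spec$anticlinal_depth - 1e-9
  free_vtx <- !(border | central)

  for (it in seq_len(iterations)) {
    v <- .cs_smooth_step(v, nbr, nbrptr, free_vtx, lambda)
    if (mu != 0) v <- .cs_smooth_step(v, nbr, nbrptr, free_vtx, mu)
  }

  out <- template
  out$vertices <- v
  V <- cell_volumes(out)
  if (any(V <= 0)) stop("smoothing inverted a cell surface (geometry error)")
  rel <- abs(V / template$cells$V0 - 1)
  if (any(rel > 0.2)) {
    stop(sprintf("smoothing changed a cell volume by %.1f%% (> 20%% limit)",
                 100 * max(rel)))
  }
  e1 <- v[tr[, 2], ] - v[tr[, 1], ]
  e2 <- v[tr[, 3], ] - v[tr[, 1], ]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  if (any(sqrt(cx^2 + cy^2 + cz^2) / 2 < 1e-6)) {
    stop("smoothing produced a degenerate triangle (geometry error)")
  }
  out$cells$V0 <- V
  out$smoothed <- TRUE
  out
}

#' Flat rectangular membrane sheet (no cells)
#'
#' A single flat triangulated sheet in the z = 0 plane, useful for uniaxial
#' patch tests: with isotropic Biot-SVK walls at `nu = 0` the stretched
#' sheet has an exactly linear nominal-stress response of slope E.
#' The sheet has no cells, so it cannot be pressurized.
#'
#' @param width,height Sheet extent (um) along x and y.
#' @param spacing Lattice spacing (um).
#' @param thickness Membrane thickness (um).
#' @return A `tissue_template` with zero cells whose `anticlinal_depth` is
#'   set to the membrane thickness, so [to_stress_strain()] on a stretch
#'   normalizes by the true cross-section `width * thickness`.
#' @export
flat_sheet_template <- function(width = 40, height = 20, spacing = 4,
                                thickness = 1) {
  nx <- as.integer(round(width / spacing))
  ny <- as.integer(round(height / spacing))
  stopifnot(nx >= 1, ny >= 1, thickness > 0)
  gx <- rep(0:nx, ny + 1L) * spacing
  gy <- rep(0:ny, each = nx + 1L) * spacing
  vertices <- cbind(x = gx, y = gy, z = 0)
  id <- function(ix, iy) iy * (nx + 1L) + ix + 1L
  sq <- expand.grid(ix = 0:(nx - 1L), iy = 0:(ny - 1L))
  par <- (sq$ix + sq$iy) %% 2L
  ll <- id(sq$ix, sq$iy); lr <- id(sq$ix + 1L, sq$iy)
  ur <- id(sq$ix + 1L, sq$iy + 1L); ul <- id(sq$ix, sq$iy + 1L)
  triangles <- rbind(
    cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, lr, ur),
          ifelse(par == 0, ur, ul)),
    cbind(ifelse(par == 0, ll, lr), ifelse(par == 0, ur, ul),
          ifelse(par == 0, ul, ll)))
  tolb <- 1e-6
  spec <- list(cell_width = NA_real_, aspect_ratio = NA_real_,
               staggered = FALSE, template_extent = c(width, height),
               vertex_spacing = spacing, extrusion_segments = 0L,
               segment_length = 0, anticlinal_depth = thickness,
               connection_band_fraction = NA_real_,
               wall_thickness = thickness, smoothing_iterations = 0L,
               rng_seed = 0L)
  class(spec) <- "template_spec"
  structure(list(
    vertices = vertices, triangles = triangles,
    wall_type = factor(rep("outer-periclinal", nrow(triangles)),
                       levels = c("outer-periclinal", "inner-periclinal",
                                  "anticlinal", "shared-band")),
    cell_label = rep(NA_integer_, nrow(triangles)),
    thickness = rep(thickness, nrow(triangles)),
    faces = matrix(integer(), 0, 3), face_cell = integer(),
    cellptr = 0L,
    cells = data.frame(id = integer(), x0 = numeric(), x1 = numeric(),
                       y0 = numeric(), y1 = numeric(), ax = integer(),
                       bx = integer(), ay = integer(), by = integer(),
                       clipped = logical(), V0 = numeric()),
    boundary = list(left = which(vertices[, 1] < tolb),
                    right = which(vertices[, 1] > width - tolb),
                    bottom = which(vertices[, 2] < tolb),
                    top = which(vertices[, 2] > height - tolb)),
    spec = spec, h = spacing, levels_z = 0, band = c(NA_real_, NA_real_),
    central = c(NA_real_, NA_real_), smoothed = FALSE
  ), class = "tissue_template")
}

#' Build an idealized tissue template in one call
#'
#' Convenience wrapper: [make_cell_grid()] + [extrude_template()] +
#' [smooth_template()].
#'
#' @param spec A [template_spec()], or arguments passed to it via `...`.
#' @param smooth Apply smoothing (default TRUE)?
#' @param ... Passed to [template_spec()] when `spec` is missing.
#' @return A `tissue_template`.
#' @examples
#' \donttest{
#' tmpl <- build_template(template_spec(aspect_ratio = 1, staggered = FALSE,
#'                                      template_extent = c(60, 60),
#'                                      vertex_spacing = 4))
#' }
#' @export
build_template <- function(spec = template_spec(...), smooth = TRUE, ...) {
  tmpl <- extrude_template(make_cell_grid(spec))
  if (smooth) tmpl <- smooth_template(tmpl)
  tmpl
}
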