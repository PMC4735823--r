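#' A single ECM fibre segment
#'
#' A fibre is a straight line 2 um thick (one pixel) and, when generated,
#' 30-40 um long, described by continuous endpoints in um in the lattice
#' frame.
#'
#' @param start,end numeric length-2 points (x, y) in um.
#' @param thickness fibre thickness in um (one pixel).
#' @return An object of class `fibre_segment`.
#' @examples
#' fibre_segment(c(0, 0), c(30, 0))
#' @export
fibre_segment <- function(start, end, thickness = 2) {
  stopifnot(length(start) == 2, length(end) == 2,
            is.finite(start), is.finite(end))
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 thickness = thickness,
                 length = sqrt(sum((end - start)^2))),
            class = "fibre_segment")
}

# Liang-Barsky clip of a segment to [0, xmax] x [0, ymax]; NULL if outside.
clip_segment_box <- function(x0, y0, x1, y1, xmax, ymax) {
  dx <- x1 - x0; dy <- y1 - y0
  p <- c(-dx, dx, -dy, dy)
  q <- c(x0, xmax - x0, y0, ymax - y0)
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(NULL)
    } else {
      t <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, t) else t1 <- min(t1, t)
    }
  }
  if (t0 > t1) return(NULL)
  c(x0 + t0 * dx, y0 + t0 * dy, x0 + t1 * dx, y0 + t1 * dy)
}

# 8-connected Bresenham chain between integer pixels, endpoints included.
bresenham_pixels <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); sx <- if (x0 < x1) 1L else -1L
  dy <- -abs(y1 - y0); sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  out <- matrix(0L, n, 2)
  x <- x0; y <- y0
  for (k in seq_len(n)) {
    out[k, ] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}

#' Rasterize a fibre segment onto the pixel lattice
#'
#' Maps the (clipped) continuous segment to a one-pixel-thick 8-connected
#' Bresenham chain. The pixel containing a point x um is `floor(x / dx)`
#' (0-based), clamped to the lattice; the returned indices are 1-based row
#' and column indices into the lattice matrix.
#'
#' @param seg a [fibre_segment()].
#' @param dx pixel size in um.
#' @param lattice_px lattice side length in pixels.
#' @return Integer matrix with columns `i`, `j` (1-based pixel indices).
#' @examples
#' nrow(rasterize_segment(fibre_segment(c(0, 0), c(30, 0))))  # 16 pixels
#' @export
rasterize_segment <- function(seg, dx = 2, lattice_px = 500) {
  stopifnot(inherits(seg, "fibre_segment"))
  to_px <- function(v) pmin(pmax(floor(v / dx), 0), lattice_px - 1)
  p0 <- to_px(seg$start); p1 <- to_px(seg$end)
  px <- bresenham_pixels(as.integer(p0[1]), as.integer(p0[2]),
                         as.integer(p1[1]), as.integer(p1[2]))
  px <- px + 1L
  colnames(px) <- c("i", "j")
  px
}

#' Generate a fibrillar ECM mesh
#'
#' Draws `xi` straight fibres of length uniform on 30-40 um. In `random`
#' mode the fibre centre is uniform over the lattice and the angle uniform
#' on [0, pi); in `aligned` mode every fibre is horizontal (angle 0),
#' emulating a linearized, crosslinked matrix. Fibres extending past the
#' lattice are clipped; overlapping fibres share pixels (the pixel set is
#' deduplicated). Fibre density is controlled purely through `xi`
#' (reference densities 400, 600, 1000 on the 500 x 500 lattice).
#'
#' @param xi number of fibres (non-negative integer).
#' @param mode `"random"` or `"aligned"` fibre orientation.
#' @param seed optional integer seed for reproducible meshes.
#' @param lattice_px lattice side in pixels.
#' @param dx pixel size in um.
#' @return An object of class `fibre_mesh`: list with `segments`
#'   (data.frame of endpoints, angle, length in um), `pixels` (deduplicated
#'   1-based pixel index matrix), `count`, `orientation_mode`, `lattice_px`,
#'   `dx`.
#' @examples
#' mesh <- generate_fibre_mesh(50, "random", seed = 1)
#' nrow(mesh$pixels)
#' @export
generate_fibre_mesh <- function(xi, mode = c("random", "aligned"),
                                seed = NULL, lattice_px = 500, dx = 2) {
  mode <- match.arg(mode)
  if (length(xi) != 1 || !is.finite(xi) || xi < 0 || xi != round(xi)) {
    stop("xi must be a single non-negative integer")
  }
  xi <- as.integer(xi)
  if (!is.null(seed)) set.seed(seed)
  size <- lattice_px * dx

  if (xi == 0) {
    segs <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                       y1 = numeric(0), angle = numeric(0),
                       length = numeric(0))
    pixels <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    return(structure(list(segments = segs, pixels = pixels, count = 0L,
                          orientation_mode = mode, lattice_px = lattice_px,
                          dx = dx),
                     class = "fibre_mesh"))
  }

  cx <- runif(xi, 0, size)
  cy <- runif(xi, 0, size)
  len <- runif(xi, 30, 40)
  ang <- if (mode == "aligned") rep(0, xi) else runif(xi, 0, pi)

  x0 <- cx - len / 2 * cos(ang); y0 <- cy - len / 2 * sin(ang)
  x1 <- cx + len / 2 * cos(ang); y1 <- cy + len / 2 * sin(ang)

  seg_list <- vector("list", xi)
  keep <- logical(xi)
  for (k in seq_len(xi)) {
    cl <- clip_segment_box(x0[k], y0[k], x1[k], y1[k], size, size)
    if (is.null(cl)) next   # cannot happen: the centre lies inside
    keep[k] <- TRUE
    x0[k] <- cl[1]; y0[k] <- cl[2]; x1[k] <- cl[3]; y1[k] <- cl[4]
    seg_list[[k]] <- rasterize_segment(
      fibre_segment(c(cl[1], cl[2]), c(cl[3], cl[4])), dx, lattice_px)
  }
  pixels <- unique(do.call(rbind, seg_list[keep]))
  segs <- data.frame(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                     angle = ang, length = len)[keep, , drop = FALSE]

  structure(list(segments = segs, pixels = pixels, count = xi,
                 orientation_mode = mode, lattice_px = lattice_px, dx = dx),
            class = "fibre_mesh")
}

#' @export
print.fibre_mesh <- function(x, ...) {
  cat(sprintf("fibre_mesh: %d fibres (%s), %d pixels on %dx%d lattice\n",
              x$count, x$orientation_mode, nrow(x$pixels),
              x$lattice_px, x$lattice_px))
  invisible(x)
}

#' Initial tumour cell aggregate on a block grid
#'
#' Places square 10 x 10-pixel (20 um) cells on a block grid whose central
#' block is centred on the lattice centre; a block becomes a cell iff its
#' centre lies within `disk_radius` of the aggregate centre. The default
#' radius of 90 um is the smallest radius (scanning in 1-px steps) that
#' yields exactly 69 cells, the reference aggregate size; its bounding
#' half-width is then exactly 100 um, i.e. a nominal 200-um diameter
#' population.
#'
#' @param disk_radius aggregate disk radius in um.
#' @param cell_side cell side length in um; must be a whole number of
#'   pixels.
#' @param lattice_px lattice side in pixels.
#' @param dx pixel size in um.
#' @param centre_px aggregate centre in continuous pixel coordinates
#'   (defaults to the lattice centre).
#' @return An object of class `aggregate_layout`: `cell_pixel_map` (list of
#'   1-based pixel index matrices per cell id), `n_cells`, `disk_radius`,
#'   `cell_side`, `nominal_radius` (the disk guaranteed to contain every
#'   admitted block along each axis, `disk_radius + cell_side / 2`; 100 um
#'   for the defaults, i.e. the nominal 200-um population diameter), plus
#'   lattice geometry.
#' @examples
#' build_initial_aggregate()$n_cells  # 69
#' @export
build_initial_aggregate <- function(disk_radius = 90, cell_side = 20,
                                    lattice_px = 500, dx = 2,
                                    centre_px = lattice_px / 2) {
  b <- cell_side / dx
  if (b != round(b)) stop("cell_side must be a whole number of pixels")
  b <- as.integer(b)
  r_px <- disk_radius / dx
  if (r_px > lattice_px / 2) stop("aggregate disk does not fit in the lattice")
  if (disk_radius < cell_side / 2) stop("disk smaller than one cell block")

  m_max <- ceiling(r_px / b) + 1
  grid <- expand.grid(m = -m_max:m_max, n = -m_max:m_max)
  cx <- centre_px + grid$m * b
  cy <- centre_px + grid$n * b
  inside <- (cx - centre_px)^2 + (cy - centre_px)^2 <= r_px^2
  grid <- grid[inside, , drop = FALSE]
  # deterministic id order: row-major from bottom-left
  ord <- order(grid$n, grid$m)
  grid <- grid[ord, , drop = FALSE]

  cells <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    # block centred at centre_px + m*b: 0-based pixels centre+m*b-b/2 .. +b/2-1
    i0 <- as.integer(centre_px + grid$m[k] * b - b / 2)
    j0 <- as.integer(centre_px + grid$n[k] * b - b / 2)
    if (i0 < 0 || j0 < 0 || i0 + b > lattice_px || j0 + b > lattice_px) {
      stop("aggregate block extends past the lattice")
    }
    px <- as.matrix(expand.grid(i = (i0 + 1):(i0 + b), j = (j0 + 1):(j0 + b)))
    cells[[k]] <- px
  }
  names(cells) <- seq_along(cells)
  structure(list(cell_pixel_map = cells, n_cells = length(cells),
                 disk_radius = disk_radius, cell_side = cell_side,
                 nominal_radius = disk_radius + cell_side / 2,
                 lattice_px = lattice_px, dx = dx, centre_px = centre_px),
            class = "aggregate_layout")
}

#' @export
print.aggregate_layout <- function(x, ...) {
  cat(sprintf("aggregate_layout: %d cells of %g um side, disk radius %g um\n",
              x$n_cells, x$cell_side, x$disk_radius))
  invisible(x)
}

#' Smallest aggregate disk radius producing a given cell count
#'
#' Scans the disk radius upward in 1-pixel steps and returns the smallest
#' radius (um) whose block-inclusion rule yields exactly `n` cells, or NA
#' if none is found below the lattice half-width.
#'
#' @param n target cell count.
#' @inheritParams build_initial_aggregate
#' @return Radius in um, or NA.
#' @examples
#' aggregate_radius_for_n(69)  # 90
#' @export
aggregate_radius_for_n <- function(n = 69, cell_side = 20, lattice_px = 500,
                                   dx = 2) {
  for (r_px in seq_len(floor(lattice_px / 2) - 1)) {
    lay <- tryCatch(
      build_initial_aggregate(r_px * dx, cell_side, lattice_px, dx),
      error = function(e) NULL)
    if (!is.null(lay) && lay$n_cells == n) return(r_px * dx)
    if (!is.null(lay) && lay$n_cells > n) return(NA_real_)
  }
  NA_real_
}

#' Assemble a simulation lattice from a mesh and an aggregate
#'
#' Rasterizes the fibre mesh, then places the cell aggregate on top: fibre
#' pixels under the initial aggregate are removed (the aggregate core
#' starts fibre-free, and a pixel holds exactly one entity class).
#'
#' @param mesh a [generate_fibre_mesh()] result, or NULL for no fibres.
#' @param layout a [build_initial_aggregate()] result, or NULL for no
#'   cells.
#' @param lattice_px lattice side in pixels (taken from the inputs when
#'   omitted).
#' @param dx pixel size in um.
#' @return A `sim_lattice` object; see [sim_lattice()].
#' @examples
#' lat <- build_lattice(generate_fibre_mesh(100, seed = 1),
#'                      build_initial_aggregate())
#' lat
#' @export
build_lattice <- function(mesh = NULL, layout = NULL, lattice_px = NULL,
                          dx = 2) {
  if (is.null(lattice_px)) {
    lattice_px <- if (!is.null(mesh)) mesh$lattice_px
                  else if (!is.null(layout)) layout$lattice_px
                  else stop("lattice_px required when mesh and layout are NULL")
  }
  sigma <- matrix(0L, lattice_px, lattice_px)
  if (!is.null(mesh) && nrow(mesh$pixels) > 0) sigma[mesh$pixels] <- -1L
  removed <- 0L
  if (!is.null(layout)) {
    for (id in seq_along(layout$cell_pixel_map)) {
      px <- layout$cell_pixel_map[[id]]
      removed <- removed + sum(sigma[px] == -1L)
      if (any(sigma[px] >= 1L)) stop("cell blocks overlap")
      sigma[px] <- as.integer(id)
    }
  }
  sim_lattice(sigma, dx = dx, removed_fibre_px = removed)
}
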