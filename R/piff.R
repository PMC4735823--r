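#' PIFF pixel-layout documents
#'
#' PIFF is the plain-text pixel initialization format used to seed lattice
#' simulations: one record per rectangular pixel run,
#' `<cellID> <TypeName> <x1> <x2> <y1> <y2> <z1> <z2>`, space-separated,
#' 0-based inclusive coordinates, `z1 = z2 = 0` in 2D. Type names are
#' `Cell`, `Fibre` or `Fluid`. This package writes the single-section
#' rectangle-run dialect only (PIFF has drifted across tool versions).
#'
#' @param records data.frame with columns `cell_id`, `type`, `x1`, `x2`,
#'   `y1`, `y2`, `z1`, `z2`.
#' @return An object of class `piff_document`.
#' @examples
#' piff_document(data.frame(cell_id = 1L, type = "Cell", x1 = 0L, x2 = 9L,
#'                          y1 = 0L, y2 = 9L, z1 = 0L, z2 = 0L))
#' @export
piff_document <- function(records) {
  need <- c("cell_id", "type", "x1", "x2", "y1", "y2", "z1", "z2")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  records <- records[, need, drop = FALSE]
  bad <- !records$type %in% c("Cell", "Fibre", "Fluid")
  if (any(bad)) stop("unknown type name(s): ",
                     paste(unique(records$type[bad]), collapse = ", "))
  if (any(records$x1 > records$x2) || any(records$y1 > records$y2)) {
    stop("PIFF runs require x1 <= x2 and y1 <= y2")
  }
  if (any(records$x1 < 0) || any(records$y1 < 0)) {
    stop("PIFF coordinates are 0-based and non-negative")
  }
  if (any(records$z1 != 0) || any(records$z2 != 0)) {
    stop("2D PIFF requires z1 = z2 = 0")
  }
  rownames(records) <- NULL
  structure(list(records = records), class = "piff_document")
}

#' @export
print.piff_document <- function(x, ...) {
  cat(sprintf("piff_document: %d records (%s)\n", nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$records$type)),
                            table(x$records$type)), collapse = ", ")))
  invisible(x)
}

#' Read a PIFF layout file
#'
#' @param path file path.
#' @return A [piff_document()].
#' @seealso [write_piff()], [piff_to_lattice()]
#' @export
read_piff <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  recs <- vector("list", sum(keep))
  z <- 0L
  for (ln in which(keep)) {
    parts <- strsplit(lines[ln], "[[:space:]]+")[[1]]
    if (length(parts) != 8) {
      stop(sprintf("malformed PIFF line %d: expected 8 fields, got %d",
                   ln, length(parts)))
    }
    num <- suppressWarnings(as.integer(parts[c(1, 3:8)]))
    if (anyNA(num)) stop(sprintf("malformed PIFF line %d: non-integer field", ln))
    z <- z + 1L
    recs[[z]] <- data.frame(cell_id = num[1], type = parts[2],
                            x1 = num[2], x2 = num[3], y1 = num[4],
                            y2 = num[5], z1 = num[6], z2 = num[7])
  }
  if (z == 0) {
    return(piff_document(data.frame(cell_id = integer(0), type = character(0),
                                    x1 = integer(0), x2 = integer(0),
                                    y1 = integer(0), y2 = integer(0),
                                    z1 = integer(0), z2 = integer(0))))
  }
  piff_document(do.call(rbind, recs[seq_len(z)]))
}

#' Write a PIFF layout file
#'
#' @param doc a [piff_document()] or a `sim_lattice` (converted with
#'   [lattice_to_piff()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_piff <- function(doc, path) {
  if (inherits(doc, "sim_lattice")) doc <- lattice_to_piff(doc)
  stopifnot(inherits(doc, "piff_document"))
  r <- doc$records
  writeLines(sprintf("%d %s %d %d %d %d %d %d", r$cell_id, r$type,
                     r$x1, r$x2, r$y1, r$y2, r$z1, r$z2), path)
  invisible(path)
}

# horizontal runs of TRUE in a logical vector -> (start, end) 0-based
runs_of <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values]) - 1L
}

#' Convert a lattice to a canonical PIFF document
#'
#' Emits maximal horizontal runs: fibre records first (cell id 0), then
#' cells in ascending id, each ordered by y then x. Fluid is the implied
#' background and is not written, so an empty document reads back as an
#' all-fluid lattice.
#'
#' @param lattice a `sim_lattice`.
#' @return A [piff_document()].
#' @export
lattice_to_piff <- function(lattice) {
  stopifnot(inherits(lattice, "sim_lattice"))
  sigma <- lattice$sigma
  recs <- list()
  z <- 0L
  for (id in c(-1L, seq_len(lattice$n_cells))) {
    type <- if (id == -1L) "Fibre" else "Cell"
    out_id <- if (id == -1L) 0L else id
    cols <- which(apply(sigma == id, 2, any))
    for (j in cols) {
      rr <- runs_of(sigma[, j] == id)
      for (q in seq_len(nrow(rr))) {
        z <- z + 1L
        recs[[z]] <- data.frame(cell_id = out_id, type = type,
                                x1 = rr[q, 1], x2 = rr[q, 2],
                                y1 = j - 1L, y2 = j - 1L, z1 = 0L, z2 = 0L)
      }
    }
  }
  if (z == 0) {
    return(piff_document(data.frame(cell_id = integer(0), type = character(0),
                                    x1 = integer(0), x2 = integer(0),
                                    y1 = integer(0), y2 = integer(0),
                                    z1 = integer(0), z2 = integer(0))))
  }
  piff_document(do.call(rbind, recs))
}

#' Reconstruct a lattice from a PIFF document
#'
#' Pixels not covered by any record are fluid. Overlapping records are
#' resolved last-writer-wins with a warning. `Fibre` records become
#' `sigma = -1` regardless of their cell id; `Fluid` records clear pixels.
#' Cell ids are compacted to contiguous `1..K` preserving order.
#'
#' @param doc a [piff_document()].
#' @param lattice_px lattice side in pixels.
#' @param dx pixel size in um.
#' @return A `sim_lattice`.
#' @export
piff_to_lattice <- function(doc, lattice_px = 500, dx = 2) {
  stopifnot(inherits(doc, "piff_document"))
  sigma <- matrix(0L, lattice_px, lattice_px)
  covered <- matrix(FALSE, lattice_px, lattice_px)
  overlapped <- FALSE
  r <- doc$records
  for (q in seq_len(nrow(r))) {
    if (r$x2[q] >= lattice_px || r$y2[q] >= lattice_px) {
      stop(sprintf("PIFF record %d exceeds the %d-pixel lattice", q, lattice_px))
    }
    ii <- (r$x1[q] + 1L):(r$x2[q] + 1L)
    jj <- (r$y1[q] + 1L):(r$y2[q] + 1L)
    if (any(covered[ii, jj])) overlapped <- TRUE
    val <- switch(r$type[q], Fibre = -1L, Fluid = 0L, Cell = r$cell_id[q])
    sigma[ii, jj] <- val
    covered[ii, jj] <- TRUE
  }
  if (overlapped) warning("overlapping PIFF records: last writer wins")
  ids <- sort(unique(sigma[sigma >= 1L]))
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    sigma[sigma >= 1L] <- match(sigma[sigma >= 1L], ids)
  }
  sim_lattice(sigma, dx = dx)
}
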