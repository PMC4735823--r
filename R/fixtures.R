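#' Deterministic toy fixtures for oracle tests
#'
#' Small hand-constructed inputs with known geometry:
#' \describe{
#'   \item{`two_cells`}{30 x 30 lattice with two 10 x 10 cells sharing a
#'     10-edge boundary; returns the lattice and the shared edge count.}
#'   \item{`round_trip`}{a 2-cell trajectory where each cell walks 5 px
#'     out and 5 px back: `d_total` = 20 um, `d_net` = 0.}
#'   \item{`secretion_unit`}{12 x 12 lattice with one fibre pixel and one
#'     8-adjacent single-pixel cell, plus a zero field.}
#' }
#'
#' @param name fixture name.
#' @return A named list; contents depend on the fixture.
#' @examples
#' make_fixture("two_cells")$shared_edges
#' @export
make_fixture <- function(name) {
  switch(name,
    two_cells = {
      sigma <- matrix(0L, 30, 30)
      sigma[6:15, 11:20] <- 1L
      sigma[16:25, 11:20] <- 2L
      list(lattice = sim_lattice(sigma), shared_edges = 10L,
           outer_edges_per_cell = 30L)
    },
    round_trip = {
      out <- c(0:5, 4:0) * 2           # px -> um with dx = 2
      traj <- rbind(
        data.frame(mcs = 0:10, cell_id = 1L, x_um = 20 + out, y_um = 20),
        data.frame(mcs = 0:10, cell_id = 2L, x_um = 40, y_um = 40 + out))
      list(trajectory = traj, d_total_um = 20, d_net_um = 0)
    },
    secretion_unit = {
      sigma <- matrix(0L, 12, 12)
      sigma[6, 6] <- -1L
      sigma[7, 7] <- 1L   # diagonal (Moore) contact
      list(lattice = sim_lattice(sigma), field = matrix(0, 12, 12),
           fibre_pixel = cbind(6L, 6L), cell_pixel = cbind(7L, 7L))
    },
    stop("unknown fixture: ", name,
         " (valid: two_cells, round_trip, secretion_unit)"))
}
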