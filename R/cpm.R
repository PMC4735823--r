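#' Initialize full simulation state
#'
#' Couples a lattice to energy and MMP parameters and allocates the
#' per-cell bookkeeping: polarity vectors (zero at t = 0), the ring buffer
#' of the last `tau` per-MCS centroid displacements (empty at t = 0), and
#' the MMP field (zero everywhere).
#'
#' @param lattice a `sim_lattice`.
#' @param epar [energy_params()].
#' @param mpar [mmp_params()].
#' @return An object of class `cpm_state`.
#' @examples
#' st <- initialize_state(build_lattice(NULL, build_initial_aggregate()))
#' st
#' @export
initialize_state <- function(lattice, epar = energy_params(),
                             mpar = mmp_params()) {
  stopifnot(inherits(lattice, "sim_lattice"),
            inherits(epar, "cpm_energy_params"),
            inherits(mpar, "cpm_mmp_params"))
  K <- lattice$n_cells
  structure(list(
    sigma = lattice$sigma,
    field = matrix(0, nrow(lattice$sigma), ncol(lattice$sigma)),
    epar = epar, mpar = mpar, dx = lattice$dx, n_cells = K,
    polarity = matrix(0, K, 2),
    hist = matrix(0, K, 2 * epar$tau),
    hist_len = integer(K), hist_head = integer(K),
    alive = rep(TRUE, K), mcs = 0L),
    class = "cpm_state")
}

#' @export
print.cpm_state <- function(x, ...) {
  cc <- pixel_counts(x$sigma)
  cat(sprintf("cpm_state at MCS %d: %d/%d cells alive, %d fibre px, total MMP %.3g\n",
              x$mcs, sum(x$alive), x$n_cells, cc[["fibre"]], sum(x$field)))
  invisible(x)
}

#' Total Hamiltonian energy of a configuration
#'
#' Sums the four energy terms over the whole lattice: interface (adhesion)
#' energy over all first-order lattice edges between different domains,
#' the quadratic area and perimeter constraints per cell, and the motility
#' work potential `-mu0 phat_c . r_c` per cell (zero for unpolarized
#' cells). Fluid carries no constraint or motility terms.
#'
#' @param state a `cpm_state`, or a `sim_lattice` (zero polarity assumed).
#' @param epar [energy_params()]; defaults to the state's own.
#' @return Energy in kT.
#' @examples
#' total_energy(sim_lattice(matrix(0L, 10, 10)))  # empty lattice: 0... plus nothing
#' @export
total_energy <- function(state, epar = NULL) {
  if (inherits(state, "sim_lattice")) {
    sigma <- state$sigma
    K <- state$n_cells
    pol <- matrix(0, K, 2)
    if (is.null(epar)) epar <- energy_params()
  } else {
    stopifnot(inherits(state, "cpm_state"))
    sigma <- state$sigma
    pol <- state$polarity
    if (is.null(epar)) epar <- state$epar
  }
  cpp_total_energy(sigma, unclass(epar), pol)
}

#' Local energy change of a proposed pixel copy
#'
#' Energy difference `E(after) - E(before)` for copying the source pixel's
#' domain id onto the target pixel, computed from the pixels, areas,
#' perimeters and centroids the copy touches. Agrees with a full
#' [total_energy()] recompute to floating-point accuracy (polarities held
#' fixed, as they are between per-MCS updates).
#'
#' @param state a `cpm_state`.
#' @param source,target 1-based `c(i, j)` pixel indices; must be lattice
#'   4-neighbours and neither may be a fibre pixel.
#' @return dE in kT, or `NA` when source and target share a domain id (a
#'   skipped attempt).
#' @export
delta_energy <- function(state, source, target) {
  stopifnot(inherits(state, "cpm_state"))
  cpp_delta_energy(state$sigma, unclass(state$epar), state$polarity,
                   as.integer(source), as.integer(target))
}

#' Metropolis acceptance rule
#'
#' Accept when `dE < 0`; otherwise accept with Boltzmann probability
#' `exp(-dE / T_m)` compared against the uniform draw `u`.
#'
#' @param dE energy change in kT (vectorized).
#' @param T_m noise strength, > 0.
#' @param u uniform random draws in `[0, 1)`.
#' @return Logical vector.
#' @examples
#' metropolis_accept(c(-5, 0, 0.01), T_m = 0.01, u = c(0.9, 0.9, 0.1))
#' @export
metropolis_accept <- function(dE, T_m, u) {
  stopifnot(T_m > 0)
  dE < 0 | u < exp(-dE / T_m)
}

#' Polarity from a displacement history
#'
#' The polarity of a cell is the direction of the sum of its last `tau`
#' per-MCS centroid displacements, normalized to a unit vector; the zero
#' vector when the history is empty or sums to zero. Early in a run
#' (fewer than `tau` recorded displacements) the available history is
#' used.
#'
#' @param history numeric matrix with up to `tau` rows of `(dx, dy)`
#'   displacements (um or px; only the direction matters).
#' @param tau polarity timescale in MCS.
#' @return Unit vector `c(x, y)`, or `c(0, 0)`.
#' @examples
#' update_polarity(matrix(c(3, 4), 1, 2))  # 0.6 0.8
#' @export
update_polarity <- function(history, tau = 10) {
  if (is.null(history) || length(history) == 0) return(c(0, 0))
  history <- matrix(history, ncol = 2)
  if (nrow(history) > tau) stop("history holds more than tau displacements")
  s <- colSums(history)
  n <- sqrt(sum(s^2))
  if (n > 1e-12) s / n else c(0, 0)
}

#' Motility work term of a proposed copy
#'
#' The active-motility contribution to dE: `-mu0 * phat . dr_c` summed
#' over the affected cells, where `dr_c` is the centroid shift caused by
#' gaining or losing the pixel. Negative (favourable) when the cell
#' extends along its polarity.
#'
#' @param polarity unit polarity vector of the cell.
#' @param centroid current centroid (px).
#' @param area current area (px).
#' @param pixel centre coordinate of the gained/lost pixel (px).
#' @param mu0 motility strength.
#' @param gaining TRUE when the cell gains the pixel, FALSE when it loses
#'   it.
#' @return Energy contribution in kT.
#' @export
motility_delta <- function(polarity, centroid, area, pixel, mu0,
                           gaining = TRUE) {
  if (gaining) {
    dr <- (pixel - centroid) / (area + 1)
  } else {
    if (area <= 1) return(mu0 * sum(polarity * centroid))
    dr <- (centroid * area - pixel) / (area - 1) - centroid
  }
  -mu0 * sum(polarity * dr)
}

#' Run the hybrid simulation
#'
#' Advances the state by `n_mcs` Monte Carlo steps. Each MCS performs `N`
#' copy attempts (`N` = number of evolvable cell + fluid pixels at the
#' start of the step; source uniform among them, target uniform among its
#' 4-neighbours; attempts onto fibre pixels, outside the lattice or within
#' one domain are aborted but count toward `N`), then appends each cell's
#' centroid displacement to its history and updates its polarity, then --
#' when proteolysis is enabled -- runs the 36 one-second MMP substeps
#' (secretion at cell-contacted fibre pixels, forward-Euler
#' diffusion/decay) and finally applies threshold-1 ECM degradation once.
#'
#' @param state a `cpm_state`.
#' @param n_mcs number of Monte Carlo steps (36 s each).
#' @param record_every record the trajectory every this many MCS (0 = no
#'   trajectory).
#' @param proteolysis run the MMP field and ECM degradation.
#' @param seed optional integer seed.
#' @return A list of class `cpm_result`: `state` (advanced `cpm_state`),
#'   `trajectory` (data.frame `mcs, cell_id, x_um, y_um, area_px,
#'   polarity_x, polarity_y`, including the entry state), and `series`
#'   (per-MCS data.frame with attempt/acceptance counts, degradation
#'   events, fibre pixel count, total MMP and the instrumented PDE substep
#'   count).
#' @examples
#' lat <- build_lattice(generate_fibre_mesh(30, seed = 2, lattice_px = 100),
#'                      build_initial_aggregate(20, lattice_px = 100))
#' res <- run_simulation(initialize_state(lat), n_mcs = 2, seed = 1)
#' head(res$series)
#' @export
run_simulation <- function(state, n_mcs, record_every = 1,
                           proteolysis = TRUE, seed = NULL) {
  stopifnot(inherits(state, "cpm_state"), n_mcs >= 0)
  if (!is.null(seed)) set.seed(seed)
  K <- state$n_cells
  mpar <- state$mpar
  r_diff <- mpar$D * mpar$dt / mpar$dx^2

  st0 <- cpp_cell_stats(state$sigma, K)
  traj0 <- if (K > 0) data.frame(
    mcs = state$mcs, cell_id = seq_len(K),
    x_um = st0$cx * state$dx, y_um = st0$cy * state$dx,
    area_px = st0$area,
    polarity_x = state$polarity[, 1], polarity_y = state$polarity[, 2])
  else data.frame(mcs = integer(0), cell_id = integer(0), x_um = numeric(0),
                  y_um = numeric(0), area_px = numeric(0),
                  polarity_x = numeric(0), polarity_y = numeric(0))

  if (n_mcs == 0) {
    return(structure(list(state = state, trajectory = traj0,
                          series = data.frame()), class = "cpm_result"))
  }

  out <- cpp_run_simulation(
    state$sigma, state$field, state$hist, state$hist_len, state$hist_head,
    state$polarity, state$alive, unclass(state$epar),
    r_diff, mpar$delta_mmp * mpar$dt, mpar$lambda * mpar$dt,
    mpar$substeps, proteolysis, as.integer(n_mcs),
    as.integer(record_every), as.integer(state$mcs))

  died <- state$alive & !out$alive
  if (any(died)) {
    message(sprintf("cell(s) %s lost all pixels and were removed from the records",
                    paste(which(died), collapse = ", ")))
  }

  new_state <- state
  new_state$sigma <- out$sigma
  new_state$field <- out$field
  new_state$hist <- out$hist
  new_state$hist_len <- out$hist_len
  new_state$hist_head <- out$hist_head
  new_state$polarity <- out$polarity
  new_state$alive <- out$alive
  new_state$mcs <- state$mcs + as.integer(n_mcs)

  n_rec <- length(out$rec_mcs)
  traj <- if (K > 0 && n_rec > 0) {
    data.frame(
      mcs = rep(out$rec_mcs, each = K),
      cell_id = rep(seq_len(K), n_rec),
      x_um = as.vector(out$rec_cx) * state$dx,
      y_um = as.vector(out$rec_cy) * state$dx,
      area_px = as.vector(out$rec_area),
      polarity_x = as.vector(out$rec_polx),
      polarity_y = as.vector(out$rec_poly))
  } else traj0[0, ]
  trajectory <- rbind(traj0, traj)

  structure(list(state = new_state, trajectory = trajectory,
                 series = as.data.frame(out$series)),
            class = "cpm_result")
}

#' @export
print.cpm_result <- function(x, ...) {
  cat(sprintf("cpm_result: %d MCS recorded, %d trajectory rows\n",
              nrow(x$series), nrow(x$trajectory)))
  invisible(x)
}

#' Advance the state by one Monte Carlo step
#'
#' Convenience wrapper over [run_simulation()] returning only the updated
#' state.
#'
#' @inheritParams run_simulation
#' @return The advanced `cpm_state`.
#' @export
run_mcs <- function(state, proteolysis = TRUE, seed = NULL) {
  run_simulation(state, 1, record_every = 0, proteolysis = proteolysis,
                 seed = seed)$state
}
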