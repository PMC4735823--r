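# trajectory data.frame -> list(mcs, X, Y) with cells in rows
traj_wide <- function(traj) {
  stopifnot(all(c("mcs", "cell_id", "x_um", "y_um") %in% names(traj)))
  mcs <- sort(unique(traj$mcs))
  ids <- sort(unique(traj$cell_id))
  X <- matrix(NA_real_, length(ids), length(mcs))
  Y <- X
  ii <- cbind(match(traj$cell_id, ids), match(traj$mcs, mcs))
  X[ii] <- traj$x_um
  Y[ii] <- traj$y_um
  list(mcs = mcs, ids = ids, X = X, Y = Y)
}

drop_incomplete_cells <- function(w, context) {
  ok <- stats::complete.cases(w$X) & stats::complete.cases(w$Y)
  if (!all(ok)) {
    warning(sprintf("%s: dropping %d cell(s) with missing positions",
                    context, sum(!ok)))
    w$X <- w$X[ok, , drop = FALSE]
    w$Y <- w$Y[ok, , drop = FALSE]
    w$ids <- w$ids[ok]
  }
  w
}

#' Population-mean total distance travelled
#'
#' Sum over successive recorded steps of the centroid displacement
#' magnitude, per cell, then averaged over cells. With the default per-MCS
#' recording this adds the centroidal movement between successive MCS
#' (36-s) steps. A measure of cell dynamicity: a cell that wanders and
#' returns scores high here but zero on [net_translocation()].
#'
#' @param traj trajectory data.frame from [run_simulation()] (columns
#'   `mcs`, `cell_id`, `x_um`, `y_um`).
#' @return Mean total path length in um.
#' @examples
#' fx <- make_fixture("round_trip")
#' total_distance(fx$trajectory)  # 20 um out and back
#' @export
total_distance <- function(traj) {
  w <- drop_incomplete_cells(traj_wide(traj), "total_distance")
  if (ncol(w$X) < 2) {
    warning("trajectory has a single time point; total distance is 0")
    return(0)
  }
  steps <- sqrt(diff(t(w$X))^2 + diff(t(w$Y))^2)  # (T-1) x n_cells
  mean(colSums(steps))
}

#' Population-mean net translocation
#'
#' Distance between each cell's initial and final recorded positions,
#' averaged over cells: the effective invasion distance, insensitive to
#' circuitous paths.
#'
#' @inheritParams total_distance
#' @return Mean displacement in um. Never exceeds [total_distance()].
#' @examples
#' fx <- make_fixture("round_trip")
#' net_translocation(fx$trajectory)  # 0
#' @export
net_translocation <- function(traj) {
  w <- drop_incomplete_cells(traj_wide(traj), "net_translocation")
  Tn <- ncol(w$X)
  if (Tn < 2) return(0)
  mean(sqrt((w$X[, Tn] - w$X[, 1])^2 + (w$Y[, Tn] - w$Y[, 1])^2))
}

#' Radius of gyration of the cell population
#'
#' `sqrt(mean(d_j^2))` where `d_j` is the distance of cell `j`'s final
#' position from the initial population centre -- a population-scattering
#' measure.
#'
#' @param positions n x 2 matrix (or data.frame) of final cell positions
#'   in um, or a trajectory data.frame (final time point is used).
#' @param centre initial population centre `c(x, y)` in um; the reference
#'   geometry uses pixel (250, 250), i.e. `c(500, 500)` um.
#' @return RoG in um.
#' @examples
#' radius_of_gyration(cbind(c(10, 10, 20, 20), 0), centre = c(0, 0))
#' @export
radius_of_gyration <- function(positions, centre) {
  if (is.data.frame(positions) && "mcs" %in% names(positions)) {
    w <- drop_incomplete_cells(traj_wide(positions), "radius_of_gyration")
    Tn <- ncol(w$X)
    positions <- cbind(w$X[, Tn], w$Y[, Tn])
  }
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 1, length(centre) == 2)
  d2 <- (positions[, 1] - centre[1])^2 + (positions[, 2] - centre[2])^2
  sqrt(mean(d2))
}

#' Percent ECM degradation
#'
#' Reduction in fibre pixel count relative to the initial count.
#'
#' @param initial_fibre_px initial fibre pixel count (> 0).
#' @param final_fibre_px final fibre pixel count.
#' @return Percentage in [0, 100].
#' @examples
#' percent_ecm_degradation(1000, 900)  # 10
#' @export
percent_ecm_degradation <- function(initial_fibre_px, final_fibre_px) {
  if (initial_fibre_px <= 0) {
    stop("percent ECM degradation is undefined for zero initial fibre pixels")
  }
  100 * (initial_fibre_px - final_fibre_px) / initial_fibre_px
}

#' Cluster statistics of the cell population
#'
#' Two cells are adjacent when any of their pixels are lattice
#' 4-neighbours; clusters are the connected components of the resulting
#' cell-adjacency graph. Few large clusters indicate collective migration;
#' many singletons indicate single-cell (mesenchymal-like) invasion.
#'
#' @param lattice a `sim_lattice`, `cpm_state`, or bare sigma matrix.
#' @return List with `n_clusters`, `sizes` (cells per cluster, decreasing),
#'   `mean_size`, and `membership` (data.frame `cell_id`, `cluster`).
#' @examples
#' cluster_stats(build_lattice(NULL, build_initial_aggregate()))$n_clusters
#' @export
cluster_stats <- function(lattice) {
  sigma <- if (inherits(lattice, c("sim_lattice", "cpm_state"))) {
    lattice$sigma
  } else lattice
  ids <- sort(unique(sigma[sigma >= 1L]))
  if (length(ids) == 0) stop("lattice contains no cells")

  h_a <- sigma[-nrow(sigma), ]; h_b <- sigma[-1, ]
  v_a <- sigma[, -ncol(sigma)]; v_b <- sigma[, -1]
  sel_h <- h_a >= 1L & h_b >= 1L & h_a != h_b
  sel_v <- v_a >= 1L & v_b >= 1L & v_a != v_b
  edges <- rbind(cbind(h_a[sel_h], h_b[sel_h]), cbind(v_a[sel_v], v_b[sel_v]))
  edges <- unique(edges)

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  comp <- igraph::components(g)
  membership <- data.frame(
    cell_id = as.integer(igraph::V(g)$name),
    cluster = as.integer(comp$membership))
  membership <- membership[order(membership$cell_id), ]
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  list(n_clusters = comp$no, sizes = sizes, mean_size = mean(sizes),
       membership = membership)
}

#' Per-replicate invasion metrics report
#'
#' Condenses one simulation run into the standard panel: mean total
#' distance, mean net translocation, radius of gyration about the initial
#' population centre, percent ECM degradation and cluster statistics.
#'
#' @param result a `cpm_result` from [run_simulation()].
#' @param initial_fibre_px fibre pixel count before the run (0 allowed;
#'   degradation is then reported as NA).
#' @param centre_um initial population centre in um.
#' @return One-row data.frame (`d_total_um`, `d_net_um`, `rog_um`,
#'   `pct_degradation`, `n_clusters`, `mean_cluster_size`,
#'   `alignment_x`: the mean |cos| of the angle between each cell's net
#'   displacement and the x axis — the fibre axis of aligned meshes;
#'   NA for cells that did not move).
#' @export
metrics_report <- function(result, initial_fibre_px,
                           centre_um = c(500, 500)) {
  stopifnot(inherits(result, "cpm_result"))
  traj <- result$trajectory
  cl <- cluster_stats(result$state$sigma)
  final_fibre <- sum(result$state$sigma == -1L)
  d_tot <- total_distance(traj)
  d_net <- net_translocation(traj)
  if (d_net > d_tot + 1e-9) stop("metric integrity: d_net exceeds d_total")
  w <- drop_incomplete_cells(traj_wide(traj), "metrics_report")
  Tn <- ncol(w$X)
  dx <- w$X[, Tn] - w$X[, 1]; dy <- w$Y[, Tn] - w$Y[, 1]
  nrm <- sqrt(dx^2 + dy^2)
  moved <- nrm > 1e-9
  data.frame(
    d_total_um = d_tot,
    d_net_um = d_net,
    rog_um = radius_of_gyration(traj, centre_um),
    pct_degradation = if (initial_fibre_px > 0) {
      percent_ecm_degradation(initial_fibre_px, final_fibre)
    } else NA_real_,
    n_clusters = cl$n_clusters,
    mean_cluster_size = cl$mean_size,
    alignment_x = if (any(moved)) mean(abs(dx[moved]) / nrm[moved]) else NA_real_)
}
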