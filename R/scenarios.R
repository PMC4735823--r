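#' Scenario configuration
#'
#' A declarative description of a simulation experiment: the parameter
#' grid (any of `J_cc`, `lambda`, `xi`, `psi` may be vectors and are
#' crossed), proteolysis on/off, run length, replicate count and base
#' seed. `scale` shrinks the lattice side by that factor (fibre count is
#' scaled by the area ratio `scale^2`) for desk-scale runs; the reference
#' grid uses `scale = 1`, 1800 MCS (~18 h) and 10 replicates per
#' condition.
#'
#' @param J_cc cell-cell adhesion energies; 1 / 16 / 40 model high /
#'   medium / low cell-cell adhesion.
#' @param lambda MMP secretion rates (1/s), 0.01-0.1.
#' @param xi fibre counts at reference scale (400 / 600 / 1000).
#' @param psi fibre orientation modes, `"random"` and/or `"aligned"`.
#' @param proteolysis logical: run MMP secretion/diffusion/degradation.
#' @param n_mcs Monte Carlo steps per replicate (36 s each).
#' @param n_replicates replicates per condition.
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`, so
#'   replicate meshes are shared across conditions (paired comparisons).
#' @param cell_ecm_adhesion_override set `J_ce = J_cf` to remove the
#'   preference of cells for fibre contact.
#' @param scale lattice reduction factor in (0, 1].
#' @param geometry `"aggregate"` (central tumour aggregate in an ECM
#'   mesh), `"channels"` (speed-calibration lattice of fibre-free paths)
#'   or `"confinement"` (non-degradable circular enclosure).
#' @return An object of class `scenario_config`.
#' @examples
#' preset("fig2")
#' @export
scenario_config <- function(J_cc = 1, lambda = 0.05, xi = 600,
                            psi = "random", proteolysis = TRUE,
                            n_mcs = 1800, n_replicates = 10, base_seed = 1,
                            cell_ecm_adhesion_override = FALSE, scale = 1,
                            geometry = "aggregate") {
  if (!all(psi %in% c("random", "aligned"))) {
    stop("psi must be 'random' and/or 'aligned'")
  }
  if (!geometry %in% c("aggregate", "channels", "confinement")) {
    stop("unknown geometry: ", geometry)
  }
  if (n_mcs < 0 || n_replicates < 1) {
    stop("n_mcs must be >= 0 and n_replicates >= 1")
  }
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (any(xi < 0)) stop("xi must be non-negative")
  structure(list(J_cc = as.numeric(J_cc), lambda = as.numeric(lambda),
                 xi = as.numeric(xi), psi = as.character(psi),
                 proteolysis = isTRUE(proteolysis),
                 n_mcs = as.integer(n_mcs),
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 cell_ecm_adhesion_override = isTRUE(cell_ecm_adhesion_override),
                 scale = as.numeric(scale), geometry = geometry),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("scenario_config [%s]: J_cc={%s} lambda={%s} xi={%s} psi={%s}\n",
              x$geometry, paste(x$J_cc, collapse = ","),
              paste(x$lambda, collapse = ","), paste(x$xi, collapse = ","),
              paste(x$psi, collapse = ",")))
  cat(sprintf("  proteolysis=%s, %d MCS x %d replicates, base_seed=%d, scale=%g\n",
              x$proteolysis, x$n_mcs, x$n_replicates, x$base_seed, x$scale))
  invisible(x)
}

#' Preset experiment configurations
#'
#' Named configurations reproducing the reference sweeps: `fig2` (cell-cell
#' adhesion sweep at lambda = 0.05), `fig3` (adhesion x secretion-rate
#' grid), `fig4` (adhesion x fibre-density grid at lambda = 0.05),
#' `fig4_high_lambda` (same grid at the two-fold secretion rate 0.1),
#' `fig5` (random vs aligned meshes without proteolysis), and the two
#' calibration geometries `calibration_speed` (fibre-free channels) and
#' `calibration_rotation` (non-degradable circular confinement).
#'
#' @param name preset name.
#' @return A [scenario_config()].
#' @examples
#' preset("fig5")$proteolysis  # FALSE
#' @export
preset <- function(name) {
  known <- c("fig2", "fig3", "fig4", "fig4_high_lambda", "fig5",
             "calibration_speed", "calibration_rotation")
  if (!is.character(name) || length(name) != 1 || !name %in% known) {
    stop("unknown preset; valid presets: ", paste(known, collapse = ", "))
  }
  switch(name,
    fig2 = scenario_config(J_cc = c(1, 16, 40), lambda = 0.05, xi = 600),
    fig3 = scenario_config(J_cc = c(1, 16, 40),
                           lambda = c(0.01, 0.05, 0.1), xi = 600),
    fig4 = scenario_config(J_cc = c(1, 16, 40), lambda = 0.05,
                           xi = c(400, 600, 1000)),
    fig4_high_lambda = scenario_config(J_cc = c(1, 16, 40), lambda = 0.1,
                                       xi = c(400, 600, 1000)),
    fig5 = scenario_config(J_cc = c(1, 16, 40), lambda = 0,
                           xi = c(400, 600, 1000),
                           psi = c("random", "aligned"),
                           proteolysis = FALSE),
    calibration_speed = scenario_config(J_cc = 16, lambda = 0, xi = 0,
                                        proteolysis = FALSE, n_mcs = 150,
                                        n_replicates = 3,
                                        geometry = "channels"),
    calibration_rotation = scenario_config(J_cc = 1, lambda = 0, xi = 0,
                                           proteolysis = FALSE, n_mcs = 250,
                                           n_replicates = 1,
                                           geometry = "confinement"))
}

build_run_inputs <- function(cond, cfg, epar_base, seed) {
  lattice_px <- round(500 * cfg$scale)
  xi_eff <- round(cond$xi * cfg$scale^2)
  mesh <- generate_fibre_mesh(xi_eff, cond$psi, seed = seed,
                              lattice_px = lattice_px)
  layout <- build_initial_aggregate(lattice_px = lattice_px)
  lattice <- build_lattice(mesh, layout)
  margin_um <- lattice_px * lattice$dx / 2 - layout$nominal_radius
  epar <- energy_params(
    J_cc = cond$J_cc,
    J_ce = if (cfg$cell_ecm_adhesion_override) epar_base$J_cf else epar_base$J_ce,
    J_cf = epar_base$J_cf, J_ef = epar_base$J_ef, J_ee = epar_base$J_ee,
    J_ff = epar_base$J_ff, lambda_a = epar_base$lambda_a,
    lambda_p = epar_base$lambda_p, a0 = epar_base$a0, p0 = epar_base$p0,
    T_m = epar_base$T_m, mu0 = epar_base$mu0, tau = epar_base$tau)
  mpar <- mmp_params(lambda = cond$lambda)
  list(lattice = lattice, epar = epar, mpar = mpar,
       lattice_px = lattice_px, margin_um = margin_um)
}

#' Run a scenario sweep
#'
#' Expands the configuration's parameter grid, builds a fresh mesh and
#' aggregate per replicate (replicate `r` seeded with `base_seed + r`, so
#' the same meshes recur across conditions), runs each replicate for
#' `n_mcs` MCS and collects the invasion metrics panel plus the per-MCS
#' total-MMP and fibre-count series. Deterministic given the
#' configuration.
#'
#' @param cfg a [scenario_config()] with `geometry = "aggregate"`.
#' @param epar_base [energy_params()] supplying everything except the
#'   swept `J_cc` (and `J_ce` under the adhesion override).
#' @param record_every trajectory recording stride in MCS.
#' @param verbose print progress.
#' @return An object of class `sweep_result`: `config`, `conditions`
#'   (the grid with condition ids), `metrics` (one row per condition x
#'   replicate), `series` (per-MCS MMP/fibre/acceptance counts), and
#'   `manifest` (seeds, package version, simulated duration, margin).
#' @examples
#' cfg <- scenario_config(J_cc = c(1, 40), n_mcs = 2, n_replicates = 1,
#'                        scale = 0.4, xi = 300)
#' run_scenario(cfg)$metrics
#' @export
run_scenario <- function(cfg, epar_base = energy_params(),
                         record_every = 1, verbose = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$geometry != "aggregate") {
    stop("run_scenario handles the aggregate geometry; use calibrate_speed()",
         " or calibrate_rotation() for the calibration geometries")
  }
  conditions <- expand.grid(J_cc = cfg$J_cc, lambda = cfg$lambda,
                            xi = cfg$xi, psi = cfg$psi,
                            stringsAsFactors = FALSE)
  conditions <- cbind(condition = seq_len(nrow(conditions)), conditions)

  metrics <- list()
  series <- list()
  seeds <- integer(0)
  margin_um <- NA_real_
  z <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (r in seq_len(cfg$n_replicates)) {
      seed <- cfg$base_seed + r
      seeds <- union(seeds, seed)
      inp <- build_run_inputs(cond, cfg, epar_base, seed)
      if (is.na(margin_um)) margin_um <- inp$margin_um
      initial_fibre <- sum(inp$lattice$sigma == -1L)
      state <- initialize_state(inp$lattice, inp$epar, inp$mpar)
      res <- run_simulation(state, cfg$n_mcs, record_every = record_every,
                            proteolysis = cfg$proteolysis)
      centre <- rep(inp$lattice_px / 2 * inp$lattice$dx, 2)
      row <- suppressWarnings(
        metrics_report(res, initial_fibre, centre_um = centre))
      z <- z + 1L
      metrics[[z]] <- cbind(
        data.frame(condition = cond$condition, replicate = r, seed = seed,
                   J_cc = cond$J_cc, lambda = cond$lambda, xi = cond$xi,
                   psi = cond$psi), row)
      if (nrow(res$series) > 0) {
        series[[z]] <- data.frame(
          condition = cond$condition, replicate = r,
          mcs = res$series$mcs, mmp_total = res$series$mmp_total,
          fibre_px = res$series$fibre_px,
          n_accepted = res$series$n_accepted,
          n_degraded = res$series$n_degraded)
      }
      if (verbose) {
        message(sprintf("condition %d/%d replicate %d done",
                        ci, nrow(conditions), r))
      }
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("invadopotts")),
    base_seed = cfg$base_seed, seeds = sort(seeds),
    simulated_hours = cfg$n_mcs * 36 / 3600,
    aggregate_margin_um = margin_um,
    config_hash = config_hash(cfg))
  structure(list(config = cfg, conditions = conditions,
                 metrics = do.call(rbind, metrics),
                 series = if (z > 0 && length(series) > 0) {
                   do.call(rbind, series[!vapply(series, is.null, TRUE)])
                 } else data.frame(),
                 manifest = manifest),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d conditions x %d replicates (%.3g h simulated each)\n",
              nrow(x$conditions), x$config$n_replicates,
              x$manifest$simulated_hours))
  invisible(x)
}

#' Condition-level summary of a sweep
#'
#' Mean and standard error of the mean (SEM) across replicates for every
#' metric, per condition.
#'
#' @param sweep a `sweep_result`.
#' @return data.frame, one row per condition.
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  m <- sweep$metrics
  cols <- c("d_total_um", "d_net_um", "rog_um", "pct_degradation",
            "n_clusters", "mean_cluster_size", "alignment_x")
  out <- list()
  for (ci in unique(m$condition)) {
    sub <- m[m$condition == ci, ]
    row <- sub[1, c("condition", "J_cc", "lambda", "xi", "psi")]
    for (cl in cols) {
      v <- sub[[cl]]
      row[[paste0(cl, "_mean")]] <- mean(v)
      row[[paste0(cl, "_sem")]] <- stats::sd(v) / sqrt(length(v))
    }
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sided rank test between two sweep conditions
#'
#' Extracts the per-replicate values of a metric under two condition
#' filters and applies a one-sided Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param sweep a `sweep_result`.
#' @param metric metric column name, e.g. `"d_net_um"`.
#' @param a,b named lists filtering the condition grid, e.g.
#'   `list(J_cc = 40)`.
#' @param alternative `"greater"` tests a > b.
#' @return The `htest` p-value.
#' @export
compare_conditions <- function(sweep, metric, a, b,
                               alternative = "greater") {
  pick <- function(flt) {
    sel <- rep(TRUE, nrow(sweep$metrics))
    for (nm in names(flt)) sel <- sel & sweep$metrics[[nm]] == flt[[nm]]
    sweep$metrics[[metric]][sel]
  }
  va <- pick(a); vb <- pick(b)
  if (length(va) == 0 || length(vb) == 0) stop("empty condition filter")
  suppressWarnings(
    stats::wilcox.test(va, vb, alternative = alternative)$p.value)
}

#' Lattice of parallel fibre-free migration channels
#'
#' The speed-calibration geometry: full-width horizontal fibre walls every
#' `period` pixels partition the lattice into open channels ("sparse ECM
#' with pre-existing paths"); single cells are seeded inside distinct
#' channels. With proteolysis off the walls are non-degradable.
#'
#' @param lattice_px lattice side in pixels.
#' @param period wall spacing in pixels (channel height `period - 1`).
#' @param n_cells number of 10x10 cells to seed.
#' @param dx pixel size in um.
#' @return A `sim_lattice`.
#' @export
build_channel_lattice <- function(lattice_px = 250, period = 14,
                                  n_cells = 12, dx = 2) {
  if (period < 12) stop("period must leave room for a 10-px cell")
  sigma <- matrix(0L, lattice_px, lattice_px)
  walls <- seq(period, lattice_px, by = period)
  sigma[, walls] <- -1L
  # channel c spans columns (walls[c-1], walls[c]) exclusive
  ch_tops <- c(0L, walls)
  id <- 0L
  cx <- 10L
  for (c in seq_len(length(ch_tops) - 1)) {
    if (id >= n_cells) break
    j0 <- ch_tops[c] + 1L + max(0L, (period - 1L - 10L) %/% 2L)
    if (j0 + 9L > lattice_px || ch_tops[c + 1] - ch_tops[c] < 11L) next
    if (cx + 9L > lattice_px - 10L) cx <- 10L
    id <- id + 1L
    sigma[(cx + 1L):(cx + 10L), (j0 + 1L):(j0 + 10L)] <- id
    cx <- cx + 35L
  }
  sim_lattice(sigma, dx = dx)
}

#' Calibrate the migration speed on pre-existing paths
#'
#' Runs cells seeded in fibre-free channels and returns the population
#' speed: the mean per-MCS centroid displacement (um) times 100 MCS/h
#' (one MCS = 36 s). The first `tau` MCS are excluded while the polarity
#' history fills. The reference calibration target is ~23 um/h.
#'
#' @param cfg a [scenario_config()] with `geometry = "channels"` (see
#'   `preset("calibration_speed")`); `n_replicates` seeds are averaged.
#' @param epar [energy_params()].
#' @param lattice_px lattice side in pixels.
#' @return List with `speed_um_h` (pooled mean), `per_seed` (per-seed
#'   speeds) and `n_mcs`.
#' @export
calibrate_speed <- function(cfg = preset("calibration_speed"),
                            epar = energy_params(), lattice_px = 250) {
  stopifnot(inherits(cfg, "scenario_config"))
  per_seed <- numeric(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    seed <- cfg$base_seed + r
    lat <- build_channel_lattice(lattice_px = lattice_px)
    state <- initialize_state(lat, epar, mmp_params(lambda = 0))
    res <- run_simulation(state, cfg$n_mcs, record_every = 1,
                          proteolysis = FALSE, seed = seed)
    w <- traj_wide(res$trajectory)
    keep <- w$mcs > epar$tau
    X <- w$X[, keep, drop = FALSE]; Y <- w$Y[, keep, drop = FALSE]
    steps <- sqrt(diff(t(X))^2 + diff(t(Y))^2)
    per_seed[r] <- mean(steps) * 100
  }
  list(speed_um_h = mean(per_seed), per_seed = per_seed, n_mcs = cfg$n_mcs)
}

#' Lattice of cells confined in a non-degradable circular enclosure
#'
#' A ring of fibre pixels of the given radius encloses a block aggregate;
#' with proteolysis off the enclosure cannot be degraded. Used for the
#' rotational-motion calibration.
#'
#' @param lattice_px lattice side in pixels.
#' @param radius_px enclosure inner radius in pixels.
#' @param dx pixel size in um.
#' @return A `sim_lattice`.
#' @export
build_confinement_lattice <- function(lattice_px = 100, radius_px = 32,
                                      dx = 2) {
  c0 <- lattice_px / 2
  ij <- expand.grid(i = seq_len(lattice_px), j = seq_len(lattice_px))
  d <- sqrt((ij$i - 0.5 - c0)^2 + (ij$j - 0.5 - c0)^2)
  sigma <- matrix(0L, lattice_px, lattice_px)
  sigma[as.matrix(ij[d >= radius_px & d < radius_px + 2.5, ])] <- -1L
  lay <- build_initial_aggregate(disk_radius = (radius_px - 6) * dx,
                                 cell_side = 10 * dx,
                                 lattice_px = lattice_px, dx = dx)
  for (id in seq_along(lay$cell_pixel_map)) {
    sigma[lay$cell_pixel_map[[id]]] <- id
  }
  sim_lattice(sigma, dx = dx)
}

#' Persistent rotation of confined cells
#'
#' Runs the confinement geometry and computes the time-averaged angular
#' momentum of the cell centroids about the enclosure centre,
#' `L(t) = mean_c [ (r_c - r_0) x dr_c ]_z`. The observed statistic
#' `|mean_t L(t)|` is compared against a null built by randomly rotating
#' every per-MCS displacement (isotropized increments, trajectories
#' rebuilt from the same start), which destroys coherent rotation while
#' preserving step lengths. Persistent rotation gives a small permutation
#' p-value.
#'
#' @param cfg a [scenario_config()] with `geometry = "confinement"`.
#' @param epar [energy_params()].
#' @param n_null null resamples.
#' @param lattice_px,radius_px enclosure geometry (pixels).
#' @return List with `statistic` (um^2/MCS), `p_value`, and the per-MCS
#'   angular momentum series `L`.
#' @export
calibrate_rotation <- function(cfg = preset("calibration_rotation"),
                               epar = energy_params(), n_null = 199,
                               lattice_px = 100, radius_px = 32) {
  stopifnot(inherits(cfg, "scenario_config"))
  lat <- build_confinement_lattice(lattice_px, radius_px)
  state <- initialize_state(lat, epar, mmp_params(lambda = 0))
  res <- run_simulation(state, cfg$n_mcs, record_every = 1,
                        proteolysis = FALSE, seed = cfg$base_seed + 1)
  w <- traj_wide(res$trajectory)
  c0 <- lattice_px / 2 * lat$dx
  ang_mom <- function(X, Y) {
    dX <- diff(t(X)); dY <- diff(t(Y))            # (T-1) x n
    rx <- t(X)[-nrow(t(X)), , drop = FALSE] - c0
    ry <- t(Y)[-nrow(t(Y)), , drop = FALSE] - c0
    rowMeans(rx * dY - ry * dX)
  }
  L <- ang_mom(w$X, w$Y)
  stat <- abs(mean(L))
  n <- nrow(w$X)
  dX <- diff(t(w$X)); dY <- diff(t(w$Y))
  null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    th <- matrix(runif(length(dX), 0, 2 * pi), nrow(dX), ncol(dX))
    rdX <- dX * cos(th) - dY * sin(th)
    rdY <- dX * sin(th) + dY * cos(th)
    Xb <- t(apply(rbind(w$X[, 1], rdX), 2, cumsum))
    Yb <- t(apply(rbind(w$Y[, 1], rdY), 2, cumsum))
    null[b] <- abs(mean(ang_mom(Xb, Yb)))
  }
  list(statistic = stat, p_value = (1 + sum(null >= stat)) / (n_null + 1),
       L = L)
}

#' Static summary of a scenario's bookkeeping
#'
#' Reports, without running any dynamics, the simulated duration
#' (`n_mcs` x 36 s per MCS, in hours), the margin between the nominal cell
#' population and the lattice boundary, the PDE substep cadence, and the
#' size of the condition grid. The reference configuration (1800 MCS,
#' scale 1) simulates 18 h with a 400-um margin.
#'
#' @param cfg a [scenario_config()].
#' @return List with `simulated_hours`, `margin_um`, `pde_substeps_per_mcs`,
#'   `n_conditions`, `n_runs`, `lattice_um`, `mcs_seconds`.
#' @examples
#' scenario_summary(preset("fig2"))$simulated_hours  # 18
#' @export
scenario_summary <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  mpar <- mmp_params()
  lattice_px <- round(500 * cfg$scale)
  lay <- build_initial_aggregate(lattice_px = lattice_px)
  mcs_seconds <- mpar$substeps * mpar$dt
  list(simulated_hours = cfg$n_mcs * mcs_seconds / 3600,
       margin_um = lattice_px * lay$dx / 2 - lay$nominal_radius,
       pde_substeps_per_mcs = mpar$substeps,
       n_conditions = length(cfg$J_cc) * length(cfg$lambda) *
         length(cfg$xi) * length(cfg$psi),
       n_runs = length(cfg$J_cc) * length(cfg$lambda) * length(cfg$xi) *
         length(cfg$psi) * cfg$n_replicates,
       lattice_um = lattice_px * lay$dx,
       mcs_seconds = mcs_seconds)
}

# FNV-style content hash of the serialized config (manifest bookkeeping)
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  b <- utf8ToInt(s)
  h <- 2166136261
  for (x in b) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(x))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write / read a scenario configuration as YAML
#'
#' Round-trips every field losslessly through a human-readable file.
#'
#' @param cfg a [scenario_config()].
#' @param path file path.
#' @return `write_scenario_config` returns `path` invisibly;
#'   `read_scenario_config` returns the `scenario_config`.
#' @export
write_scenario_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  do.call(scenario_config, yaml::read_yaml(path))
}

#' Write sweep outputs to a directory
#'
#' Emits the per-replicate metrics CSV, the MMP/fibre time-series CSV, the
#' configuration YAML and a JSON run manifest. Floating-point values are
#' written at 6 significant digits for cross-platform byte
#' reproducibility.
#'
#' @param sweep a `sweep_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "sweep_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    for (cl in names(df)) {
      if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
        df[[cl]] <- signif(df[[cl]], 6)
      }
    }
    df
  }
  utils::write.csv(fmt(sweep$metrics), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(sweep$series), file.path(dir, "mmp_series.csv"),
                   row.names = FALSE)
  write_scenario_config(sweep$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(sweep$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
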