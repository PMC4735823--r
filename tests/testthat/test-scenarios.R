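test_that("presets encode the reference condition grids", {
  expect_false(preset("fig5")$proteolysis)
  expect_equal(preset("fig5")$lambda, 0)
  expect_equal(sort(preset("fig5")$psi), c("aligned", "random"))
  expect_equal(preset("fig2")$lambda, 0.05)
  expect_equal(preset("fig2")$J_cc, c(1, 16, 40))
  expect_equal(preset("fig3")$lambda, c(0.01, 0.05, 0.1))
  expect_equal(preset("fig4")$xi, c(400, 600, 1000))
  expect_equal(preset("fig4_high_lambda")$lambda, 0.1)
  expect_equal(preset("fig2")$n_mcs, 1800L)
  expect_equal(preset("fig2")$n_replicates, 10L)
  expect_equal(preset("calibration_speed")$geometry, "channels")
  expect_error(preset("fig9"), "valid presets")
})

test_that("scenario configs validate their arguments", {
  expect_error(scenario_config(psi = "diagonal"), "psi")
  expect_error(scenario_config(n_replicates = 0), "n_replicates")
  expect_error(scenario_config(scale = 0), "scale")
  expect_error(scenario_config(lambda = -0.1), "lambda")
  expect_error(scenario_config(geometry = "torus"), "geometry")
})

test_that("scenario bookkeeping reports duration, margin and cadence", {
  s <- scenario_summary(preset("fig2"))
  expect_equal(s$simulated_hours, 18)            # 1800 MCS x 36 s
  expect_equal(s$margin_um, 400)                 # 200-um aggregate in 1 mm
  expect_equal(s$pde_substeps_per_mcs, 36L)
  expect_equal(s$n_runs, 30L)                    # 3 conditions x 10 reps
  expect_equal(s$mcs_seconds, 36)
})

test_that("a zero-MCS scenario returns initial-state metrics", {
  cfg <- scenario_config(J_cc = 1, n_mcs = 0, n_replicates = 1,
                         xi = 150, scale = 0.5, base_seed = 3)
  sw <- run_scenario(cfg)
  expect_equal(sw$metrics$d_total_um, 0)
  expect_equal(sw$metrics$d_net_um, 0)
  expect_equal(sw$metrics$n_clusters, 1)
  expect_equal(sw$metrics$mean_cluster_size, 69)
})

test_that("sweeps are deterministic and carry one row per run", {
  cfg <- scenario_config(J_cc = c(1, 40), lambda = c(0.01, 0.05), xi = 150,
                         n_mcs = 3, n_replicates = 2, base_seed = 11,
                         scale = 0.5)
  sw1 <- run_scenario(cfg)
  sw2 <- run_scenario(cfg)
  expect_equal(nrow(sw1$metrics), 2 * 2 * 2)
  expect_identical(sw1$metrics, sw2$metrics)
  expect_identical(sw1$series, sw2$series)
  expect_equal(sw1$manifest$seeds, c(12, 13))    # base_seed + replicate
  # same replicate seed -> same mesh across conditions (paired design)
  expect_equal(unique(table(sw1$metrics$seed)), 4L)
})

test_that("the adhesion override sets cell-ECM equal to cell-fluid energy", {
  cfg <- scenario_config(J_cc = 1, xi = 100, n_mcs = 1, n_replicates = 1,
                         scale = 0.5, cell_ecm_adhesion_override = TRUE)
  inp <- invadopotts:::build_run_inputs(
    data.frame(condition = 1, J_cc = 1, lambda = 0.05, xi = 100,
               psi = "random"), cfg, energy_params(), seed = 2)
  expect_equal(inp$epar$J_ce, inp$epar$J_cf)
})

test_that("channel and confinement geometries are well-formed", {
  ch <- build_channel_lattice(lattice_px = 250, n_cells = 12)
  expect_equal(ch$n_cells, 12L)
  expect_true(all(cell_stats(ch)$area_px == 100))
  # walls are full-width horizontal fibre rows
  walls <- which(apply(ch$sigma == -1L, 2, all))
  expect_gt(length(walls), 10)

  cf <- build_confinement_lattice(lattice_px = 100, radius_px = 32)
  expect_gt(cf$n_cells, 10)
  # every cell sits strictly inside the ring
  st <- cell_stats(cf)
  r <- sqrt((st$cx_um - 100)^2 + (st$cy_um - 100)^2) / 2
  expect_true(all(r < 32))
})

test_that("active motility is required for calibrated migration speeds", {
  cfg <- scenario_config(J_cc = 16, lambda = 0, xi = 0, proteolysis = FALSE,
                         n_mcs = 100, n_replicates = 2, base_seed = 1,
                         geometry = "channels")
  fast <- calibrate_speed(cfg, energy_params())
  slow <- calibrate_speed(cfg, energy_params(mu0 = 0))
  # without active motility the noise-driven baseline falls below the
  # calibration acceptance band (23 um/h +/- 25%)
  expect_lt(slow$speed_um_h, 0.75 * 23)
  expect_lt(slow$speed_um_h, fast$speed_um_h)
  # doubling motility strictly increases speed
  faster <- calibrate_speed(cfg, energy_params(mu0 = 1200))
  expect_gt(faster$speed_um_h, fast$speed_um_h)
})
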