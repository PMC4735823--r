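test_that("total distance and net translocation on constructed paths", {
  fx <- make_fixture("round_trip")
  expect_equal(total_distance(fx$trajectory), 20)   # 5 px out + 5 back, in um
  expect_equal(net_translocation(fx$trajectory), 0)

  # one cell moving 1 px per step for 5 steps: 10 um total and net
  traj <- data.frame(mcs = 0:5, cell_id = 1L, x_um = 2 * (0:5), y_um = 0)
  expect_equal(total_distance(traj), 10)
  expect_equal(net_translocation(traj), 10)

  # stationary cells
  traj0 <- data.frame(mcs = 0:3, cell_id = 1L, x_um = 4, y_um = 4)
  expect_equal(total_distance(traj0), 0)

  # single time point warns and returns 0
  expect_warning(d <- total_distance(traj[1, ]), "single time point")
  expect_equal(d, 0)
})

test_that("net translocation never exceeds total distance", {
  set.seed(13)
  for (rep in 1:20) {
    n_cells <- sample(2:6, 1); n_t <- sample(3:30, 1)
    traj <- expand.grid(mcs = seq_len(n_t), cell_id = seq_len(n_cells))
    traj$x_um <- stats::rnorm(nrow(traj), sd = 5)
    traj$y_um <- stats::rnorm(nrow(traj), sd = 5)
    expect_lte(net_translocation(traj), total_distance(traj) + 1e-12)
  }
})

test_that("radius of gyration follows the root-mean-square definition", {
  expect_equal(radius_of_gyration(cbind(c(0, 0), c(0, 0)), c(0, 0)), 0)
  expect_equal(radius_of_gyration(cbind(3, 4), c(0, 0)), 5)
  pos <- rbind(c(10, 0), c(0, 10), c(20, 0), c(0, 20))
  expect_equal(radius_of_gyration(pos, c(0, 0)), sqrt(250))
  expect_equal(sqrt(250), 15.81, tolerance = 1e-3)
})

test_that("RoG of the untouched aggregate equals the block-layout closed form", {
  lay <- build_initial_aggregate()
  lat <- build_lattice(NULL, lay)
  st <- cell_stats(lat)
  got <- radius_of_gyration(cbind(st$cx_um, st$cy_um), c(500, 500))
  # analytic: block centres at 500 + 20*m um with the centre-in-disk rule
  centres <- do.call(rbind, lapply(lay$cell_pixel_map, function(px) {
    colMeans(px - 0.5) * 2
  }))
  expected <- sqrt(mean((centres[, 1] - 500)^2 + (centres[, 2] - 500)^2))
  expect_equal(got, expected)
  offs <- sort(unique(round(centres[, 1] - 500)))
  expect_true(all(offs %% 20 == 0))
})

test_that("percent ECM degradation is exact arithmetic with guarded input", {
  expect_equal(percent_ecm_degradation(1000, 1000), 0)
  expect_equal(percent_ecm_degradation(1000, 900), 10)
  expect_equal(percent_ecm_degradation(500, 0), 100)
  expect_error(percent_ecm_degradation(0, 0), "undefined")
})

test_that("cluster statistics agree with brute-force contact search", {
  # intact aggregate: one cluster of 69
  lat <- build_lattice(NULL, build_initial_aggregate())
  cl <- cluster_stats(lat)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$sizes, 69L)

  # mutually detached cells: one cluster each
  sg <- matrix(0L, 40, 40)
  for (k in 1:9) {
    i0 <- 4 * ((k - 1) %% 3) * 3 + 2; j0 <- 12 * ((k - 1) %/% 3) + 2
    sg[i0:(i0 + 1), j0:(j0 + 1)] <- k
  }
  expect_equal(cluster_stats(sim_lattice(sg))$n_clusters, 9L)

  # hand-built components {3, 2, 1}: cells 1-2-3 chained, 4-5 touching, 6 alone
  sg <- matrix(0L, 30, 30)
  sg[2:4, 2:4] <- 1L; sg[5:7, 2:4] <- 2L; sg[8:10, 2:4] <- 3L
  sg[2:4, 10:12] <- 4L; sg[2:4, 13:15] <- 5L
  sg[20:22, 20:22] <- 6L
  cl <- cluster_stats(sim_lattice(sg))
  expect_equal(cl$n_clusters, 3L)
  expect_equal(cl$sizes, c(3L, 2L, 1L))
  orc <- oracle_clusters(sg)
  expect_equal(cl$n_clusters, orc$n)
  expect_equal(cl$sizes, orc$sizes)

  # random lattices: partition property and oracle agreement
  set.seed(31)
  for (rep in 1:10) {
    sg <- random_toy_sigma(25, p_fibre = 0.1, n_cells = 6)
    if (max(sg) < 1) next
    cl <- cluster_stats(sim_lattice(sg))
    orc <- oracle_clusters(sg)
    expect_equal(cl$n_clusters, orc$n)
    expect_equal(cl$sizes, orc$sizes)
    expect_equal(sum(cl$sizes), length(unique(sg[sg >= 1L])))
    expect_equal(cl$n_clusters * cl$mean_size, sum(cl$sizes))
  }
})

test_that("metrics report assembles a consistent one-row panel", {
  lat <- build_lattice(generate_fibre_mesh(30, seed = 3, lattice_px = 100),
                       build_initial_aggregate(30, lattice_px = 100))
  fib0 <- sum(lat$sigma == -1L)
  st <- initialize_state(lat, energy_params(), mmp_params(lambda = 0.05))
  res <- run_simulation(st, 15, seed = 2)
  m <- metrics_report(res, fib0, centre_um = c(100, 100))
  expect_equal(nrow(m), 1L)
  expect_lte(m$d_net_um, m$d_total_um)
  expect_gte(m$pct_degradation, 0)
  expect_lte(m$pct_degradation, 100)
  expect_gte(m$n_clusters, 1)
  expect_equal(m$n_clusters * m$mean_cluster_size,
               sum(cluster_stats(res$state$sigma)$sizes))
})
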