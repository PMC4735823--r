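test_that("fibre rasterization matches enumerated Bresenham chains", {
  # horizontal 30-um segment: pixels x = 0..15 at y = 0
  px <- rasterize_segment(fibre_segment(c(0, 0), c(30, 0)))
  expect_equal(nrow(px), 16L)
  expect_true(all(px[, "j"] == 1L))
  expect_equal(sort(px[, "i"]), 1:16)

  # 45-degree segment of length 40 um: endpoints land in pixels (0,0) and
  # (14,14), an 8-connected diagonal chain of 15 pixels
  px <- rasterize_segment(fibre_segment(c(0, 0), c(28.28, 28.28)))
  expect_equal(nrow(px), 15L)
  expect_true(all(px[, "i"] == px[, "j"]))

  # zero-length segment collapses to a single pixel
  expect_equal(nrow(rasterize_segment(fibre_segment(c(10, 10), c(10, 10)))), 1L)
})

test_that("per-segment pixel counts stay inside the Bresenham band", {
  mesh <- generate_fibre_mesh(400, "random", seed = 11)
  for (k in seq_len(nrow(mesh$segments))) {
    s <- mesh$segments[k, ]
    L <- sqrt((s$x1 - s$x0)^2 + (s$y1 - s$y0)^2)  # clipped length, um
    n <- nrow(rasterize_segment(fibre_segment(c(s$x0, s$y0), c(s$x1, s$y1))))
    expect_gte(n, floor(ceiling(L / 2) / sqrt(2)))
    expect_lte(n, ceiling(L / 2) + 1)
  }
  # union of rasterized segments, deduplicated, is the mesh pixel set
  expect_lte(nrow(mesh$pixels), 400 * 21)
  expect_gte(nrow(mesh$pixels), 400 * 10)   # heavy overlap would be a bug
  expect_false(any(duplicated(mesh$pixels)))
})

test_that("mesh generation respects mode, count, seed and errors", {
  expect_error(generate_fibre_mesh(-1), "non-negative")
  empty <- generate_fibre_mesh(0, "random", seed = 1)
  expect_equal(nrow(empty$pixels), 0L)

  m1 <- generate_fibre_mesh(50, "random", seed = 7)
  m2 <- generate_fibre_mesh(50, "random", seed = 7)
  expect_identical(m1$pixels, m2$pixels)

  al <- generate_fibre_mesh(1000, "aligned", seed = 3)
  expect_true(all(al$segments$angle == 0))
  expect_equal(stats::var(al$segments$angle), 0)
  expect_true(all(al$segments$length >= 30 & al$segments$length <= 40))
  # all clipped endpoints inside the 1000-um frame
  expect_true(all(al$segments$x0 >= 0 & al$segments$x1 <= 1000))
})

test_that("random meshes have circularly uniform axial angles (Rayleigh)", {
  mesh <- generate_fibre_mesh(600, "random", seed = 21)
  th <- 2 * mesh$segments$angle          # axial data doubled to the circle
  n <- length(th)
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  expect_gt(p, 0.01)
})

test_that("fibre pixel count grows with fibre number across seeds", {
  mean_px <- function(xi) {
    mean(vapply(1:20, function(s) {
      nrow(generate_fibre_mesh(xi, "random", seed = 1000 + s)$pixels)
    }, numeric(1)))
  }
  counts <- c(mean_px(400), mean_px(600), mean_px(1000))
  expect_true(all(diff(counts) > 0))
})

test_that("initial aggregate packs 69 disjoint 100-pixel cells", {
  lay <- build_initial_aggregate()
  expect_equal(lay$n_cells, 69L)
  all_px <- do.call(rbind, lay$cell_pixel_map)
  expect_equal(nrow(all_px), 69L * 100L)
  expect_false(any(duplicated(all_px)))
  expect_true(all(vapply(lay$cell_pixel_map, nrow, integer(1)) == 100L))

  # the packing rule is deterministic
  expect_identical(build_initial_aggregate()$cell_pixel_map,
                   lay$cell_pixel_map)
  # 90 um is the smallest disk radius yielding 69 cells in 1-px steps
  expect_equal(aggregate_radius_for_n(69), 90)
  # one-block disk
  expect_equal(build_initial_aggregate(disk_radius = 10)$n_cells, 1L)
  expect_error(build_initial_aggregate(disk_radius = 600),
               "does not fit")
})

test_that("cells overwrite fibres at initialization and never overlap", {
  mesh <- generate_fibre_mesh(600, "random", seed = 2)
  lay <- build_initial_aggregate()
  lat <- build_lattice(mesh, lay)
  # no pixel is simultaneously cell and fibre by construction; the removed
  # count is consistent with the mesh/aggregate overlap
  overlap <- sum(duplicated(rbind(mesh$pixels, do.call(rbind, lay$cell_pixel_map))))
  expect_equal(lat$removed_fibre_px, overlap)
  expect_equal(sum(lat$sigma == -1L), nrow(mesh$pixels) - overlap)
  st <- cell_stats(lat)
  expect_true(all(st$area_px == 100))
  # centroid of the central cell block sits on the lattice centre (500 um)
  expect_true(any(abs(st$cx_um - 500) < 1e-9 & abs(st$cy_um - 500) < 1e-9))
})
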