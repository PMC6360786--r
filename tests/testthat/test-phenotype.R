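test_that("plant height is the maximum normalized z, NA when empty", {
  expect_equal(plant_height(fab_plant(rbind(c(0.1, 0.1, 0.41)))), 0.41)
  empty <- plant_cloud(NULL, "e", cell_bounds = c(0, 0, 0.5, 0.3),
                       missing = TRUE)
  expect_true(is.na(plant_height(empty)))
  # max semantics: a residual outlier dominates (denoise first!)
  p <- fab_plant(rbind(c(0.1, 0.1, 1.2), c(0.2, 0.2, 9)))
  expect_equal(plant_height(p), 9)
})

test_that("voxel occupancy is binary and matches the exhaustive oracle", {
  # two points in one voxel count once
  p <- fab_plant(rbind(c(0.101, 0.101, 0.501), c(0.102, 0.102, 0.502),
                       c(0.3, 0.2, 1.0)))
  g <- voxelize(p, 0.05)
  expect_equal(sum(g$slab_occupied), 2)
  expect_true(all(g$n_l + g$n_p ==
                    vapply(1:5, function(k)
                      sum(g$layer_of_slab == k) * g$slab_total, 0)))
  # random cloud vs brute-force per-voxel membership
  set.seed(33)
  pts <- cbind(runif(400, 0, 0.5), runif(400, 0, 0.3), runif(400, 0, 1.0))
  pts[1, ] <- c(0.2, 0.1, 1.0)  # pin the height
  pl <- fab_plant(pts)
  vg <- voxelize(pl, 0.07)
  occ_brute <- unique(cbind(pmin(floor(pts[, 1] / 0.07), vg$dims[1] - 1),
                            pmin(floor(pts[, 2] / 0.07), vg$dims[2] - 1),
                            pmin(floor(pts[, 3] / 0.07), vg$dims[3] - 1)))
  expect_equal(nrow(vg$occupied), nrow(occ_brute))
  expect_equal(sum(vg$slab_occupied),
               nrow(occ_brute))
  for (z in 0:(vg$dims[3] - 1))
    expect_equal(vg$slab_occupied[z + 1], sum(occ_brute[, 3] == z))
  expect_error(voxelize(pl, 2), "height")
  expect_error(voxelize(pl, 0), "positive")
})

test_that("the printed PAD formula evaluates exactly", {
  g1 <- fab_grid(n_l = 50, n_p = 50, delta_h = 1)
  expect_equal(compute_pad(g1, 1, pad_config(theta_c = 0, G = 0.5)), 1.0,
               tolerance = 1e-15)
  g2 <- fab_grid(n_l = 20, n_p = 80, delta_h = 0.36)
  got <- compute_pad(g2, 1, pad_config(theta_c = 60 * pi / 180, G = 0.5))
  expect_equal(got, cos(pi / 3) / 0.5 / 0.36 * 0.2, tolerance = 1e-15)
  # zero occupancy gives zero PAD
  g3 <- fab_grid(n_l = 0, n_p = 100, delta_h = 0.5)
  expect_equal(compute_pad(g3, 1), 0)
  expect_error(compute_pad(g1, 7), "k")
})

test_that("PAD is bounded by its occupancy limit", {
  set.seed(34)
  for (i in 1:20) {
    pts <- cbind(runif(200, 0, 0.5), runif(200, 0, 0.3), runif(200, 0, 1.5))
    pl <- fab_plant(pts)
    cfg <- pad_config(theta_c = runif(1, 0, 1), G = runif(1, 0.3, 0.8))
    g <- voxelize(pl, runif(1, 0.02, 0.2))
    for (k in 1:5)
      expect_lte(compute_pad(g, k, cfg),
                 cos(cfg$theta_c) / (cfg$G * g$delta_h) + 1e-12)
  }
})

test_that("PAI follows the printed sum and the consistent mode", {
  expect_equal(compute_pai(rep(0, 5)), 0)
  expect_equal(compute_pai(c(0.2, 0.5, 0.6, 0.4, 0.3)), 2.0)
  expect_equal(compute_pai(c(0.2, 0.5, 0.6, 0.4, 0.3), delta_h = 0.36,
                           units_consistent = TRUE), 2.0 * 0.36)
  expect_true(is.na(compute_pai(c(0.2, NA, 0.6, 0.4, 0.3))))
})

test_that("occupancy fraction is non-decreasing under voxel doubling", {
  set.seed(35)
  pts <- cbind(runif(600, 0, 0.512), runif(600, 0, 0.256),
               runif(600, 0, 1.024))
  pts[1, 3] <- 1.024  # exact height so all dyadic sizes divide the box
  pl <- fab_plant(pts, cell_bounds = c(0, 0, 0.512, 0.256))
  sizes <- c(0.004, 0.008, 0.016, 0.032, 0.064)
  frac <- vapply(sizes, function(v) {
    g <- voxelize(pl, v)
    sum(g$slab_occupied) / (g$slab_total * g$dims[3])
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("PLA handles full cover, degenerate spacing and translation", {
  # points on every pixel center of a small cell: PLA = 1
  cb <- c(0, 0, 0.05, 0.03)
  g <- expand.grid(x = seq(0.0005, 0.0495, by = 0.001),
                   y = seq(0.0005, 0.0295, by = 0.001))
  p <- fab_plant(cbind(g$x, g$y, 0.5), cell_bounds = cb)
  expect_equal(compute_pla(p), 1.0)
  # two coincident x-y points: the floor engages, one pixel occupied
  p2 <- fab_plant(rbind(c(0.01, 0.01, 0.2), c(0.01, 0.01, 0.6)),
                  cell_bounds = cb)
  expect_equal(compute_pla(p2), 1 / (50 * 30))
  expect_true(is.na(compute_pla(fab_plant(rbind(c(0.01, 0.01, 0.2)),
                                          cell_bounds = cb))))
  # a dense compact patch of 0.03 m^2 in the 0.15 m^2 cell tends to 0.20
  side <- sqrt(0.03)
  gg <- expand.grid(x = seq(0.16, 0.16 + side, by = 5e-4),
                    y = seq(0.06, 0.06 + side, by = 5e-4))
  p3 <- fab_plant(cbind(gg$x, gg$y, 0.8))
  expect_equal(compute_pla(p3), 0.2, tolerance = 0.01)
  # rigid in-plane translation inside the cell barely moves PLA
  set.seed(37)
  pts <- cbind(runif(3000, 0.1, 0.3), runif(3000, 0.05, 0.2),
               runif(3000, 0, 1))
  a <- compute_pla(fab_plant(pts))
  b <- compute_pla(fab_plant(sweep(pts, 2, c(0.07, 0.041, 0))))
  expect_equal(a, b, tolerance = 0.05)
})

test_that("voxel-size calibration selects the error-minimizing size", {
  sp <- demo_spec()
  g <- generate_plant(sp, point_spacing = 0.004, seed = 51)
  pl <- fab_plant(g$cloud$points)
  cal <- calibrate_voxel_size(pl, g$truth,
                              sizes = seq(0.001, 0.012, by = 0.0005))
  expect_equal(nrow(cal$curve), 23L)
  expect_equal(cal$optimal_size,
               cal$curve$voxel_size[which.min(cal$curve$pad_error)])
  # when truth equals the estimate at some size, that size is selected
  mid <- 0.006
  vg <- voxelize(pl, mid)
  pads <- compute_pad_profile(vg)
  truth2 <- g$truth
  truth2[paste0("true_pad_l", 1:5)] <- as.list(pads)
  cal2 <- calibrate_voxel_size(pl, truth2, sizes = c(0.003, mid, 0.009))
  expect_equal(cal2$optimal_size, mid)
  expect_error(calibrate_voxel_size(pl, g$truth, sizes = numeric(0)),
               "empty")
})

test_that("extract_phenotypes produces a full, consistent table", {
  specs <- sample_plant_specs(2, height_range = c(1.0, 1.4), seed = 61)
  sc <- generate_scene(scene_spec(2, 1, terrain_amplitude = 0,
                                  outlier_rate = 0, occlusion_rate = 0,
                                  seed = 61), specs, stage = "D45")
  keep <- sc$cloud$label == "vegetation" &
    sc$cloud$points[, 1] >= 0 & sc$cloud$points[, 1] < 1 &
    sc$cloud$points[, 2] >= 0 & sc$cloud$points[, 2] < 0.3
  plants <- segment_grid(subset_cloud(sc$cloud, keep), origin = c(0, 0),
                         n_cols = 2, n_rows = 1, stage = "D45")
  ph <- extract_phenotypes(plants)
  expect_equal(nrow(ph), 2L)
  expect_true(all(c("height", "pad_l1", "pad_l5", "pai", "pai_printed",
                    "pla") %in% names(ph)))
  # printed PAI is the plain sum, consistent PAI the height-weighted sum
  expect_equal(ph$pai_printed[1], sum(unlist(ph[1, paste0("pad_l", 1:5)])))
  expect_equal(ph$pai[1], ph$pai_printed[1] * ph$height[1] / 5,
               tolerance = 1e-9)
  expect_equal(ph$height, sc$truth$true_height, tolerance = 0.02)
})
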