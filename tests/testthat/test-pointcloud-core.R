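test_that("point-cloud IO round trips across formats", {
  dir <- withr::local_tempdir()
  set.seed(1)
  pc <- point_cloud(cbind(runif(1000, 0, 5), runif(1000, 0, 3),
                          runif(1000, 0, 2)))
  # binary PLY: exact (double precision)
  write_cloud(pc, file.path(dir, "a.ply"))
  expect_identical(read_cloud(file.path(dir, "a.ply"))$points, pc$points)
  # ascii PLY
  write_cloud(pc, file.path(dir, "b.ply"), binary = FALSE)
  expect_equal(read_cloud(file.path(dir, "b.ply"))$points, pc$points,
               tolerance = 1e-12)
  # XYZ text
  write_cloud(pc, file.path(dir, "c.xyz"))
  expect_equal(read_cloud(file.path(dir, "c.xyz"))$points, pc$points,
               tolerance = 1e-12)
  # LAS: quantized to the header scale
  write_cloud(pc, file.path(dir, "d.las"), scale = 0.001)
  back <- read_cloud(file.path(dir, "d.las"))
  expect_equal(n_points(back), 1000L)
  expect_lt(max(abs(back$points - pc$points)), 0.001 / 2 + 1e-9)
})

test_that("IO edge cases behave", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.xyz")
  file.create(f)
  expect_equal(n_points(read_cloud(f)), 0L)
  expect_error(read_cloud(file.path(dir, "x.weird")), "format")
  expect_error(read_cloud(file.path(dir, "missing.ply")), "exist")
  writeLines(c("1 2 3", "4 five 6"), file.path(dir, "bad.xyz"))
  expect_error(read_cloud(file.path(dir, "bad.xyz")), "malformed|line")
  # empty cloud round trips
  e <- point_cloud(NULL)
  for (fmt in c("ply", "las", "xyz")) {
    p <- file.path(dir, paste0("e.", fmt))
    write_cloud(e, p)
    expect_equal(n_points(read_cloud(p)), 0L)
  }
})

test_that("outlier removal matches its definition and the brute force", {
  # uniform 10 x 10 grid plus one far point: exactly the far point goes
  g <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  pts <- rbind(cbind(g, 0), c(50, 50, 5))
  res <- remove_outliers(point_cloud(pts), k_neighbors = 8, n_sigma = 3)
  expect_equal(res$removed, 1L)
  expect_equal(res$removed_idx, 101L)
  # perfectly uniform spacing (a ring: every point has identical neighbor
  # geometry): zero spread, nothing removed at any n
  th <- 2 * pi * (0:59) / 60
  ring <- cbind(cos(th), sin(th), 0)
  res2 <- remove_outliers(point_cloud(ring), k_neighbors = 4,
                          n_sigma = 1e-6)
  expect_equal(res2$removed, 0L)
  # 500 Gaussian points + 10 planted outliers vs O(N^2) recomputation
  set.seed(42)
  pts3 <- rbind(matrix(rnorm(1500), ncol = 3),
                matrix(rnorm(30, mean = 12), ncol = 3))
  md <- brute_knn_mean(pts3, 10)
  thr <- mean(md) + 3 * sd(md)
  res3 <- remove_outliers(point_cloud(pts3), k_neighbors = 10, n_sigma = 3)
  expect_setequal(res3$removed_idx, which(md > thr))
  expect_gte(res3$removed, 10L)  # at least the planted ones
  expect_error(remove_outliers(point_cloud(pts3[1:5, ]), k_neighbors = 10),
               "k_neighbors")
})

test_that("ground classification separates flat ground from plants", {
  set.seed(7)
  g <- cbind(runif(4000, 0, 4), runif(4000, 0, 2), 0)
  cl <- classify_ground(point_cloud(g))
  expect_true(all(cl$label == "ground"))
  plant <- cbind(runif(500, 1.8, 2.2), runif(500, 0.8, 1.2),
                 runif(500, 0.3, 1.5))
  cl2 <- classify_ground(point_cloud(rbind(g, plant)), max_dist = 0.1)
  expect_true(all(cl2$label[1:4000] == "ground"))
  expect_true(all(cl2$label[4001:4500] == "vegetation"))
  expect_error(classify_ground(point_cloud(cbind(0.1, 0.1, 0))),
               "seed cells")
})

test_that("labels partition the cloud after classification", {
  set.seed(8)
  pts <- cbind(runif(2000, 0, 3), runif(2000, 0, 3),
               c(rep(0, 1500), runif(500, 0.5, 1)))
  cl <- classify_ground(point_cloud(pts))
  expect_true(all(cl$label %in% c("ground", "vegetation")))
})

test_that("kriged DTM reproduces constants, planes and data points", {
  set.seed(3)
  xy <- cbind(runif(500, 0, 2), runif(500, 0, 2))
  # constant field
  dtm <- build_dtm(point_cloud(cbind(xy, 2.0)), resolution = 0.1)
  expect_equal(as.vector(dtm$z), rep(2.0, length(dtm$z)), tolerance = 1e-8)
  # analytic plane
  z <- 0.01 * xy[, 1] + 0.02 * xy[, 2]
  dtm2 <- build_dtm(point_cloud(cbind(xy, z)), resolution = 0.1)
  cx <- dtm2$origin[1] + (seq_len(ncol(dtm2$z)) - 0.5) * 0.1
  cy <- dtm2$origin[2] + (seq_len(nrow(dtm2$z)) - 0.5) * 0.1
  want <- outer(cy, cx, function(y, x) 0.01 * x + 0.02 * y)
  # interpolated cells (inside the data extent); rim cells extrapolate
  inx <- cx > min(xy[, 1]) & cx < max(xy[, 1])
  iny <- cy > min(xy[, 2]) & cy < max(xy[, 2])
  expect_lt(max(abs(dtm2$z[iny, inx] - want[iny, inx])), 1e-3)
  # exact interpolation at a colocated cell center: place a spiked data
  # point exactly on a known interior cell center (the origin is set by the
  # unchanged extent of the base points)
  res <- 0.1
  ctr <- c(dtm2$origin[1] + 7.5 * res, dtm2$origin[2] + 6.5 * res)
  pts <- rbind(cbind(xy, z), c(ctr, 5))
  dtm3 <- build_dtm(point_cloud(pts), resolution = res)
  expect_equal(dtm3$origin, dtm2$origin)
  expect_equal(dtm3$z[7, 8], 5)
  expect_error(build_dtm(point_cloud(cbind(xy[1:5, ], 0))), "ground points")
})

test_that("height normalization subtracts the terrain", {
  set.seed(5)
  xy <- cbind(runif(100, 0, 1), runif(100, 0, 1))
  dtm <- build_dtm(point_cloud(cbind(xy, 1.0)), resolution = 0.05)
  cl <- normalize_heights(point_cloud(cbind(0.5, 0.5, 2.5)), dtm)
  expect_equal(unname(cl$points[1, 3]), 1.5, tolerance = 1e-6)
  # normalizing the ground returns themselves lands near zero
  gr <- normalize_heights(point_cloud(cbind(xy, 1.0)), dtm)
  expect_lt(max(abs(gr$points[, 3])), 1e-6)
  expect_error(normalize_heights(point_cloud(cbind(9, 9, 1)), dtm),
               "outside the DTM")
})

test_that("resampling reaches the target density and is reproducible", {
  set.seed(9)
  n <- 6000
  pts <- cbind(runif(n, 0, 1), runif(n, 0, 0.6), 0)  # 2D Poisson, ~5 mm nn
  cl <- point_cloud(pts)
  cur <- avg_point_distance(cl)
  expect_identical(resample_to_point_distance(cl, cur, seed = 1), cl)
  out <- resample_to_point_distance(cl, 2 * cur, seed = 1)
  expect_lte(n_points(out), n)
  got <- avg_point_distance(out)
  expect_lt(abs(got - 2 * cur) / (2 * cur), 0.08)
  # density-scaling: doubling the nn distance of a Poisson cloud keeps ~1/4
  expect_equal(n_points(out) / n, 0.25, tolerance = 0.1)
  out2 <- resample_to_point_distance(cl, 2 * cur, seed = 1)
  expect_identical(out$points, out2$points)
  expect_error(resample_to_point_distance(cl, cur / 2), "below the current")
})

test_that("DTM writes a well-formed ESRI ASCII grid", {
  dir <- withr::local_tempdir()
  set.seed(2)
  dtm <- build_dtm(point_cloud(cbind(runif(50), runif(50), 1)),
                   resolution = 0.2)
  f <- file.path(dir, "dtm.asc")
  write_dtm_asc(dtm, f)
  hdr <- readLines(f, n = 6)
  expect_match(hdr[1], "^ncols")
  expect_equal(length(readLines(f)) - 6L, nrow(dtm$z))
})
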