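#' Statistical outlier removal
#'
#' Classic k-nearest-neighbor outlier filtering: each point's mean distance to
#' its `k_neighbors` nearest neighbors is computed; points whose mean distance
#' exceeds `avg + n_sigma * std` of these means (global average and standard
#' deviation) are removed.
#'
#' @param cloud a `point_cloud` with more than `k_neighbors` points.
#' @param k_neighbors number of neighbors per point (default 10).
#' @param n_sigma threshold multiplier n (default 3).
#' @return a list with `cloud` (the filtered `point_cloud`), `removed`
#'   (number of points removed), `removed_idx` (their indices in the input)
#'   and `threshold` (the distance cutoff applied).
#' @export
remove_outliers <- function(cloud, k_neighbors = 10L, n_sigma = 3) {
  stopifnot(inherits(cloud, "point_cloud"), k_neighbors >= 1L, n_sigma > 0)
  n <- n_points(cloud)
  if (n <= k_neighbors)
    stop("cloud has ", n, " points; need more than k_neighbors = ", k_neighbors)
  d <- FNN::get.knn(cloud$points, k = as.integer(k_neighbors))$nn.dist
  mean_d <- rowMeans(d)
  spread <- stats::sd(mean_d)
  # a spread below machine tolerance is a degenerate (perfectly uniform)
  # cloud: nothing is an outlier, and the filter is idempotent there
  if (spread < 1e-12 * max(mean(mean_d), 1e-300)) spread <- 0
  thr <- mean(mean_d) + n_sigma * spread
  drop <- if (spread == 0) integer(0) else which(mean_d > thr)
  out <- if (length(drop)) subset_cloud(cloud, -drop) else cloud
  list(cloud = out, removed = length(drop), removed_idx = drop, threshold = thr)
}

#' Ground classification by progressive TIN densification
#'
#' Simplified progressive triangulated-irregular-network densification: seed
#' points are the lowest point of each coarse grid cell; a Delaunay
#' triangulation of the seeds is built and iteratively densified with points
#' whose vertical distance to the containing triangle is at most `max_dist`
#' and whose angles to the triangle's vertices are at most `max_angle`.
#' All points accepted by the final surface are labeled `"ground"`, the rest
#' `"vegetation"`.
#'
#' @param cloud a non-empty `point_cloud`.
#' @param cell seed-grid cell size in meters (default 1.0).
#' @param max_angle maximum point-to-vertex elevation angle in degrees
#'   (default 30).
#' @param max_dist maximum vertical distance to the TIN facet in meters
#'   (default 0.05).
#' @param iterations densification iterations (default 3).
#' @return the `point_cloud` with every point labeled ground or vegetation.
#' @export
classify_ground <- function(cloud, cell = 1.0, max_angle = 30, max_dist = 0.05,
                            iterations = 3L) {
  stopifnot(inherits(cloud, "point_cloud"), cell > 0, max_dist > 0,
            max_angle > 0, iterations >= 1L)
  n <- n_points(cloud)
  if (n == 0L) stop("cannot classify an empty cloud")
  pts <- cloud$points
  seeds <- lowest_per_cell(pts, cell)
  if (length(seeds) < 3L)
    stop("only ", length(seeds), " seed cells; need at least 3 to triangulate")
  # a cell holding only canopy (e.g. leaf overhang beyond the plot rim) gives
  # a high seed; screen seeds against the median of their neighboring seeds,
  # keeping low ones (low is safe, high is suspect)
  if (length(seeds) > 4L) {
    sp <- pts[seeds, , drop = FALSE]
    k <- min(4L, length(seeds) - 1L)
    nn <- FNN::get.knn(sp[, 1:2, drop = FALSE], k = k)$nn.index
    med <- apply(matrix(sp[nn, 3], nrow = nrow(sp)), 1, stats::median)
    seeds <- seeds[sp[, 3] - med <= 3 * max_dist]
    if (length(seeds) < 3L)
      stop("fewer than 3 seed cells survive elevation screening")
  }
  # boundary pseudo-vertices keep the whole extent inside the triangulation
  # (the per-cell minima alone leave a rim outside their convex hull)
  vpts <- rbind(pts[seeds, , drop = FALSE], boundary_vertices(pts, seeds, cell))
  ground <- rep(FALSE, n)
  ground[seeds] <- TRUE
  tan_max <- tan(max_angle * pi / 180)
  for (it in seq_len(iterations)) {
    surf <- tin_surface(vpts)
    cand <- which(!ground)
    if (!length(cand)) break
    ev <- tin_evaluate(surf, pts[cand, , drop = FALSE])
    dz <- pts[cand, 3] - ev$z
    ok <- is.finite(ev$z) & abs(dz) <= max_dist & ev$tan_angle <= tan_max
    ground[cand[ok]] <- TRUE
    # grow the TIN with the lowest newly accepted point per refined cell
    if (it < iterations && any(ok)) {
      newly <- cand[ok]
      sub <- lowest_per_cell(pts[newly, , drop = FALSE], cell / 2^it)
      vpts <- rbind(vpts, pts[newly[sub], , drop = FALSE])
    }
  }
  cloud$label <- ifelse(ground, "ground", "vegetation")
  cloud
}

# pseudo-vertices along the bounding box, spaced at the seed-cell size, each
# at the elevation of the nearest seed point; they keep the rim inside the
# triangulation without letting a single coarse corner warp a long edge
boundary_vertices <- function(pts, seeds, cell = 1.0) {
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  m <- 0.01 * max(diff(rx), diff(ry), 1)
  bx <- seq(rx[1] - m, rx[2] + m, length.out = max(2L, ceiling(diff(rx) / cell) + 1L))
  by <- seq(ry[1] - m, ry[2] + m, length.out = max(2L, ceiling(diff(ry) / cell) + 1L))
  ring <- rbind(cbind(bx, ry[1] - m), cbind(bx, ry[2] + m),
                cbind(rx[1] - m, by), cbind(rx[2] + m, by))
  ring <- unique(ring)
  sp <- pts[seeds, , drop = FALSE]
  nn <- FNN::get.knnx(sp[, 1:2, drop = FALSE], ring, k = 1L)$nn.index
  cbind(ring, sp[nn, 3])
}

# index of the lowest point in each (cell x cell) x-y bin
lowest_per_cell <- function(pts, cell) {
  ix <- floor(pts[, 1] / cell)
  iy <- floor(pts[, 2] / cell)
  key <- paste(ix, iy)
  idx <- seq_len(nrow(pts))
  o <- order(key, pts[, 3])
  first <- !duplicated(key[o])
  sort(idx[o][first])
}

# Delaunay TIN over vertex points; tiny deterministic jitter breaks the
# cocircular degeneracies of near-regular seed grids
tin_surface <- function(vpts) {
  eps <- 1e-7 * max(diff(range(vpts[, 1])), diff(range(vpts[, 2])), 1)
  set <- (seq_len(nrow(vpts)) * 2654435761) %% 1024 / 1024  # deterministic
  xs <- vpts[, 1] + eps * (set - 0.5)
  ys <- vpts[, 2] + eps * (((set * 31) %% 1) - 0.5)
  dd <- deldir::deldir(xs, ys, suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  list(v = vpts, tri = tri)
}

# evaluate TIN at query x-y: interpolated z of containing triangle and the
# largest tan(elevation angle) from the query point to the triangle vertices.
# Queries outside the hull get z = NA.
tin_evaluate <- function(surf, qpts) {
  nq <- nrow(qpts)
  zhat <- rep(NA_real_, nq)
  tana <- rep(Inf, nq)
  v <- surf$v
  unassigned <- rep(TRUE, nq)
  for (t in seq_len(nrow(surf$tri))) {
    a <- v[surf$tri[t, 1], ]; b <- v[surf$tri[t, 2], ]; c <- v[surf$tri[t, 3], ]
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-14) next
    qx <- qpts[, 1] - a[1]; qy <- qpts[, 2] - a[2]
    l2 <- (qx * (c[2] - a[2]) - qy * (c[1] - a[1])) / det
    l3 <- (qy * (b[1] - a[1]) - qx * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    tol <- -1e-10
    inside <- unassigned & l1 >= tol & l2 >= tol & l3 >= tol
    if (!any(inside)) next
    zhat[inside] <- l1[inside] * a[3] + l2[inside] * b[3] + l3[inside] * c[3]
    # elevation angle to each vertex
    tv <- rep(0, sum(inside))
    qi <- qpts[inside, , drop = FALSE]
    for (vv in list(a, b, c)) {
      hd <- sqrt((qi[, 1] - vv[1])^2 + (qi[, 2] - vv[2])^2)
      tv <- pmax(tv, abs(qi[, 3] - vv[3]) / pmax(hd, 1e-9))
    }
    tana[inside] <- tv
    unassigned[inside] <- FALSE
  }
  list(z = zhat, tan_angle = tana)
}

#' Normalize point heights against a DTM
#'
#' Subtracts the bilinearly interpolated terrain elevation from each point's
#' z, so ground points map to approximately 0 and vegetation z becomes height
#' above ground.
#'
#' @param cloud a `point_cloud`.
#' @param dtm a `terrain_model` from [build_dtm()] covering the cloud extent.
#' @return the normalized `point_cloud`.
#' @export
normalize_heights <- function(cloud, dtm) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(dtm, "terrain_model"))
  if (n_points(cloud) == 0L) return(cloud)
  z0 <- dtm_at(dtm, cloud$points[, 1], cloud$points[, 2])
  if (anyNA(z0)) {
    bad <- which(is.na(z0))
    rng <- apply(cloud$points[bad, 1:2, drop = FALSE], 2, range)
    stop(sprintf(
      "%d points fall outside the DTM (x in [%.3f, %.3f], y in [%.3f, %.3f])",
      length(bad), rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
  }
  cloud$points[, 3] <- cloud$points[, 3] - z0
  cloud
}

#' Thin a cloud to a target average point distance
#'
#' Random thinning (seeded, hence reproducible) iterated until the mean 3D
#' nearest-neighbor distance is within 5% of `target`, equalizing point
#' density across scans of different growth stages.
#'
#' @param cloud a `point_cloud`.
#' @param target target mean nearest-neighbor distance in meters; must be at
#'   least the cloud's current value.
#' @param seed integer RNG seed.
#' @param tol relative tolerance on the achieved distance (default 0.05).
#' @return the thinned `point_cloud` (never more points than the input).
#' @export
resample_to_point_distance <- function(cloud, target, seed = 1L, tol = 0.05) {
  stopifnot(inherits(cloud, "point_cloud"), target > 0)
  cur <- avg_point_distance(cloud)
  if (target < cur * (1 - 1e-9))
    stop(sprintf("target %.4g m is below the current average point distance %.4g m",
                 target, cur))
  if (target <= cur * (1 + tol)) return(cloud)
  with_seed(seed, {
    out <- cloud
    # mean nn distance scales roughly as n^(-1/2) on surface-like clouds
    for (i in 1:20) {
      cur <- avg_point_distance(out)
      if (cur >= target * (1 - tol)) break
      keep_frac <- min((cur / target)^2 * 1.05, 0.95)
      keep <- sort(sample.int(n_points(out), max(2L, round(keep_frac * n_points(out)))))
      out <- subset_cloud(out, keep)
    }
    out
  })
}
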