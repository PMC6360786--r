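#' Specification of a synthetic maize plant
#'
#' Describes one plant for the synthetic scene generator: total height, the
#' number of leaves and the one-sided leaf area in each of the five vertical
#' strata (equal fifths of the plant height, root layer excluded), the mean
#' leaf inclination, and the stem diameter.
#'
#' @param height plant height in meters (> 0).
#' @param leaf_count_per_layer integer vector of length 5.
#' @param one_sided_area_per_layer numeric vector of length 5, m^2 (>= 0).
#' @param leaf_inclination_mean mean leaf inclination above horizontal,
#'   degrees (default 50; maize canopies lean erectophile).
#' @param stem_diameter stem diameter in meters (default 0.02).
#' @param projected_fraction_target optional target for the projected canopy
#'   fraction in `[0, 1]`; steers leaf azimuth dispersion (high target spreads
#'   leaves, low target stacks them). The recorded truth is always the exact
#'   rasterized projection, not this target.
#' @return a `plant_spec` object.
#' @export
plant_spec <- function(height, leaf_count_per_layer, one_sided_area_per_layer,
                       leaf_inclination_mean = 50, stem_diameter = 0.02,
                       projected_fraction_target = NULL) {
  stopifnot(is.numeric(height), length(height) == 1L, height > 0,
            length(leaf_count_per_layer) == 5L,
            length(one_sided_area_per_layer) == 5L,
            all(one_sided_area_per_layer >= 0),
            all(leaf_count_per_layer >= 0),
            stem_diameter > 0)
  if (any(one_sided_area_per_layer > 0 & leaf_count_per_layer == 0))
    stop("layers with positive leaf area need at least one leaf")
  if (!is.null(projected_fraction_target))
    stopifnot(projected_fraction_target >= 0, projected_fraction_target <= 1)
  structure(list(height = height,
                 leaf_count_per_layer = as.integer(leaf_count_per_layer),
                 one_sided_area_per_layer = as.numeric(one_sided_area_per_layer),
                 leaf_inclination_mean = leaf_inclination_mean,
                 stem_diameter = stem_diameter,
                 projected_fraction_target = projected_fraction_target),
            class = "plant_spec")
}

#' Generate one synthetic maize plant with exact ground truth
#'
#' Builds a plant in the local frame of its grid cell: the stem is a vertical
#' cylinder of the given height; each leaf is a ruled ribbon surface (tapered
#' width, drooping arc) attached inside its stratum and sized so the summed
#' one-sided area per vertical fifth equals the requested area. Surfaces are
#' sampled on a raster of spacing `point_spacing` (emulating a scanner's
#' regular sweep) with small jitter and optional Gaussian range noise. The
#' truth record is computed from the triangle mesh itself: per-layer areas by
#' exact slab clipping of every triangle, PAD as area / (cell footprint area
#' x layer height), PAI as their height-weighted sum, and PLA as the
#' projected-union fraction over the cell footprint rasterized at 1 mm.
#'
#' @param spec a [plant_spec()].
#' @param point_spacing sensor point spacing in meters (> 0).
#' @param seed integer RNG seed.
#' @param cell_bounds cell footprint `c(xmin, ymin, xmax, ymax)` in meters
#'   (default the 0.50 x 0.30 m planting cell at the origin).
#' @param noise_sd isotropic Gaussian noise added to sampled points, meters
#'   (default 0.001, the order of a phase-shift TLS ranging error at close
#'   range).
#' @param plant_id identifier stored in the truth record.
#' @return a list with `cloud` (a `point_cloud`, labels `"vegetation"`),
#'   `truth` (a one-row data.frame: plant_id, true_height, true_area_l1..l5,
#'   true_pad_l1..l5, true_pai, true_pla, cell x/y min/max), and `mesh`
#'   (the leaf triangle mesh, an N x 9 matrix of vertex coordinates).
#' @export
generate_plant <- function(spec, point_spacing, seed = 1L,
                           cell_bounds = c(0, 0, 0.5, 0.3),
                           noise_sd = 0.001, plant_id = "p1") {
  stopifnot(inherits(spec, "plant_spec"))
  if (point_spacing <= 0) stop("point_spacing must be positive")
  with_seed(seed, {
    built <- build_plant_geometry(spec, cell_bounds)
    # geometry is built around the stem at the origin; shift to cell center
    if (!is.null(built$mesh)) {
      built$mesh[, c(1, 4, 7)] <- built$mesh[, c(1, 4, 7)] + built$center[1]
      built$mesh[, c(2, 5, 8)] <- built$mesh[, c(2, 5, 8)] + built$center[2]
    }
    pts <- sample_plant_points(built, spec, point_spacing, noise_sd)
    truth <- plant_truth(built$mesh, spec$height, cell_bounds, plant_id)
    list(cloud = point_cloud(pts, rep("vegetation", nrow(pts))),
         truth = truth, mesh = built$mesh,
         organ = attr(pts, "organ"))
  })
}

## ---- geometry -------------------------------------------------------------

# A leaf ribbon: centerline in the vertical plane of azimuth `phi`, starting
# at the stem surface with inclination `beta0` (deg above horizontal) and
# drooping linearly to beta0 - droop at the tip; lateral direction is
# horizontal and perpendicular to phi, so the ruled surface area is exactly
# integral(width ds) -- width can be solved analytically for a target area.
leaf_mesh <- function(attach_z, phi, beta0, length, width, stem_r,
                      n_seg = 16L) {
  s <- seq(0, 1, length.out = n_seg + 1L)
  beta <- (beta0 - (beta0 + 45) * s) * pi / 180  # droops past horizontal
  ds <- length / n_seg
  # integrate the centerline (midpoint rule keeps arc length exact)
  bm <- (beta[-1] + beta[-length(beta)]) / 2
  dx <- cumsum(c(0, cos(bm) * ds))
  dz <- cumsum(c(0, sin(bm) * ds))
  cx <- (stem_r + dx) * cos(phi)
  cy <- (stem_r + dx) * sin(phi)
  cz <- attach_z + dz
  # elliptic width taper, zero at the very tip
  w <- width * sqrt(pmax(0, 1 - s^2))
  lx <- -sin(phi); ly <- cos(phi)
  left <- cbind(cx - w / 2 * lx, cy - w / 2 * ly, cz)
  right <- cbind(cx + w / 2 * lx, cy + w / 2 * ly, cz)
  tri <- vector("list", 2L * n_seg)
  for (i in seq_len(n_seg)) {
    tri[[2L * i - 1L]] <- c(left[i, ], right[i, ], left[i + 1L, ])
    tri[[2L * i]] <- c(right[i, ], right[i + 1L, ], left[i + 1L, ])
  }
  do.call(rbind, tri)
}

# one-sided area multiplier of the elliptic taper at the mesh's resolution:
# the ribbon's triangle area is exactly len x width x trapz(sqrt(1-s^2)), so
# the width solved from it reproduces the requested area to machine precision
leaf_taper <- function(n_seg = 16L) {
  s <- seq(0, 1, length.out = n_seg + 1L)
  w <- sqrt(pmax(0, 1 - s^2))
  sum((w[-1] + w[-length(w)]) / 2) / n_seg
}
LEAF_TAPER <- leaf_taper(16L)

# z-range (min, max) of the drooping centerline, per unit arc length,
# relative to the attachment point
leaf_unit_zrange <- function(beta0, n_seg = 16L) {
  s <- seq(0, 1, length.out = n_seg + 1L)
  beta <- (beta0 - (beta0 + 45) * s) * pi / 180
  bm <- (beta[-1] + beta[-length(beta)]) / 2
  z <- cumsum(c(0, sin(bm) / n_seg))
  range(z)
}

build_plant_geometry <- function(spec, cell_bounds) {
  h <- spec$height
  dh <- h / 5
  cw <- cell_bounds[3] - cell_bounds[1]
  ch <- cell_bounds[4] - cell_bounds[2]
  cx <- (cell_bounds[1] + cell_bounds[3]) / 2
  cy <- (cell_bounds[2] + cell_bounds[4]) / 2
  # lateral reach by stratum: leaf length peaks mid-canopy and the flag
  # leaves near the tassel are short, so upper leaves stay near the stem
  reach_cap_by_layer <- 0.45 * c(0.75, 1.0, 1.0, 0.8, 0.5)
  stem_r <- spec$stem_diameter / 2
  # maize is distichous: leaves emerge in two opposite ranks, in the field
  # oriented roughly perpendicular to the planting row; stacked projections
  # keep the projected canopy fraction low even at high PAI. A higher
  # projected_fraction_target loosens the rank alignment.
  tgt <- spec$projected_fraction_target
  az_jitter <- if (is.null(tgt)) 10 else 5 + 80 * tgt  # degrees
  mesh <- NULL
  leaf_no <- 0L
  for (k in 1:5) {
    nl <- spec$leaf_count_per_layer[k]
    ak <- spec$one_sided_area_per_layer[k]
    if (nl == 0L || ak == 0) next
    a_leaf <- ak / nl
    for (j in seq_len(nl)) {
      leaf_no <- leaf_no + 1L
      beta0 <- stats::rnorm(1, spec$leaf_inclination_mean, 15)
      beta0 <- min(max(beta0, 10), 80)
      zr <- leaf_unit_zrange(beta0)
      # keep the ribbon inside its stratum so truth matches the request
      len <- min(0.85 * dh / diff(zr), reach_cap_by_layer[k])
      if (len < 0.03) { beta0 <- 12; zr <- leaf_unit_zrange(beta0)
                        len <- min(0.85 * dh / diff(zr), reach_cap_by_layer[k]) }
      width <- a_leaf / (len * LEAF_TAPER)
      if (width > 0.9 * len) {
        # flatten the leaf: a lower inclination permits a longer ribbon
        beta0 <- 15; zr <- leaf_unit_zrange(beta0)
        len <- min(0.85 * dh / diff(zr), reach_cap_by_layer[k])
        width <- a_leaf / (len * LEAF_TAPER)
      }
      if (width > 1.2 * len)
        stop(sprintf(
          "area request infeasible for layer %d: %.4f m^2 per leaf needs width %.3f m at length %.3f m",
          k, a_leaf, width, len))
      vspan <- len * diff(zr)
      lo <- (k - 1) * dh
      # attach so the whole arc (which rises then droops below the
      # attachment) stays inside [lo, lo + dh]
      z0 <- lo + 0.05 * dh - len * zr[1] +
        stats::runif(1) * max(0.9 * dh - vspan, 0)
      phi <- (180 * (leaf_no %% 2) + stats::rnorm(1, 0, az_jitter)) * pi / 180
      mesh <- rbind(mesh, leaf_mesh(z0, phi, beta0, len, width, stem_r))
    }
  }
  list(mesh = mesh, stem_r = stem_r, height = h,
       center = c(cx, cy), cell_bounds = cell_bounds)
}

sample_plant_points <- function(built, spec, ps, noise_sd) {
  pts <- NULL
  mesh <- built$mesh          # already in cell coordinates
  n_leaf <- 0L
  if (!is.null(mesh)) {
    pts <- sample_mesh_uniform(mesh, ps)
    n_leaf <- if (is.null(pts)) 0L else nrow(pts)
  }
  # stem: cylinder sampled uniformly at the same density, with the top rim
  # always present so the apex is observed
  r <- built$stem_r
  h <- built$height
  ntheta <- max(3L, ceiling(2 * pi * r / ps))
  nz <- max(2L, ceiling(h / ps))
  g <- expand.grid(i = seq_len(ntheta), j = seq_len(nz))
  th <- (g$i - stats::runif(nrow(g))) * 2 * pi / ntheta
  zz <- (g$j - stats::runif(nrow(g))) * h / nz
  stem <- cbind(r * cos(th), r * sin(th), zz)
  rim_t <- seq(0, 2 * pi, length.out = 9L)[-1]
  rim <- cbind(r * cos(rim_t), r * sin(rim_t), h)
  stem[, 1] <- stem[, 1] + built$center[1]
  stem[, 2] <- stem[, 2] + built$center[2]
  rim[, 1] <- rim[, 1] + built$center[1]
  rim[, 2] <- rim[, 2] + built$center[2]
  pts <- rbind(pts, stem, rim)
  if (noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd), ncol = 3)
  pts[, 3] <- pmax(pts[, 3], 0)
  attr(pts, "organ") <- c(rep("leaf", n_leaf),
                          rep("stem", nrow(pts) - n_leaf))
  pts
}

# quasi-blue-noise sampling of a triangle mesh at pitch `ps`: a jittered
# lattice in each triangle's own plane (density 1/ps^2, one point per lattice
# cell). The field pipeline measures phenotypes on a cloud resampled to a
# uniform point distance, whose pattern is evenly spread rather than
# Poisson-clustered; the generator emulates that pattern.
sample_mesh_uniform <- function(mesh, ps) {
  out <- vector("list", nrow(mesh))
  for (i in seq_len(nrow(mesh))) {
    a <- mesh[i, 1:3]
    e1 <- mesh[i, 4:6] - a; e2 <- mesh[i, 7:9] - a
    nrm <- crossprod3(e1, e2)
    area2 <- sqrt(sum(nrm^2))
    if (area2 < 2 * 1e-12) next
    # orthonormal basis of the triangle plane
    u1 <- e1 / sqrt(sum(e1^2))
    v1 <- crossprod3(nrm / area2, u1)
    p1 <- c(sum(e1 * u1), 0)                  # vertex b in plane coords
    p2 <- c(sum(e2 * u1), sum(e2 * v1))       # vertex c in plane coords
    ulim <- range(0, p1[1], p2[1]); vlim <- range(0, p1[2], p2[2])
    off <- stats::runif(2, 0, ps)
    gu <- seq(ulim[1] - off[1], ulim[2] + ps, by = ps)
    gv <- seq(vlim[1] - off[2], vlim[2] + ps, by = ps)
    gx <- rep(gu, times = length(gv)) + stats::runif(length(gu) * length(gv), 0, ps)
    gy <- rep(gv, each = length(gu)) + stats::runif(length(gu) * length(gv), 0, ps)
    # barycentric membership test in plane coordinates
    det <- p1[1] * p2[2] - p2[1] * p1[2]
    l2 <- (gx * p2[2] - gy * p2[1]) / det
    l3 <- (gy * p1[1] - gx * p1[2]) / det
    keep <- l2 >= 0 & l3 >= 0 & l2 + l3 <= 1
    if (!any(keep)) next
    gx <- gx[keep]; gy <- gy[keep]
    out[[i]] <- cbind(a[1] + gx * u1[1] + gy * v1[1],
                      a[2] + gx * u1[2] + gy * v1[2],
                      a[3] + gx * u1[3] + gy * v1[3])
  }
  do.call(rbind, out)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---- analytic truth -------------------------------------------------------

# area of each triangle clipped to z-slabs [breaks[k], breaks[k+1])
mesh_layer_areas <- function(mesh, breaks) {
  nk <- length(breaks) - 1L
  areas <- numeric(nk)
  if (is.null(mesh) || nrow(mesh) == 0L) return(areas)
  for (i in seq_len(nrow(mesh))) {
    tri <- rbind(mesh[i, 1:3], mesh[i, 4:6], mesh[i, 7:9])
    zr <- range(tri[, 3])
    for (k in seq_len(nk)) {
      if (zr[2] <= breaks[k] || zr[1] >= breaks[k + 1L]) next
      poly <- clip_poly_halfspace(tri, breaks[k], below = FALSE)
      if (is.null(poly)) next
      poly <- clip_poly_halfspace(poly, breaks[k + 1L], below = TRUE)
      if (is.null(poly)) next
      areas[k] <- areas[k] + polygon_area3(poly)
    }
  }
  areas
}

# Sutherland-Hodgman clip of a planar 3D polygon against z >= z0 (below =
# FALSE) or z <= z0 (below = TRUE)
clip_poly_halfspace <- function(poly, z0, below) {
  n <- nrow(poly)
  keep <- if (below) poly[, 3] <= z0 else poly[, 3] >= z0
  if (all(keep)) return(poly)
  if (!any(keep)) return(NULL)
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- poly[i, ]; b <- poly[j, ]
    ka <- keep[i]; kb <- keep[j]
    if (ka) out[[length(out) + 1L]] <- a
    if (xor(ka, kb)) {
      t <- (z0 - a[3]) / (b[3] - a[3])
      out[[length(out) + 1L]] <- a + t * (b - a)
    }
  }
  if (length(out) < 3L) return(NULL)
  do.call(rbind, out)
}

# area of a planar polygon in 3D (Newell's method)
polygon_area3 <- function(poly) {
  n <- nrow(poly)
  s <- c(0, 0, 0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + crossprod3(poly[i, ], poly[j, ])
  }
  0.5 * sqrt(sum(s^2))
}

# exact projected-union fraction of the mesh over the cell footprint,
# rasterized at `res` (1 mm default per the truth definition)
projected_union_fraction <- function(mesh, cell_bounds, res = 0.001) {
  nx <- max(1L, round((cell_bounds[3] - cell_bounds[1]) / res))
  ny <- max(1L, round((cell_bounds[4] - cell_bounds[2]) / res))
  if (is.null(mesh) || nrow(mesh) == 0L) return(0)
  occ <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(mesh))) {
    ax <- mesh[i, 1]; ay <- mesh[i, 2]
    bx <- mesh[i, 4]; by <- mesh[i, 5]
    cx <- mesh[i, 7]; cy <- mesh[i, 8]
    det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
    if (abs(det) < 1e-14) next
    xlo <- max(floor((min(ax, bx, cx) - cell_bounds[1]) / res) + 1L, 1L)
    xhi <- min(ceiling((max(ax, bx, cx) - cell_bounds[1]) / res), nx)
    ylo <- max(floor((min(ay, by, cy) - cell_bounds[2]) / res) + 1L, 1L)
    yhi <- min(ceiling((max(ay, by, cy) - cell_bounds[2]) / res), ny)
    if (xlo > xhi || ylo > yhi) next
    px <- cell_bounds[1] + (xlo:xhi - 0.5) * res
    py <- cell_bounds[2] + (ylo:yhi - 0.5) * res
    qx <- rep(px, times = length(py)) - ax
    qy <- rep(py, each = length(px)) - ay
    l2 <- (qx * (cy - ay) - qy * (cx - ax)) / det
    l3 <- (qy * (bx - ax) - qx * (by - ay)) / det
    inside <- l2 >= 0 & l3 >= 0 & (l2 + l3) <= 1
    if (any(inside)) {
      sub <- occ[ylo:yhi, xlo:xhi, drop = FALSE]
      sub[matrix(inside, ncol = xhi - xlo + 1L, byrow = TRUE)] <- TRUE
      occ[ylo:yhi, xlo:xhi] <- sub
    }
  }
  sum(occ) / (nx * ny)
}

plant_truth <- function(mesh, height, cell_bounds, plant_id) {
  dh <- height / 5
  areas <- mesh_layer_areas(mesh, breaks = seq(0, height, by = dh))
  foot <- (cell_bounds[3] - cell_bounds[1]) * (cell_bounds[4] - cell_bounds[2])
  pad <- areas / (foot * dh)
  pai <- sum(pad * dh)
  pla <- projected_union_fraction(mesh, cell_bounds)
  out <- data.frame(plant_id = plant_id, true_height = height,
                    t(stats::setNames(areas, paste0("true_area_l", 1:5))),
                    t(stats::setNames(pad, paste0("true_pad_l", 1:5))),
                    true_pai = pai, true_pla = pla,
                    cell_xmin = cell_bounds[1], cell_ymin = cell_bounds[2],
                    cell_xmax = cell_bounds[3], cell_ymax = cell_bounds[4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
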