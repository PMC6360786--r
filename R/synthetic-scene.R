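#' Specification of a synthetic plot scene
#'
#' Layout and sensor parameters for a gridded maize plot: one variety per
#' column (x direction, 50 cm spacing by default), `plants_per_variety`
#' individuals along each column (y direction, 30 cm spacing), gently varying
#' terrain, scanner-like point spacing, uniform outlier noise and
#' occlusion-style point loss biased to the lower canopy.
#'
#' @param n_varieties number of varieties (columns).
#' @param plants_per_variety individuals per variety (rows).
#' @param column_spacing,row_spacing grid spacings in meters (defaults
#'   0.50 and 0.30).
#' @param terrain_amplitude amplitude of the smooth terrain undulation, m.
#' @param sensor_point_spacing sampling pitch on surfaces, m.
#' @param outlier_rate fraction of points injected uniformly in the bounding
#'   box, in `[0, 1)`.
#' @param occlusion_rate fraction of plant points removed, biased to lower
#'   layers and the stem, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(n_varieties, plants_per_variety,
                       column_spacing = 0.50, row_spacing = 0.30,
                       terrain_amplitude = 0.02, sensor_point_spacing = 0.004,
                       outlier_rate = 0.005, occlusion_rate = 0.1, seed = 1L) {
  stopifnot(n_varieties >= 1, plants_per_variety >= 1,
            column_spacing > 0, row_spacing > 0, terrain_amplitude >= 0,
            sensor_point_spacing > 0,
            outlier_rate >= 0, outlier_rate < 1,
            occlusion_rate >= 0, occlusion_rate < 1)
  structure(list(n_varieties = as.integer(n_varieties),
                 plants_per_variety = as.integer(plants_per_variety),
                 column_spacing = column_spacing, row_spacing = row_spacing,
                 terrain_amplitude = terrain_amplitude,
                 sensor_point_spacing = sensor_point_spacing,
                 outlier_rate = outlier_rate, occlusion_rate = occlusion_rate,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# smooth terrain: sum of low-frequency sinusoids scaled so the largest
# excursion equals the amplitude; identically 0 for amplitude 0
scene_terrain_fun <- function(amplitude, seed) {
  if (amplitude == 0) return(function(x, y) rep(0, length(x)))
  ph <- with_seed(seed + 7L, stats::runif(3, 0, 2 * pi))
  raw <- function(x, y) {
    0.6 * sin(2 * pi * x / 7.3 + ph[1]) * cos(2 * pi * y / 5.1 + ph[2]) +
      0.4 * sin(2 * pi * (x + 0.7 * y) / 9.7 + ph[3])
  }
  function(x, y) amplitude * raw(x, y)  # |raw| <= 1
}

#' Generate a full synthetic plot scene with ground truth
#'
#' Places one plant per grid cell (column = variety, row = individual),
#' drapes everything over a smooth terrain surface, samples ground points at
#' the sensor pitch, removes a fraction of plant points preferentially from
#' the lower canopy (occlusion), and injects uniform outliers. Everything is
#' deterministic for a fixed `scene$seed`.
#'
#' @param scene a [scene_spec()].
#' @param plant_specs either one [plant_spec()] per plant
#'   (`n_varieties * plants_per_variety`, cell order: rows within columns) or
#'   one per variety (replicated across that variety's rows with height and
#'   area jitter of 5%).
#' @param stage optional growth-stage tag stored with the layout.
#' @return a list with `cloud` (labels `"ground"`/`"vegetation"`/`"outlier"`
#'   reflect the generating truth), `truth` (one row per plant, see
#'   [generate_plant()], plus variety/row columns), `terrain` (the true
#'   terrain function of (x, y)), and `layout` (grid origin, dims, spacings).
#' @export
generate_scene <- function(scene, plant_specs, stage = NA_character_) {
  stopifnot(inherits(scene, "scene_spec"))
  if (inherits(plant_specs, "plant_spec")) plant_specs <- list(plant_specs)
  nv <- scene$n_varieties; np <- scene$plants_per_variety
  n_cells <- nv * np
  per_variety <- length(plant_specs) == nv && n_cells != nv
  if (!per_variety && length(plant_specs) != n_cells)
    stop("plant_specs must have length n_varieties (", nv,
         ") or n_varieties * plants_per_variety (", n_cells, ")")
  cs <- scene$column_spacing; rs <- scene$row_spacing
  terrain <- scene_terrain_fun(scene$terrain_amplitude, scene$seed)
  with_seed(scene$seed, {
    clouds <- vector("list", n_cells)
    truths <- vector("list", n_cells)
    meshes <- vector("list", n_cells)
    cell <- 0L
    for (v in seq_len(nv)) {
      for (r in seq_len(np)) {
        cell <- cell + 1L
        sp <- if (per_variety) jitter_spec(plant_specs[[v]]) else
          plant_specs[[cell]]
        cb <- c((v - 1) * cs, (r - 1) * rs, v * cs, r * rs)
        pid <- sprintf("v%02d_r%02d", v, r)
        g <- generate_plant(sp, scene$sensor_point_spacing,
                            seed = NULL, cell_bounds = cb, plant_id = pid)
        # drape on the terrain at the plant base
        base_z <- terrain((cb[1] + cb[3]) / 2, (cb[2] + cb[4]) / 2)
        g$cloud$points[, 3] <- g$cloud$points[, 3] + base_z
        tr <- g$truth
        tr$variety <- v; tr$row <- r; tr$stage <- stage
        clouds[[cell]] <- g$cloud
        truths[[cell]] <- tr
        meshes[[cell]] <- g$mesh
      }
    }
    # cell-level PLA truth: the projected union over the cell footprint of
    # every plant's surfaces, neighbor overhang included -- what an image of
    # the cell from above would show (and what the cell's points contain)
    all_mesh <- do.call(rbind, meshes)
    if (!is.null(all_mesh)) {
      mxr <- range(all_mesh[, c(1, 4, 7)])
      for (cell in seq_len(n_cells)) {
        tr <- truths[[cell]]
        cb <- c(tr$cell_xmin, tr$cell_ymin, tr$cell_xmax, tr$cell_ymax)
        hit <- pmin(all_mesh[, 1], all_mesh[, 4], all_mesh[, 7]) < cb[3] &
          pmax(all_mesh[, 1], all_mesh[, 4], all_mesh[, 7]) > cb[1] &
          pmin(all_mesh[, 2], all_mesh[, 5], all_mesh[, 8]) < cb[4] &
          pmax(all_mesh[, 2], all_mesh[, 5], all_mesh[, 8]) > cb[2]
        truths[[cell]]$true_pla <-
          projected_union_fraction(all_mesh[hit, , drop = FALSE], cb)
      }
    }
    veg <- do.call(rbind, lapply(clouds, function(cl) cl$points))
    veg_plant <- rep(vapply(truths, function(t) t$plant_id, ""),
                     vapply(clouds, n_points, 0L))
    # occlusion: biased random deletion (lower layers and stem are the
    # hardest to scan)
    if (scene$occlusion_rate > 0 && nrow(veg) > 0L) {
      zrel <- veg[, 3] - terrain(veg[, 1], veg[, 2])
      w <- pmax(1.6 - 1.2 * zrel / max(zrel), 0.2)
      drop_n <- round(scene$occlusion_rate * nrow(veg))
      if (drop_n > 0L) {
        drop <- sample.int(nrow(veg), drop_n, prob = w)
        veg <- veg[-drop, , drop = FALSE]
        veg_plant <- veg_plant[-drop]
      }
    }
    # ground raster at the sensor pitch, jittered in x-y, z on the terrain
    ps <- scene$sensor_point_spacing
    gx <- seq(ps / 2, nv * cs - ps / 2, by = ps)
    gy <- seq(ps / 2, np * rs - ps / 2, by = ps)
    gpts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    gpts <- gpts + matrix(stats::runif(length(gpts), -0.2 * ps, 0.2 * ps),
                          ncol = 2)
    gpts[, 1] <- pmin(pmax(gpts[, 1], 0), nv * cs)
    gpts[, 2] <- pmin(pmax(gpts[, 2], 0), np * rs)
    ground <- cbind(gpts, terrain(gpts[, 1], gpts[, 2]))
    pts <- rbind(ground, veg)
    lab <- c(rep("ground", nrow(ground)), rep("vegetation", nrow(veg)))
    # outliers: uniform in the bounding box, count = rate x scene size
    if (scene$outlier_rate > 0) {
      n_out <- round(scene$outlier_rate * nrow(pts))
      if (n_out > 0L) {
        zr <- range(pts[, 3])
        out <- cbind(stats::runif(n_out, 0, nv * cs),
                     stats::runif(n_out, 0, np * rs),
                     stats::runif(n_out, zr[1], zr[2] + 0.5))
        pts <- rbind(pts, out)
        lab <- c(lab, rep("outlier", n_out))
      }
    }
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    list(cloud = point_cloud(pts, lab),
         truth = truth,
         point_plant_id = c(rep(NA_character_, nrow(ground)), veg_plant,
                            rep(NA_character_,
                                length(lab) - nrow(ground) - length(veg_plant))),
         terrain = terrain,
         layout = list(origin = c(0, 0), n_cols = nv, n_rows = np,
                       col_spacing = cs, row_spacing = rs, stage = stage,
                       point_spacing = scene$sensor_point_spacing))
  })
}

# 5% height/area jitter when one spec stands in for a whole variety
jitter_spec <- function(sp) {
  f <- function(x) x * (1 + stats::rnorm(length(x), 0, 0.05))
  plant_spec(height = max(f(sp$height), 0.05),
             leaf_count_per_layer = sp$leaf_count_per_layer,
             one_sided_area_per_layer = pmax(f(sp$one_sided_area_per_layer), 0),
             leaf_inclination_mean = sp$leaf_inclination_mean,
             stem_diameter = sp$stem_diameter,
             projected_fraction_target = sp$projected_fraction_target)
}

#' Sample plant specifications spanning realistic stage ranges
#'
#' Draws plant specs whose heights and plant-area indices span given ranges,
#' with a mid-heavy vertical area profile typical of maize. Useful for
#' recovery experiments over a population of plants.
#'
#' @param n number of specs.
#' @param height_range height range in meters (default the 0.4-2.4 m span of
#'   a maize drought trial across growth stages).
#' @param pai_range plant-area-index range, m^2/m^2 (area = PAI x 0.15 m^2
#'   cell footprint).
#' @param seed integer RNG seed.
#' @param cell_area footprint used to convert PAI to absolute area (m^2).
#' @return a list of [plant_spec()] objects.
#' @export
sample_plant_specs <- function(n, height_range = c(0.4, 2.4),
                               pai_range = c(0.3, 3.5), seed = 1L,
                               cell_area = 0.15) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      h <- stats::runif(1, height_range[1], height_range[2])
      # taller plants carry more area: couple PAI to height with noise
      u <- (h - height_range[1]) / diff(height_range)
      pai <- pai_range[1] + diff(pai_range) *
        min(max(u + stats::rnorm(1, 0, 0.15), 0), 1)
      area <- pai * cell_area
      prof <- c(0.10, 0.22, 0.28, 0.25, 0.15)
      prof <- prof * stats::runif(5, 0.7, 1.3)
      prof <- prof / sum(prof)
      # single-leaf one-sided area grows with plant stature (~0.01 m^2 for
      # juveniles up to ~0.035 m^2 at full height); counts follow layer area
      unit_leaf <- min(0.035, max(0.008, 0.014 * h))
      plant_spec(height = h,
                 leaf_count_per_layer = pmax(1L, round(area * prof / unit_leaf)),
                 one_sided_area_per_layer = area * prof,
                 leaf_inclination_mean = stats::runif(1, 40, 60))
    })
  })
}
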