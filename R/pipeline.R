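#' Run the full preprocessing and phenotype-extraction pipeline
#'
#' Chains the preprocessing steps on a plot cloud exactly as the field
#' workflow does: statistical outlier removal, progressive-TIN ground
#' classification, ordinary-kriging DTM, height normalization, grid
#' segmentation, and phenotype extraction. Points outside the planting grid
#' (leaf overhang beyond the rim) are cropped before segmentation, and
#' normalized heights are floored at 0.
#'
#' @param cloud the raw plot `point_cloud`.
#' @param layout grid layout: a list with `origin`, `n_cols`, `n_rows`,
#'   `col_spacing`, `row_spacing` (e.g. `generate_scene()$layout`).
#' @param stage growth-stage tag for the phenotype records.
#' @param cfg a [pad_config()].
#' @param outlier_k,outlier_n outlier-removal parameters.
#' @param dtm_resolution DTM raster resolution in meters.
#' @param point_spacing the acquisition/resampling point spacing in meters
#'   (a known parameter of the workflow); used as the PLA pixel floor.
#' @return a list: `phenos` (the phenotype table), `plants` (the segmented
#'   `plant_cloud`s), `dtm`, and `n_outliers_removed`.
#' @export
run_pipeline <- function(cloud, layout, stage = NA_character_,
                         cfg = pad_config(), outlier_k = 10L, outlier_n = 3,
                         dtm_resolution = 0.05, point_spacing = NULL) {
  den <- remove_outliers(cloud, k_neighbors = outlier_k, n_sigma = outlier_n)
  lab <- classify_ground(den$cloud)
  ext <- c(apply(den$cloud$points[, 1:2, drop = FALSE], 2, min),
           apply(den$cloud$points[, 1:2, drop = FALSE], 2, max))
  dtm <- build_dtm(lab, resolution = dtm_resolution, extent = ext)
  norm <- normalize_heights(lab, dtm)
  x0 <- layout$origin[1]; y0 <- layout$origin[2]
  x1 <- x0 + layout$n_cols * layout$col_spacing
  y1 <- y0 + layout$n_rows * layout$row_spacing
  # keep grid-interior points and drop the near-ground band: residual
  # ground returns that escaped the ground filter would otherwise flood the
  # canopy rasters of sparse plants
  keep <- norm$points[, 1] >= x0 & norm$points[, 1] < x1 &
    norm$points[, 2] >= y0 & norm$points[, 2] < y1 &
    norm$points[, 3] >= 0.02
  norm <- subset_cloud(norm, keep)
  plants <- segment_grid(norm, origin = layout$origin,
                         n_cols = layout$n_cols, n_rows = layout$n_rows,
                         col_spacing = layout$col_spacing,
                         row_spacing = layout$row_spacing, stage = stage)
  phenos <- extract_phenotypes(plants, cfg = cfg)
  list(phenos = phenos, plants = plants, dtm = dtm,
       n_outliers_removed = den$removed)
}

#' Generate per-stage recovery scenes spanning published stage ranges
#'
#' Builds one synthetic scene per growth stage, with per-variety plant specs
#' drawn from that stage's published height and PAI ranges (each scan date
#' of a trial covers one stage, so plants within a scene have comparable
#' stature, as in the field). Returns pooled phenotype estimates merged with
#' the generator truth.
#'
#' @param stages stages to simulate (default all six).
#' @param n_varieties,plants_per_variety per-stage scene size.
#' @param summary_table stage range table (default
#'   [reference_stage_summary()]).
#' @param seed integer seed; each stage derives its own sub-seed.
#' @param ... passed to [scene_spec()] (e.g. `occlusion_rate`,
#'   `outlier_rate`, `sensor_point_spacing`).
#' @return a data.frame: one row per plant, phenotype estimates (`height`,
#'   `pai`, `pla`, `pad_l*`) alongside truth columns (`true_*`).
#' @export
recovery_experiment <- function(stages = maize_stages, n_varieties = 5L,
                                plants_per_variety = 2L,
                                summary_table = reference_stage_summary(),
                                seed = 1L, ...) {
  # the field procedure: calibrate the voxel size on a few individuals
  # first, then apply the found multiplier to every plant
  cfg <- pad_config(voxel_multiplier = calibrate_multiplier(seed))
  out <- list()
  for (i in seq_along(stages)) {
    st <- stages[i]
    hr <- unlist(summary_table[summary_table$stage == st &
                                 summary_table$phenotype == "height",
                               c("min", "max")])
    pr <- unlist(summary_table[summary_table$stage == st &
                                 summary_table$phenotype == "pai",
                               c("min", "max")])
    specs <- sample_plant_specs(n_varieties, height_range = hr,
                                pai_range = pr, seed = seed + 31L * i)
    sc <- generate_scene(
      scene_spec(n_varieties, plants_per_variety, seed = seed + 101L * i, ...),
      specs, stage = st)
    res <- run_pipeline(sc$cloud, sc$layout, stage = st, cfg = cfg,
                        point_spacing = sc$layout$point_spacing)
    m <- merge(res$phenos, sc$truth, by = "plant_id")
    m$stage <- st
    out[[i]] <- m
  }
  do.call(rbind, out)
}

#' Calibrate the voxel-size multiplier on a few reference plants
#'
#' Mirrors the field procedure: generate three mid-season reference plants,
#' run the 1-12 mm voxel sweep against their exact truth, and return the
#' mean selected size as a multiple of the plants' average point distance.
#' The multiplier then drives [extract_phenotypes()] for every plant.
#'
#' @param seed integer seed.
#' @param point_spacing sensor pitch in meters (default 0.004).
#' @return the calibrated voxel multiplier (dimensionless).
#' @export
calibrate_multiplier <- function(seed = 1L, point_spacing = 0.004) {
  mults <- vapply(1:3, function(i) {
    sp <- plant_spec(height = c(1.6, 1.8, 2.0)[i],
                     leaf_count_per_layer = c(3L, 4L, 5L, 4L, 3L),
                     one_sided_area_per_layer = c(0.03, 0.07, 0.09, 0.08, 0.045))
    g <- generate_plant(sp, point_spacing, seed = seed + 1000L * i)
    pl <- plant_cloud(g$cloud$points, plant_id = sprintf("cal%d", i),
                      cell_bounds = c(0, 0, 0.5, 0.3))
    calibrate_voxel_size(pl, g$truth)$multiplier
  }, 0)
  mean(mults)
}
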