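#' Segment a normalized plot cloud into individual plants by planting grid
#'
#' Each vegetation point is assigned to exactly one 50 cm x 30 cm grid cell
#' by half-open binning (`[lo, hi)` in both axes: a point exactly on a shared
#' edge goes to the higher-index cell, never to both). Column index maps to
#' variety, row index to the individual. Leaves overhanging into a neighbor's
#' cell are deliberately not reassigned -- that is a known error source of
#' grid segmentation, kept faithful to the field method.
#'
#' @param cloud a normalized `point_cloud`; if it carries labels, only
#'   `"vegetation"` points are segmented, otherwise all points are.
#' @param origin grid origin `c(x0, y0)` in meters. Default snaps the cloud's
#'   min corner down to the spacing.
#' @param n_cols,n_rows grid dimensions (varieties, individuals per variety).
#' @param col_spacing,row_spacing cell sizes in meters (defaults 0.50, 0.30).
#' @param stage growth-stage tag (e.g. `"D60"`) attached to every plant.
#' @return a list of `plant_cloud` objects, cell order rows-within-columns;
#'   empty cells yield empty clouds with `missing = TRUE`.
#' @export
segment_grid <- function(cloud, origin = NULL, n_cols, n_rows,
                         col_spacing = 0.50, row_spacing = 0.30,
                         stage = NA_character_) {
  stopifnot(inherits(cloud, "point_cloud"), n_cols >= 1, n_rows >= 1,
            col_spacing > 0, row_spacing > 0)
  pts <- cloud$points
  if (any(cloud$label == "vegetation")) {
    pts <- pts[cloud$label == "vegetation", , drop = FALSE]
  }
  if (is.null(origin)) {
    origin <- if (nrow(pts)) {
      c(floor(min(pts[, 1]) / col_spacing) * col_spacing,
        floor(min(pts[, 2]) / row_spacing) * row_spacing)
    } else c(0, 0)
  }
  ix <- floor((pts[, 1] - origin[1]) / col_spacing)
  iy <- floor((pts[, 2] - origin[2]) / row_spacing)
  orphan <- ix < 0 | ix >= n_cols | iy < 0 | iy >= n_rows
  if (any(orphan))
    stop(sum(orphan), " vegetation points fall outside the ", n_cols, " x ",
         n_rows, " grid; enlarge the grid or fix the origin")
  out <- vector("list", n_cols * n_rows)
  cell_of <- ix * n_rows + iy + 1L
  idx_by_cell <- split(seq_len(nrow(pts)), cell_of)
  cell <- 0L
  for (v in seq_len(n_cols)) {
    for (r in seq_len(n_rows)) {
      cell <- cell + 1L
      sel <- idx_by_cell[[as.character(cell)]]
      cb <- c(origin[1] + (v - 1) * col_spacing,
              origin[2] + (r - 1) * row_spacing,
              origin[1] + v * col_spacing,
              origin[2] + r * row_spacing)
      out[[cell]] <- plant_cloud(
        points = pts[sel, , drop = FALSE],
        plant_id = sprintf("v%02d_r%02d", v, r),
        variety = v, row = r, stage = stage, cell_bounds = cb,
        missing = is.null(sel) || length(sel) == 0L)
    }
  }
  out
}

#' Per-plant point cloud
#'
#' @param points N x 3 matrix of normalized points (z = height above ground).
#' @param plant_id,variety,row,stage identity of the individual.
#' @param cell_bounds `c(xmin, ymin, xmax, ymax)` of the grid cell, meters.
#' @param missing flag for empty cells.
#' @return a `plant_cloud` object.
#' @export
plant_cloud <- function(points, plant_id, variety = NA_integer_,
                        row = NA_integer_, stage = NA_character_,
                        cell_bounds, missing = FALSE) {
  if (is.null(points) || length(points) == 0L)
    points <- matrix(numeric(0), ncol = 3)
  points <- as.matrix(points)
  colnames(points) <- c("x", "y", "z")
  if (nrow(points) && min(points[, 3]) < -0.02)
    stop("plant points below the -0.02 m ground tolerance; normalize first")
  structure(list(points = points, plant_id = plant_id, variety = variety,
                 row = row, stage = stage, cell_bounds = as.numeric(cell_bounds),
                 missing = isTRUE(missing) || nrow(points) == 0L),
            class = "plant_cloud")
}

#' @export
print.plant_cloud <- function(x, ...) {
  cat(sprintf("<plant_cloud> %s (variety %s, row %s, stage %s): %d points%s\n",
              x$plant_id, x$variety, x$row, x$stage, nrow(x$points),
              if (x$missing) " [missing]" else ""))
  invisible(x)
}

#' Write per-plant clouds and their cell map
#'
#' Clouds are written as `{stage}_{variety}_{row}.ply`; the cell map CSV
#' records ids, cell bounds and point counts.
#'
#' @param plants list of `plant_cloud`s from [segment_grid()].
#' @param dir output directory (created if needed).
#' @return the cell-map data.frame, invisibly.
#' @export
write_plant_clouds <- function(plants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- do.call(rbind, lapply(plants, function(p) {
    f <- sprintf("%s_%s_%s.ply", p$stage, p$variety, p$row)
    write_cloud(point_cloud(p$points), file.path(dir, f), format = "ply")
    data.frame(plant_id = p$plant_id, variety = p$variety, row = p$row,
               stage = p$stage, file = f, n_points = nrow(p$points),
               xmin = p$cell_bounds[1], ymin = p$cell_bounds[2],
               xmax = p$cell_bounds[3], ymax = p$cell_bounds[4],
               missing = p$missing, stringsAsFactors = FALSE)
  }))
  utils::write.csv(map, file.path(dir, "cell_map.csv"), row.names = FALSE)
  invisible(map)
}
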