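# fixtures shared across test files; everything is generated in code

# a moderate mid-season plant spec used by several tests
demo_spec <- function(height = 1.8) {
  plant_spec(height = height,
             leaf_count_per_layer = c(3L, 4L, 5L, 4L, 3L),
             one_sided_area_per_layer = c(0.03, 0.07, 0.09, 0.08, 0.045))
}

# fabricate a plant_cloud from raw points without running the generator
fab_plant <- function(points, cell_bounds = c(0, 0, 0.5, 0.3), stage = "D60") {
  plant_cloud(points, plant_id = "t1", variety = 1L, row = 1L,
              stage = stage, cell_bounds = cell_bounds)
}

# fabricate a voxel_grid directly from layer counts (for arithmetic checks
# of the printed PAD formula)
fab_grid <- function(n_l, n_p, delta_h) {
  structure(list(dims = c(nx = 1L, ny = 1L, nz = length(n_l)),
                 voxel_size = delta_h, height = delta_h * length(n_l),
                 delta_h = delta_h, n_layers = length(n_l),
                 layer_of_slab = seq_along(n_l),
                 slab_occupied = n_l, slab_total = n_l[1] + n_p[1],
                 n_l = n_l, n_p = n_p,
                 occupied = NULL),
            class = "voxel_grid")
}

# brute-force mean distance to k nearest neighbours (O(N^2) oracle)
brute_knn_mean <- function(pts, k) {
  D <- as.matrix(stats::dist(pts))
  apply(D, 1, function(r) mean(sort(r)[2:(k + 1)]))
}

# minimal phenotype table for dynamics / significance tests
fab_phenos <- function(values_by_stage, variety = 1L, phenotype = "height") {
  do.call(rbind, lapply(names(values_by_stage), function(st) {
    v <- values_by_stage[[st]]
    out <- data.frame(plant_id = paste0(st, "_", seq_along(v)),
                      variety = variety, row = seq_along(v), stage = st,
                      stringsAsFactors = FALSE)
    out[[phenotype]] <- v
    out
  }))
}
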