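#' Read and write generator specifications as YAML
#'
#' A scene config YAML holds a `scene:` block (the [scene_spec()] fields) and
#' a `plants:` list (one [plant_spec()] block per variety or per plant).
#'
#' @param path YAML file path.
#' @return `read_scene_config` returns a list with `scene` (a `scene_spec`)
#'   and `plants` (list of `plant_spec`).
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scene)) stop("config lacks a 'scene' block: ", path)
  if (is.null(cfg$plants)) stop("config lacks a 'plants' list: ", path)
  scene <- do.call(scene_spec, cfg$scene)
  plants <- lapply(cfg$plants, function(p) do.call(plant_spec, p))
  list(scene = scene, plants = plants)
}

#' @rdname read_scene_config
#' @param scene a [scene_spec()].
#' @param plants list of [plant_spec()].
#' @export
write_scene_config <- function(scene, plants, path) {
  stopifnot(inherits(scene, "scene_spec"))
  strip <- function(x) { x <- unclass(x); x[!vapply(x, is.null, TRUE)] }
  yaml::write_yaml(list(scene = strip(scene),
                        plants = lapply(plants, strip)), path,
                   precision = 15L)
  invisible(path)
}

#' Write a scene's outputs to a directory
#'
#' Writes the scene cloud as LAS and PLY, the truth table and layout as CSV,
#' mirroring the generator's file interface.
#'
#' @param sc a scene as returned by [generate_scene()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cloud(sc$cloud, file.path(dir, "scene.las"), format = "las")
  write_cloud(sc$cloud, file.path(dir, "scene.ply"), format = "ply")
  utils::write.csv(sc$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sc$layout[c("n_cols", "n_rows",
                                             "col_spacing", "row_spacing")]),
                   file.path(dir, "layout.csv"), row.names = FALSE)
  invisible(dir)
}
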