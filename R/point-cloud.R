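#' Point cloud container
#'
#' A `point_cloud` is the package's representation of an unordered set of 3D
#' points in a local metric frame (meters), optionally carrying a per-point
#' classification label (`"ground"`, `"vegetation"`, `"outlier"` or
#' `"unlabeled"`).
#'
#' @param points numeric matrix with N rows and 3 columns (x, y, z), meters.
#'   A data.frame with columns x, y, z is accepted and converted.
#' @param label optional character vector of length N; defaults to
#'   `"unlabeled"` for every point.
#' @return an object of class `point_cloud`: a list with elements `points`
#'   (N x 3 matrix, columns named x, y, z) and `label` (character of length N).
#' @examples
#' pc <- point_cloud(cbind(runif(10), runif(10), 0))
#' n_points(pc)
#' @export
point_cloud <- function(points, label = NULL) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y", "z") %in% names(points)))
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  if (is.null(points) || length(points) == 0L) {
    points <- matrix(numeric(0), ncol = 3)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("`points` must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L && !all(is.finite(points)))
    stop("point coordinates must be finite")
  colnames(points) <- c("x", "y", "z")
  if (is.null(label)) {
    label <- rep("unlabeled", nrow(points))
  } else {
    label <- as.character(label)
    if (length(label) != nrow(points))
      stop("`label` length must equal the number of points")
    bad <- setdiff(unique(label), c("ground", "vegetation", "outlier", "unlabeled"))
    if (length(bad))
      stop("unknown point labels: ", paste(bad, collapse = ", "))
  }
  structure(list(points = points, label = label), class = "point_cloud")
}

#' @rdname point_cloud
#' @param x a `point_cloud`.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "point_cloud"))
  nrow(x$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- n_points(x)
  cat(sprintf("<point_cloud> %d points", n))
  if (n > 0L) {
    r <- apply(x$points, 2, range)
    cat(sprintf("\n  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f]",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
    tb <- table(x$label)
    cat("\n  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Subset a point cloud by index
#' @param cloud a `point_cloud`.
#' @param idx integer or logical index over points.
#' @return a `point_cloud` with the selected points.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE], cloud$label[idx])
}

#' Mean nearest-neighbor distance of a cloud
#'
#' The package's working definition of "average point distance": the mean 3D
#' distance from each point to its single nearest neighbor.
#'
#' @param cloud a `point_cloud` with at least 2 points.
#' @return mean nearest-neighbor distance in meters.
#' @export
avg_point_distance <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"), n_points(cloud) >= 2L)
  d <- FNN::get.knn(cloud$points, k = 1L)$nn.dist
  mean(d)
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards (NULL seed = use the current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
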