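#' Digital terrain model by ordinary kriging
#'
#' Interpolates ground elevations onto a regular raster (default 5 cm) with
#' ordinary kriging. An isotropic exponential variogram is fitted to the
#' empirical semivariogram (15 lag bins, weighted least squares, weights
#' N(h)/h^2) on a subsample of the ground points; the nugget is fixed at 0 so
#' the interpolator is exact at data locations. Each cell is predicted from
#' its `n_neighbors` nearest ground points (moving-window kriging); kriging
#' weights sum to 1 per cell by construction of the ordinary-kriging system.
#' If a kriging system is singular the cell falls back to inverse-distance
#' weighting with a warning.
#'
#' @param ground a `point_cloud` of ground returns, or a labeled cloud from
#'   [classify_ground()] (then only points labeled `"ground"` are used).
#' @param resolution raster resolution in meters (default 0.05).
#' @param n_neighbors points per kriging window (default 24).
#' @param pad extra margin around the point extent, meters (default one cell).
#' @param extent optional `c(xmin, ymin, xmax, ymax)` the raster must cover
#'   (e.g. the full cloud extent including canopy overhang); the union of
#'   this and the ground-point extent is used.
#' @return a `terrain_model`: list with `origin` (x0, y0), `resolution`,
#'   `z` (ny x nx elevation matrix), and the fitted `variogram`
#'   (psill, range, nugget).
#' @export
build_dtm <- function(ground, resolution = 0.05, n_neighbors = 24L,
                      pad = resolution, extent = NULL) {
  stopifnot(inherits(ground, "point_cloud"), resolution > 0)
  if (any(ground$label == "ground")) {
    ground <- subset_cloud(ground, ground$label == "ground")
  }
  pts <- ground$points
  if (nrow(pts) < 10L)
    stop("need at least 10 ground points, got ", nrow(pts))
  vg <- fit_exponential_variogram(pts)
  lo <- c(min(pts[, 1]), min(pts[, 2])); hi <- c(max(pts[, 1]), max(pts[, 2]))
  if (!is.null(extent)) {
    lo <- pmin(lo, extent[1:2]); hi <- pmax(hi, extent[3:4])
  }
  x0 <- lo[1] - pad; y0 <- lo[2] - pad
  nx <- max(1L, ceiling((hi[1] + pad - x0) / resolution))
  ny <- max(1L, ceiling((hi[2] + pad - y0) / resolution))
  cx <- x0 + (seq_len(nx) - 0.5) * resolution
  cy <- y0 + (seq_len(ny) - 0.5) * resolution
  grid <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  k <- min(as.integer(n_neighbors), nrow(pts))
  nn <- FNN::get.knnx(pts[, 1:2, drop = FALSE], grid, k = k)
  zhat <- numeric(nrow(grid))
  n_fallback <- 0L
  for (i in seq_len(nrow(grid))) {
    j <- nn$nn.index[i, ]
    res <- krige_cell(pts[j, , drop = FALSE], grid[i, ], vg)
    if (is.null(res)) {
      n_fallback <- n_fallback + 1L
      w <- 1 / pmax(nn$nn.dist[i, ], 1e-12)^2
      zhat[i] <- sum(w * pts[j, 3]) / sum(w)
    } else zhat[i] <- res
  }
  if (n_fallback > 0L)
    warning(n_fallback, " DTM cells fell back to inverse-distance weighting ",
            "(singular kriging system)")
  structure(list(origin = c(x0, y0), resolution = resolution,
                 z = matrix(zhat, nrow = ny, ncol = nx, byrow = TRUE),
                 variogram = vg),
            class = "terrain_model")
}

# gamma(h) for zero-nugget models; "gaussian" captures very smooth fields
# (a plane's empirical semivariogram is quadratic near the origin, which no
# exponential can represent)
vgm_eval <- function(h, vg) {
  if (vg$model == "gaussian") vg$psill * (1 - exp(-(h / vg$range)^2))
  else vg$psill * (1 - exp(-h / vg$range))
}

fit_exponential_variogram <- function(pts, n_lags = 15L, max_pairs = 2000L) {
  n <- nrow(pts)
  if (n > max_pairs) {
    # deterministic thinning keeps the fit reproducible without touching RNG
    keep <- unique(round(seq(1L, n, length.out = max_pairs)))
    pts <- pts[keep, , drop = FALSE]
    n <- nrow(pts)
  }
  d <- as.matrix(stats::dist(pts[, 1:2, drop = FALSE]))
  g <- outer(pts[, 3], pts[, 3], "-")^2 / 2
  ut <- upper.tri(d)
  h <- d[ut]; sv <- g[ut]
  hmax <- max(h) / 2
  if (hmax <= 0 || all(sv == 0)) {
    # constant field (or colocated points): flat variogram
    return(list(model = "exponential", psill = max(stats::var(pts[, 3]), 1e-12),
                range = 1, nugget = 0, lags = NULL))
  }
  br <- seq(0, hmax, length.out = n_lags + 1L)
  bin <- cut(h, br, include.lowest = TRUE)
  emp <- data.frame(h = tapply(h, bin, mean), gamma = tapply(sv, bin, mean),
                    n = as.vector(table(bin)))
  emp <- emp[is.finite(emp$h) & emp$n > 0, ]
  psill0 <- max(mean(sv), 1e-12)
  range0 <- hmax / 3
  best <- NULL
  for (model in c("exponential", "gaussian")) {
    fit <- tryCatch(
      stats::optim(
        c(log(psill0), log(range0)),
        function(p) {
          gm <- vgm_eval(emp$h, list(model = model, psill = exp(p[1]),
                                     range = exp(p[2])))
          sum(emp$n / pmax(emp$h, 1e-9)^2 * (emp$gamma - gm)^2)
        },
        method = "Nelder-Mead"),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$sse)
      best <- list(model = model, psill = exp(fit$par[1]),
                   range = exp(fit$par[2]), nugget = 0, sse = fit$value,
                   lags = emp)
  }
  if (is.null(best))
    best <- list(model = "exponential", psill = psill0, range = range0,
                 nugget = 0, lags = emp)
  best
}

# ordinary kriging prediction at one location; NULL on singular system
krige_cell <- function(npts, loc, vg) {
  # exact interpolation: colocated data point wins outright
  d0 <- sqrt((npts[, 1] - loc[1])^2 + (npts[, 2] - loc[2])^2)
  hit <- which(d0 < 1e-9)
  if (length(hit)) return(npts[hit[1], 3])
  # collapse duplicate data locations (they make the system singular)
  key <- paste(round(npts[, 1], 9), round(npts[, 2], 9))
  if (anyDuplicated(key)) {
    z <- tapply(npts[, 3], key, mean)
    xy <- do.call(rbind, lapply(strsplit(names(z), " "), as.numeric))
    npts <- cbind(xy, as.numeric(z))
    d0 <- sqrt((npts[, 1] - loc[1])^2 + (npts[, 2] - loc[2])^2)
  }
  m <- nrow(npts)
  if (m < 2L) return(npts[1, 3])
  # constant neighborhood: the prediction is that constant (the kriging
  # system is singular there, but no fallback warning is warranted)
  if (stats::sd(npts[, 3]) < 1e-12) return(mean(npts[, 3]))
  D <- as.matrix(stats::dist(npts[, 1:2, drop = FALSE]))
  G <- vgm_eval(D, vg)
  if (identical(vg$model, "gaussian"))
    diag(G) <- diag(G) - 1e-8 * vg$psill   # ridge: gaussian kriging is
                                           # notoriously ill-conditioned
  A <- rbind(cbind(G, 1), c(rep(1, m), 0))
  b <- c(vgm_eval(d0, vg), 1)
  w <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) return(NULL)
  sum(w[seq_len(m)] * npts[, 3])
}

#' Evaluate a terrain model
#'
#' Bilinear interpolation of the DTM raster at arbitrary x-y locations.
#' Locations beyond the outermost cell centers are clamped to the edge value
#' within half a cell, and `NA` beyond the raster extent.
#'
#' @param dtm a `terrain_model`.
#' @param x,y numeric vectors of coordinates (meters).
#' @return elevations in meters.
#' @export
dtm_at <- function(dtm, x, y) {
  stopifnot(inherits(dtm, "terrain_model"))
  res <- dtm$resolution
  nx <- ncol(dtm$z); ny <- nrow(dtm$z)
  # continuous cell-center coordinates
  gx <- (x - dtm$origin[1]) / res - 0.5
  gy <- (y - dtm$origin[2]) / res - 0.5
  out <- rep(NA_real_, length(x))
  ok <- gx >= -0.5 & gx <= nx - 0.5 & gy >= -0.5 & gy <= ny - 0.5
  gxc <- pmin(pmax(gx[ok], 0), nx - 1)
  gyc <- pmin(pmax(gy[ok], 0), ny - 1)
  i0 <- pmin(floor(gxc), nx - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(gyc), ny - 2); j0 <- pmax(j0, 0)
  if (nx == 1L) i0 <- rep(0, length(gxc))
  if (ny == 1L) j0 <- rep(0, length(gyc))
  tx <- gxc - i0; ty <- gyc - j0
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  z00 <- dtm$z[cbind(j0 + 1, i0 + 1)]
  z10 <- dtm$z[cbind(j0 + 1, i1 + 1)]
  z01 <- dtm$z[cbind(j1 + 1, i0 + 1)]
  z11 <- dtm$z[cbind(j1 + 1, i1 + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
  out
}

#' Write a terrain model as an ESRI ASCII grid
#' @param dtm a `terrain_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dtm_asc <- function(dtm, path) {
  stopifnot(inherits(dtm, "terrain_model"))
  hdr <- c(sprintf("ncols %d", ncol(dtm$z)),
           sprintf("nrows %d", nrow(dtm$z)),
           sprintf("xllcorner %.6f", dtm$origin[1]),
           sprintf("yllcorner %.6f", dtm$origin[2]),
           sprintf("cellsize %.6f", dtm$resolution),
           "NODATA_value -9999")
  body <- apply(dtm$z[rev(seq_len(nrow(dtm$z))), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
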