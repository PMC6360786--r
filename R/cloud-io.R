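#' Read and write point clouds
#'
#' Supported formats: whitespace-delimited XYZ text, PLY (ascii and
#' binary_little_endian, float or double vertex coordinates), and LAS 1.2
#' point format 0 (uncompressed). Format is inferred from the file extension
#' when `format = "auto"`. Round trips are lossless to the format's precision:
#' XYZ to the printed digits, double PLY exactly, float PLY to single
#' precision, LAS to its header scale (quantization step).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"las"`, `"ply"`, `"xyz"`.
#' @return `read_cloud` returns a `point_cloud`; `write_cloud` returns `path`
#'   invisibly.
#' @seealso [point_cloud()]
#' @export
read_cloud <- function(path, format = c("auto", "las", "ply", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
    xyz = read_xyz(path),
    ply = read_ply(path),
    las = read_las(path)
  )
}

#' @rdname read_cloud
#' @param cloud a `point_cloud`.
#' @param binary for PLY: write binary_little_endian (default) or ascii.
#' @param scale for LAS: coordinate quantization step in meters (default 0.001).
#' @export
write_cloud <- function(cloud, path, format = c("auto", "las", "ply", "xyz"),
                        binary = TRUE, scale = 0.001) {
  stopifnot(inherits(cloud, "point_cloud"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    xyz = write_xyz(cloud, path),
    ply = write_ply(cloud, path, binary = binary),
    las = write_las(cloud, path, scale = scale)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("las", "ply", "xyz", "txt"))
    stop("cannot infer point-cloud format from extension '.", ext,
         "'; pass `format` explicitly (las/ply/xyz)")
  if (ext == "txt") "xyz" else ext
}

## ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  if (file.size(path) == 0L) return(point_cloud(NULL))
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, select = 1:3,
                        colClasses = "numeric", showProgress = FALSE)),
    error = function(e) stop("malformed XYZ file '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0L) return(point_cloud(NULL))
  m <- suppressWarnings(matrix(as.numeric(as.matrix(dt)), nrow = nrow(dt)))
  if (!all(is.finite(m))) {
    bad <- which(!stats::complete.cases(m))[1]
    stop("malformed XYZ file '", path, "': non-numeric record at line ", bad)
  }
  point_cloud(m)
}

write_xyz <- function(cloud, path) {
  dt <- data.table::as.data.table(cloud$points)
  data.table::fwrite(dt, path, sep = " ", col.names = FALSE)
}

## ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ascii lines terminated by "end_header"
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed PLY '", path, "': header truncated")
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 500L) stop("malformed PLY '", path, "': no end_header")
  }
  if (!identical(trimws(header[1]), "ply"))
    stop("malformed PLY '", path, "': missing magic line")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (!length(fmt_line)) stop("malformed PLY '", path, "': no format line")
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  el <- grep("^element vertex ", header, value = TRUE)
  if (!length(el)) stop("malformed PLY '", path, "': no vertex element")
  nv <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]][3])
  # property lines following the vertex element, until next element/end
  iel <- grep("^element vertex ", header)[1]
  rest <- header[(iel + 1):length(header)]
  stopn <- grep("^(element |end_header)", rest)[1]
  props <- grep("^property ", rest[seq_len(stopn - 1)], value = TRUE)
  pp <- do.call(rbind, strsplit(trimws(props), "\\s+"))
  ptypes <- pp[, 2]
  pnames <- pp[, 3]
  if (!all(c("x", "y", "z") %in% pnames))
    stop("malformed PLY '", path, "': vertex element lacks x/y/z")
  if (nv == 0L) return(point_cloud(NULL))
  if (fmt == "ascii") {
    lines <- readLines(con, n = nv)
    if (length(lines) < nv)
      stop("malformed PLY '", path, "': truncated at vertex ",
           length(lines) + 1L)
    vals <- matrix(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))),
                   nrow = nv, byrow = TRUE)
    colnames(vals) <- pnames[seq_len(ncol(vals))]
    m <- vals[, c("x", "y", "z"), drop = FALSE]
  } else if (fmt == "binary_little_endian") {
    sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
               short = 2L, ushort = 2L, uchar = 1L, char = 1L)
    sz <- sizes[ptypes]
    if (anyNA(sz)) stop("unsupported PLY property type in '", path, "'")
    rec <- sum(sz)
    raw <- readBin(con, "raw", n = rec * nv)
    if (length(raw) < rec * nv)
      stop("malformed PLY '", path, "': truncated at vertex ",
           length(raw) %/% rec + 1L)
    m <- matrix(0, nv, 3, dimnames = list(NULL, c("x", "y", "z")))
    off <- c(0L, cumsum(sz))
    for (ax in c("x", "y", "z")) {
      j <- match(ax, pnames)
      b <- sz[j]
      # gather this property's bytes from every record
      idx <- as.vector(outer(seq_len(b), (seq_len(nv) - 1L) * rec + off[j], "+"))
      m[, ax] <- readBin(raw[idx], "double", n = nv, size = b, endian = "little")
    }
  } else stop("unsupported PLY format '", fmt, "' in ", path)
  point_cloud(m)
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply",
              sprintf("format %s 1.0", fmt),
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (n == 0L) return(invisible(path))
  if (binary) {
    writeBin(as.vector(t(cloud$points)), con, size = 8, endian = "little")
  } else {
    writeLines(apply(cloud$points, 1, function(p)
      paste(formatC(p, format = "g", digits = 17), collapse = " ")), con)
  }
  invisible(path)
}

## ---- LAS 1.2, point format 0 ---------------------------------------------
## Minimal uncompressed LAS support: 227-byte header, 20-byte point records
## holding scaled int32 xyz. No R LAS library is available in this stack.

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("malformed LAS '", path, "': bad signature")
  seek(con, 24)
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  seek(con, 94)
  hdr_size <- readBin(con, "integer", size = 2, signed = FALSE)
  offset_to_points <- readBin(con, "integer", size = 4)
  n_vlr <- readBin(con, "integer", size = 4)
  pdrf <- readBin(con, "integer", size = 1, signed = FALSE)
  rec_len <- readBin(con, "integer", size = 2, signed = FALSE)
  n_pts <- readBin(con, "integer", size = 4)
  if (pdrf > 5L) stop("unsupported LAS point data record format ", pdrf)
  seek(con, 131)
  sc <- readBin(con, "double", n = 6)  # x/y/z scale then x/y/z offset
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n = rec_len * n_pts)
  if (length(raw) < rec_len * n_pts)
    stop("malformed LAS '", path, "': truncated at record ",
         length(raw) %/% rec_len + 1L)
  if (n_pts == 0L) return(point_cloud(NULL))
  m <- matrix(0, n_pts, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (j in 1:3) {
    idx <- as.vector(outer(seq_len(4L), (seq_len(n_pts) - 1L) * rec_len +
                             (j - 1L) * 4L, "+"))
    ints <- readBin(raw[idx], "integer", n = n_pts, size = 4, endian = "little")
    m[, j] <- ints * sc[j] + sc[j + 3]
  }
  point_cloud(m)
}

write_las <- function(cloud, path, scale = 0.001) {
  stopifnot(scale > 0)
  n <- n_points(cloud)
  pts <- cloud$points
  offs <- if (n) apply(pts, 2, min) else c(0, 0, 0)
  qi <- if (n) round(sweep(pts, 2, offs) / scale) else
    matrix(0, 0, 3)
  if (n && any(abs(qi) > .Machine$integer.max))
    stop("coordinates exceed int32 range at scale ", scale)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)                  # source id, encoding
  writeBin(rep(0L, 4), con, size = 4)                  # GUID, 16 bytes
  writeBin(c(1L, 2L), con, size = 1)                   # version 1.2
  writeChar(formatC("maizetls", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("maizetls", width = 32, flag = "-"), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)                # day, year
  writeBin(227L, con, size = 2)                        # header size
  writeBin(227L, con, size = 4)                        # offset to point data
  writeBin(0L, con, size = 4)                          # number of VLRs
  writeBin(0L, con, size = 1)                          # point format 0
  writeBin(20L, con, size = 2)                         # record length
  writeBin(as.integer(n), con, size = 4)
  writeBin(rep(0L, 5), con, size = 4)                  # points by return
  writeBin(rep(scale, 3), con)                         # xyz scale
  writeBin(as.numeric(offs), con)                      # xyz offset
  mx <- if (n) apply(pts, 2, max) else c(0, 0, 0)
  writeBin(as.numeric(c(mx[1], offs[1], mx[2], offs[2], mx[3], offs[3])), con)
  # point records: int32 xyz + 8 zero bytes of ancillary fields
  if (n) {
    rec <- matrix(as.raw(0), 20, n)
    xyzraw <- writeBin(as.integer(t(qi)), raw(), size = 4, endian = "little")
    rec[1:12, ] <- matrix(xyzraw, 12, n)
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}
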