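#' Gridded elevation surface
#'
#' Light-weight container for a single-band planar raster: an `ny x nx`
#' numeric matrix plus its cell size and origin. Row `i`, column `j` holds the
#' value at the cell centre `x = x0 + (j - 0.5) * cell_size`,
#' `y = y0 + (i - 0.5) * cell_size` (row 1 is the southern edge, all grids
#' share one planar coordinate system). Used for the DEM, for monthly climate
#' layers and for probability surfaces alike.
#'
#' @param values numeric matrix (`ny x nx`), elevations in m a.s.l. for a DEM.
#' @param cell_size cell edge length in map units (m).
#' @param origin numeric length-2, `(x0, y0)` of the grid's lower-left corner.
#' @param nodata sentinel value marking missing cells (stored as `NA`
#'   internally; the sentinel is only used on disk).
#' @return an object of class `oro_grid`.
#' @export
oro_grid <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("grid must be at least 2 x 2", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar", call. = FALSE)
  storage.mode(values) <- "double"
  values[values == nodata] <- NA_real_
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "oro_grid")
}

#' @export
print.oro_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<oro_grid> %d x %d cells, cell_size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  range: [%g, %g], NA cells: %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.oro_grid <- function(x) dim(x$values)

# x/y coordinates of all cell centres, matching the matrix layout
grid_x <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
grid_y <- function(g) g$origin[2] + (seq_len(nrow(g$values)) - 0.5) * g$cell_size

#' Locate the cell containing a point
#'
#' @param g an [oro_grid].
#' @param x,y point coordinates in map units.
#' @return integer matrix with columns `row`, `col`; `NA` rows for points
#'   outside the grid extent.
#' @export
cell_at <- function(g, x, y) {
  nyx <- dim(g$values)
  col <- floor((x - g$origin[1]) / g$cell_size) + 1L
  row <- floor((y - g$origin[2]) / g$cell_size) + 1L
  bad <- col < 1L | col > nyx[2] | row < 1L | row > nyx[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read grid values at point locations
#'
#' @inheritParams cell_at
#' @return numeric vector of cell values (`NA` outside the grid).
#' @export
grid_extract <- function(g, x, y) {
  rc <- cell_at(g, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- g$values[rc[ok, , drop = FALSE]]
  out
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band format (`ncols/nrows/xllcorner/yllcorner/cellsize/`
#' `NODATA_value` header followed by rows north to south); readable by any
#' GIS. `NA` cells are written as the grid's nodata sentinel.
#'
#' @param g an [oro_grid].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  v <- g$values
  v[is.na(v)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %.10g", g$nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # ASCII grids run north to south; our rows run south to north
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return an [oro_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-first rows
  oro_grid(m, cell_size = hdr$cellsize,
           origin = c(hdr$xllcorner, hdr$yllcorner),
           nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
}

# Horn (3x3) slope and aspect in radians; edges use one-sided differences
# via edge padding. Aspect measured clockwise from north, downslope direction.
slope_aspect <- function(g) {
  v <- g$values
  ny <- nrow(v); nx <- ncol(v)
  pad <- v[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  cs <- g$cell_size
  idx_r <- seq_len(ny) + 1L; idx_c <- seq_len(nx) + 1L
  z <- function(dr, dc) pad[idx_r + dr, idx_c + dc]
  # dz/dx positive eastwards, dz/dy positive northwards (row index grows north)
  dzdx <- ((z(1, 1) + 2 * z(0, 1) + z(-1, 1)) -
           (z(1, -1) + 2 * z(0, -1) + z(-1, -1))) / (8 * cs)
  dzdy <- ((z(1, -1) + 2 * z(1, 0) + z(1, 1)) -
           (z(-1, -1) + 2 * z(-1, 0) + z(-1, 1))) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  # azimuth of the downslope direction, clockwise from north
  aspect <- atan2(-dzdx, -dzdy) %% (2 * pi)
  list(slope = slope, aspect = aspect)
}
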