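#' Regular longitude/latitude grid geometry
#'
#' Defines the shared geometry of all raster layers handled by the package:
#' a regular grid of square cells in geographic coordinates (WGS84), with
#' the cell size expressed in arc-minutes as is conventional for the
#' 2.5 arc-min bioclimatic products this mirrors.
#'
#' @param origin_lon,origin_lat longitude/latitude of the *center* of the
#'   lower-left (south-west) cell, decimal degrees.
#' @param cell_arcmin cell size in arc-minutes (2.5 by default).
#' @param n_rows,n_cols grid dimensions.
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(origin_lon, origin_lat, cell_arcmin = 2.5,
                          n_rows, n_cols) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat),
            cell_arcmin > 0, n_rows >= 1, n_cols >= 1)
  structure(list(origin_lon = origin_lon, origin_lat = origin_lat,
                 cell_arcmin = cell_arcmin,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells of %.3g arc-min, SW center (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_arcmin, x$origin_lon, x$origin_lat))
  invisible(x)
}

geometry_equal <- function(a, b, tol = 1e-9) {
  inherits(a, "grid_geometry") && inherits(b, "grid_geometry") &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_arcmin - b$cell_arcmin) < tol
}

#' Cell center coordinates of a grid
#'
#' @param geometry a [grid_geometry()].
#' @return data.frame with `cell` (index, column-major from the SW corner
#'   rowwise: cell = (row-1)*n_cols + col), `row`, `col`, `lon`, `lat`.
#' @export
grid_cells <- function(geometry) {
  step <- geometry$cell_arcmin / 60
  row <- rep(seq_len(geometry$n_rows), each = geometry$n_cols)
  col <- rep(seq_len(geometry$n_cols), times = geometry$n_rows)
  data.frame(cell = seq_len(geometry$n_rows * geometry$n_cols),
             row = row, col = col,
             lon = geometry$origin_lon + (col - 1) * step,
             lat = geometry$origin_lat + (row - 1) * step)
}

#' Single-variable raster surface
#'
#' A vector of cell values on a [grid_geometry()], with a logical validity
#' mask. Values are stored in cell order (see [grid_cells()]).
#'
#' @param geometry a [grid_geometry()].
#' @param values numeric vector, one per cell.
#' @param mask logical vector; `TRUE` marks valid cells. Default all valid.
#' @param name optional layer name.
#' @return object of class `grid_surface`.
#' @export
grid_surface <- function(geometry, values, mask = NULL, name = NULL) {
  n <- geometry$n_rows * geometry$n_cols
  stopifnot(length(values) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n, is.logical(mask))
  if (any(!is.finite(values[mask])))
    stop("non-finite values on unmasked cells")
  structure(list(geometry = geometry, values = as.numeric(values),
                 mask = mask, name = name),
            class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("grid_surface%s: %d x %d, %d valid cells, range [%.4g, %.4g]\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$geometry$n_rows, x$geometry$n_cols, sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

surface_matrix <- function(s) {
  m <- matrix(s$values, nrow = s$geometry$n_rows,
              ncol = s$geometry$n_cols, byrow = TRUE)
  m[matrix(!s$mask, nrow = s$geometry$n_rows, byrow = TRUE)] <- NA
  m
}

#' Write a surface as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`.asc`); masked cells are written
#' as the nodata value.
#'
#' @param s a [grid_surface()].
#' @param path output file.
#' @param nodata nodata sentinel (default -9999).
#' @export
write_esri_ascii <- function(s, path, nodata = -9999) {
  g <- s$geometry
  step <- g$cell_arcmin / 60
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_lon - step / 2),
           sprintf("yllcorner %.10g", g$origin_lat - step / 2),
           sprintf("cellsize %.10g", step),
           sprintf("NODATA_value %g", nodata))
  m <- surface_matrix(s)
  m[is.na(m)] <- nodata
  # ASCII grids run north to south
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @param name optional layer name.
#' @return a [grid_surface()].
#' @export
read_esri_ascii <- function(path, name = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("incomplete ESRI ASCII header")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("cell count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]   # back to south-up storage
  geom <- grid_geometry(origin_lon = hdr$xllcorner + hdr$cellsize / 2,
                        origin_lat = hdr$yllcorner + hdr$cellsize / 2,
                        cell_arcmin = hdr$cellsize * 60,
                        n_rows = nr, n_cols = nc)
  v <- as.numeric(t(m))
  mask <- v != nodata
  v[!mask] <- NA_real_
  v[!mask] <- 0
  grid_surface(geom, v, mask = mask, name = name)
}
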