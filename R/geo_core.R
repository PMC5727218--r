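#' Construct a multi-layer environmental grid
#'
#' An `env_grid` is the package's in-memory form of a bioclim-style raster
#' stack: a set of equally-dimensioned real-valued layers (e.g. BIO1--BIO19)
#' on a regular lon/lat grid, with a shared NODATA mask. Row 1 is the
#' northernmost row, matching the ESRI ASCII grid layout.
#'
#' @param layers named list of numeric matrices, all with identical dimensions.
#' @param xll,yll longitude/latitude of the lower-left corner of the grid, in
#'   degrees.
#' @param cellsize cell size in degrees (> 0).
#' @param mask logical matrix, `TRUE` where a cell carries data. Defaults to
#'   all `TRUE`. Cells masked out are written as NODATA.
#' @return an object of class `env_grid`.
#' @export
env_grid <- function(layers, xll = 0, yll = 0, cellsize = 1, mask = NULL) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty named list of matrices")
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  dims <- lapply(layers, dim)
  if (any(vapply(dims, is.null, logical(1L))))
    stop("all layers must be matrices")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1L))))
    stop("all layers must share dimensions")
  if (cellsize <= 0) stop("cellsize must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, d0[1L], d0[2L])
  if (!identical(dim(mask), d0)) stop("mask dimensions must match layers")
  lon_max <- xll + d0[2L] * cellsize
  lat_max <- yll + d0[1L] * cellsize
  if (xll < -180 || lon_max > 180 + 1e-9 || yll < -90 || lat_max > 90 + 1e-9)
    stop("grid extent outside valid lon/lat ranges")
  structure(
    list(n_rows = d0[1L], n_cols = d0[2L], xll = xll, yll = yll,
         cellsize = cellsize, mask = mask, layers = layers),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells, %d layer(s) [%s]\n",
              x$n_rows, x$n_cols, length(x$layers),
              paste(utils::head(names(x$layers), 5L), collapse = ", ")))
  cat(sprintf("  origin (%g, %g), cellsize %g deg, %d/%d cells unmasked\n",
              x$xll, x$yll, x$cellsize, sum(x$mask), length(x$mask)))
  invisible(x)
}

# cell centers; row 1 = north
cell_centers <- function(grid) {
  lon <- grid$xll + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
  lat <- grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) * grid$cellsize
  list(lon = lon, lat = lat)
}

#' Map lon/lat points to grid cell indices
#'
#' Cells are half-open: `[x, x + cellsize)` in longitude and latitude, so a
#' point on a shared edge belongs to the cell with the larger column index /
#' the more northern cell boundary owner (deterministic standard raster
#' convention). Internal helper, exported for testability.
#'
#' @param grid an `env_grid`.
#' @param lon,lat numeric vectors of coordinates in degrees.
#' @return data.frame with columns `row`, `col` (1-based; row 1 = north).
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  # latitude measured from the south edge; row 1 is the northern row
  from_south <- floor((lat - grid$yll) / grid$cellsize) + 1L
  row <- grid$n_rows - from_south + 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  data.frame(row = as.integer(row), col = as.integer(col), outside = bad)
}

#' Read one layer from an ESRI ASCII grid file
#'
#' Parses the six-line ESRI ASCII header (ncols, nrows, xllcorner, yllcorner,
#' cellsize, NODATA_value) followed by row-major values, row 1 = north.
#' The write/read pair is lossless for values and mask.
#'
#' @param path file path.
#' @param layer_name name given to the layer (default: file base name).
#' @return an `env_grid` with a single layer; NODATA cells are masked and
#'   stored as `NA`.
#' @export
read_ascii_grid <- function(path, layer_name = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("ESRI ASCII grid: file too short for header")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("ESRI ASCII grid: malformed header line %d: '%s'", i, lines[i]))
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ESRI ASCII grid: missing header field(s): ", paste(miss, collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- unlist(strsplit(trimws(lines[-(1:6)]), "\\s+"))
  body <- body[nzchar(body)]
  if (length(body) != nr * nc)
    stop(sprintf(
      "ESRI ASCII grid: body has %d values but header declares %d x %d = %d (first body line: '%s')",
      length(body), nr, nc, nr * nc, trimws(lines[7L])))
  m <- matrix(as.numeric(body), nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m != hdr$nodata_value
  m[!mask] <- NA_real_
  if (is.null(layer_name)) layer_name <- sub("\\.[^.]*$", "", basename(path))
  lays <- stats::setNames(list(m), layer_name)
  env_grid(lays, xll = hdr$xllcorner, yll = hdr$yllcorner,
           cellsize = hdr$cellsize, mask = mask)
}

#' Write one layer of an `env_grid` as an ESRI ASCII grid
#'
#' @param grid an `env_grid`.
#' @param layer layer name or index to write.
#' @param path output file path.
#' @param nodata NODATA sentinel written for masked cells (default -9999).
#' @param digits significant digits for values (default 15, lossless for
#'   doubles in practice).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, layer, path, nodata = -9999, digits = 15) {
  stopifnot(inherits(grid, "env_grid"))
  m <- grid$layers[[layer]]
  if (is.null(m)) stop("no such layer: ", layer)
  m[!grid$mask | is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Great-circle distance in kilometres
#'
#' Haversine formula on a spherical Earth of radius 6371.0 km. Symmetric,
#' non-negative, zero only for identical points. Vectorized over pairs.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range: lon in [-180,180], lat in [-90,90]")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  6371.0 * 2 * asin(sqrt(a))
}

# full pairwise haversine distance matrix between two point sets
haversine_matrix <- function(lon1, lat1, lon2, lat2) {
  n1 <- length(lon1); n2 <- length(lon2)
  outer(seq_len(n1), seq_len(n2), function(i, j)
    haversine_km(lon1[i], lat1[i], lon2[j], lat2[j]))
}

#' Extract layer values at point locations
#'
#' Returns one row per point and one column per layer, taken from the cell
#' containing each point (half-open cell convention, see [cell_index()]).
#' Points falling in masked cells are kept but flagged, never silently
#' dropped.
#'
#' @param grid an `env_grid`.
#' @param lon,lat point coordinates in degrees.
#' @return list with `values` (numeric matrix, points x layers), `masked`
#'   (logical, point fell in a NODATA cell), `cell` (row/col data.frame).
#' @export
extract_cell_values <- function(grid, lon, lat) {
  idx <- cell_index(grid, lon, lat)
  if (any(idx$outside)) {
    bad <- which(idx$outside)
    stop(sprintf("point(s) outside grid extent: %s",
                 paste(sprintf("(%g, %g)", lon[bad], lat[bad]), collapse = ", ")))
  }
  lin <- cbind(idx$row, idx$col)
  vals <- vapply(grid$layers, function(m) m[lin], numeric(nrow(idx)))
  if (length(lon) == 1L) vals <- matrix(vals, nrow = 1L,
                                        dimnames = list(NULL, names(grid$layers)))
  masked <- !grid$mask[lin]
  list(values = vals, masked = masked, cell = idx[, c("row", "col")])
}

#' Read / write an occurrence CSV
#'
#' The occurrence table format is a CSV with required columns
#' `taxon,lon,lat`; extra columns are preserved.
#'
#' @param path file path.
#' @return data.frame with at least `taxon`, `lon`, `lat`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
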