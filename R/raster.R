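#' Rectangular grid raster
#'
#' The common currency of every layer in the package: a rectangular matrix of
#' cell values with a square cell size in metres, an origin (the x,y of the
#' lower-left corner of the grid, in metres) and a nodata sentinel.  Row 1 is
#' the top of the map; cell centres sit at half-cell offsets from the origin.
#'
#' @param values numeric matrix of cell values (row 1 = northernmost row).
#' @param cell_size cell edge length in metres (default 500, the working
#'   resolution used throughout the package).
#' @param origin numeric length-2, x/y of the lower-left grid corner (metres).
#' @param nodata value marking invalid cells; cells equal to `nodata` (or
#'   `NA`) are excluded from all statistics.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size = 500, origin = c(0, 0),
                        nodata = NA_real_) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L)
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("grid dimensions must be positive")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a positive scalar (metres)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = nodata),
    class = "grid_raster"
  )
}

#' @export
is_grid_raster <- function(x) inherits(x, "grid_raster")

#' @export
as.matrix.grid_raster <- function(x, ...) x$values

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  v <- raster_values(x)
  cat(sprintf("<grid_raster> %d x %d cells, %g m resolution\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  if (length(v)) {
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g (%d valid cells)\n",
                min(v), mean(v), max(v), length(v)))
  } else {
    cat("  no valid cells\n")
  }
  invisible(x)
}

#' @export
plot.grid_raster <- function(x, main = NULL, ...) {
  m <- x$values
  m[is_nodata_cell(x)] <- NA
  # transpose/flip so the printed orientation (row 1 = north) is preserved
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  asp = nrow(m) / ncol(m), axes = FALSE, main = main, ...)
  invisible(x)
}

# logical matrix of invalid cells
is_nodata_cell <- function(x) {
  v <- x$values
  bad <- is.na(v)
  if (!is.na(x$nodata)) bad <- bad | (v == x$nodata)
  bad
}

#' Valid cell values of a raster
#'
#' @param x a `grid_raster`.
#' @return Numeric vector of the values of all valid (non-nodata) cells.
#' @export
raster_values <- function(x) {
  stopifnot(is_grid_raster(x))
  x$values[!is_nodata_cell(x)]
}

# Construct a raster sharing x's geometry but holding new values.
raster_like <- function(x, values, nodata = x$nodata) {
  grid_raster(matrix(values, nrow(x$values), ncol(x$values)),
              cell_size = x$cell_size, origin = x$origin, nodata = nodata)
}

#' Check that rasters share geometry
#'
#' All layers entering a joint computation must share shape, cell size and
#' origin; misalignment is an error, never silently resampled.
#'
#' @param ... two or more `grid_raster` objects.
#' @return Invisibly `TRUE`; stops on misalignment.
#' @export
check_aligned <- function(...) {
  rs <- list(...)
  stopifnot(length(rs) >= 2L)
  ref <- rs[[1L]]
  for (r in rs[-1L]) {
    if (!is_grid_raster(r) || !is_grid_raster(ref))
      stop("all inputs must be grid_raster objects")
    if (!identical(dim(r$values), dim(ref$values)))
      stop("rasters are misaligned: differing dimensions")
    if (!isTRUE(all.equal(r$cell_size, ref$cell_size)))
      stop("rasters are misaligned: differing cell size")
    if (!isTRUE(all.equal(r$origin, ref$origin)))
      stop("rasters are misaligned: differing origin")
  }
  invisible(TRUE)
}

#' Scale a raster to the unit interval
#'
#' Divides every valid cell by the raster maximum, so values land in
#' \[0, 1\] with the maximum exactly 1 and ordering preserved.  This is the
#' standard pre-processing applied to all continuous layers before they are
#' aggregated to planning units.
#'
#' @param x a `grid_raster` with positive maximum.
#' @return The rescaled `grid_raster`.
#' @export
normalize_layer <- function(x) {
  stopifnot(is_grid_raster(x))
  v <- raster_values(x)
  if (!length(v) || max(v) <= 0)
    stop("cannot normalize: raster maximum is not positive")
  out <- x
  keep <- !is_nodata_cell(x)
  out$values[keep] <- x$values[keep] / max(v)
  out
}

#' Binary forest mask from a categorical land-cover raster
#'
#' @param landcover `grid_raster` of integer class codes.
#' @param forest_class_set integer codes counted as forest (default: the
#'   five forest classes of [landcover_classes()]).
#' @param known_codes the universe of legal codes; any other code in the
#'   raster is an error.
#' @return 0/1 `grid_raster` (1 = forest).
#' @export
classify_forest <- function(landcover,
                            forest_class_set = forest_codes(),
                            known_codes = landcover_classes()$code) {
  stopifnot(is_grid_raster(landcover))
  codes <- raster_values(landcover)
  unknown <- setdiff(unique(codes), known_codes)
  if (length(unknown))
    stop("unknown land-cover code(s): ", paste(unknown, collapse = ", "))
  out <- raster_like(landcover, 0)
  keep <- !is_nodata_cell(landcover)
  out$values[keep] <- as.numeric(landcover$values[keep] %in% forest_class_set)
  out$values[!keep] <- NA_real_
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format; the companion reader is
#' [read_esri_ascii()].  NODATA cells are written as the header's
#' `NODATA_value`.
#'
#' @param x a `grid_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata_value sentinel written for invalid cells.
#' @export
write_esri_ascii <- function(x, path, nodata_value = -9999) {
  stopifnot(is_grid_raster(x))
  v <- x$values
  v[is_nodata_cell(x)] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$origin[1L]),
    sprintf("yllcorner %.10g", x$origin[2L]),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %.10g", nodata_value)
  ), con)
  write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_esri_ascii()] or any conforming tool.
#' @return A `grid_raster`; cells equal to the header's `NODATA_value`
#'   become `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- lapply(strsplit(trimws(lines), "\\s+"), function(p)
    list(key = tolower(p[[1L]]), value = as.numeric(p[[2L]])))
  kv <- setNames(vapply(hdr, `[[`, numeric(1), "value"),
                 vapply(hdr, `[[`, character(1), "key"))
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (!k %in% names(kv)) stop("malformed ESRI ASCII header: missing ", k)
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(as.integer(kv[["nrows"]]), as.integer(kv[["ncols"]]))))
    stop("ESRI ASCII body does not match header dimensions")
  if ("nodata_value" %in% names(kv)) m[m == kv[["nodata_value"]]] <- NA_real_
  grid_raster(m, cell_size = kv[["cellsize"]],
              origin = c(kv[["xllcorner"]], kv[["yllcorner"]]))
}

#' Moran's I spatial autocorrelation of a raster
#'
#' Rook-neighbour Moran's I, used as a diagnostic that generated surfaces
#' are spatially structured rather than white noise.
#'
#' @param x a `grid_raster` with no nodata cells.
#' @return Moran's I statistic (scalar).
#' @export
morans_i <- function(x) {
  stopifnot(is_grid_raster(x))
  m <- x$values
  if (anyNA(m)) stop("morans_i expects a complete raster")
  z <- m - mean(m)
  num <- sum(z[-nrow(z), ] * z[-1L, ]) + sum(z[, -ncol(z)] * z[, -1L])
  w <- (nrow(m) - 1L) * ncol(m) + nrow(m) * (ncol(m) - 1L)
  (length(m) / w) * (num / sum(z^2))
}
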