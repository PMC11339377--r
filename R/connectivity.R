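#' Resistant-kernel parameters
#'
#' @param bandwidth dispersal threshold in cost units (accumulated
#'   resistance-weighted metres); 125000 and 250000 bracket plausible
#'   dispersal for a mid-sized forest carnivore at the least-cost
#'   (resistance 1) condition.
#' @param neighbourhood cell adjacency for movement (8, queen's move).
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(bandwidth = 125000, neighbourhood = 8) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (!neighbourhood %in% c(4, 8)) stop("neighbourhood must be 4 or 8")
  structure(list(bandwidth = bandwidth, neighbourhood = as.integer(neighbourhood)),
            class = "kernel_params")
}

# Weighted lattice graph over the valid cells of a resistance raster.
# Edge weight between adjacent cells a,b: distance_factor * (r_a + r_b)/2 *
# cell_size, distance_factor 1 orthogonal / sqrt(2) diagonal -- the standard
# cost-distance convention.  Returns the igraph plus the cell->vertex map.
resistance_graph <- function(resistance, neighbourhood = 8) {
  stopifnot(is_grid_raster(resistance))
  r <- resistance$values
  if (any(r[!is_nodata_cell(resistance)] < 1))
    stop("resistance must be >= 1 everywhere")
  nr <- nrow(r); nc <- ncol(r)
  valid <- !is_nodata_cell(resistance)
  cell_id <- matrix(NA_integer_, nr, nc)
  cell_id[valid] <- seq_len(sum(valid))
  cs <- resistance$cell_size

  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (neighbourhood == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(); to <- integer(); w <- numeric()
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    rows_a <- seq_len(nr - abs(dr)); cols_a <- seq_len(nc - abs(dc))
    if (dr >= 0) { ra <- rows_a; rb <- rows_a + dr } else { ra <- rows_a - dr; rb <- rows_a }
    if (dc >= 0) { ca <- cols_a; cb <- cols_a + dc } else { ca <- cols_a - dc; cb <- cols_a }
    a <- cell_id[ra, ca, drop = FALSE]; b <- cell_id[rb, cb, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    dfac <- if (dr != 0L && dc != 0L) sqrt(2) else 1
    wa <- r[ra, ca, drop = FALSE]; wb <- r[rb, cb, drop = FALSE]
    from <- c(from, a[ok]); to <- c(to, b[ok])
    w <- c(w, dfac * (wa[ok] + wb[ok]) / 2 * cs)
  }
  g <- igraph::make_empty_graph(n = sum(valid), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, cell_id = cell_id, valid = valid,
       nrows = nr, ncols = nc)
}

# rows/cols -> vertex indices on a resistance_graph
cells_to_vertices <- function(rg, rows, cols) {
  v <- rg$cell_id[cbind(rows, cols)]
  if (anyNA(v)) stop("source on a nodata cell")
  v
}

#' Accumulated least-cost surface from one source cell
#'
#' Dijkstra least-accumulated cost from the source over the 8- (or 4-)
#' neighbour lattice; cells whose cost exceeds `max_cost` are marked
#' unreachable (`Inf`).
#'
#' @param resistance resistance `grid_raster` (>= 1 on valid cells).
#' @param source length-2 integer `(row, col)` of the source cell.
#' @param max_cost reachability threshold in cost units.
#' @param neighbourhood 4 or 8.
#' @return `grid_raster` of accumulated costs (0 at the source).
#' @export
accumulate_cost <- function(resistance, source, max_cost = Inf,
                            neighbourhood = 8) {
  rg <- resistance_graph(resistance, neighbourhood)
  v <- cells_to_vertices(rg, source[1L], source[2L])
  d <- as.numeric(igraph::distances(rg$graph, v = v, algorithm = "dijkstra"))
  out <- matrix(NA_real_, rg$nrows, rg$ncols)
  out[rg$valid] <- d
  out[!is.na(out) & out > max_cost] <- Inf
  raster_like(resistance, out)
}

#' Regular source-point lattice on forest
#'
#' Deterministic grid of candidate dispersal sources: every `spacing`-th
#' cell (offset to the block centre), kept only where the mask is 1.
#'
#' @param forest_mask 0/1 `grid_raster`.
#' @param spacing lattice period in cells (>= 1).
#' @param seed accepted for interface symmetry; placement is deterministic.
#' @return data.frame `row`, `col` of source cells.
#' @export
place_sources <- function(forest_mask, spacing, seed = NULL) {
  stopifnot(is_grid_raster(forest_mask))
  if (spacing < 1) stop("spacing must be >= 1")
  f <- forest_mask$values > 0
  if (!any(f, na.rm = TRUE)) stop("no forest cells to place sources on")
  off <- ceiling(spacing / 2)
  rows <- seq(off, nrow(f), by = spacing)
  cols <- seq(off, ncol(f), by = spacing)
  pts <- expand.grid(row = rows, col = cols)
  keep <- f[cbind(pts$row, pts$col)]
  keep[is.na(keep)] <- FALSE
  pts[keep, , drop = FALSE]
}

#' Cumulative resistant-kernel density surface
#'
#' For each source the kernel is a linear decay of the accumulated least
#' cost, `k_s(x) = max(0, 1 - cost_s(x)/bandwidth)` -- density 1 in the
#' source's own cell, 0 at and beyond the bandwidth -- and the surface is
#' the superposed sum over sources.
#'
#' @param resistance resistance `grid_raster`.
#' @param sources data.frame `row`, `col` (at least one source).
#' @param params a [kernel_params()].
#' @return kernel-density `grid_raster` (>= 0).
#' @export
resistant_kernel_density <- function(resistance, sources,
                                     params = kernel_params()) {
  stopifnot(inherits(params, "kernel_params"))
  if (is.null(sources) || nrow(sources) == 0L) stop("empty source set")
  rg <- resistance_graph(resistance, params$neighbourhood)
  v <- cells_to_vertices(rg, sources$row, sources$col)
  d <- igraph::distances(rg$graph, v = v, algorithm = "dijkstra")
  contrib <- 1 - d / params$bandwidth
  contrib[contrib < 0 | !is.finite(contrib)] <- 0
  k <- colSums(contrib)
  out <- matrix(NA_real_, rg$nrows, rg$ncols)
  out[rg$valid] <- k
  raster_like(resistance, out)
}

#' Threshold a kernel surface into core habitat
#'
#' The threshold is the given percentile of the kernel density over cells
#' with positive density (computing it over the full raster of mostly zeros
#' would make a low percentile trivially 0); a cell is core iff its density
#' strictly exceeds the threshold.
#'
#' When comparing scenario maps, pass the baseline map's threshold via
#' `threshold` so every scenario is cut at the same absolute density.
#'
#' @param K kernel-density `grid_raster`.
#' @param percentile percentile in \[0, 100) (default 10).
#' @param threshold absolute density threshold; overrides `percentile`.
#' @return 0/1 `grid_raster` of core habitat.
#' @export
threshold_core <- function(K, percentile = 10, threshold = NULL) {
  stopifnot(is_grid_raster(K))
  v <- raster_values(K)
  pos <- v[v > 0]
  if (!length(pos)) stop("kernel surface is identically zero")
  thr <- if (!is.null(threshold)) threshold else
    quantile(pos, percentile / 100, names = FALSE)
  out <- raster_like(K, as.numeric(K$values > thr))
  out$values[is_nodata_cell(K)] <- NA_real_
  out
}

# 8-connected component labels of a binary raster; 0 = background.
label_patches <- function(binary) {
  stopifnot(is_grid_raster(binary))
  b <- binary$values > 0
  b[is.na(b)] <- FALSE
  nr <- nrow(b); nc <- ncol(b)
  idx <- which(b)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- match(idx, idx)
  cellpos <- matrix(NA_integer_, nr, nc)
  cellpos[idx] <- seq_along(idx)
  from <- integer(); to <- integer()
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    dr <- s[1L]; dc <- s[2L]
    rows_a <- seq_len(nr - abs(dr)); cols_a <- seq_len(nc - abs(dc))
    if (dc >= 0) { ca <- cols_a; cb <- cols_a + dc } else { ca <- cols_a - dc; cb <- cols_a }
    ra <- rows_a; rb <- rows_a + dr
    a <- cellpos[ra, ca, drop = FALSE]; bb <- cellpos[rb, cb, drop = FALSE]
    ok <- !is.na(a) & !is.na(bb)
    from <- c(from, a[ok]); to <- c(to, bb[ok])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' FRAGSTATS-style patch metrics of a binary habitat map
#'
#' Patches are 8-connected components.  Reports the percentage of the
#' landscape under habitat (`pland`), the patch count (`np`), the largest
#' patch index (`lpi`, % of landscape), the area-weighted mean patch size
#' (`awmps = sum(a^2)/sum(a)`, km2) and the correlation length
#' (`correlation_length_km`): the area-weighted mean radius of gyration,
#' where a patch's radius of gyration is the mean Euclidean distance of its
#' cell centres to the patch centroid -- the expected within-patch
#' traversal distance from a random start.
#'
#' @param binary 0/1 `grid_raster`.
#' @param cell_size cell edge in metres (default: the raster's own).
#' @return list of class `patch_metrics` with fields `pland`, `np`, `lpi`,
#'   `awmps_km2`, `correlation_length_km`, `total_habitat_km2`.
#' @export
patch_metrics <- function(binary, cell_size = binary$cell_size) {
  stopifnot(is_grid_raster(binary))
  lab <- label_patches(binary)
  n_land <- sum(!is_nodata_cell(binary))
  cell_km2 <- (cell_size / 1000)^2
  np <- max(lab)
  if (np == 0L) {
    return(structure(list(pland = 0, np = 0L, lpi = 0, awmps_km2 = 0,
                          correlation_length_km = 0, total_habitat_km2 = 0),
                     class = "patch_metrics"))
  }
  cells <- which(lab > 0, arr.ind = TRUE)
  patch <- lab[lab > 0]
  x <- (cells[, "col"] - 0.5) * cell_size / 1000
  y <- (cells[, "row"] - 0.5) * cell_size / 1000
  a <- as.numeric(table(factor(patch, levels = seq_len(np)))) * cell_km2
  cx <- tapply(x, patch, mean); cy <- tapply(y, patch, mean)
  gyr <- vapply(seq_len(np), function(i) {
    k <- patch == i
    mean(sqrt((x[k] - cx[[i]])^2 + (y[k] - cy[[i]])^2))
  }, numeric(1))
  tot <- sum(a)
  structure(list(
    pland = 100 * tot / (n_land * cell_km2),
    np = as.integer(np),
    lpi = 100 * max(a) / (n_land * cell_km2),
    awmps_km2 = sum(a^2) / tot,
    correlation_length_km = sum((a / tot) * gyr),
    total_habitat_km2 = tot
  ), class = "patch_metrics")
}

#' @export
print.patch_metrics <- function(x, ...) {
  cat(sprintf(paste0("<patch_metrics> pland %.1f%%, np %d, lpi %.1f%%, ",
                     "awmps %.1f km2, correlation length %.2f km\n"),
              x$pland, x$np, x$lpi, x$awmps_km2, x$correlation_length_km))
  invisible(x)
}
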