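#' Aggregate raster layers to a planning-unit table
#'
#' Tiles the grid into square blocks of `unit_size_cells` x `unit_size_cells`
#' cells (edge blocks may be truncated, mirroring coastal partial units) and
#' aggregates each layer over the member cells: forest and protected area
#' in km2, kernel and carbon sums, and the mean loss risk over forest cells.
#' Cell-level adjacency yields the shared boundary length between
#' neighbouring units and each unit's total perimeter (landscape exterior
#' included).
#'
#' @param layers named list of aligned `grid_raster`s with elements
#'   `forest` (0/1), `pa` (0/1), `kernel`, `carbon`, `risk`.
#' @param unit_size_cells block edge in cells (e.g. 20 cells of 500 m = a
#'   10 x 10 km unit).
#' @return list of class `planning_units` with elements:
#'   `units` (data.frame: id, row_block, col_block, n_cells, area_km2,
#'   forest_area_km2, pa_area_km2, kernel_sum, carbon_sum, mean_risk,
#'   available, locked), `boundary` (data.frame id1 < id2, length_km),
#'   `perimeter_km` (named by id), `unit_map` (`grid_raster` of unit ids),
#'   `cell_size`, `unit_size_cells`.
#' @export
build_planning_units <- function(layers, unit_size_cells) {
  needed <- c("forest", "pa", "kernel", "carbon", "risk")
  if (!all(needed %in% names(layers)))
    stop("layers must name: ", paste(needed, collapse = ", "))
  do.call(check_aligned, layers[needed])
  if (unit_size_cells < 1L) stop("unit_size_cells must be >= 1")
  f <- layers$forest$values
  nr <- nrow(f); nc <- ncol(f)
  cs_km <- layers$forest$cell_size / 1000
  cell_km2 <- cs_km^2

  rb <- (seq_len(nr) - 1L) %/% unit_size_cells
  cb <- (seq_len(nc) - 1L) %/% unit_size_cells
  n_cb <- max(cb) + 1L
  uid_mat <- outer(rb, cb, function(r, c) r * n_cb + c + 1L)
  valid <- !is_nodata_cell(layers$forest)
  uid <- uid_mat
  uid[!valid] <- NA_integer_

  ids <- sort(unique(uid[valid]))
  agg <- function(v, fun = sum) {
    x <- tapply(v[valid], uid[valid], fun)
    out <- setNames(numeric(length(ids)), ids)
    out[names(x)] <- x
    out
  }
  n_cells <- agg(rep(1, sum(valid)))
  forest_cells <- agg(as.numeric(f[valid] > 0))
  pa_cells <- agg(as.numeric(layers$pa$values[valid] > 0))
  kernel_sum <- agg(layers$kernel$values[valid])
  carbon_sum <- agg(layers$carbon$values[valid])
  risk_sum_forest <- agg(layers$risk$values[valid] * (f[valid] > 0))
  mean_risk <- ifelse(forest_cells > 0, risk_sum_forest / forest_cells, 0)

  units <- data.frame(
    id = as.integer(ids),
    row_block = as.integer((ids - 1L) %/% n_cb),
    col_block = as.integer((ids - 1L) %% n_cb),
    n_cells = as.integer(n_cells),
    area_km2 = n_cells * cell_km2,
    forest_area_km2 = forest_cells * cell_km2,
    pa_area_km2 = pa_cells * cell_km2,
    kernel_sum = as.numeric(kernel_sum),
    carbon_sum = as.numeric(carbon_sum),
    mean_risk = as.numeric(mean_risk),
    available = NA, locked = NA
  )

  # cell-edge bookkeeping: horizontal and vertical valid-cell pairs
  edge_pairs <- function(a, b) data.frame(u = a, v = b)
  hp <- NULL; vp <- NULL
  if (nr > 1L) {
    a <- uid[-nr, ]; b <- uid[-1L, ]
    keep <- !is.na(a) & !is.na(b)
    vp <- edge_pairs(a[keep], b[keep])
  }
  if (nc > 1L) {
    a <- uid[, -nc]; b <- uid[, -1L]
    keep <- !is.na(a) & !is.na(b)
    hp <- edge_pairs(a[keep], b[keep])
  }
  pairs <- rbind(hp, vp)
  internal_edges <- setNames(numeric(length(ids)), ids)
  boundary <- data.frame(id1 = integer(), id2 = integer(), length_km = numeric())
  if (!is.null(pairs) && nrow(pairs)) {
    same <- pairs$u == pairs$v
    if (any(same)) {
      t1 <- table(pairs$u[same])
      internal_edges[names(t1)] <- as.numeric(t1)
    }
    if (any(!same)) {
      p <- pairs[!same, , drop = FALSE]
      lo <- pmin(p$u, p$v); hi <- pmax(p$u, p$v)
      key <- paste(lo, hi)
      t2 <- table(key)
      parts <- strsplit(names(t2), " ", fixed = TRUE)
      boundary <- data.frame(
        id1 = as.integer(vapply(parts, `[[`, character(1), 1L)),
        id2 = as.integer(vapply(parts, `[[`, character(1), 2L)),
        length_km = as.numeric(t2) * cs_km
      )
    }
  }
  # perimeter of each unit = 4*cells - 2*internal edges (cell_km each),
  # counting edges against nodata or the map exterior as exposed
  shared_sum <- setNames(numeric(length(ids)), ids)
  if (nrow(boundary)) {
    s1 <- tapply(boundary$length_km, boundary$id1, sum)
    s2 <- tapply(boundary$length_km, boundary$id2, sum)
    shared_sum[names(s1)] <- shared_sum[names(s1)] + s1
    shared_sum[names(s2)] <- shared_sum[names(s2)] + s2
  }
  perimeter_km <- 4 * n_cells * cs_km - 2 * internal_edges * cs_km - shared_sum
  # perimeter_km currently = exterior edge length; total unit perimeter is
  # exterior + shared with neighbours
  perimeter_km <- perimeter_km + shared_sum

  structure(list(units = units, boundary = boundary,
                 perimeter_km = perimeter_km,
                 unit_map = raster_like(layers$forest, as.numeric(uid_mat)),
                 cell_size = layers$forest$cell_size,
                 unit_size_cells = as.integer(unit_size_cells)),
            class = "planning_units")
}

#' @export
print.planning_units <- function(x, ...) {
  u <- x$units
  cat(sprintf("<planning_units> %d units of up to %d x %d cells\n",
              nrow(u), x$unit_size_cells, x$unit_size_cells))
  if (!all(is.na(u$available)))
    cat(sprintf("  available %d, locked %d\n", sum(u$available), sum(u$locked)))
  invisible(x)
}

#' Apply habitat and protection eligibility rules
#'
#' A unit is `available` for selection iff it holds at least
#' `min_forest_km2` of forest; it is `locked` (treated as already protected)
#' iff it holds strictly more than `min_pa_km2` of existing protected area.
#' Locked units are forced available regardless of forest area, since
#' scenarios that retain the estate lock them in unconditionally.  The 16
#' km2 default for both thresholds corresponds to one female home range.
#'
#' @param pu a `planning_units` object.
#' @param min_forest_km2 forest threshold (inclusive).
#' @param min_pa_km2 protection threshold (strict).
#' @return `pu` with `available`/`locked` filled in; idempotent.
#' @export
apply_eligibility <- function(pu, min_forest_km2 = 16, min_pa_km2 = 16) {
  stopifnot(inherits(pu, "planning_units"))
  u <- pu$units
  if (any(u$forest_area_km2 < 0) || any(u$pa_area_km2 < 0))
    stop("negative areas are invalid")
  u$locked <- u$pa_area_km2 > min_pa_km2
  u$available <- (u$forest_area_km2 >= min_forest_km2) | u$locked
  pu$units <- u
  pu
}

#' Rasterise a set of planning units
#'
#' @param pu a `planning_units` object.
#' @param ids unit ids to mark.
#' @return 0/1 `grid_raster`, 1 on every cell of the listed units.
#' @export
units_to_mask <- function(pu, ids) {
  stopifnot(inherits(pu, "planning_units"))
  raster_like(pu$unit_map, as.numeric(pu$unit_map$values %in% ids))
}

#' Write a reserve problem in the MARXAN file dialect
#'
#' Emits `pu.dat` (id, cost, status: 2 = locked in), `spec.dat` (id, name,
#' target, spf), `puvspr.dat` (species, pu, amount; ordered by pu) and
#' `bound.dat` (id1, id2, boundary) for interoperability with the original
#' tool chain.
#'
#' @param problem a [reserve_problem()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_marxan <- function(problem, dir) {
  stopifnot(inherits(problem, "reserve_problem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  p1 <- wt(data.frame(id = problem$ids, cost = problem$cost,
                      status = ifelse(problem$locked, 2L, 0L)),
           file.path(dir, "pu.dat"))
  feats <- colnames(problem$amounts)
  p2 <- wt(data.frame(id = seq_along(feats), name = feats,
                      target = problem$targets, prop = NA,
                      spf = problem$spf),
           file.path(dir, "spec.dat"))
  pv <- do.call(rbind, lapply(seq_along(feats), function(j) {
    amt <- problem$amounts[, j]
    keep <- amt != 0
    data.frame(species = j, pu = problem$ids[keep], amount = amt[keep])
  }))
  pv <- pv[order(pv$pu, pv$species), ]
  p3 <- wt(pv, file.path(dir, "puvspr.dat"))
  p4 <- wt(data.frame(id1 = problem$boundary$id1, id2 = problem$boundary$id2,
                      boundary = problem$boundary$length_km),
           file.path(dir, "bound.dat"))
  invisible(c(p1, p2, p3, p4))
}

#' Read a MARXAN-dialect problem directory
#'
#' Counterpart of [write_marxan()].  Unit perimeters cannot be recovered
#' from `bound.dat` alone, so exterior exposure defaults to each unit's
#' summed shared boundary unless `perimeter_km` is supplied.
#'
#' @param dir directory holding `pu.dat`, `spec.dat`, `puvspr.dat`,
#'   `bound.dat`.
#' @param blm boundary length modifier for the reconstructed problem.
#' @param perimeter_km optional named vector of unit perimeters (km).
#' @return a [reserve_problem()].
#' @export
read_marxan <- function(dir, blm = 0.0015, perimeter_km = NULL) {
  rd <- function(f) read.table(file.path(dir, f), header = TRUE, sep = "\t")
  pu <- rd("pu.dat"); sp <- rd("spec.dat"); pv <- rd("puvspr.dat")
  bd <- rd("bound.dat")
  amounts <- matrix(0, nrow(pu), nrow(sp),
                    dimnames = list(NULL, sp$name))
  for (k in seq_len(nrow(pv))) {
    i <- match(pv$pu[k], pu$id); j <- pv$species[k]
    amounts[i, j] <- pv$amount[k]
  }
  if (is.null(perimeter_km)) {
    perimeter_km <- setNames(numeric(nrow(pu)), pu$id)
    for (k in seq_len(nrow(bd))) {
      perimeter_km[as.character(bd$id1[k])] <-
        perimeter_km[as.character(bd$id1[k])] + bd$boundary[k]
      perimeter_km[as.character(bd$id2[k])] <-
        perimeter_km[as.character(bd$id2[k])] + bd$boundary[k]
    }
  }
  reserve_problem(ids = pu$id, cost = pu$cost, amounts = amounts,
                  targets = sp$target, spf = sp$spf, blm = blm,
                  locked = pu$status == 2L,
                  boundary = data.frame(id1 = bd$id1, id2 = bd$id2,
                                        length_km = bd$boundary),
                  perimeter_km = perimeter_km)
}
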