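#' Fixed habitat points with a pairwise cost-distance matrix
#'
#' The individual-based simulation runs on a fixed set of habitat points
#' (one potential territory each); movement between points is governed by
#' their least-cost distance through the resistance surface.
#'
#' @param coords data.frame `row`, `col` of point cells.
#' @param costmat symmetric matrix of pairwise accumulated costs, zero
#'   diagonal, `Inf` for unreachable pairs.
#' @return list of class `habitat_points`.
#' @export
habitat_points <- function(coords, costmat) {
  n <- nrow(coords)
  costmat <- as.matrix(costmat)
  stopifnot(nrow(costmat) == n, ncol(costmat) == n)
  if (any(abs(diag(costmat)) > 1e-9)) stop("cost matrix diagonal must be 0")
  if (any(costmat < 0)) stop("costs must be non-negative")
  if (max(abs(costmat - t(costmat)), na.rm = TRUE) > 1e-6)
    stop("cost matrix must be symmetric")
  structure(list(coords = coords, costmat = costmat, n = n),
            class = "habitat_points")
}

#' @export
print.habitat_points <- function(x, ...) {
  finite <- x$costmat[upper.tri(x$costmat)]
  cat(sprintf("<habitat_points> %d points; %.1f%% of pairs mutually reachable\n",
              x$n, if (length(finite)) 100 * mean(is.finite(finite)) else 100))
  invisible(x)
}

#' Lay out habitat points on core habitat and compute their cost matrix
#'
#' Points sit on a regular lattice restricted to core cells, spaced so each
#' point commands roughly one territory (default one per 16 km2, a female
#' home range).  Pairwise costs come from multi-source least-cost paths on
#' the resistance surface; pairs with no finite-cost route are `Inf`.
#'
#' @param core_mask 0/1 `grid_raster` of core habitat (nonempty).
#' @param resistance resistance `grid_raster`.
#' @param spacing lattice period in cells; `NULL` derives it from
#'   `home_range_km2` and the cell size.
#' @param home_range_km2 territory area used to derive the default spacing.
#' @param seed accepted for interface symmetry; layout is deterministic.
#' @return a [habitat_points()].
#' @export
build_points <- function(core_mask, resistance, spacing = NULL,
                         home_range_km2 = 16, seed = NULL) {
  stopifnot(is_grid_raster(core_mask), is_grid_raster(resistance))
  check_aligned(core_mask, resistance)
  if (!any(core_mask$values > 0, na.rm = TRUE)) stop("core mask is empty")
  if (is.null(spacing))
    spacing <- max(1L, round(sqrt(home_range_km2 * 1e6) / core_mask$cell_size))
  pts <- place_sources(core_mask, spacing, seed = seed)
  if (nrow(pts) == 0L) {
    # degenerate lattice (core too sparse): fall back to the single best cell
    idx <- which(core_mask$values > 0, arr.ind = TRUE)
    pts <- data.frame(row = idx[1L, 1L], col = idx[1L, 2L])
  }
  rg <- resistance_graph(resistance, 8)
  v <- cells_to_vertices(rg, pts$row, pts$col)
  d <- igraph::distances(rg$graph, v = v, to = v, algorithm = "dijkstra")
  dimnames(d) <- NULL
  habitat_points(pts, d)
}

#' Population-genetic simulation parameters
#'
#' Defaults follow common usage of spatially explicit neutral simulators:
#' 30 unlinked diploid loci with 10 alleles each at initialisation, linear
#' cost-distance mating and dispersal kernels sharing the dispersal
#' threshold, Poisson fecundity 4, non-overlapping generations, no
#' mutation (so allele loss is a clean drift signal).
#'
#' @param n_loci diploid loci per individual.
#' @param n_alleles_init alleles per locus in the founder population.
#' @param generations generations to simulate (default 200).
#' @param max_cost mating/dispersal cost threshold (cost units).
#' @param offspring_mean Poisson mean litter size per mated female.
#' @param replicates independent simulation replicates.
#' @param seed integer master seed.
#' @return list of class `popgen_params`.
#' @export
popgen_params <- function(n_loci = 30, n_alleles_init = 10, generations = 200,
                          max_cost = 125000, offspring_mean = 4,
                          replicates = 10, seed = 1) {
  if (generations < 1) stop("generations must be >= 1")
  if (max_cost <= 0) stop("max_cost must be > 0")
  structure(list(n_loci = as.integer(n_loci),
                 n_alleles_init = as.integer(n_alleles_init),
                 generations = as.integer(generations),
                 max_cost = max_cost, offspring_mean = offspring_mean,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "popgen_params")
}

#' Initialise a fully occupied founder population
#'
#' Every habitat point starts occupied; sex is a fair coin and every allele
#' is drawn i.i.d. uniform from the initial allele universe, so expected
#' founder heterozygosity is `1 - 1/n_alleles_init`.
#'
#' @param points a [habitat_points()] (>= 2 points).
#' @param params a [popgen_params()].
#' @return list of class `pop_state`: `occupied` (logical per point),
#'   `sex` (0 female / 1 male), `geno` (points x loci x 2 integer array).
#' @export
init_population <- function(points, params) {
  stopifnot(inherits(points, "habitat_points"))
  if (points$n < 2L) stop("need at least 2 habitat points")
  n <- points$n
  geno <- array(sample.int(params$n_alleles_init, n * params$n_loci * 2,
                           replace = TRUE),
                dim = c(n, params$n_loci, 2L))
  structure(list(occupied = rep(TRUE, n),
                 sex = rbinom(n, 1L, 0.5),
                 geno = geno),
            class = "pop_state")
}

#' Advance the population one (non-overlapping) generation
#'
#' Mating: every female whose cost distance to at least one male is within
#' `max_cost` breeds; litter size is Poisson(`offspring_mean`) and each
#' offspring's sire is drawn independently among reachable males with
#' probability proportional to `max(0, 1 - cost/max_cost)` (multiple
#' paternity within a litter).  Inheritance is Mendelian: one uniformly
#' random allele per parent per locus; offspring sex is a fair coin.
#' Dispersal: offspring, considered in random order, settle at the nearest
#' (by cost, ties to the lowest point index) unoccupied point within
#' `max_cost` of the natal point; the rest die.  Parents die; the settlers
#' are the next generation.
#'
#' @param state a `pop_state`.
#' @param points a [habitat_points()].
#' @param params a [popgen_params()].
#' @return the next `pop_state`.
#' @export
step_generation <- function(state, points, params) {
  stopifnot(inherits(state, "pop_state"), inherits(points, "habitat_points"))
  n <- points$n
  empty_state <- function() {
    structure(list(occupied = rep(FALSE, n), sex = rep(NA_integer_, n),
                   geno = array(NA_integer_, dim = dim(state$geno))),
              class = "pop_state")
  }
  females <- which(state$occupied & state$sex == 0L)
  males <- which(state$occupied & state$sex == 1L)
  if (!length(females) || !length(males)) return(empty_state())

  w_all <- 1 - points$costmat[females, males, drop = FALSE] / params$max_cost
  w_all[w_all < 0 | !is.finite(w_all)] <- 0
  moms <- integer(); dads <- integer()
  for (i in seq_along(females)) {
    w <- w_all[i, ]
    if (sum(w) <= 0) next
    n_off <- rpois(1L, params$offspring_mean)
    if (n_off == 0L) next
    sires <- males[sample.int(length(males), n_off, replace = TRUE, prob = w)]
    moms <- c(moms, rep(females[i], n_off))
    dads <- c(dads, sires)
  }
  if (!length(moms)) return(empty_state())

  ord <- sample.int(length(moms))
  moms <- moms[ord]; dads <- dads[ord]
  newocc <- rep(FALSE, n)
  settled_at <- integer(length(moms))
  for (k in seq_along(moms)) {
    reach <- points$costmat[moms[k], ] <= params$max_cost & !newocc
    if (!any(reach)) { settled_at[k] <- NA_integer_; next }
    cand <- which(reach)
    p <- cand[which.min(points$costmat[moms[k], cand])]
    newocc[p] <- TRUE
    settled_at[k] <- p
  }
  keep <- !is.na(settled_at)
  if (!any(keep)) return(empty_state())
  moms <- moms[keep]; dads <- dads[keep]; settled_at <- settled_at[keep]
  n_set <- length(settled_at)
  L <- params$n_loci

  # Mendelian sampling, vectorised over offspring x loci
  pick_m <- matrix(sample(1:2, n_set * L, replace = TRUE), n_set, L)
  pick_d <- matrix(sample(1:2, n_set * L, replace = TRUE), n_set, L)
  off_i <- rep(seq_len(n_set), L)
  loc_i <- rep(seq_len(L), each = n_set)
  from_m <- state$geno[cbind(moms[off_i], loc_i, as.vector(pick_m))]
  from_d <- state$geno[cbind(dads[off_i], loc_i, as.vector(pick_d))]

  geno <- array(NA_integer_, dim = dim(state$geno))
  geno[cbind(settled_at[off_i], loc_i, 1L)] <- from_m
  geno[cbind(settled_at[off_i], loc_i, 2L)] <- from_d
  sex <- rep(NA_integer_, n)
  sex[settled_at] <- rbinom(n_set, 1L, 0.5)
  structure(list(occupied = newocc, sex = sex, geno = geno),
            class = "pop_state")
}

#' Population-genetic summary of a state
#'
#' @param state a `pop_state`.
#' @return list: `Ho` (observed heterozygosity, the fraction of
#'   heterozygous individual-by-locus genotypes; 0 if extinct),
#'   `total_alleles` (distinct alleles summed over loci), `N` (occupied
#'   points).
#' @export
summarize_population <- function(state) {
  stopifnot(inherits(state, "pop_state"))
  occ <- which(state$occupied)
  if (!length(occ))
    return(list(Ho = 0, total_alleles = 0L, N = 0L))
  g1 <- state$geno[occ, , 1L, drop = FALSE]
  g2 <- state$geno[occ, , 2L, drop = FALSE]
  ho <- mean(g1 != g2)
  ta <- sum(vapply(seq_len(dim(state$geno)[2L]), function(l)
    length(unique(c(g1[, l, 1L], g2[, l, 1L]))), integer(1)))
  list(Ho = ho, total_alleles = as.integer(ta), N = length(occ))
}

#' Run the replicated individual-based simulation
#'
#' For each replicate the founder population is drawn afresh and stepped
#' for `params$generations` generations; observed heterozygosity, total
#' allele count and population size are recorded each generation.
#' Deterministic per (seed, replicate).
#'
#' @param resistance resistance `grid_raster` (ignored when `points` is
#'   supplied directly).
#' @param core_mask 0/1 `grid_raster` of habitat (ignored when `points` is
#'   supplied).
#' @param params a [popgen_params()].
#' @param points optionally, a ready-made [habitat_points()].
#' @return data.frame: `replicate`, `generation` (0 = founders), `Ho`,
#'   `total_alleles`, `N`.
#' @export
run_simulation <- function(resistance = NULL, core_mask = NULL,
                           params = popgen_params(), points = NULL) {
  if (is.null(points)) {
    if (is.null(resistance) || is.null(core_mask))
      stop("supply either points or resistance + core_mask")
    points <- build_points(core_mask, resistance)
  }
  out <- vector("list", params$replicates)
  for (rep_i in seq_len(params$replicates)) {
    out[[rep_i]] <- with_seed(params$seed + rep_i, {
      state <- init_population(points, params)
      rows <- vector("list", params$generations + 1L)
      s <- summarize_population(state)
      rows[[1L]] <- data.frame(replicate = rep_i, generation = 0L,
                               Ho = s$Ho, total_alleles = s$total_alleles,
                               N = s$N)
      for (g in seq_len(params$generations)) {
        state <- step_generation(state, points, params)
        s <- summarize_population(state)
        rows[[g + 1L]] <- data.frame(replicate = rep_i, generation = g,
                                     Ho = s$Ho,
                                     total_alleles = s$total_alleles,
                                     N = s$N)
      }
      do.call(rbind, rows)
    })
  }
  do.call(rbind, out)
}
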