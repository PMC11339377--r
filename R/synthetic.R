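#' Land-cover class table
#'
#' Eight-class legend used by the synthetic generator: five forest classes
#' (mangrove, peat swamp, lowland, lower montane, upper montane) and three
#' non-forest classes (plantation/regrowth, lowland mosaic, water).  Forest
#' classes are the ones treated as habitat for a forest-interior carnivore.
#'
#' @return data.frame with columns `code`, `name`, `forest`.
#' @export
landcover_classes <- function() {
  data.frame(
    code = 1:8,
    name = c("mangrove", "peat_swamp_forest", "lowland_forest",
             "lower_montane_forest", "upper_montane_forest",
             "plantation_regrowth", "lowland_mosaic", "water"),
    forest = c(rep(TRUE, 5L), rep(FALSE, 3L))
  )
}

#' @rdname landcover_classes
#' @export
forest_codes <- function() landcover_classes()$code[landcover_classes()$forest]

#' Default per-class landscape resistance table
#'
#' Resistance to movement for each land-cover class, in multiples of the
#' least-cost (forest) condition.  Forest classes are near 1; converted and
#' open classes are substantially higher; water is near-barrier.  The values
#' are configurable placeholders in the spirit of expert-opinion resistance
#' surfaces; only their ordering (forest cheapest) matters for the
#' qualitative scenario comparison.
#'
#' @return named numeric vector, names matching [landcover_classes()] names.
#' @export
default_resistance_table <- function() {
  c(mangrove = 1, peat_swamp_forest = 1, lowland_forest = 1,
    lower_montane_forest = 1, upper_montane_forest = 2,
    plantation_regrowth = 10, lowland_mosaic = 8, water = 30)
}

#' Synthetic landscape configuration
#'
#' Bundles every knob of the generator.  Defaults describe a 64 x 64 cell
#' (32 x 32 km at 500 m) landscape with just over half forest cover, a
#' protected-area estate of 8% of the land biased "high and far", and a
#' forest-loss risk surface that falls with elevation and with distance to
#' the nearest non-forest cell and is depressed inside protected areas.
#'
#' @param nrows,ncols grid dimensions in cells (>= 8).
#' @param cell_size cell edge, metres.
#' @param forest_fraction target share of cells under forest (0-1 open).
#' @param pa_fraction share of cells inside protected areas (may be 0).
#' @param roughness elevation relief amplitude, metres per unit deviation of
#'   the spectral noise field (0 = perfectly flat landscape).
#' @param risk_coefficients list with `intercept`, `elevation_slope`,
#'   `edge_distance_slope`, `pa_offset` on the logit scale.
#' @param plantation_resistance resistance of the plantation/regrowth class
#'   that deforested cells are assumed to convert to (>= 1).
#' @param resistance_table per-class resistance lookup.
#' @param n_pa_blobs number of contiguous reserves grown for the PA mask.
#' @param seed integer master seed of the generator.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(nrows = 64, ncols = 64, cell_size = 500,
                             forest_fraction = 0.55, pa_fraction = 0.08,
                             roughness = 300,
                             risk_coefficients = list(
                               intercept = -1.7, elevation_slope = -1.2,
                               edge_distance_slope = -1.2, pa_offset = -1.5),
                             plantation_resistance = 10,
                             resistance_table = default_resistance_table(),
                             n_pa_blobs = 6, seed = 1) {
  if (nrows < 8L || ncols < 8L) stop("grid must be at least 8 x 8 cells")
  if (!(forest_fraction > 0 && forest_fraction < 1))
    stop("forest_fraction must be in (0, 1)")
  if (!(pa_fraction >= 0 && pa_fraction < 1))
    stop("pa_fraction must be in [0, 1)")
  if (plantation_resistance < 1) stop("plantation_resistance must be >= 1")
  needed <- c("intercept", "elevation_slope", "edge_distance_slope", "pa_offset")
  if (!all(needed %in% names(risk_coefficients)))
    stop("risk_coefficients must name: ", paste(needed, collapse = ", "))
  structure(list(
    nrows = as.integer(nrows), ncols = as.integer(ncols),
    cell_size = cell_size, forest_fraction = forest_fraction,
    pa_fraction = pa_fraction, roughness = roughness,
    risk_coefficients = risk_coefficients,
    plantation_resistance = plantation_resistance,
    resistance_table = resistance_table,
    n_pa_blobs = as.integer(n_pa_blobs), seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Zero-mean, unit-sd spatially autocorrelated field via spectral (1/f^beta)
# filtering of Gaussian white noise.  beta = 2 gives fractal-Brownian-like
# relief.  Consumes the current RNG stream.
spectral_noise_field <- function(nrows, ncols, beta = 2) {
  wn <- matrix(rnorm(nrows * ncols), nrows, ncols)
  fx <- c(0:(floor(nrows / 2)), -((ceiling(nrows / 2) - 1):1)) / nrows
  fy <- c(0:(floor(ncols / 2)), -((ceiling(ncols / 2) - 1):1)) / ncols
  f <- sqrt(outer(fx^2, fy^2, `+`))
  amp <- ifelse(f > 0, f^(-beta / 2), 0)  # kill DC component
  field <- Re(fft(fft(wn) * amp, inverse = TRUE)) / length(wn)
  s <- sd(as.vector(field))
  if (s == 0) return(field * 0)
  (field - mean(field)) / s
}

#' Generate a synthetic elevation surface
#'
#' Fractal relief built by spectral (1/f^2) filtering of white noise,
#' shifted to a 500 m mean and clamped at sea level.  `roughness` scales the
#' relief amplitude in metres; `roughness = 0` yields a perfectly flat
#' surface.
#'
#' @param nrows,ncols grid dimensions (positive).
#' @param roughness relief amplitude, metres (>= 0).
#' @param seed integer seed; a fixed seed gives a bit-identical raster.
#' @param cell_size cell edge, metres.
#' @param base_elevation mean elevation, metres.
#' @return elevation `grid_raster` (metres).
#' @export
generate_elevation <- function(nrows, ncols, roughness = 300, seed = 1,
                               cell_size = 500, base_elevation = 500) {
  if (nrows <= 0 || ncols <= 0) stop("grid dimensions must be positive")
  if (roughness < 0) stop("roughness must be >= 0")
  vals <- if (roughness == 0) {
    matrix(base_elevation, nrows, ncols)
  } else {
    with_seed(seed, {
      pmax(base_elevation + roughness * spectral_noise_field(nrows, ncols), 0)
    })
  }
  grid_raster(vals, cell_size = cell_size)
}

#' Generate a categorical land-cover raster
#'
#' Cells are split into forest and non-forest by thresholding a latent score
#' that mixes elevation with an autocorrelated noise field, so remaining
#' forest is spatially clumped and biased upslope (clearance historically
#' proceeds from the accessible lowlands).  The realised forest share equals
#' `forest_fraction` up to ties.  Forest cells are then stratified into the
#' five forest classes by elevation quantile (mangrove lowest through upper
#' montane highest); non-forest cells become water (lowest 5% by elevation),
#' else plantation/regrowth or lowland mosaic.
#'
#' @param elevation elevation `grid_raster`.
#' @param forest_fraction target forest share, strictly in (0, 1).
#' @param seed integer seed.
#' @param elevation_weight weight of elevation (vs noise) in the latent
#'   forest score.
#' @return land-cover `grid_raster` of codes per [landcover_classes()].
#' @export
generate_landcover <- function(elevation, forest_fraction, seed = 1,
                               elevation_weight = 0.6) {
  stopifnot(is_grid_raster(elevation))
  if (!(forest_fraction > 0 && forest_fraction < 1))
    stop("forest_fraction must be in (0, 1)")
  e <- elevation$values
  if (any(!is.finite(e))) stop("elevation must be finite everywhere")
  nr <- nrow(e); nc <- ncol(e)
  with_seed(seed, {
    noise <- spectral_noise_field(nr, nc)
    ez <- if (sd(e) > 0) (e - mean(e)) / sd(e) else e * 0
    score <- elevation_weight * ez + (1 - elevation_weight) * noise +
      1e-9 * runif(nr * nc)  # break ties so shares are exact
    thr <- quantile(score, 1 - forest_fraction, names = FALSE)
    forest <- score > thr
    code <- matrix(NA_real_, nr, nc)
    # forest classes stratified by elevation quantile within forest
    ef <- e[forest]
    qf <- quantile(ef, c(0.10, 0.30, 0.70, 0.90), names = FALSE)
    fc <- findInterval(ef, qf, left.open = TRUE) + 1L  # 1..5
    code[forest] <- fc
    # non-forest: water in the lowest 5% by elevation, rest split by noise
    en <- e[!forest]
    water <- en <= quantile(en, 0.05, names = FALSE)
    nf <- ifelse(water, 8L, ifelse(noise[!forest] > 0, 6L, 7L))
    code[!forest] <- nf
    grid_raster(code, cell_size = elevation$cell_size, origin = elevation$origin)
  })
}

#' Generate a "high and far" protected-area mask
#'
#' Grows a handful of contiguous reserve blobs by elevation-ranked region
#' growing from seeds placed on high-elevation forest, emulating the
#' historical bias of protection toward remote, high, low-threat terrain.
#'
#' @param elevation elevation `grid_raster`.
#' @param forest_mask 0/1 `grid_raster` of forest (seed cells must be forest).
#' @param pa_fraction share of all cells to protect (`0` gives an empty
#'   mask); must be below the forest share.
#' @param seed integer seed.
#' @param n_blobs number of reserve seeds (connected reserves may merge, so
#'   this is an upper bound on the component count).
#' @return 0/1 `grid_raster` (1 = protected).
#' @export
generate_pa_mask <- function(elevation, forest_mask, pa_fraction, seed = 1,
                             n_blobs = 6) {
  stopifnot(is_grid_raster(elevation), is_grid_raster(forest_mask))
  check_aligned(elevation, forest_mask)
  if (pa_fraction < 0 || pa_fraction >= 1) stop("pa_fraction must be in [0, 1)")
  e <- elevation$values
  f <- forest_mask$values > 0
  if (pa_fraction == 0)
    return(raster_like(elevation, 0))
  if (pa_fraction >= mean(f))
    stop("pa_fraction must be below the forest share")
  nr <- nrow(e); nc <- ncol(e)
  n_target <- max(1L, round(pa_fraction * nr * nc))
  with_seed(seed, {
    # seeds: sample among forest cells in the top elevation decile
    hi <- which(f & e >= quantile(e[f], 0.9))
    seeds <- sample(hi, min(n_blobs, length(hi)))
    inpa <- matrix(FALSE, nr, nc)
    inpa[seeds] <- TRUE
    # frontier priority: elevation plus a small jitter to vary blob shapes
    jitter <- matrix(runif(nr * nc, 0, 0.05 * max(1, diff(range(e)))), nr, nc)
    prio <- e + jitter
    frontier <- rep(NA_real_, nr * nc)
    push_neighbours <- function(idx) {
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          j <- (cc - 1L) * nr + rr
          if (!inpa[j]) frontier[j] <<- prio[j]
        }
      }
    }
    for (s in seeds) push_neighbours(s)
    while (sum(inpa) < n_target && any(!is.na(frontier))) {
      nxt <- which.max(frontier)
      frontier[nxt] <- NA_real_
      if (inpa[nxt]) next
      inpa[nxt] <- TRUE
      push_neighbours(nxt)
    }
    raster_like(elevation, as.numeric(inpa))
  })
}

#' Generate a forest-loss probability raster
#'
#' A deliberate reduction of machine-learnt loss-risk surfaces to a logistic
#' in three standardised covariates: elevation, Euclidean distance to the
#' nearest non-forest cell ("distance to deforestation frontier") and
#' protection status.  Only forested cells carry risk; non-forest cells are
#' 0.  With the default negative slopes, risk is highest in low, frontier,
#' unprotected forest -- the joint structure the scenario comparison relies
#' on.
#'
#' @param elevation,landcover,pa_mask aligned `grid_raster` layers.
#' @param risk_coefficients list with `intercept`, `elevation_slope`,
#'   `edge_distance_slope`, `pa_offset` (logit scale).
#' @return risk `grid_raster`, values in \[0, 1\].
#' @export
generate_risk <- function(elevation, landcover, pa_mask,
                          risk_coefficients = synthetic_config()$risk_coefficients) {
  stopifnot(is_grid_raster(elevation), is_grid_raster(landcover),
            is_grid_raster(pa_mask))
  check_aligned(elevation, landcover, pa_mask)
  co <- risk_coefficients
  forest <- classify_forest(landcover)$values > 0
  e <- elevation$values
  d <- edge_distance(forest, elevation$cell_size)
  zs <- function(x) {
    xf <- x[forest]
    if (length(xf) > 1L && sd(xf) > 0) (x - mean(xf)) / sd(xf) else x * 0
  }
  eta <- co$intercept + co$elevation_slope * zs(e) +
    co$edge_distance_slope * zs(d) + co$pa_offset * (pa_mask$values > 0)
  risk <- plogis(eta)
  risk[!forest] <- 0
  raster_like(elevation, risk)
}

# Euclidean distance (metres) from each forest cell to the nearest
# non-forest cell; 0 on non-forest.  All-forest grids get the grid diagonal
# (no frontier anywhere).
edge_distance <- function(forest, cell_size) {
  if (all(forest)) {
    d <- matrix(sqrt(nrow(forest)^2 + ncol(forest)^2), nrow(forest), ncol(forest))
  } else if (!any(forest)) {
    d <- matrix(0, nrow(forest), ncol(forest))
  } else {
    d <- EBImage::distmap(matrix(as.numeric(forest), nrow(forest)))
    d <- matrix(as.numeric(d), nrow(forest), ncol(forest))
  }
  d * cell_size
}

#' Generate an above-ground biomass carbon raster
#'
#' Per-cell AGB in megagrams: class-dependent means with multiplicative
#' lognormal noise on forest cells, exactly 0 elsewhere.  Default class
#' means follow typical tropical AGB densities (lowland forest richest,
#' upper montane and mangrove leaner) scaled by the cell area.
#'
#' @param landcover land-cover `grid_raster`.
#' @param elevation elevation `grid_raster` (geometry reference).
#' @param seed integer seed.
#' @param class_means named numeric, mean AGB in Mg *per cell* for each
#'   forest class; `NULL` uses per-hectare defaults times the cell area.
#' @param sdlog lognormal log-scale sd of the cell-level noise.
#' @return carbon `grid_raster` (Mg per cell, >= 0).
#' @export
generate_carbon <- function(landcover, elevation = NULL, seed = 1,
                            class_means = NULL, sdlog = 0.3) {
  stopifnot(is_grid_raster(landcover))
  if (!is.null(elevation)) check_aligned(landcover, elevation)
  cell_ha <- (landcover$cell_size / 100)^2
  if (is.null(class_means)) {
    per_ha <- c(mangrove = 120, peat_swamp_forest = 180, lowland_forest = 240,
                lower_montane_forest = 190, upper_montane_forest = 140)
    class_means <- per_ha * cell_ha
  }
  cls <- landcover_classes()
  code <- landcover$values
  carbon <- matrix(0, nrow(code), ncol(code))
  with_seed(seed, {
    for (i in seq_len(nrow(cls))) {
      if (!cls$forest[i]) next
      idx <- which(code == cls$code[i])
      if (!length(idx)) next
      m <- class_means[[cls$name[i]]]
      if (is.null(m) || is.na(m)) stop("no carbon mean for class ", cls$name[i])
      carbon[idx] <- rlnorm(length(idx), log(m) - sdlog^2 / 2, sdlog)
    }
  })
  carbon[is_nodata_cell(landcover)] <- NA_real_
  raster_like(landcover, carbon)
}

#' Landscape resistance from land cover
#'
#' Pure per-class lookup; every code in the raster must have a table entry,
#' and the table must keep forest classes no more resistant than non-forest
#' classes with minimum 1 (the least-cost condition).
#'
#' @param landcover land-cover `grid_raster`.
#' @param table named numeric resistance per class name
#'   (default [default_resistance_table()]).
#' @return resistance `grid_raster` (>= 1).
#' @export
generate_resistance <- function(landcover, table = default_resistance_table()) {
  stopifnot(is_grid_raster(landcover))
  cls <- landcover_classes()
  codes <- unique(raster_values(landcover))
  unknown <- setdiff(codes, cls$code)
  if (length(unknown))
    stop("unknown land-cover code(s): ", paste(unknown, collapse = ", "))
  have <- cls$name[match(codes, cls$code)]
  missing <- setdiff(have, names(table))
  if (length(missing))
    stop("resistance table lacks entries for: ", paste(missing, collapse = ", "))
  if (any(table < 1)) stop("resistance values must be >= 1")
  lut <- setNames(table[cls$name[match(cls$code, cls$code)]], cls$code)
  out <- raster_like(landcover, NA_real_)
  keep <- !is_nodata_cell(landcover)
  out$values[keep] <- unname(table[cls$name[match(landcover$values[keep], cls$code)]])
  out
}

#' Generate a complete synthetic landscape
#'
#' Orchestrates the individual generators under a fanned-out seed so the
#' whole landscape is bit-identical for a fixed configuration: elevation,
#' land cover, forest mask, "high and far" protected areas, forest-loss
#' risk, carbon and baseline resistance, all sharing one geometry.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_landscape` with elements `elevation`,
#'   `landcover`, `forest`, `pa_mask`, `risk`, `carbon`, `resistance` and
#'   the `config` used.
#' @export
generate_landscape <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$seed
  elevation <- generate_elevation(config$nrows, config$ncols,
                                  roughness = config$roughness,
                                  seed = s + 1L, cell_size = config$cell_size)
  landcover <- generate_landcover(elevation, config$forest_fraction,
                                  seed = s + 2L)
  forest <- classify_forest(landcover)
  pa_mask <- generate_pa_mask(elevation, forest, config$pa_fraction,
                              seed = s + 3L, n_blobs = config$n_pa_blobs)
  risk <- generate_risk(elevation, landcover, pa_mask, config$risk_coefficients)
  carbon <- generate_carbon(landcover, elevation, seed = s + 4L)
  resistance <- generate_resistance(landcover, config$resistance_table)
  structure(list(elevation = elevation, landcover = landcover, forest = forest,
                 pa_mask = pa_mask, risk = risk, carbon = carbon,
                 resistance = resistance, config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("<synthetic_landscape> %d x %d cells at %g m (seed %d)\n",
              x$config$nrows, x$config$ncols, x$config$cell_size,
              x$config$seed))
  cat(sprintf("  forest share %.2f, PA share %.2f, mean risk on forest %.3f\n",
              mean(x$forest$values), mean(x$pa_mask$values),
              mean(x$risk$values[x$forest$values > 0])))
  invisible(x)
}

#' Write every layer of a landscape as ESRI ASCII grids
#'
#' @param landscape a `synthetic_landscape`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- c("elevation", "landcover", "forest", "pa_mask", "risk",
              "carbon", "resistance")
  paths <- vapply(layers, function(nm) {
    write_esri_ascii(landscape[[nm]], file.path(dir, paste0(nm, ".asc")))
  }, character(1))
  invisible(paths)
}
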