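#' Pipeline configuration
#'
#' One seeded configuration drives the whole seven-scenario comparison.
#' Defaults are desk-scale: a 64 x 64 cell landscape, 4 x 4 cell planning
#' units, 2000-iteration x 20-run annealing, a single dispersal bandwidth
#' of 12500 cost units -- dispersal spanning about an eighth of the map
#' edge at least cost, the same ratio the canonical 125 kcu bandwidth has
#' to its ~1000 km study area -- and a shortened genetic simulation; every
#' element can be raised toward production scale.
#'
#' @param landscape a [synthetic_config()] for the synthetic landscape.
#' @param unit_size_cells planning-unit edge in cells.
#' @param area_fraction share of planning units in the final designs.
#' @param min_forest_frac,min_pa_frac eligibility thresholds as a fraction
#'   of the full unit area (0.16 reproduces the 16 km2-in-100 km2 rule at
#'   any unit size, keeping desk-scale units comparable to production
#'   10 x 10 km units).
#' @param bandwidths dispersal bandwidths (cost units) to evaluate; scale
#'   them with the landscape extent (see above).
#' @param source_spacing kernel source-point lattice period (cells).
#' @param core_percentile kernel percentile defining core habitat.
#' @param annealing an [annealing_params()].
#' @param popgen a [popgen_params()].
#' @param run_popgen run the genetic simulation stage?
#' @param seed master seed; stage seeds are fanned out as documented in
#'   [run_pipeline()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(landscape = synthetic_config(),
                            unit_size_cells = 4, area_fraction = 0.17,
                            min_forest_frac = 0.16, min_pa_frac = 0.16,
                            bandwidths = 12500, source_spacing = 8,
                            core_percentile = 10,
                            annealing = annealing_params(iterations = 2000,
                                                         runs = 20),
                            popgen = popgen_params(generations = 50,
                                                   n_loci = 15,
                                                   replicates = 5),
                            run_popgen = TRUE, seed = 1) {
  structure(list(landscape = landscape, unit_size_cells = unit_size_cells,
                 area_fraction = area_fraction,
                 min_forest_frac = min_forest_frac, min_pa_frac = min_pa_frac,
                 bandwidths = bandwidths,
                 source_spacing = source_spacing,
                 core_percentile = core_percentile, annealing = annealing,
                 popgen = popgen, run_popgen = run_popgen,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `landscape`, `annealing` and `popgen` keys take the arguments of their
#' respective constructors.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$landscape)) args$landscape <- do.call(synthetic_config, y$landscape)
  if (!is.null(y$annealing)) args$annealing <- do.call(annealing_params, y$annealing)
  if (!is.null(y$popgen)) args$popgen <- do.call(popgen_params, y$popgen)
  for (k in c("unit_size_cells", "area_fraction", "min_forest_frac",
              "min_pa_frac", "bandwidths",
              "source_spacing", "core_percentile", "run_popgen", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

#' Run the full counterfactual comparison
#'
#' Pipeline: generate the landscape; compute the baseline resistant kernel;
#' aggregate to planning units and apply eligibility; for each scenario
#' that adds reserves, rank units by annealing selection frequency and take
#' the top `round(area_fraction * n_units)`; for every scenario derive the
#' effective-protection mask, project resistance and carbon, recompute the
#' kernel at each bandwidth, threshold core habitat, score patch metrics,
#' and (optionally) run the genetic simulation on the projected landscape.
#'
#' Stage seeds fan out from the master seed: landscape uses the landscape
#' config's own seed; the annealer for scenario s uses `seed + 100 + s`;
#' the genetic simulation for scenario s uses `seed + 200 + s`, so stages
#' are independently rerunnable.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all layer rasters (ESRI
#'   ASCII), the planning-unit table, per-scenario selections and the
#'   report are written there.
#' @return list of class `scenario_report`: `report` (data.frame, one row
#'   per scenario x bandwidth), `selections`, `frequencies`, `pu`,
#'   `landscape`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  landscape <- generate_landscape(config$landscape)
  cat_stage <- function(...) message("[cfreserve] ", sprintf(...))

  cat_stage("landscape %dx%d generated (seed %d)",
            config$landscape$nrows, config$landscape$ncols,
            config$landscape$seed)
  sources <- place_sources(landscape$forest, config$source_spacing)
  kp0 <- kernel_params(bandwidth = config$bandwidths[1L])
  kernel0 <- resistant_kernel_density(landscape$resistance, sources, kp0)

  pu <- build_planning_units(
    list(forest = landscape$forest, pa = landscape$pa_mask,
         kernel = kernel0, carbon = landscape$carbon, risk = landscape$risk),
    config$unit_size_cells)
  unit_area_km2 <- (config$unit_size_cells * config$landscape$cell_size / 1000)^2
  pu <- apply_eligibility(pu,
                          min_forest_km2 = config$min_forest_frac * unit_area_km2,
                          min_pa_km2 = config$min_pa_frac * unit_area_km2)
  k <- reserve_size(nrow(pu$units), config$area_fraction)
  n_locked <- sum(pu$units$locked)
  cat_stage("%d planning units (%d available, %d locked), design size %d",
            nrow(pu$units), sum(pu$units$available), n_locked, k)

  scen <- scenario_catalog()
  selections <- list(); frequencies <- list()
  for (s in scen$id[scen$add_new_reserves]) {
    prob <- build_scenario_problem(
      pu, mode = scen$mode[s], retain = scen$retain_existing_pas[s])
    ap <- config$annealing
    ap$seed <- config$seed + 100L + s
    freq <- selection_frequency(prob, ap)
    locked_ids <- prob$ids[prob$locked]
    ks <- min(k, length(prob$ids))
    selections[[as.character(s)]] <-
      top_k_selection(freq, max(ks, length(locked_ids)), locked_ids)
    frequencies[[as.character(s)]] <- freq
    cat_stage("scenario %d: selection frequencies over %d runs", s, ap$runs)
  }

  # one absolute core threshold per bandwidth, fixed from the baseline
  # kernel map so every scenario is cut at the same density
  thr_bw <- setNames(vapply(config$bandwidths, function(bw) {
    K1 <- resistant_kernel_density(landscape$resistance, sources,
                                   kernel_params(bandwidth = bw))
    v <- raster_values(K1)
    quantile(v[v > 0], config$core_percentile / 100, names = FALSE)
  }, numeric(1)), config$bandwidths)

  rows <- list()
  for (s in scen$id) {
    new_res <- if (scen$add_new_reserves[s])
      units_to_mask(pu, selections[[as.character(s)]]) else NULL
    prot <- effective_protection_mask(scen[s, ], landscape$pa_mask, new_res)
    res_s <- update_resistance(landscape$resistance, landscape$risk,
                               config$landscape$plantation_resistance, prot)
    carb_s <- update_carbon(landscape$carbon, landscape$risk, prot)
    for (bw in config$bandwidths) {
      kp <- kernel_params(bandwidth = bw)
      K <- resistant_kernel_density(res_s, sources, kp)
      core <- threshold_core(K, threshold = thr_bw[[as.character(bw)]])
      pm <- patch_metrics(core)
      row <- data.frame(
        scenario = s, label = scen$label[s], bandwidth = bw,
        pland = pm$pland, np = pm$np, lpi = pm$lpi,
        awmps_km2 = pm$awmps_km2,
        correlation_length_km = pm$correlation_length_km,
        carbon_gt = total_carbon(carb_s),
        Ho_median = NA_real_, Ho_q1 = NA_real_, Ho_q3 = NA_real_,
        alleles_median = NA_real_, N_median = NA_real_
      )
      if (config$run_popgen) {
        pg <- config$popgen
        pg$max_cost <- bw
        pg$seed <- config$seed + 200L + s
        sim <- run_simulation(res_s, core, pg)
        fin <- sim[sim$generation == max(sim$generation), ]
        row$Ho_median <- median(fin$Ho)
        row$Ho_q1 <- quantile(fin$Ho, 0.25, names = FALSE)
        row$Ho_q3 <- quantile(fin$Ho, 0.75, names = FALSE)
        row$alleles_median <- median(fin$total_alleles)
        row$N_median <- median(fin$N)
      }
      rows[[length(rows) + 1L]] <- row
    }
    cat_stage("scenario %d (%s) scored", s, scen$label[s])
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, selections = selections,
                        frequencies = frequencies, pu = pu,
                        landscape = landscape, config = config),
                   class = "scenario_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("<scenario_report>\n")
  df <- x$report
  df$label <- substr(df$label, 1, 34)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

# Write all pipeline artifacts as plain text.
write_report <- function(x, dir) {
  stopifnot(inherits(x, "scenario_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_landscape(x$landscape, file.path(dir, "landscape"))
  write.csv(x$report, file.path(dir, "scenario_report.csv"), row.names = FALSE)
  write.csv(x$pu$units, file.path(dir, "planning_units.csv"), row.names = FALSE)
  for (s in names(x$selections)) {
    write.csv(data.frame(id = x$selections[[s]]),
              file.path(dir, sprintf("selection_s%s.csv", s)),
              row.names = FALSE)
    write.csv(data.frame(id = as.integer(names(x$frequencies[[s]])),
                         frequency = as.integer(x$frequencies[[s]])),
              file.path(dir, sprintf("selection_frequency_s%s.csv", s)),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Percent change of a value against a reference
#'
#' `100 * (x - reference) / reference`, rounded to `digits`.
#'
#' @param x value(s) to compare.
#' @param reference reference value (nonzero).
#' @param digits decimal places of the result (default 0, integer percent).
#' @return percent change.
#' @export
percent_change <- function(x, reference, digits = 0) {
  if (any(reference == 0)) stop("reference must be nonzero")
  round(100 * (x - reference) / reference, digits)
}

#' Relative change of a report metric between scenarios
#'
#' @param report a `scenario_report` (or its `report` data.frame).
#' @param metric column name, e.g. `"pland"` or `"carbon_gt"`.
#' @param scenario scenario id to evaluate.
#' @param reference reference scenario id (default 7, business-as-usual).
#' @param bandwidth bandwidth to use (default: the first in the report).
#' @param digits decimal places (default 0).
#' @return percent change of `metric` for `scenario` vs `reference`.
#' @export
relative_change <- function(report, metric, scenario, reference = 7,
                            bandwidth = NULL, digits = 0) {
  df <- if (inherits(report, "scenario_report")) report$report else report
  if (!metric %in% names(df)) stop("unknown metric: ", metric)
  if (is.null(bandwidth)) bandwidth <- df$bandwidth[1L]
  pick <- function(s) {
    v <- df[df$scenario == s & df$bandwidth == bandwidth, metric]
    if (!length(v)) stop("scenario ", s, " not present in the report")
    v[[1L]]
  }
  percent_change(pick(scenario), pick(reference), digits)
}
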