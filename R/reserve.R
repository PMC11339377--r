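#' Reserve selection problem
#'
#' Container for a MARXAN-style site-selection problem: per-unit costs, a
#' unit x feature amount matrix, per-feature targets and penalty factors, a
#' boundary-length modifier, a locked-in unit set, and the shared-boundary
#' graph.  On construction the greedy completion cost of each feature (the
#' cost of meeting that feature's target alone by best amount-per-cost
#' order) is precomputed; it calibrates the shortfall penalty so that the
#' penalty is zero iff all targets are met and scales like the cost of
#' fixing the shortfall.
#'
#' @param ids integer unit ids.
#' @param cost per-unit cost (same length as `ids`).
#' @param amounts numeric matrix, units x features, with feature column
#'   names.
#' @param targets per-feature required amount (> 0 for active features).
#' @param spf per-feature penalty factor (recycled if scalar).
#' @param blm boundary length modifier (>= 0).
#' @param locked logical per unit; locked units are always selected.
#' @param boundary data.frame `id1`, `id2`, `length_km` of shared edges
#'   (symmetric relation stored once).
#' @param perimeter_km named (by id) or positional per-unit total perimeter.
#' @return list of class `reserve_problem`.
#' @export
reserve_problem <- function(ids, cost, amounts, targets, spf = 2,
                            blm = 0.0015, locked = NULL, boundary = NULL,
                            perimeter_km = NULL) {
  n <- length(ids)
  amounts <- as.matrix(amounts)
  stopifnot(length(cost) == n, nrow(amounts) == n)
  if (is.null(colnames(amounts)))
    colnames(amounts) <- paste0("feature", seq_len(ncol(amounts)))
  nf <- ncol(amounts)
  stopifnot(length(targets) == nf)
  if (any(targets <= 0)) stop("targets must be > 0 for active features")
  spf <- rep_len(spf, nf)
  if (blm < 0) stop("blm must be >= 0")
  if (is.null(locked)) locked <- rep(FALSE, n)
  stopifnot(length(locked) == n)
  if (is.null(boundary))
    boundary <- data.frame(id1 = integer(), id2 = integer(),
                           length_km = numeric())
  if (is.null(perimeter_km)) perimeter_km <- rep(0, n)
  if (!is.null(names(perimeter_km)))
    perimeter_km <- perimeter_km[as.character(ids)]
  stopifnot(length(perimeter_km) == n)
  bad <- !(boundary$id1 %in% ids) | !(boundary$id2 %in% ids)
  if (any(bad)) stop("boundary references unknown unit id(s)")

  # greedy completion cost per feature
  gcost <- vapply(seq_len(nf), function(f) {
    amt <- amounts[, f]
    keep <- which(amt > 0)
    if (!length(keep)) return(sum(cost))
    ord <- keep[order(amt[keep] / cost[keep], decreasing = TRUE)]
    got <- cumsum(amt[ord])
    k <- which(got >= targets[f])[1L]
    if (is.na(k)) sum(cost[ord]) else sum(cost[ord[seq_len(k)]])
  }, numeric(1))

  # CSR adjacency over unit positions (0-based, for the C++ core)
  i1 <- match(boundary$id1, ids); i2 <- match(boundary$id2, ids)
  deg_from <- c(i1, i2); deg_to <- c(i2, i1)
  len2 <- c(boundary$length_km, boundary$length_km)
  ord <- order(deg_from)
  deg_from <- deg_from[ord]; deg_to <- deg_to[ord]; len2 <- len2[ord]
  ptr <- c(0L, cumsum(tabulate(deg_from, nbins = n)))

  structure(list(ids = as.integer(ids), cost = as.numeric(cost),
                 amounts = amounts, targets = as.numeric(targets),
                 spf = as.numeric(spf), blm = blm,
                 locked = as.logical(locked), boundary = boundary,
                 perimeter_km = as.numeric(perimeter_km),
                 gcost = gcost,
                 adj = list(ptr = as.integer(ptr),
                            idx = as.integer(deg_to - 1L),
                            len = as.numeric(len2))),
            class = "reserve_problem")
}

#' @export
print.reserve_problem <- function(x, ...) {
  cat(sprintf("<reserve_problem> %d units, %d features (%s)\n",
              length(x$ids), ncol(x$amounts),
              paste(colnames(x$amounts), collapse = ", ")))
  cat(sprintf("  blm %g, spf %s, locked %d\n", x$blm,
              paste(unique(x$spf), collapse = "/"), sum(x$locked)))
  invisible(x)
}

#' Build a scenario-specific selection problem from a planning-unit table
#'
#' Proactive mode treats the loss risk as a third conservation feature (so
#' high-risk forest is actively sought) and costs every unit by its area;
#' expedient mode keeps only the kernel and carbon features and costs units
#' by risk-weighted area, steering selection toward low-risk terrain.  Only
#' available units enter; the existing-PA units are locked in when
#' `retain = TRUE` and free otherwise ("starting from scratch").  Every
#' feature target is `target_fraction` of its total over included units.
#'
#' @param pu an eligibility-applied [build_planning_units()] result.
#' @param mode `"proactive"` or `"expedient"`.
#' @param retain lock in existing protected units?
#' @param target_fraction per-feature target as share of the feature total.
#' @param spf species penalty factor.
#' @param blm boundary length modifier.
#' @return a [reserve_problem()] over the available units.
#' @export
build_scenario_problem <- function(pu, mode = c("proactive", "expedient"),
                                   retain = FALSE, target_fraction = 0.30,
                                   spf = 2, blm = 0.0015) {
  stopifnot(inherits(pu, "planning_units"))
  mode <- match.arg(mode)
  u <- pu$units
  if (all(is.na(u$available))) stop("apply_eligibility() first")
  keep <- which(u$available)
  if (!length(keep)) stop("no available planning units")
  u <- u[keep, , drop = FALSE]
  amounts <- cbind(kernel_sum = u$kernel_sum, carbon_sum = u$carbon_sum)
  if (mode == "proactive")
    amounts <- cbind(amounts, risk_sum = u$mean_risk * u$area_km2)
  active <- colSums(amounts) > 0
  if (!all(active)) amounts <- amounts[, active, drop = FALSE]
  targets <- target_fraction * colSums(amounts)
  cost <- if (mode == "proactive") u$area_km2 else
    pmax(u$mean_risk, 0.01) * u$area_km2
  b <- pu$boundary
  b <- b[b$id1 %in% u$id & b$id2 %in% u$id, , drop = FALSE]
  reserve_problem(ids = u$id, cost = cost, amounts = amounts,
                  targets = targets, spf = spf, blm = blm,
                  locked = if (retain) u$locked else rep(FALSE, nrow(u)),
                  boundary = b,
                  perimeter_km = pu$perimeter_km[as.character(u$id)])
}

#' Exposed boundary length of a selected unit set
#'
#' Total perimeter of the selection: edges between two selected units
#' contribute nothing; edges between a selected unit and an unselected unit
#' or the landscape exterior contribute their length.
#'
#' @param problem a `reserve_problem`.
#' @param selected integer ids of selected units.
#' @return boundary length in km.
#' @export
boundary_length <- function(problem, selected) {
  stopifnot(inherits(problem, "reserve_problem"))
  unknown <- setdiff(selected, problem$ids)
  if (length(unknown)) stop("unknown unit id(s): ", paste(unknown, collapse = ", "))
  sel <- problem$ids %in% selected
  bl <- sum(problem$perimeter_km[sel])
  b <- problem$boundary
  both <- (b$id1 %in% selected) & (b$id2 %in% selected)
  bl - 2 * sum(b$length_km[both])
}

#' Annealing objective of a candidate solution
#'
#' `sum(cost) + blm * boundary_length + sum_f spf_f *
#' (shortfall_f / target_f) * G_f`, where `G_f` is the precomputed greedy
#' completion cost of feature `f` and the shortfall term vanishes when all
#' targets are met.
#'
#' @param problem a `reserve_problem`.
#' @param selected integer ids of selected units.
#' @return list with `objective`, `cost`, `boundary_km`, `penalty` and
#'   per-feature `shortfall`.
#' @export
reserve_objective <- function(problem, selected) {
  stopifnot(inherits(problem, "reserve_problem"))
  sel <- problem$ids %in% selected
  held <- colSums(problem$amounts[sel, , drop = FALSE])
  shortfall <- pmax(0, problem$targets - held)
  pen <- sum(problem$spf * (shortfall / problem$targets) * problem$gcost)
  bl <- boundary_length(problem, selected)
  cost <- sum(problem$cost[sel])
  list(objective = cost + problem$blm * bl + pen, cost = cost,
       boundary_km = bl, penalty = pen,
       shortfall = setNames(shortfall, colnames(problem$amounts)))
}

#' Annealing run parameters
#'
#' @param iterations proposals per run (default 10000, a desk-scale setting;
#'   production runs of the original tool use 1e6).
#' @param runs number of independent runs for selection frequencies
#'   (default 100; production 1e4).
#' @param t_initial starting temperature; `NULL` auto-calibrates to the mean
#'   |delta objective| of 100 presampled moves.
#' @param cooling geometric cooling factor per iteration in (0, 1); `NULL`
#'   sets the factor so temperature decays by 1e4 over the run.
#' @param seed integer master seed.
#' @return list of class `annealing_params`.
#' @export
annealing_params <- function(iterations = 10000, runs = 100,
                             t_initial = NULL, cooling = NULL, seed = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (!is.null(cooling) && !(cooling > 0 && cooling < 1))
    stop("cooling must be in (0, 1)")
  structure(list(iterations = as.integer(iterations), runs = as.integer(runs),
                 t_initial = t_initial, cooling = cooling,
                 seed = as.integer(seed)),
            class = "annealing_params")
}

#' Single simulated-annealing run
#'
#' Starts from the locked set plus an independent coin flip per free unit,
#' toggles one uniformly random non-locked unit per iteration, accepts
#' improving moves always and worsening moves with probability
#' `exp(-delta/T)` under a geometric temperature schedule, and returns the
#' best state seen.  Deterministic for a fixed `run_seed`.
#'
#' @param problem a `reserve_problem`.
#' @param params an [annealing_params()].
#' @param run_seed integer seed of this run.
#' @return list of class `reserve_solution`: `selected` (ids), `objective`,
#'   `feature_shortfalls`.
#' @export
anneal_run <- function(problem, params = annealing_params(), run_seed = 1) {
  stopifnot(inherits(problem, "reserve_problem"))
  n <- length(problem$ids)
  cooling <- if (is.null(params$cooling))
    (1e-4)^(1 / params$iterations) else params$cooling
  t0 <- if (is.null(params$t_initial)) -1 else params$t_initial
  res <- with_seed(run_seed, {
    init <- problem$locked | (runif(n) < 0.5 & !problem$locked)
    .anneal_cpp(problem$cost, problem$amounts, problem$targets, problem$spf,
                problem$gcost, problem$blm, problem$perimeter_km,
                problem$adj$ptr, problem$adj$idx, problem$adj$len,
                problem$locked, init, params$iterations, t0, cooling)
  })
  ids <- problem$ids[res$selected]
  full <- reserve_objective(problem, ids)
  structure(list(selected = ids, objective = res$objective,
                 objective_recomputed = full$objective,
                 feature_shortfalls = full$shortfall),
            class = "reserve_solution")
}

#' @export
print.reserve_solution <- function(x, ...) {
  cat(sprintf("<reserve_solution> %d units, objective %.6g\n",
              length(x$selected), x$objective))
  if (any(x$feature_shortfalls > 0))
    cat("  unmet targets: ",
        paste(names(which(x$feature_shortfalls > 0)), collapse = ", "), "\n")
  invisible(x)
}

#' Selection frequency across annealing runs
#'
#' Runs the annealer `params$runs` times under fanned-out seeds and counts,
#' for every unit, how many runs included it -- the conservation-priority
#' ranking used to assemble the final design.  Locked units score the full
#' run count by construction.
#'
#' @param problem a `reserve_problem`.
#' @param params an [annealing_params()].
#' @return named integer vector (names = unit ids), values in `[0, runs]`.
#' @export
selection_frequency <- function(problem, params = annealing_params()) {
  stopifnot(params$runs >= 1)
  run_seeds <- with_seed(params$seed, sample.int(.Machine$integer.max - 1L,
                                                 params$runs))
  counts <- setNames(integer(length(problem$ids)), problem$ids)
  for (r in seq_len(params$runs)) {
    sol <- anneal_run(problem, params, run_seed = run_seeds[r])
    counts[as.character(sol$selected)] <-
      counts[as.character(sol$selected)] + 1L
  }
  counts
}

#' Assemble the final reserve from selection frequencies
#'
#' Locked units enter first; the remainder is filled in descending
#' selection frequency with ties broken by ascending unit id, up to exactly
#' `k` units.
#'
#' @param frequencies named integer vector from [selection_frequency()].
#' @param k total design size in units (>= number of locked units).
#' @param locked integer ids guaranteed membership.
#' @return sorted integer vector of `k` unit ids.
#' @export
top_k_selection <- function(frequencies, k, locked = integer()) {
  ids <- as.integer(names(frequencies))
  if (is.null(names(frequencies)) || anyNA(ids))
    stop("frequencies must be named by unit id")
  locked <- as.integer(locked)
  if (k < length(locked)) stop("k is smaller than the locked set")
  if (k > length(ids)) stop("k exceeds the number of units")
  free <- setdiff(ids, locked)
  ordfree <- free[order(-frequencies[as.character(free)], free)]
  sort(c(locked, head(ordfree, k - length(locked))))
}

#' Reserve size from an area target
#'
#' Number of planning units protecting a given fraction of the landscape:
#' `round(fraction * n_units)`.
#'
#' @param n_units total planning-unit count.
#' @param fraction area fraction to protect (default 0.17).
#' @return integer unit count.
#' @export
reserve_size <- function(n_units, fraction = 0.17) {
  as.integer(round(fraction * n_units))
}
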