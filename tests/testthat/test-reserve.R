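# Two adjacent 10 km square units sharing a 10 km edge.
two_square_problem <- function(blm = 1) {
  reserve_problem(ids = 1:2, cost = c(1, 1),
                  amounts = matrix(c(1, 1), 2, dimnames = list(NULL, "f")),
                  targets = 0.5, blm = blm,
                  boundary = data.frame(id1 = 1, id2 = 2, length_km = 10),
                  perimeter_km = c(40, 40))
}

test_that("boundary length counts exposed perimeter only", {
  prob <- two_square_problem()
  expect_equal(boundary_length(prob, 1), 40)
  expect_equal(boundary_length(prob, 1:2), 60)  # 80 - 2 x 10 shared
  expect_equal(boundary_length(prob, integer()), 0)
  expect_error(boundary_length(prob, 3), "unknown")
})

test_that("objective collapses to cost when targets are met and blm is 0", {
  prob <- reserve_problem(ids = 1:3, cost = c(1, 1, 10),
                          amounts = matrix(c(5, 5, 10), 3,
                                           dimnames = list(NULL, "f")),
                          targets = 10, spf = 2, blm = 0)
  # greedy completion: units 1+2 (best amount per cost) -> G = 2
  expect_equal(prob$gcost, 2)
  expect_equal(reserve_objective(prob, c(1, 2))$objective, 2)
  expect_equal(reserve_objective(prob, 3)$objective, 10)
  expect_lt(reserve_objective(prob, c(1, 2))$objective,
            reserve_objective(prob, 3)$objective)
  # empty solution: pure penalty spf * (target/target) * G
  empty <- reserve_objective(prob, integer())
  expect_equal(empty$objective, 2 * 1 * 2)
  expect_equal(unname(empty$shortfall), 10)
})

test_that("boundary term rewards clumping", {
  prob <- two_square_problem(blm = 1)
  # both units: cost 2 + blm * 60; single: 1 + blm * 40 but target unmet
  expect_equal(reserve_objective(prob, 1:2)$objective, 2 + 60)
  expect_equal(reserve_objective(prob, 1:2)$penalty, 0)
})

test_that("annealing matches exhaustive search on small problems", {
  hits <- 0L
  for (trial in 1:10) {
    prob <- random_toy_problem(8, seed = trial)
    opt <- brute_force_optimum(prob)
    best <- min(vapply(1:20, function(r)
      anneal_run(prob, annealing_params(iterations = 2000),
                 run_seed = trial * 1000 + r)$objective, numeric(1)))
    if (abs(best - opt$objective) < 1e-8 * max(1, abs(opt$objective)))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("annealing bookkeeping matches recomputation and respects locks", {
  prob <- random_toy_problem(12, seed = 99)
  prob$locked[c(3, 7)] <- TRUE
  for (s in 1:5) {
    sol <- anneal_run(prob, annealing_params(iterations = 3000), run_seed = s)
    expect_true(all(c(3, 7) %in% sol$selected))
    expect_equal(sol$objective, sol$objective_recomputed,
                 tolerance = 1e-9)
  }
  # determinism per seed
  a <- anneal_run(prob, annealing_params(iterations = 1000), run_seed = 42)
  b <- anneal_run(prob, annealing_params(iterations = 1000), run_seed = 42)
  expect_identical(a$selected, b$selected)
  expect_identical(a$objective, b$objective)
})

test_that("annealing with no free units returns the locked set", {
  prob <- random_toy_problem(4, seed = 2)
  prob$locked[] <- TRUE
  sol <- anneal_run(prob, annealing_params(iterations = 100), run_seed = 1)
  expect_equal(sort(sol$selected), 1:4)
})

test_that("selection frequency ranks a strictly optimal pair near the top", {
  prob <- reserve_problem(ids = 1:3, cost = c(1, 1, 10),
                          amounts = matrix(c(5, 5, 10), 3,
                                           dimnames = list(NULL, "f")),
                          targets = 10, spf = 2, blm = 0)
  freq <- selection_frequency(prob, annealing_params(iterations = 500,
                                                     runs = 30, seed = 11))
  expect_true(all(freq[c("1", "2")] >= 28))
  expect_lt(freq[["3"]], 15)
  # locked units appear in every run
  prob$locked[3] <- TRUE
  freq2 <- selection_frequency(prob, annealing_params(iterations = 200,
                                                      runs = 10, seed = 3))
  expect_equal(unname(freq2[["3"]]), 10)
})

test_that("dominated units are selected no more often than their dominators", {
  # unit 2 dominates unit 3: cheaper, more of every feature, same geometry
  set.seed(14)
  prob <- reserve_problem(ids = 1:4, cost = c(1, 1, 2, 1),
                          amounts = matrix(c(4, 5, 2, 4), 4,
                                           dimnames = list(NULL, "f")),
                          targets = 8, spf = 2, blm = 0)
  freq <- selection_frequency(prob, annealing_params(iterations = 500,
                                                     runs = 40, seed = 8))
  expect_lte(freq[["3"]], freq[["2"]])
})

test_that("top-k assembly respects locks, frequency order and id ties", {
  freq <- setNames(c(5L, 5L, 3L, 7L), 1:4)
  # highest is unit 4 (7), then the 5/5 tie between units 1 and 2 -> 1 by id
  expect_equal(top_k_selection(freq, 2), sort(c(4, 1)))
  expect_equal(top_k_selection(freq, 3), sort(c(4, 1, 2)))
  expect_equal(top_k_selection(freq, 2, locked = 3), sort(c(3, 4)))
  expect_equal(top_k_selection(freq, 1, locked = 3), 3)
  expect_error(top_k_selection(freq, 0, locked = 3), "smaller")
  expect_error(top_k_selection(freq, 5), "exceeds")
})

test_that("scenario problems carry the documented features and costs", {
  L <- generate_landscape(synthetic_config(seed = 17))
  K <- resistant_kernel_density(L$resistance, place_sources(L$forest, 8),
                                kernel_params(bandwidth = 12500))
  pu <- apply_eligibility(build_planning_units(
    list(forest = L$forest, pa = L$pa_mask, kernel = K,
         carbon = L$carbon, risk = L$risk), 4),
    min_forest_km2 = 0.64, min_pa_km2 = 0.64)
  pro <- build_scenario_problem(pu, "proactive", retain = FALSE)
  exp_ <- build_scenario_problem(pu, "expedient", retain = TRUE)
  expect_equal(ncol(pro$amounts), 3)
  expect_equal(ncol(exp_$amounts), 2)
  expect_true(all(pro$targets == 0.30 * colSums(pro$amounts)))
  # redistribute -> nothing locked; retain -> the protected units
  expect_false(any(pro$locked))
  expect_equal(sum(exp_$locked), sum(pu$units$locked[pu$units$available]))
  # proactive costs area; expedient costs risk-weighted area
  u <- pu$units[pu$units$available, ]
  expect_equal(pro$cost, u$area_km2)
  expect_equal(exp_$cost, pmax(u$mean_risk, 0.01) * u$area_km2)
})

test_that("a positive boundary-length modifier yields more clumped
           solutions than none", {
  # 6x6 lattice of equal units; features reward any 12 units, so clumping
  # is decided by the boundary term alone
  n_side <- 6L
  ids <- seq_len(n_side^2)
  rows <- (ids - 1L) %/% n_side; cols <- (ids - 1L) %% n_side
  horiz <- which(cols < n_side - 1L)
  vert <- which(rows < n_side - 1L)
  boundary <- data.frame(
    id1 = c(ids[horiz], ids[vert]),
    id2 = c(ids[horiz] + 1L, ids[vert] + n_side),
    length_km = 4)
  set.seed(30)
  amounts <- matrix(runif(n_side^2, 0.9, 1.1), dimnames = list(NULL, "f"))
  mk <- function(blm) reserve_problem(
    ids = ids, cost = rep(1, n_side^2), amounts = amounts,
    targets = 12, spf = 2, blm = blm, boundary = boundary,
    perimeter_km = rep(16, n_side^2))
  components_of <- function(sel) {
    adj <- boundary[boundary$id1 %in% sel & boundary$id2 %in% sel, ]
    g <- igraph::graph_from_data_frame(adj[, 1:2], directed = FALSE,
                                       vertices = data.frame(name = sel))
    igraph::components(g)$no
  }
  comp <- sapply(1:10, function(s) {
    loose <- anneal_run(mk(0), annealing_params(iterations = 4000),
                        run_seed = s)
    tight <- anneal_run(mk(0.05), annealing_params(iterations = 4000),
                        run_seed = s)
    c(loose = components_of(loose$selected),
      tight = components_of(tight$selected))
  })
  expect_lt(mean(comp["tight", ]), mean(comp["loose", ]))
})
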