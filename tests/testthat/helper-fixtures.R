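# Shared fixtures and independent oracles, all built in code.

uniform_raster <- function(nr, nc, value = 1, cell_size = 500) {
  grid_raster(matrix(value, nr, nc), cell_size = cell_size)
}

# Independent shortest-path oracle: Bellman-Ford edge relaxation on the
# same lattice/edge-weight convention, no igraph involved.
bf_costs <- function(res_mat, source_rc, cell_size, neighbourhood = 8) {
  nr <- nrow(res_mat); nc <- ncol(res_mat)
  n <- nr * nc
  idx <- function(r, c) (c - 1L) * nr + r
  from <- integer(); to <- integer(); w <- numeric()
  sh <- list(c(1, 0), c(0, 1))
  if (neighbourhood == 8) sh <- c(sh, list(c(1, 1), c(1, -1)))
  for (r in seq_len(nr)) for (c in seq_len(nc)) for (s in sh) {
    rr <- r + s[1]; cc <- c + s[2]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    dfac <- if (s[1] != 0 && s[2] != 0) sqrt(2) else 1
    from <- c(from, idx(r, c)); to <- c(to, idx(rr, cc))
    w <- c(w, dfac * (res_mat[r, c] + res_mat[rr, cc]) / 2 * cell_size)
  }
  d <- rep(Inf, n)
  d[idx(source_rc[1], source_rc[2])] <- 0
  for (iter in seq_len(n)) {
    changed <- FALSE
    relax <- function(a, b) {
      upd <- d[a] + w < d[b]
      if (any(upd)) { d[b[upd]] <<- (d[a] + w)[upd]; changed <<- TRUE }
    }
    relax(from, to); relax(to, from)
    if (!changed) break
  }
  matrix(d, nr, nc)
}

# Random small reserve problem on a line of units (neighbours share edges).
random_toy_problem <- function(n_units = 10, n_features = 2, seed = 1,
                               blm = 0.0015) {
  set.seed(seed)
  amounts <- matrix(runif(n_units * n_features, 0, 1), n_units,
                    dimnames = list(NULL, paste0("f", seq_len(n_features))))
  cost <- runif(n_units, 0.5, 1.5)
  boundary <- data.frame(id1 = seq_len(n_units - 1L),
                         id2 = 2:n_units,
                         length_km = runif(n_units - 1L, 2, 6))
  reserve_problem(ids = seq_len(n_units), cost = cost, amounts = amounts,
                  targets = 0.3 * colSums(amounts), spf = 2, blm = blm,
                  boundary = boundary,
                  perimeter_km = runif(n_units, 12, 16))
}

# Exhaustive-search optimum of a reserve problem (locked units respected).
brute_force_optimum <- function(problem) {
  n <- length(problem$ids)
  free <- which(!problem$locked)
  best <- Inf; best_sel <- NULL
  for (mask in 0:(2^length(free) - 1L)) {
    sel <- problem$locked
    if (length(free))
      sel[free] <- bitwAnd(mask, bitwShiftL(1L, seq_along(free) - 1L)) != 0L
    obj <- reserve_objective(problem, problem$ids[sel])$objective
    if (obj < best) { best <- obj; best_sel <- problem$ids[sel] }
  }
  list(objective = best, selected = best_sel)
}

# Hand-built population state for inheritance tests.
make_state <- function(occupied, sex, geno) {
  structure(list(occupied = occupied, sex = sex, geno = geno),
            class = "pop_state")
}
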