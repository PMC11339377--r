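test_that("elevation: flat at zero roughness, seeded, autocorrelated", {
  flat <- generate_elevation(16, 16, roughness = 0, seed = 1)
  expect_equal(var(as.vector(flat$values)), 0)
  a <- generate_elevation(32, 32, roughness = 300, seed = 9)
  b <- generate_elevation(32, 32, roughness = 300, seed = 9)
  expect_identical(a$values, b$values)
  expect_true(all(is.finite(a$values)))
  expect_gt(morans_i(a), 0)
  expect_error(generate_elevation(0, 4), "positive")
  expect_error(generate_elevation(4, 4, roughness = -1), ">= 0")
})

test_that("elevation variance grows with roughness (Monte Carlo over seeds)", {
  v <- sapply(1:20, function(s) {
    c(lo = var(as.vector(generate_elevation(64, 64, 0.5, seed = s)$values)),
      hi = var(as.vector(generate_elevation(64, 64, 2, seed = s)$values)))
  })
  expect_true(all(v["hi", ] > v["lo", ]))
})

test_that("landcover hits the forest share and stratifies by elevation", {
  e <- generate_elevation(64, 64, seed = 3)
  lc <- generate_landcover(e, 0.6, seed = 4)
  share <- mean(classify_forest(lc)$values)
  expect_gte(share, 0.55); expect_lte(share, 0.65)
  cls <- landcover_classes()
  up <- lc$values == cls$code[cls$name == "upper_montane_forest"]
  low <- lc$values == cls$code[cls$name == "lowland_forest"]
  expect_gt(mean(e$values[up]), mean(e$values[low]))
  expect_gte(length(unique(as.vector(lc$values))), 7)
  # limiting case: almost everything forest
  lc99 <- generate_landcover(e, 0.999, seed = 4)
  expect_gte(mean(classify_forest(lc99)$values), 0.99)
  expect_error(generate_landcover(e, 1.2), "\\(0, 1\\)")
})

test_that("protected areas sit high and far and form few blobs", {
  expect_equal(sum(generate_pa_mask(generate_elevation(32, 32, seed = 1),
                                    uniform_raster(32, 32, 1), 0)$values), 0)
  higher <- vapply(1:20, function(s) {
    e <- generate_elevation(64, 64, seed = s)
    lc <- generate_landcover(e, 0.55, seed = s + 100)
    f <- classify_forest(lc)
    pa <- generate_pa_mask(e, f, 0.15, seed = s + 200)
    inpa <- pa$values > 0
    mean(e$values[inpa]) > mean(e$values[!inpa])
  }, logical(1))
  expect_gte(mean(higher), 0.95)
  # blob count bounded by the number of seeds
  e <- generate_elevation(64, 64, seed = 5)
  f <- classify_forest(generate_landcover(e, 0.55, seed = 6))
  pa <- generate_pa_mask(e, f, 0.15, seed = 7, n_blobs = 6)
  lab <- patch_metrics(pa)
  expect_lte(lab$np, 10)
  expect_equal(mean(pa$values), 0.15, tolerance = 0.01)
})

test_that("risk surface is a logistic with the stated structure", {
  e <- generate_elevation(48, 48, seed = 11)
  lc <- generate_landcover(e, 0.6, seed = 12)
  f <- classify_forest(lc)
  pa <- generate_pa_mask(e, f, 0.1, seed = 13)
  # all-zero coefficients: risk is exactly 0.5 on forest, 0 elsewhere
  r0 <- generate_risk(e, lc, pa, list(intercept = 0, elevation_slope = 0,
                                      edge_distance_slope = 0, pa_offset = 0))
  expect_true(all(r0$values[f$values > 0] == 0.5))
  expect_true(all(r0$values[f$values == 0] == 0))
  # protection depresses risk
  r <- generate_risk(e, lc, pa, list(intercept = -1, elevation_slope = 0,
                                     edge_distance_slope = 0, pa_offset = -2))
  fo <- f$values > 0
  expect_lt(mean(r$values[fo & pa$values > 0]), mean(r$values[fo & pa$values == 0]))
  # higher cell -> lower risk when only elevation acts
  re <- generate_risk(e, lc, pa, list(intercept = 0, elevation_slope = -1,
                                      edge_distance_slope = 0, pa_offset = 0))
  i <- which(fo)[order(e$values[fo])]
  expect_gt(re$values[i[1]], re$values[i[length(i)]])
  expect_true(all(r$values >= 0 & r$values <= 1))
  expect_error(generate_risk(e, lc, uniform_raster(8, 8)), "misaligned")
})

test_that("carbon is zero off forest with the requested class mean", {
  e <- generate_elevation(10, 10, roughness = 0)
  cls <- landcover_classes()
  lc <- grid_raster(matrix(cls$code[cls$name == "lowland_forest"], 10, 10))
  carb <- generate_carbon(lc, e, seed = 2,
                          class_means = c(lowland_forest = 100))
  expect_gte(mean(carb$values), 80); expect_lte(mean(carb$values), 120)
  expect_true(all(carb$values >= 0))
  lc2 <- grid_raster(matrix(cls$code[cls$name == "water"], 4, 4))
  expect_true(all(generate_carbon(lc2, seed = 1)$values == 0))
})

test_that("resistance is a pure per-class lookup", {
  cls <- landcover_classes()
  lc <- grid_raster(matrix(c(cls$code[cls$name == "lowland_forest"],
                             cls$code[cls$name == "plantation_regrowth"]), 1, 2))
  res <- generate_resistance(lc)
  expect_equal(as.vector(res$values),
               unname(default_resistance_table()[c("lowland_forest",
                                                   "plantation_regrowth")]))
  tab <- default_resistance_table()
  tab["plantation_regrowth"] <- 20
  expect_equal(generate_resistance(lc, tab)$values[1, 2], 20)
  expect_error(generate_resistance(grid_raster(matrix(42, 1, 1))), "unknown")
  # forest never more resistant than non-forest under the default table
  t0 <- default_resistance_table()
  expect_lte(max(t0[cls$name[cls$forest]]), min(t0[cls$name[!cls$forest]]))
})

test_that("a fixed seed reproduces the landscape bit for bit, with the
           joint structure the analysis assumes", {
  cfg <- synthetic_config(seed = 21)
  L1 <- generate_landscape(cfg)
  L2 <- generate_landscape(cfg)
  for (nm in c("elevation", "landcover", "risk", "carbon", "pa_mask",
               "resistance"))
    expect_identical(L1[[nm]]$values, L2[[nm]]$values)
  fo <- L1$forest$values > 0
  expect_lt(cor(L1$risk$values[fo], L1$elevation$values[fo]), 0)
  inpa <- L1$pa_mask$values > 0
  expect_lt(mean(L1$risk$values[inpa & fo]), mean(L1$risk$values[!inpa & fo]))
  expect_gt(mean(L1$elevation$values[inpa]), mean(L1$elevation$values[!inpa]))
  expect_true(all((L1$carbon$values > 0) == fo))
  expect_true(all(L1$resistance$values >= 1))
})
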