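# Applying models to birth records, pregnancy multipliers, area assignment
# and aggregation arithmetic.

test_that("predict_births applies a constant model and accounts for excluded coordinates", {
  b <- small_bundle()$birth_table
  cm <- constant_model(0.4, 200)
  b$lon[c(3, 17, 40)] <- NA
  out <- predict_births(cm, b)
  expect_equal(out$n_excluded, 3L)
  expect_equal(nrow(out$estimates), nrow(b) - 3L)
  expect_equal(length(unique(out$estimates$y_hat)), 1L)
})

test_that("pregnancy multipliers follow the inverse-probability formulas", {
  # a certain-unintended birth at the 71% live-birth rate: 1.4 pregnancies
  r <- pregnancy_multipliers(1, 0.71, 0.71)
  expect_equal(r$u_hat, 1 / 0.71)
  expect_equal(r$p_hat, 1 / 0.71)
  expect_equal(round(r$p_hat, 1), 1.4)
  # no pregnancy loss: a birth is exactly one pregnancy
  r <- pregnancy_multipliers(c(0.2, 0.9), c(1, 1), c(1, 1))
  expect_equal(r$u_hat, c(0.2, 0.9))
  expect_equal(r$p_hat, c(1, 1))
  # direct evaluation
  r <- pregnancy_multipliers(0.5, 0.5, 1)
  expect_equal(r$u_hat, 1.0)
  expect_equal(r$p_hat, 1.5)
  # flooring
  r <- pregnancy_multipliers(1, 0.01, 1, g_floor = 0.05)
  expect_equal(r$u_hat, 1 / 0.05)
  expect_error(pregnancy_multipliers(0.5, 0.5, 0.5, g_floor = 0), "g_floor")
})

test_that("multiplier invariants: u <= p, p >= 1, monotone in y at fixed g", {
  set.seed(31)
  y <- runif(200); g1 <- runif(200, 0.05, 1); g0 <- runif(200, 0.05, 1)
  r <- pregnancy_multipliers(y, g1, g0)
  expect_true(all(r$u_hat <= r$p_hat + 1e-12))
  expect_true(all(r$p_hat >= 1 - 1e-12))
  ord <- order(y)
  r2 <- pregnancy_multipliers(y[ord], rep(0.7, 200), rep(0.9, 200))
  expect_true(all(diff(r2$u_hat) >= 0))
})

test_that("area assignment matches brute-force containment and handles edge cases", {
  polys <- generate_polygons(6, seed = 4)
  # centroids map to their own polygon
  for (id in polys$ids) {
    ring <- polys$rings[[id]]
    expect_equal(assign_area(mean(range(ring[, 2])), mean(range(ring[, 1])),
                             polys), id)
  }
  # outside the tiling box
  expect_true(is.na(assign_area(-5, -5, polys)))
  expect_error(assign_area(1, 1,
                           structure(list(ids = character(0), rings = list()),
                                     class = "uisae_polygons")),
               "empty polygon")
  set.seed(32)
  n <- 2000
  lon <- runif(n, -10, 310); lat <- runif(n, -10, 245)
  expect_identical(assign_area(lat, lon, polys),
                   brute_assign_rect(lat, lon, polys))
  # boundary points resolve to the lexicographically smallest id
  ring1 <- polys$rings[[polys$ids[1]]]
  edge_x <- max(ring1[, 1])   # shared with the neighbouring polygon
  mid_y <- mean(range(ring1[, 2]))
  got <- assign_area(mid_y, edge_x, polys)
  expect_equal(got, min(polys$ids[vapply(polys$ids, function(id) {
    point_in <- brute_assign_rect(mid_y, edge_x,
      structure(list(ids = id, rings = polys$rings[id]),
                class = "uisae_polygons"))
    !is.na(point_in)
  }, logical(1))]))
})

test_that("aggregation arithmetic matches the forced example", {
  be <- data.frame(area_id = "A01", age = c(20, 25, 30),
                   y_hat = c(0.2, 0.4, 0.6), u_hat = c(0.2, 0.4, 0.6),
                   p_hat = c(1, 1, 1))
  pop <- data.frame(area_id = "A01",
                    age_lo = default_age_bins()$age_lo,
                    age_hi = default_age_bins()$age_hi,
                    women = c(0, 0, 50, 25, 25, 0))   # 100 women total
  ae <- aggregate_areas(be, pop, years_span = 3)
  row <- ae[ae$area_id == "A01" & ae$age_group == "all", ]
  expect_equal(row$unintended_births_per_year, 0.4)
  expect_equal(row$pct_births_unintended, 40.0)
  expect_equal(row$incidence_births_per_1000, 4.0)
  expect_equal(row$pregnancies_per_year, 1.0)
})

test_that("statewide totals equal the sum over areas and zero-birth areas add nothing", {
  set.seed(33)
  polys <- generate_polygons(5, seed = 5)
  n <- 400
  be <- data.frame(area_id = sample(polys$ids[1:4], n, replace = TRUE),
                   age = runif(n, 15, 45), y_hat = runif(n))
  mult <- pregnancy_multipliers(be$y_hat, runif(n, 0.4, 0.9),
                                runif(n, 0.5, 1))
  be <- cbind(be, mult)
  pop <- generate_population_table(polys, seed = 5)
  ae <- aggregate_areas(be, pop, years_span = 3)
  sw <- ae[ae$area_id == "ALL" & ae$age_group == "all", ]
  by_area <- ae[ae$area_id != "ALL" & ae$age_group == "all", ]
  for (cl in c("births_per_year", "unintended_births_per_year",
               "pregnancies_per_year", "unintended_pregnancies_per_year"))
    expect_equal(sum(by_area[[cl]]), sw[[cl]], tolerance = 1e-9)
  # the area with no births contributes zeros
  empty <- by_area[by_area$area_id == polys$ids[5], ]
  expect_equal(empty$births_per_year, 0)
  expect_equal(empty$unintended_pregnancies_per_year, 0)
  # age-group rows also conserve within each area
  a1 <- ae[ae$area_id == polys$ids[1], ]
  expect_equal(sum(a1$births_per_year[a1$age_group != "all"]),
               a1$births_per_year[a1$age_group == "all"], tolerance = 1e-9)
})

test_that("the g=1 limit collapses pregnancies to births exactly", {
  b <- small_bundle()
  cm <- constant_model(0.34, 300)
  pb <- predict_births(cm, b$birth_table)
  est <- pb$estimates
  mult <- pregnancy_multipliers(est$y_hat, rep(1, nrow(est)),
                                rep(1, nrow(est)))
  est <- cbind(est, mult)
  est$area_id <- est$area_id_true
  ae <- aggregate_areas(est, b$population_table)
  expect_equal(ae$pregnancies_per_year, ae$births_per_year, tolerance = 1e-12)
  expect_equal(ae$unintended_pregnancies_per_year,
               ae$unintended_births_per_year, tolerance = 1e-12)
})

test_that("statewide report rounds at the reporting grain and ignores row order", {
  set.seed(34)
  polys <- generate_polygons(3, seed = 6)
  n <- 500
  be <- data.frame(area_id = sample(polys$ids, n, replace = TRUE),
                   age = runif(n, 15, 45), y_hat = runif(n))
  be <- cbind(be, pregnancy_multipliers(be$y_hat, rep(0.6, n), rep(0.8, n)))
  pop <- generate_population_table(polys, seed = 6)
  ae1 <- aggregate_areas(be, pop)
  ae2 <- aggregate_areas(be[sample(n), ], pop)
  r1 <- statewide_report(ae1); r2 <- statewide_report(ae2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$births_per_year %% 100, 0)
  expect_equal(r1$pct_births_unintended,
               round(attr(r1, "unrounded")$pct_births_unintended, 1))
  # g1 < g0 everywhere: pregnancies are more unintended than births
  expect_gte(r1$pct_pregnancies_unintended, r1$pct_births_unintended)
})
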