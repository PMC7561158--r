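# The simulator must reproduce its own documented ground truth: stated
# baselines, exact geometry conservation, and byte-identical reruns.

test_that("polygon tiling conserves area and handles the degenerate case", {
  one <- generate_polygons(1, seed = 1)
  expect_equal(length(one$ids), 1L)
  expect_equal(sum(one$area_sqmi), 69707, tolerance = 1e-12)

  polys <- generate_polygons(47, seed = 1)
  expect_equal(length(polys$ids), 47L)
  expect_lt(abs(sum(polys$area_sqmi) - 69707) / 69707, 1e-9)
  expect_true(all(polys$area_sqmi > 0))

  expect_error(generate_polygons(0), "area_count")
})

test_that("every birth falls inside exactly one polygon", {
  polys <- generate_polygons(4, seed = 2)
  tr <- ground_truth(area_count = 4, births_per_area = 500, seed = 2)
  births <- generate_birth_table(tr, polys)
  # brute-force containment count over all 4 rectangles
  n_containing <- rep(0L, nrow(births))
  for (id in polys$ids) {
    ring <- polys$rings[[id]]
    inside <- births$lon >= min(ring[, 1]) & births$lon <= max(ring[, 1]) &
      births$lat >= min(ring[, 2]) & births$lat <= max(ring[, 2])
    n_containing <- n_containing + as.integer(inside)
  }
  expect_true(all(n_containing == 1L))
})

test_that("null-coefficient birth table recovers the baseline unintended share", {
  tr <- ground_truth(intendedness_coefficients = c(married = 0),
                     baseline_unintended_share = 0.34,
                     area_count = 5, births_per_area = 10000, seed = 11)
  polys <- generate_polygons(5, seed = 11)
  births <- generate_birth_table(tr, polys)  # n = 50,000
  se <- sqrt(0.34 * 0.66 / nrow(births))
  expect_lt(abs(mean(births$unintended_true) - 0.34), 3 * se)
})

test_that("birth generation is deterministic and respects missingness rates", {
  tr0 <- ground_truth(area_count = 3, births_per_area = 400,
                      missingness_rates = c(bmi = 0, prenatal_month = 0),
                      seed = 5)
  polys <- generate_polygons(3, seed = 5)
  b1 <- generate_birth_table(tr0, polys)
  expect_false(anyNA(b1))
  b2 <- generate_birth_table(tr0, polys)
  expect_identical(b1, b2)

  tr1 <- ground_truth(area_count = 3, births_per_area = 4000, seed = 5)
  b3 <- generate_birth_table(tr1, polys)
  for (fld in names(tr1$missingness_rates)) {
    r <- tr1$missingness_rates[[fld]]
    frac <- mean(is.na(b3[[fld]]))
    expect_lt(abs(frac - r), 3 * sqrt(r * (1 - r) / nrow(b3)) + 1e-9)
  }
})

test_that("survey subsample is self-weighting at rate 1 and HT-consistent at 0.05", {
  bundle <- small_bundle()
  births <- bundle$birth_table

  census <- generate_survey_table(births, sampling_rate = 1,
                                  weight_dispersion = 0, seed = 3)
  expect_equal(nrow(census), nrow(births))
  expect_true(all(census$weight == 1))
  y <- code_intendedness(census$raw_response)
  expect_equal(stats::weighted.mean(y, census$weight), mean(y))

  tr <- ground_truth(area_count = 5, births_per_area = 10000, seed = 11)
  polys <- generate_polygons(5, seed = 11)
  big <- generate_birth_table(tr, polys)
  smp <- generate_survey_table(big, sampling_rate = 0.05,
                               weight_dispersion = 0.3, seed = 4)
  expect_lt(abs(nrow(smp) - 2500), 3 * sqrt(50000 * 0.05 * 0.95))
  share_birth <- mean(big$unintended_true)
  y <- code_intendedness(smp$raw_response)
  se <- sqrt(share_birth * (1 - share_birth) / nrow(smp))
  expect_lt(abs(stats::weighted.mean(y, smp$weight) - share_birth), 3 * se)

  expect_identical(smp, generate_survey_table(big, 0.05, 0.3, seed = 4))
  expect_error(generate_survey_table(big[0, ], 0.5), "empty")
})

test_that("five-category response is consistent with the latent binary truth", {
  s <- small_bundle()$survey_table
  expect_true(all(s$raw_response[s$unintended_true == 1] %in%
                    c("later", "never")))
  expect_true(all(s$raw_response[s$unintended_true == 0] %in%
                    c("sooner", "then", "unsure")))
})

test_that("pregnancy table recovers the live-birth baseline and its monotone link", {
  tr <- ground_truth(livebirth_coefficients = c(unintended = 0),
                     baseline_livebirth_share = 0.71, seed = 8)
  preg <- generate_pregnancy_table(tr, n_women = 12000, seed = 8)
  expect_gt(nrow(preg), 15000)
  se <- sqrt(0.71 * 0.29 / nrow(preg))
  expect_lt(abs(mean(preg$livebirth) - 0.71), 3 * se)

  tr1 <- ground_truth(baseline_livebirth_share = 1, seed = 8)
  preg1 <- generate_pregnancy_table(tr1, n_women = 500, seed = 8)
  expect_true(all(preg1$livebirth == 1))

  # negative intendedness coefficient in g*: unintended pregnancies end in
  # live birth less often
  tr2 <- ground_truth(seed = 8)  # unintended coef -0.55
  preg2 <- generate_pregnancy_table(tr2, n_women = 12000, seed = 9)
  sh_un <- stats::weighted.mean(preg2$livebirth[preg2$unintended == 1],
                                preg2$weight[preg2$unintended == 1])
  sh_in <- stats::weighted.mean(preg2$livebirth[preg2$unintended == 0],
                                preg2$weight[preg2$unintended == 0])
  expect_lt(sh_un, sh_in)
})

test_that("population table conserves totals and the degenerate bin is exact", {
  polys1 <- generate_polygons(1, seed = 1)
  pop1 <- generate_population_table(
    polys1, women_per_area = c(1000, 1000),
    age_bins = data.frame(age_lo = 15L, age_hi = 45L), seed = 1)
  expect_equal(nrow(pop1), 1L)
  expect_equal(pop1$women, 1000L)

  polys <- generate_polygons(6, seed = 2)
  pop <- generate_population_table(polys, seed = 2)
  totals <- tapply(pop$women, pop$area_id, sum)
  expect_true(all(totals >= 15000 & totals <= 36000))
  expect_identical(pop, generate_population_table(polys, seed = 2))

  bad_bins <- data.frame(age_lo = c(15L, 22L), age_hi = c(20L, 45L))
  expect_error(generate_population_table(polys, age_bins = bad_bins),
               "partition")
})

test_that("bundle-level invariants hold", {
  b <- small_bundle()
  expect_lte(nrow(b$survey_table), nrow(b$birth_table))
  expect_true(all(b$survey_table$weight > 0))
  expect_true(all(b$pregnancy_table$weight > 0))
  expect_true(all(b$birth_table$unintended_true %in% c(0, 1)))
  expect_length(setdiff(unique(b$birth_table$area_id_true),
                        b$polygons$ids), 0)
})
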