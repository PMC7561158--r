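# Candidate fitting, K-fold selection, importance shares and predictive
# margins, each checked against independent oracles or known ground truth.

test_that("null-signal fits concentrate predictions near the weighted outcome mean", {
  set.seed(21)
  n <- 20000
  d <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.34)                     # independent of features
  w <- runif(n, 0.5, 2)
  target <- stats::weighted.mean(y, w)
  for (fam in c("logistic", "linear_sgd")) {
    m <- fit_candidate(d, y, w, fam, seed = 2)
    expect_lt(abs(mean(predict(m, d)) - target), 0.05)
  }
})

test_that("doubling a weight equals duplicating the row for the likelihood families", {
  set.seed(22)
  n <- 300
  d <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(d$a))
  w <- rep(1, n); w[1] <- 2
  m_w <- fit_candidate(d, y, w, "logistic")
  m_dup <- fit_candidate(rbind(d[1, ], d), c(y[1], y), rep(1, n + 1),
                         "logistic")
  newd <- data.frame(a = rnorm(20), b = rbinom(20, 1, 0.5))
  expect_equal(predict(m_w, newd), predict(m_dup, newd), tolerance = 1e-8)
})

test_that("every family is deterministic under a fixed seed and errors on one class", {
  set.seed(23)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5), c = rnorm(n))
  y <- rbinom(n, 1, plogis(d$a))
  held <- data.frame(a = rnorm(50), b = rbinom(50, 1, 0.5), c = rnorm(50))
  for (fam in c("random_forest", "gradient_boosting", "neural_net")) {
    p1 <- predict(fit_candidate(d, y, rep(1, n), fam, seed = 7), held)
    p2 <- predict(fit_candidate(d, y, rep(1, n), fam, seed = 7), held)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
  }
  expect_error(fit_candidate(d, rep(1L, n), rep(1, n), "logistic"),
               "single class")
})

test_that("model selection returns the singleton, never a dominated candidate, and is reproducible", {
  set.seed(24)
  n <- 1500
  d <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * d$a))
  one <- select_model(d, y, grid = candidate_grid()[2], k_folds = 3, seed = 1)
  expect_equal(one$family, "random_forest")

  sel <- select_model(d, y, grid = candidate_grid()[c(1, 2, 7)],
                      k_folds = 3, seed = 1)
  agg <- tapply(sel$cv_table$cstat, sel$cv_table$candidate, mean)
  winner_label <- unique(sel$cv_table$candidate[
    sel$cv_table$family == sel$family])[1]
  expect_gte(agg[[winner_label]] + 1e-12, max(agg))
  expect_equal(sel$cv_cstat, max(agg), tolerance = 1e-12)

  sel2 <- select_model(d, y, grid = candidate_grid()[c(1, 2, 7)],
                       k_folds = 3, seed = 1)
  expect_identical(round(sel$cv_cstat, 2), round(sel2$cv_cstat, 2))
  expect_identical(sel$cv_table, sel2$cv_table)
})

test_that("a strongly nonlinear truth selects a tree family over the linear ones", {
  set.seed(25)
  n <- 10000
  d <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
                  c = rnorm(n))
  # XOR interaction: no linear model can separate this
  p <- ifelse(xor(d$a == 1, d$b == 1), 0.75, 0.25)
  y <- rbinom(n, 1, p)
  sel <- select_model(d, y, grid = candidate_grid()[c(1, 2, 7)],
                      k_folds = 3, seed = 2)
  expect_equal(sel$family, "random_forest")
})

test_that("importance shares normalise, and known signal features occupy the top ranks", {
  set.seed(26)
  n <- 20000
  p_noise <- 20
  strong <- paste0("s", 1:5)
  d <- as.data.frame(matrix(rnorm(n * p_noise), n,
                            dimnames = list(NULL, paste0("z", 1:p_noise))))
  for (v in strong) d[[v]] <- rnorm(n)
  lp <- 1.2 * (d$s1 + d$s2 + d$s3 + d$s4 + d$s5)
  y <- rbinom(n, 1, plogis(lp))
  m <- fit_candidate(d, y, rep(1, n), "random_forest",
                     hyper = list(num_trees = 150), seed = 3)
  rep5 <- importance_report(m, top_k = 5)
  expect_equal(sum(rep5$table$share), 1, tolerance = 1e-9)
  expect_true(all(rep5$table$share >= 0))
  expect_setequal(rep5$table$feature[1:5], strong)
  expect_gt(rep5$top_k_share, 0.5)

  m1 <- fit_candidate(d[, "s1", drop = FALSE], y, rep(1, n),
                      "random_forest", hyper = list(num_trees = 50),
                      seed = 3)
  expect_equal(importance_report(m1, 1)$table$share, 1)
  m_log <- fit_candidate(d[strong], y, rep(1, n), "logistic")
  expect_error(importance_report(m_log), "importances")
})

test_that("predictive margins collapse for a constant model and match the naive oracle", {
  cm <- constant_model(0.4, 200)
  d <- data.frame(x = rnorm(100), v = rbinom(100, 1, 0.5))
  mg <- predictive_margins(cm, d, "v", c(0, 1))
  cst <- 100 * predict(cm, d)[1]
  for (cl in c("mean", "p25", "p50", "p75", "lower_adjacent",
               "upper_adjacent"))
    expect_equal(mg[[cl]], rep(cst, 2))
  expect_true(all(mg$p25 <= mg$p50 & mg$p50 <= mg$p75))
  expect_true(all(mg$lower_adjacent <= mg$p25 & mg$upper_adjacent >= mg$p75))

  set.seed(27)
  n <- 800
  d <- data.frame(a = rnorm(n), v = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.5 + d$a - 0.6 * d$v))
  m <- fit_candidate(d, y, rep(1, n), "gradient_boosting", seed = 4)
  mg <- predictive_margins(m, d, "v", c(0, 1))
  for (k in 1:2) {
    d2 <- d; d2$v <- mg$level[k]
    expect_equal(mg$mean[k], mean(100 * predict(m, d2)), tolerance = 1e-12)
  }
  expect_error(predictive_margins(m, d, "nope", 0), "unknown feature")
})

test_that("margins over a null feature are flat at large n", {
  set.seed(28)
  n <- 20000
  d <- data.frame(a = rnorm(n), null_f = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.6 + 0.9 * d$a))   # null_f truly absent
  m <- fit_candidate(d, y, rep(1, n), "logistic")
  mg <- predictive_margins(m, d, "null_f", c(0, 1))
  expect_lt(abs(mg$mean[1] - mg$mean[2]), 1)    # < 1 percentage point
})

test_that("margins for marriage recover the true marginal effect within 2 points", {
  tr <- ground_truth(area_count = 5, births_per_area = 10000,
                     missingness_rates = c(bmi = 0), seed = 11)
  polys <- generate_polygons(5, seed = 11)
  births <- generate_birth_table(tr, polys)      # n = 50,000
  survey <- generate_survey_table(births, sampling_rate = 0.2,
                                  weight_dispersion = 0.3, seed = 12)
  mf <- fit_intendedness(survey, grid = candidate_grid()[1], seed = 13)
  feats <- intersect(intendedness_feature_names(), names(births))
  mg <- predictive_margins(mf, births[feats], "married", c(0, 1))

  # true marginal effect under f*: force married for everyone, average p,
  # with the intercept recalibrated exactly as the generator calibrates it
  true_lp <- function(tab) {
    lp <- 0
    for (nm in names(tr$intendedness_coefficients)) {
      v <- if (nm == "age_c") tab$age - tr$marginals$age$mean else tab[[nm]]
      lp <- lp + tr$intendedness_coefficients[[nm]] * v
    }
    lp
  }
  a0 <- uniroot(function(a) {
    mean(plogis(a + true_lp(births))) - tr$baseline_unintended_share
  }, c(-30, 30), tol = 1e-10)$root
  truth_margin <- function(val) {
    b2 <- births; b2$married <- val
    100 * mean(plogis(a0 + true_lp(b2)))
  }
  true_effect <- truth_margin(1) - truth_margin(0)
  est_effect <- mg$mean[2] - mg$mean[1]
  expect_lt(abs(est_effect - true_effect), 2)
})
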