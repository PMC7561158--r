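# Survey-weighted candidate classifiers and K-fold c-statistic model
# selection. Five families are supported, mirroring the modelling techniques
# compared for the intendedness model: logistic regression, random forest,
# gradient boosting, a single-hidden-layer neural network, and a regularised
# linear classifier. Each honours observation weights in its fitting
# criterion and is deterministic under a fixed seed.

uisae_families <- c("logistic", "random_forest", "gradient_boosting",
                    "neural_net", "linear_sgd")

default_hyper <- function(family) {
  switch(family,
    logistic = list(),
    random_forest = list(num_trees = 300, min_node_size = 10, mtry = NULL),
    gradient_boosting = list(nrounds = 100, max_depth = 3, eta = 0.1),
    neural_net = list(size = 8, decay = 0.01, maxit = 200),
    linear_sgd = list(alpha = 0, lambda = 1e-3),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

feature_matrix <- function(data, features) {
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols))
    stop("feature schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as.matrix(data[features])
}

#' Fit one candidate survey-weighted classifier
#'
#' Fits a single model family on an already-imputed feature table, honouring
#' observation weights in the loss or splitting criterion, and returns a
#' classed model object whose \code{predict} method maps any complete
#' feature table to probabilities in [0, 1].
#'
#' @param data Data.frame of numeric features (imputation already applied;
#'   non-numeric columns are ignored).
#' @param outcome Binary 0/1 vector, one per row.
#' @param weights Positive observation weights.
#' @param family One of \code{"logistic"}, \code{"random_forest"},
#'   \code{"gradient_boosting"}, \code{"neural_net"}, \code{"linear_sgd"}.
#' @param hyper Named list of hyperparameters; unset entries take the
#'   documented defaults of [default_hyper].
#' @param seed Integer seed controlling any randomness in the fit.
#' @return An object of class \code{uisae_model}.
#' @examples
#' d <- data.frame(x = rnorm(200))
#' y <- rbinom(200, 1, plogis(d$x))
#' m <- fit_candidate(d, y, rep(1, 200), "logistic")
#' range(predict(m, d))
#' @export
fit_candidate <- function(data, outcome, weights = rep(1, nrow(data)),
                          family = "logistic", hyper = list(), seed = 1L) {
  family <- match.arg(family, uisae_families)
  stopifnot(nrow(data) == length(outcome), length(weights) == length(outcome),
            all(weights > 0), all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2)
    stop("outcome has a single class; cannot fit a classifier", call. = FALSE)
  hp <- utils::modifyList(default_hyper(family), hyper)
  features <- names(data)[vapply(data, is.numeric, logical(1))]
  if (anyNA(data[features]))
    stop("features contain NA; run impute() first", call. = FALSE)
  X <- feature_matrix(data, features)
  y <- as.numeric(outcome)

  fit <- with_seed(seed, switch(family,
    logistic = {
      df <- as.data.frame(X); df$.y <- y
      stats::glm(.y ~ ., data = df, weights = weights,
                 family = stats::quasibinomial())
    },
    linear_sgd = {
      glmnet::glmnet(X, y, family = "binomial", weights = weights,
                     alpha = hp$alpha, lambda = hp$lambda,
                     standardize = TRUE)
    },
    random_forest = {
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, case.weights = weights,
                     num.trees = hp$num_trees,
                     min.node.size = hp$min_node_size,
                     mtry = hp$mtry, importance = "impurity",
                     seed = seed, num.threads = 1)
    },
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(X, label = y, weight = weights,
                                  nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1,
                      seed = seed),
        data = dtr, nrounds = hp$nrounds, verbose = 0)
    },
    neural_net = {
      ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, center = ctr, scale = scl)
      nn <- nnet::nnet(Xs, y, weights = weights, size = hp$size,
                       decay = hp$decay, maxit = hp$maxit,
                       entropy = TRUE, trace = FALSE)
      list(net = nn, center = ctr, scale = scl)
    }
  ))

  structure(list(family = family, hyper = hp, fit = fit,
                 features = features, seed = as.integer(seed),
                 cv_cstat = NA_real_, cv_table = NULL, imputer = NULL),
            class = "uisae_model")
}

#' Predict event probabilities from a fitted candidate
#'
#' @param object A \code{uisae_model}.
#' @param newdata Data.frame carrying all feature columns the model was fit
#'   on (a schema error names any that are missing). If the model carries a
#'   frozen imputation state, missing values are imputed with it first.
#' @param ... Unused.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict.uisae_model <- function(object, newdata, ...) {
  if (!is.null(object$imputer)) newdata <- impute(newdata, object$imputer)
  X <- feature_matrix(newdata, object$features)
  p <- switch(object$family,
    logistic = {
      stats::predict(object$fit, newdata = as.data.frame(X),
                     type = "response")
    },
    linear_sgd = {
      as.vector(stats::predict(object$fit, newx = X, type = "response"))
    },
    random_forest = {
      pr <- stats::predict(object$fit, data = X, num.threads = 1)$predictions
      pr[, "1"]
    },
    gradient_boosting = {
      stats::predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))
    },
    neural_net = {
      Xs <- scale(X, center = object$fit$center, scale = object$fit$scale)
      as.vector(stats::predict(object$fit$net, Xs))
    }
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' @method print uisae_model
#' @export
print.uisae_model <- function(x, ...) {
  cat(sprintf("Survey-weighted classifier (family: %s, %d features)\n",
              x$family, length(x$features)))
  if (!is.na(x$cv_cstat))
    cat(sprintf("  cross-validated c-statistic: %.2f\n", x$cv_cstat))
  invisible(x)
}

#' @method summary uisae_model
#' @export
summary.uisae_model <- function(object, ...) {
  print(object)
  if (!is.null(object$cv_table)) {
    cat("  CV results (mean held-out c-statistic by candidate):\n")
    agg <- stats::aggregate(cstat ~ candidate + family,
                            data = object$cv_table, FUN = mean)
    agg <- agg[order(-agg$cstat), ]
    for (i in seq_len(nrow(agg)))
      cat(sprintf("    %-28s %.4f\n", agg$candidate[i], agg$cstat[i]))
  }
  invisible(object)
}

#' @export
coef.uisae_model <- function(object, ...) {
  switch(object$family,
    logistic = stats::coef(object$fit),
    linear_sgd = {
      b <- as.matrix(stats::coef(object$fit))
      stats::setNames(b[, 1], rownames(b))
    },
    stop("coefficients are only defined for the linear families",
         call. = FALSE)
  )
}

#' Default candidate grid for model selection
#'
#' One small documented grid per family, ordered by the fixed family
#' precedence used for tie-breaking (logistic first, then random forest,
#' gradient boosting, neural net, regularised linear), with simpler
#' hyperparameter settings before more complex ones within a family.
#'
#' @return A list of candidates, each a list with \code{label},
#'   \code{family}, \code{hyper}.
#' @export
candidate_grid <- function() {
  list(
    list(label = "logistic", family = "logistic", hyper = list()),
    list(label = "random_forest_t300_n10", family = "random_forest",
         hyper = list(num_trees = 300, min_node_size = 10)),
    list(label = "random_forest_t300_n50", family = "random_forest",
         hyper = list(num_trees = 300, min_node_size = 50)),
    list(label = "gradient_boosting_r100_d3", family = "gradient_boosting",
         hyper = list(nrounds = 100, max_depth = 3)),
    list(label = "gradient_boosting_r200_d4", family = "gradient_boosting",
         hyper = list(nrounds = 200, max_depth = 4)),
    list(label = "neural_net_s8", family = "neural_net",
         hyper = list(size = 8, decay = 0.01)),
    list(label = "linear_sgd_l1e3", family = "linear_sgd",
         hyper = list(alpha = 0, lambda = 1e-3))
  )
}

# Stratified-by-outcome fold assignment; every fold carries both classes
# whenever each class has at least k members.
stratified_folds <- function(outcome, k, seed) {
  with_seed(seed, {
    fold <- integer(length(outcome))
    for (cls in unique(outcome)) {
      idx <- sample(which(outcome == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Select the best candidate by cross-validated weighted c-statistic
#'
#' Runs stratified K-fold cross-validation over a candidate grid, scoring
#' each candidate by the mean held-out survey-weighted c-statistic, then
#' refits the winner on all data. Ties are broken by grid order (family
#' precedence, then smaller hyperparameter complexity). The returned model
#' records its cross-validated c-statistic and the full per-fold CV table.
#'
#' @param data Imputed feature data.frame.
#' @param outcome Binary 0/1 vector.
#' @param weights Positive observation weights.
#' @param grid Candidate list as from [candidate_grid()].
#' @param k_folds Number of folds (>= 2); default 5.
#' @param seed Integer seed (folds and fits).
#' @return A \code{uisae_model} with \code{cv_cstat} and \code{cv_table}
#'   (columns candidate, family, fold, cstat) filled in.
#' @export
select_model <- function(data, outcome, weights = rep(1, nrow(data)),
                         grid = candidate_grid(), k_folds = 5, seed = 1L) {
  stopifnot(k_folds >= 2, length(grid) >= 1)
  fold <- stratified_folds(outcome, k_folds, seed)
  rows <- list()
  for (ci in seq_along(grid)) {
    cand <- grid[[ci]]
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      m <- fit_candidate(data[tr, , drop = FALSE], outcome[tr], weights[tr],
                         cand$family, cand$hyper, seed = seed + f)
      p <- predict(m, data[!tr, , drop = FALSE])
      cs <- weighted_cstat(p, outcome[!tr], weights[!tr])
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = cand$label, family = cand$family, fold = f, cstat = cs)
    }
  }
  cv_table <- do.call(rbind, rows)
  mean_cs <- vapply(grid, function(cand) {
    mean(cv_table$cstat[cv_table$candidate == cand$label])
  }, numeric(1))
  best <- which.max(mean_cs)   # first maximum: grid order breaks ties
  winner <- grid[[best]]
  model <- fit_candidate(data, outcome, weights, winner$family, winner$hyper,
                         seed = seed)
  model$cv_cstat <- mean_cs[best]
  model$cv_table <- cv_table
  model
}
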