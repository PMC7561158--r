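# End-to-end pipeline: configuration, schema validation, the two fitting
# stages wrapped with outcome coding and frozen imputation, and run_all()
# executing simulate -> fit-intendedness -> fit-livebirth -> estimate ->
# density -> report with deterministic artifacts.

#' Feature dictionaries for the two models
#'
#' Column names of the birth-record covariates used by the intendedness
#' model f (everything shared between the survey and the birth file) and by
#' the live-birth model g (the smaller set shared between the pregnancy
#' history and the birth file; g additionally uses the intendedness flag).
#'
#' @return Character vector of feature names.
#' @export
intendedness_feature_names <- function() {
  c("age", "married", "insurance_private", "race_black", "hispanic",
    "education_years", "foreign_born", "infertility_treatment", "parity",
    "multiple_birth", "prenatal_month", "prenatal_visits", "smoked_before",
    "bmi", "risk_any", "prev_adverse", "birthweight_g", "gest_lt39",
    "breastfeeding", "infant_male", "father_college")
}

#' @rdname intendedness_feature_names
#' @export
livebirth_feature_names <- function() {
  c("age", "married", "race_black", "hispanic", "foreign_born", "parity")
}

#' Fit the intendedness model on a survey table
#'
#' Codes the five-category response to the binary unintended outcome under
#' the chosen scheme (dropping excluded rows under \code{drop_unsure}),
#' freezes the imputation state on the survey table, imputes, and selects
#' the best candidate by survey-weighted cross-validated c-statistic. The
#' frozen imputer travels with the model so birth records are imputed with
#' the survey medians.
#'
#' @param survey_table Survey data.frame with \code{raw_response},
#'   \code{weight} and the feature columns.
#' @param coding_scheme Passed to [code_intendedness()].
#' @param grid Candidate grid; default [candidate_grid()].
#' @param k_folds Cross-validation folds.
#' @param seed Integer seed.
#' @return A \code{uisae_model} with frozen \code{imputer}.
#' @export
fit_intendedness <- function(survey_table,
                             coding_scheme = "unsure_as_not_unintended",
                             grid = candidate_grid(), k_folds = 5,
                             seed = 1L) {
  y <- code_intendedness(survey_table$raw_response, coding_scheme)
  keep <- !is.na(y)
  tab <- survey_table[keep, , drop = FALSE]
  y <- y[keep]
  feats <- intersect(intendedness_feature_names(), names(tab))
  imp <- fit_imputer(tab[feats])
  X <- impute(tab[feats], imp)
  model <- select_model(X, y, tab$weight, grid = grid, k_folds = k_folds,
                        seed = seed)
  model$imputer <- imp
  model$coding_scheme <- coding_scheme
  model
}

#' Fit the live-birth model on a pregnancy-history table
#'
#' Models the probability that a pregnancy ends in a live birth as a
#' function of the shared covariates and intendedness, with survey weights,
#' selecting among candidates by cross-validated weighted c-statistic.
#'
#' @param pregnancy_table Pregnancy-history data.frame with
#'   \code{livebirth}, \code{unintended}, \code{weight} and covariates.
#' @param grid Candidate grid.
#' @param k_folds Cross-validation folds.
#' @param seed Integer seed.
#' @return A \code{uisae_model} with frozen \code{imputer}.
#' @export
fit_livebirth <- function(pregnancy_table, grid = candidate_grid(),
                          k_folds = 5, seed = 2L) {
  feats <- c(intersect(livebirth_feature_names(), names(pregnancy_table)),
             "unintended")
  imp <- fit_imputer(pregnancy_table[feats])
  X <- impute(pregnancy_table[feats], imp)
  model <- select_model(X, pregnancy_table$livebirth,
                        pregnancy_table$weight, grid = grid,
                        k_folds = k_folds, seed = seed)
  model$imputer <- imp
  model
}

#' Evaluate the live-birth model on birth records at both intendedness values
#'
#' @param model_g Fitted live-birth \code{uisae_model}.
#' @param birth_table Birth-record data.frame carrying the g covariates.
#' @return Data.frame with columns \code{g1} (fitted live-birth probability
#'   given unintended) and \code{g0} (given intended).
#' @export
predict_livebirth_probs <- function(model_g, birth_table) {
  feats <- setdiff(model_g$features,
                   grep("_missing$", model_g$features, value = TRUE))
  z <- birth_table[intersect(feats, names(birth_table))]
  z$unintended <- 1
  g1 <- predict(model_g, z)
  z$unintended <- 0
  g0 <- predict(model_g, z)
  data.frame(g1 = g1, g0 = g0)
}

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run in one serialisable list.
#' Every default is documented here; a run's config is written verbatim
#' into the artifact directory and its hash stamped on every artifact.
#'
#' @param seed Master seed for the run.
#' @param k_folds Cross-validation folds (default 5).
#' @param coding_scheme Intendedness coding scheme.
#' @param g_floor Floor for fitted live-birth probabilities before
#'   inverse-probability division (default 0.05).
#' @param years_span Years the birth file covers (default 3); every "per
#'   year" output divides by it.
#' @param age_bins Age bins data.frame.
#' @param grid_labels Labels of [candidate_grid()] entries to use; default
#'   all.
#' @param density Density options: \code{weight_column} ("y_hat" births or
#'   "u_hat" pregnancies), optional \code{cell_size} (default radius/20),
#'   optional fixed \code{radius} (default from [search_radius()]).
#' @param synth Synthetic-data options used when no input paths are given:
#'   \code{area_count}, \code{births_per_area}, \code{sampling_rate},
#'   \code{weight_dispersion}, \code{n_women}.
#' @param inputs Optional named paths (\code{survey}, \code{births},
#'   \code{pregnancies}, \code{population}, \code{polygons}) to load
#'   instead of simulating.
#' @return A list of class \code{uisae_config}.
#' @export
pipeline_config <- function(seed = 1L, k_folds = 5,
                            coding_scheme = "unsure_as_not_unintended",
                            g_floor = 0.05, years_span = 3,
                            age_bins = default_age_bins(),
                            grid_labels = NULL,
                            density = list(weight_column = "y_hat",
                                           cell_size = NULL, radius = NULL),
                            synth = list(area_count = 10L,
                                         births_per_area = 1500,
                                         sampling_rate = 0.1,
                                         weight_dispersion = 0.3,
                                         n_women = 5000L),
                            inputs = NULL) {
  structure(list(seed = as.integer(seed), k_folds = k_folds,
                 coding_scheme = coding_scheme, g_floor = g_floor,
                 years_span = years_span, age_bins = age_bins,
                 grid_labels = grid_labels, density = density,
                 synth = synth, inputs = inputs),
            class = c("uisae_config", "list"))
}

config_grid <- function(config) {
  g <- candidate_grid()
  if (is.null(config$grid_labels)) return(g)
  labs <- vapply(g, `[[`, character(1), "label")
  sel <- g[labs %in% config$grid_labels]
  if (!length(sel)) stop("no candidate grid entries match `grid_labels`",
                         call. = FALSE)
  sel
}

schema_dictionaries <- function() {
  list(
    survey = c("raw_response", "weight", intendedness_feature_names()),
    births = c("birth_id", "lon", "lat", "year",
               intendedness_feature_names(), livebirth_feature_names()),
    pregnancies = c("unintended", "livebirth", "weight",
                    livebirth_feature_names()),
    population = c("area_id", "age_lo", "age_hi", "women")
  )
}

#' Validate input tables against the documented column dictionaries
#'
#' Column-by-column check of the four tables; every violation is collected
#' and reported at once, never just the first. Birth coordinates outside
#' the polygon bounding box are counted as warnings (they will end up
#' unassigned downstream).
#'
#' @param bundle A \code{uisae_bundle} (or any list with the same
#'   elements).
#' @return A list of class \code{uisae_schema_report}: \code{violations}
#'   (character vector, empty when clean) and \code{n_warnings} (count of
#'   out-of-bounds coordinates).
#' @export
validate_schemas <- function(bundle) {
  dict <- schema_dictionaries()
  tables <- list(survey = bundle$survey_table, births = bundle$birth_table,
                 pregnancies = bundle$pregnancy_table,
                 population = bundle$population_table)
  violations <- character(0)
  for (nm in names(dict)) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      violations <- c(violations, sprintf("table `%s` is absent", nm))
      next
    }
    miss <- setdiff(dict[[nm]], names(tab))
    for (cl in miss)
      violations <- c(violations,
                      sprintf("table `%s`: missing required column `%s`",
                              nm, cl))
  }
  n_warn <- 0L
  if (!is.null(bundle$birth_table) && !is.null(bundle$polygons)) {
    bb <- bundle$polygons$bbox
    x <- bundle$birth_table$lon; y <- bundle$birth_table$lat
    out_of_box <- !is.na(x) & !is.na(y) &
      (x < bb[1] | x > bb[3] | y < bb[2] | y > bb[4])
    n_warn <- sum(out_of_box)
  }
  structure(list(violations = violations, n_warnings = n_warn),
            class = "uisae_schema_report")
}

#' @method print uisae_schema_report
#' @export
print.uisae_schema_report <- function(x, ...) {
  if (length(x$violations) == 0) {
    cat("Schema check: all tables conform\n")
  } else {
    cat("Schema check FAILED:\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  if (x$n_warnings > 0)
    cat(sprintf("  warnings: %d birth coordinates outside the polygon box\n",
                x$n_warnings))
  invisible(x)
}

write_csv_artifact <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline CSV artifact
#'
#' Reads the CSV tables the pipeline writes (a \code{#}-prefixed stamp
#' line followed by a standard CSV body).
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_csv_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

load_inputs <- function(config) {
  pi <- config$inputs
  list(
    polygons = read_polygons_geojson(pi$polygons),
    birth_table = read_csv_artifact(pi$births),
    survey_table = read_csv_artifact(pi$survey),
    pregnancy_table = read_csv_artifact(pi$pregnancies),
    population_table = read_csv_artifact(pi$population),
    truth = NULL
  )
}

#' Run the full four-step pipeline
#'
#' Executes, in order: simulate (unless input paths are configured), fit
#' the intendedness model f on the survey, fit the live-birth model g on
#' the pregnancy history, apply f to the birth records, convert births to
#' pregnancies through the floored inverse-probability multipliers, assign
#' births to areas by coordinates, aggregate to the per-area outcomes, and
#' build the kernel-density surface. When \code{outdir} is given, every
#' artifact (tables, GeoJSONs, ASCII grid, CV and importance tables,
#' statewide summary, config, MANIFEST with md5 hashes) is written there,
#' each stamped with the config hash and seed; re-running the same config
#' reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional artifact directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return A list of class \code{uisae_run}: bundle, model_f, model_g,
#'   birth_estimates, area_estimates, statewide, density, schema report,
#'   importance (when the selected f family exposes it), outdir.
#' @export
run_all <- function(config = pipeline_config(), outdir = NULL,
                    quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  grid <- config_grid(config)

  if (is.null(config$inputs)) {
    say("stage simulate: generating synthetic vital records")
    tr <- ground_truth(area_count = config$synth$area_count,
                       births_per_area = config$synth$births_per_area,
                       seed = config$seed)
    bundle <- simulate_vital_records(
      tr, sampling_rate = config$synth$sampling_rate,
      weight_dispersion = config$synth$weight_dispersion,
      n_women = config$synth$n_women, age_bins = config$age_bins)
  } else {
    say("stage load: reading configured input tables")
    bundle <- load_inputs(config)
  }

  schema <- validate_schemas(bundle)
  if (length(schema$violations))
    stop("stage validate failed:\n  ",
         paste(schema$violations, collapse = "\n  "), call. = FALSE)

  say("stage fit-intendedness: selecting f by cross-validated c-statistic")
  model_f <- fit_intendedness(bundle$survey_table, config$coding_scheme,
                              grid = grid, k_folds = config$k_folds,
                              seed = config$seed)
  say("  selected %s (cv c-statistic %.2f)", model_f$family, model_f$cv_cstat)

  say("stage fit-livebirth: selecting g")
  model_g <- fit_livebirth(bundle$pregnancy_table, grid = grid,
                           k_folds = config$k_folds,
                           seed = config$seed + 1L)
  say("  selected %s (cv c-statistic %.2f)", model_g$family, model_g$cv_cstat)

  say("stage estimate: applying models to %d birth records",
      nrow(bundle$birth_table))
  pb <- predict_births(model_f, bundle$birth_table)
  est <- pb$estimates
  gg <- predict_livebirth_probs(model_g, est)
  up <- pregnancy_multipliers(est$y_hat, gg$g1, gg$g0, config$g_floor)
  est$u_hat <- up$u_hat
  est$p_hat <- up$p_hat
  est$area_id <- assign_area(est$lat, est$lon, bundle$polygons)
  n_unassigned <- sum(is.na(est$area_id))
  est <- est[!is.na(est$area_id), , drop = FALSE]

  area_estimates <- aggregate_areas(est, bundle$population_table,
                                    years_span = config$years_span,
                                    age_bins = config$age_bins)
  statewide <- statewide_report(area_estimates,
                                n_excluded = pb$n_excluded + n_unassigned)

  say("stage density: kernel surface of expected unintended events")
  total_area <- sum(bundle$polygons$area_sqmi)
  wcol <- config$density$weight_column
  annual <- sum(est[[wcol]]) / config$years_span
  radius <- if (!is.null(config$density$radius)) config$density$radius
            else search_radius(total_area, annual)
  cell <- if (!is.null(config$density$cell_size)) config$density$cell_size
          else radius / 20
  dens <- kernel_density(
    data.frame(x = est$lon, y = est$lat, weight = est[[wcol]]),
    radius = radius, bbox = bundle$polygons$bbox, cell_size = cell,
    years_span = config$years_span)

  importance <- if (model_f$family %in% c("random_forest",
                                          "gradient_boosting"))
    importance_report(model_f, top_k = 5) else NULL

  run <- structure(list(bundle = bundle, model_f = model_f,
                        model_g = model_g, birth_estimates = est,
                        area_estimates = area_estimates,
                        statewide = statewide, density = dens,
                        schema = schema, importance = importance,
                        n_excluded = pb$n_excluded,
                        n_unassigned = n_unassigned,
                        config = config, outdir = outdir),
                   class = "uisae_run")
  if (!is.null(outdir)) write_run_artifacts(run, outdir, quiet = quiet)
  run
}

#' @method print uisae_run
#' @export
print.uisae_run <- function(x, ...) {
  cat("Unintended births & pregnancies pipeline run\n")
  print(x$statewide)
  if (!is.null(x$model_f))
    cat(sprintf("  model f: %s (cv c-stat %.2f); model g: %s (cv c-stat %.2f)\n",
                x$model_f$family, x$model_f$cv_cstat,
                x$model_g$family, x$model_g$cv_cstat))
  invisible(x)
}

write_run_artifacts <- function(run, outdir, quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.json")
  cfg <- run$config
  cfg$age_bins <- as.list(cfg$age_bins)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  hash <- unname(tools::md5sum(cfg_path))
  stamp <- sprintf("config_hash=%s seed=%d", hash, run$config$seed)

  keep <- c("birth_id", "area_id", "age", "lon", "lat", "year",
            "y_hat", "u_hat", "p_hat")
  write_csv_artifact(run$birth_estimates[intersect(keep,
                                                   names(run$birth_estimates))],
                     file.path(outdir, "birth_estimates.csv"), stamp)
  write_csv_artifact(as.data.frame(run$area_estimates),
                     file.path(outdir, "area_estimates.csv"), stamp)
  write_csv_artifact(as.data.frame(run$statewide),
                     file.path(outdir, "statewide_summary.csv"), stamp)
  write_csv_artifact(run$model_f$cv_table,
                     file.path(outdir, "cv_results_intendedness.csv"), stamp)
  write_csv_artifact(run$model_g$cv_table,
                     file.path(outdir, "cv_results_livebirth.csv"), stamp)
  if (!is.null(run$importance))
    write_csv_artifact(run$importance$table,
                       file.path(outdir, "importance_intendedness.csv"),
                       stamp)
  write_polygons_geojson(run$bundle$polygons,
                         file.path(outdir, "areas.geojson"))
  write_estimates_geojson(run$bundle$polygons, run$area_estimates,
                          file.path(outdir, "area_estimates.geojson"))
  write_ascii_grid(run$density, file.path(outdir, "density.asc"))

  files <- setdiff(list.files(outdir), "MANIFEST")
  md5 <- tools::md5sum(file.path(outdir, files))
  manifest <- c(sprintf("# %s", stamp),
                sprintf("%s  %s", unname(md5), files))
  writeLines(manifest, file.path(outdir, "MANIFEST"))
  if (!quiet) message(sprintf("artifacts written to %s (%d files)",
                              outdir, length(files) + 1))
  invisible(outdir)
}

#' Sensitivity of the statewide estimate to the "unsure" coding
#'
#' Re-runs the intendedness fit and birth-file prediction under each of the
#' three codings of the "wasn't sure what I wanted" response and reports
#' the statewide percentage of births estimated unintended under each. By
#' construction of the coding, the percentage is lowest when unsure counts
#' as not unintended, intermediate when unsure rows are dropped, and
#' highest when unsure counts as unintended.
#'
#' @param bundle A \code{uisae_bundle}.
#' @param grid Candidate grid (a single fast family is typical here).
#' @param k_folds Cross-validation folds.
#' @param seed Integer seed.
#' @return Data.frame with columns \code{coding_scheme},
#'   \code{pct_births_unintended}.
#' @export
coding_sensitivity <- function(bundle,
                               grid = candidate_grid()[1],
                               k_folds = 5, seed = 1L) {
  schemes <- c("unsure_as_not_unintended", "drop_unsure",
               "unsure_as_unintended")
  pct <- vapply(schemes, function(sc) {
    mf <- fit_intendedness(bundle$survey_table, sc, grid = grid,
                           k_folds = k_folds, seed = seed)
    pb <- predict_births(mf, bundle$birth_table)
    100 * mean(pb$estimates$y_hat)
  }, numeric(1))
  data.frame(coding_scheme = schemes, pct_births_unintended = unname(pct))
}
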