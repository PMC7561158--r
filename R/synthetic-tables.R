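# Synthetic vital-records tables: births, survey, pregnancy history, population.
# All draws are governed by the marginals block in synth_marginals() and by the
# truth's logit-scale coefficients; intercepts are calibrated by root-finding
# so marginal shares hit the stated baselines on the realised covariates.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Draw the birth-record covariate block (n rows) from documented marginals.
draw_birth_covariates <- function(n, m) {
  data.frame(
    age = rtrunc_norm(n, m$age$mean, m$age$sd, m$age$min, m$age$max),
    married = stats::rbinom(n, 1, m$married),
    insurance_private = stats::rbinom(n, 1, m$insurance_private),
    race_black = stats::rbinom(n, 1, m$race_black),
    hispanic = stats::rbinom(n, 1, m$hispanic),
    education_years = rtrunc_norm(n, m$education_years$mean,
                                  m$education_years$sd,
                                  m$education_years$min, m$education_years$max),
    foreign_born = stats::rbinom(n, 1, m$foreign_born),
    infertility_treatment = stats::rbinom(n, 1, m$infertility_treatment),
    parity = stats::rpois(n, m$parity$lambda),
    multiple_birth = stats::rbinom(n, 1, m$multiple_birth),
    prenatal_month = sample.int(9L, n, replace = TRUE, prob = m$prenatal_month),
    prenatal_visits = stats::rpois(n, m$prenatal_visits$lambda),
    smoked_before = stats::rbinom(n, 1, m$smoked_before),
    bmi = rtrunc_norm(n, m$bmi$mean, m$bmi$sd, m$bmi$min, m$bmi$max),
    risk_any = stats::rbinom(n, 1, m$risk_any),
    prev_adverse = stats::rbinom(n, 1, m$prev_adverse),
    birthweight_g = rtrunc_norm(n, m$birthweight_g$mean, m$birthweight_g$sd,
                                m$birthweight_g$min, m$birthweight_g$max),
    gest_lt39 = stats::rbinom(n, 1, m$gest_lt39),
    breastfeeding = stats::rbinom(n, 1, m$breastfeeding),
    infant_male = stats::rbinom(n, 1, m$infant_male),
    father_college = stats::rbinom(n, 1, m$father_college)
  )
}

# Linear predictor from named logit-scale coefficients over a covariate table.
# The name "age_c" denotes age centred at the generator's mean age; any other
# name must be a column of `df`.
truth_linear_predictor <- function(coefs, df, age_center) {
  lp <- numeric(nrow(df))
  for (nm in names(coefs)) {
    v <- if (nm == "age_c") df$age - age_center else df[[nm]]
    lp <- lp + coefs[[nm]] * v
  }
  lp
}

#' Generate a synthetic birth-record table
#'
#' Emulates a state birth-certificate file over a 3-year window: covariates
#' drawn from the documented marginals, a latent true intendedness drawn from
#' the truth's logistic model \eqn{f^*} (intercept calibrated so the marginal
#' unintended share matches the baseline, per area when the truth specifies
#' area-level shares), coordinates uniform within the assigned area polygon,
#' and MCAR missingness injected per the truth's rates. Births cluster
#' geographically: per-area expected counts are drawn from a gamma
#' distribution, so some areas are far busier than others.
#'
#' @param truth A [ground_truth()] object.
#' @param polygons A [generate_polygons()] tiling with
#'   \code{truth$area_count} polygons.
#' @param n_births Optional total number of births; defaults to
#'   \code{truth$births_per_area * truth$area_count}.
#' @return A data.frame with one row per birth: \code{birth_id},
#'   \code{area_id_true}, planar-mile coordinates \code{lon} (x) and
#'   \code{lat} (y), \code{year}, the covariate block, and the latent
#'   \code{unintended_true}. The latent column is ground truth for recovery
#'   checks only and is never used by the estimation stages.
#' @export
generate_birth_table <- function(truth, polygons, n_births = NULL) {
  stopifnot(inherits(truth, "uisae_truth"), inherits(polygons, "uisae_polygons"))
  if (length(polygons$ids) != truth$area_count)
    stop("polygon count does not match truth$area_count", call. = FALSE)
  n_total <- if (is.null(n_births)) {
    as.integer(round(truth$births_per_area * truth$area_count))
  } else as.integer(n_births)
  stopifnot(n_total >= 1)
  m <- truth$marginals

  with_seed(truth$seed, {
    shares <- stats::rgamma(truth$area_count, shape = 2, rate = 1)
    shares <- shares / sum(shares)
    counts <- as.vector(stats::rmultinom(1, n_total, shares))

    if (is.null(truth$area_unintended_share)) {
      df <- draw_birth_covariates(n_total, m)
    } else {
      # Geographic heterogeneity works the way it does in real vital
      # records: areas differ in covariate composition. Each area's
      # marginals are tilted along a risk axis t derived from its target
      # share (marriage and private insurance down, maternal age down,
      # parity up in higher-risk areas); a small per-area intercept
      # residual below makes the calibration exact.
      tilt <- stats::qlogis(truth$area_unintended_share) -
        stats::qlogis(truth$baseline_unintended_share)
      blocks <- lapply(seq_len(truth$area_count), function(k) {
        if (counts[k] == 0) return(NULL)
        mk <- m
        tk <- tilt[k]
        mk$married <- stats::plogis(stats::qlogis(m$married) - 2.2 * tk)
        mk$insurance_private <-
          stats::plogis(stats::qlogis(m$insurance_private) - 2.2 * tk)
        mk$age$mean <- m$age$mean - 6 * tk
        mk$parity$lambda <- m$parity$lambda * exp(0.5 * tk)
        draw_birth_covariates(counts[k], mk)
      })
      df <- do.call(rbind, blocks)
    }
    area_id <- rep(polygons$ids, counts)

    # coordinates uniform within each (rectangular) polygon
    lon <- numeric(n_total); lat <- numeric(n_total)
    pos <- 1L
    for (k in seq_along(polygons$ids)) {
      nk <- counts[k]
      if (nk == 0) next
      ring <- polygons$rings[[polygons$ids[k]]]
      idx <- pos:(pos + nk - 1L)
      lon[idx] <- stats::runif(nk, min(ring[, 1]), max(ring[, 1]))
      lat[idx] <- stats::runif(nk, min(ring[, 2]), max(ring[, 2]))
      pos <- pos + nk
    }

    lp <- truth_linear_predictor(truth$intendedness_coefficients, df,
                                 m$age$mean)
    if (is.null(truth$area_unintended_share)) {
      a <- calibrate_intercept(lp, truth$baseline_unintended_share)
      p <- stats::plogis(a + lp)
    } else {
      p <- numeric(n_total)
      for (k in seq_along(polygons$ids)) {
        idx <- which(area_id == polygons$ids[k])
        if (!length(idx)) next
        a_k <- calibrate_intercept(lp[idx], truth$area_unintended_share[k])
        p[idx] <- stats::plogis(a_k + lp[idx])
      }
    }
    unintended_true <- stats::rbinom(n_total, 1, p)

    out <- cbind(
      data.frame(birth_id = sprintf("B%07d", seq_len(n_total)),
                 area_id_true = area_id, lon = lon, lat = lat,
                 year = sample(m$years, n_total, replace = TRUE)),
      df,
      data.frame(unintended_true = unintended_true)
    )

    for (fld in names(truth$missingness_rates)) {
      r <- truth$missingness_rates[[fld]]
      if (r > 0 && fld %in% names(out)) {
        miss <- stats::runif(n_total) < r
        out[[fld]][miss] <- NA
      }
    }
    out
  })
}

#' Generate a synthetic intendedness survey (PRAMS-like)
#'
#' Subsamples the birth table and attaches (a) the five-category intendedness
#' response, generated consistently with the latent binary truth — unintended
#' births answer "later" or "never", others "sooner", "then" or "unsure",
#' with fixed documented splits — and (b) survey weights with mean
#' 1/\code{sampling_rate}, drawn as gamma perturbations around that base
#' weight (the perturbation has mean 1 and standard deviation
#' \code{weight_dispersion}; at dispersion 0 the sample is self-weighting).
#'
#' @param birth_table Output of [generate_birth_table()].
#' @param sampling_rate Inclusion probability in (0, 1].
#' @param weight_dispersion Nonnegative; 0 gives equal weights.
#' @param seed Integer seed.
#' @return A data.frame of sampled births with \code{raw_response} and
#'   \code{weight} columns appended.
#' @export
generate_survey_table <- function(birth_table, sampling_rate,
                                  weight_dispersion = 0.3, seed = 1L) {
  if (is.null(birth_table) || nrow(birth_table) == 0)
    stop("`birth_table` is empty", call. = FALSE)
  stopifnot(sampling_rate > 0, sampling_rate <= 1, weight_dispersion >= 0)
  m <- synth_marginals()

  with_seed(seed, {
    take <- stats::runif(nrow(birth_table)) < sampling_rate
    if (!any(take)) take[sample.int(nrow(birth_table), 1)] <- TRUE
    smp <- birth_table[take, , drop = FALSE]
    n <- nrow(smp)

    su <- m$split_unintended; si <- m$split_intended
    resp <- character(n)
    un <- smp$unintended_true == 1
    resp[un] <- sample(names(su), sum(un), replace = TRUE, prob = su)
    resp[!un] <- sample(names(si), sum(!un), replace = TRUE, prob = si)

    w <- rep(1 / sampling_rate, n)
    if (weight_dispersion > 0) {
      shp <- 1 / weight_dispersion^2
      w <- w * stats::rgamma(n, shape = shp, rate = shp)
    }
    smp$raw_response <- resp
    smp$weight <- w
    rownames(smp) <- NULL
    smp
  })
}

#' Generate a synthetic pregnancy-history table (NSFG-like)
#'
#' Simulates complete pregnancy histories for \code{n_women} women: each
#' woman has a Poisson number of pregnancies (possibly zero); each pregnancy
#' carries the covariates shared with birth records, an intendedness draw,
#' and a live-birth indicator drawn from the truth's logistic model
#' \eqn{g^*} with intercept calibrated so the marginal live-birth share hits
#' \code{truth$baseline_livebirth_share}. Per-woman survey weights are gamma
#' perturbations with mean 1.
#'
#' @param truth A [ground_truth()] object.
#' @param n_women Number of women (>= 1).
#' @param seed Integer seed.
#' @return A data.frame with one row per pregnancy: \code{woman_id},
#'   \code{preg_id}, covariates (\code{age}, \code{married},
#'   \code{race_black}, \code{hispanic}, \code{foreign_born}, \code{parity}),
#'   \code{unintended}, \code{livebirth}, \code{weight}.
#' @export
generate_pregnancy_table <- function(truth, n_women, seed = 2L) {
  stopifnot(inherits(truth, "uisae_truth"), n_women >= 1)
  m <- truth$marginals

  with_seed(seed, {
    npreg <- stats::rpois(n_women, m$pregnancies_per_woman$lambda)
    wt_woman <- stats::rgamma(n_women, shape = 4, rate = 4)
    keep <- npreg > 0
    if (!any(keep)) npreg[1] <- 1L

    woman_id <- rep(seq_len(n_women), npreg)
    n <- length(woman_id)
    df <- data.frame(
      woman_id = sprintf("W%06d", woman_id),
      preg_id = sprintf("P%07d", seq_len(n)),
      age = rtrunc_norm(n, 28, 7, m$age$min, m$age$max),
      married = stats::rbinom(n, 1, m$married),
      race_black = stats::rbinom(n, 1, m$race_black),
      hispanic = stats::rbinom(n, 1, m$hispanic),
      foreign_born = stats::rbinom(n, 1, m$foreign_born),
      parity = stats::rpois(n, m$parity$lambda)
    )

    lp_y <- -0.5 * df$married + 0.08 * df$parity
    a_y <- calibrate_intercept(lp_y, m$unintended_share_pregnancies)
    df$unintended <- stats::rbinom(n, 1, stats::plogis(a_y + lp_y))

    lp_g <- truth_linear_predictor(truth$livebirth_coefficients, df, 28)
    if (truth$baseline_livebirth_share >= 1) {
      df$livebirth <- 1L
    } else {
      a_g <- calibrate_intercept(lp_g, truth$baseline_livebirth_share)
      df$livebirth <- stats::rbinom(n, 1, stats::plogis(a_g + lp_g))
    }
    df$weight <- wt_woman[woman_id]
    df
  })
}

#' Default age bins for women aged 15 to 45
#'
#' Closed integer-age bins partitioning 15-45:
#' 15-17, 18-20, 21-24, 25-29, 30-34, 35-45.
#' @return A data.frame with columns \code{age_lo}, \code{age_hi}.
#' @export
default_age_bins <- function() {
  data.frame(age_lo = c(15L, 18L, 21L, 25L, 30L, 35L),
             age_hi = c(17L, 20L, 24L, 29L, 34L, 45L))
}

validate_age_bins <- function(age_bins) {
  ok <- is.data.frame(age_bins) &&
    all(c("age_lo", "age_hi") %in% names(age_bins)) &&
    nrow(age_bins) >= 1 &&
    age_bins$age_lo[1] == 15L &&
    age_bins$age_hi[nrow(age_bins)] == 45L &&
    all(age_bins$age_lo <= age_bins$age_hi) &&
    (nrow(age_bins) == 1 ||
       all(age_bins$age_lo[-1] == age_bins$age_hi[-nrow(age_bins)] + 1L))
  if (!ok) stop("`age_bins` must partition integer ages 15..45", call. = FALSE)
  invisible(age_bins)
}

#' Generate a synthetic population table (ACS-like)
#'
#' Integer counts of women aged 15-45 per area and age bin. Per-area totals
#' are uniform draws from \code{women_per_area}; bin allocation follows a
#' documented age pmf (truncated normal, mean 29, sd 8, over integer ages),
#' with largest-remainder rounding so bin counts sum exactly to the drawn
#' per-area totals.
#'
#' @param polygons A [generate_polygons()] tiling.
#' @param women_per_area Length-2 range of women per area.
#' @param age_bins Bins data.frame as from [default_age_bins()]; must
#'   partition integer ages 15..45.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{area_id}, \code{age_lo},
#'   \code{age_hi}, \code{women}.
#' @export
generate_population_table <- function(polygons,
                                      women_per_area = c(15000L, 36000L),
                                      age_bins = default_age_bins(),
                                      seed = 3L) {
  stopifnot(inherits(polygons, "uisae_polygons"))
  validate_age_bins(age_bins)

  ages <- 15:45
  pmf <- stats::dnorm(ages, 29, 8)
  pmf <- pmf / sum(pmf)
  bin_of_age <- findInterval(ages, age_bins$age_lo)
  bin_prop <- as.vector(tapply(pmf, bin_of_age, sum))

  with_seed(seed, {
    totals <- round(stats::runif(length(polygons$ids),
                                 women_per_area[1], women_per_area[2]))
    rows <- lapply(seq_along(polygons$ids), function(k) {
      raw <- totals[k] * bin_prop
      fl <- floor(raw)
      rem <- totals[k] - sum(fl)
      if (rem > 0) {
        bump <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
        fl[bump] <- fl[bump] + 1
      }
      data.frame(area_id = polygons$ids[k],
                 age_lo = age_bins$age_lo, age_hi = age_bins$age_hi,
                 women = as.integer(fl))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a full synthetic vital-records bundle
#'
#' Convenience wrapper generating, from one ground truth, everything the
#' four-step pipeline consumes: area polygons, birth-record table,
#' intendedness survey, pregnancy-history table and population table. Seeds
#' for the component generators are derived deterministically from
#' \code{truth$seed}.
#'
#' @param truth A [ground_truth()] object.
#' @param sampling_rate Survey inclusion probability.
#' @param weight_dispersion Survey weight dispersion.
#' @param n_women Women in the pregnancy-history table.
#' @param age_bins Age bins for the population table.
#' @param n_births Optional total births (see [generate_birth_table()]).
#' @return An object of class \code{uisae_bundle}: a list with elements
#'   \code{polygons}, \code{birth_table}, \code{survey_table},
#'   \code{pregnancy_table}, \code{population_table}, \code{truth}.
#' @examples
#' tr <- ground_truth(area_count = 3, births_per_area = 300, seed = 7)
#' b <- simulate_vital_records(tr, n_women = 500)
#' nrow(b$survey_table) <= nrow(b$birth_table)
#' @export
simulate_vital_records <- function(truth, sampling_rate = 0.1,
                                   weight_dispersion = 0.3, n_women = 5000,
                                   age_bins = default_age_bins(),
                                   n_births = NULL) {
  stopifnot(inherits(truth, "uisae_truth"))
  polygons <- generate_polygons(truth$area_count, seed = truth$seed)
  birth_table <- generate_birth_table(truth, polygons, n_births = n_births)
  survey_table <- generate_survey_table(birth_table, sampling_rate,
                                        weight_dispersion,
                                        seed = truth$seed + 1L)
  pregnancy_table <- generate_pregnancy_table(truth, n_women,
                                              seed = truth$seed + 2L)
  population_table <- generate_population_table(
    polygons, truth$women_per_area, age_bins, seed = truth$seed + 3L)
  structure(list(polygons = polygons, birth_table = birth_table,
                 survey_table = survey_table,
                 pregnancy_table = pregnancy_table,
                 population_table = population_table, truth = truth),
            class = "uisae_bundle")
}

#' @method print uisae_bundle
#' @export
print.uisae_bundle <- function(x, ...) {
  cat("Synthetic vital-records bundle\n")
  cat(sprintf("  areas: %d | births: %d | survey: %d | pregnancies: %d\n",
              length(x$polygons$ids), nrow(x$birth_table),
              nrow(x$survey_table), nrow(x$pregnancy_table)))
  cat(sprintf("  true unintended share (births): %.3f\n",
              mean(x$birth_table$unintended_true)))
  invisible(x)
}
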