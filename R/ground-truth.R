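#' Documented covariate marginals used by the synthetic vital-records generator
#'
#' One configuration block holding every marginal distribution constant the
#' generator uses, so that recovery tests can reference the same numbers the
#' generator drew from. Shares are Bernoulli probabilities for binary
#' covariates; continuous covariates list their generating parameters.
#'
#' The marriage share (41\% married, i.e. 59\% unmarried) and the baseline
#' outcome shares (34\% of births from unintended pregnancies, 71\% of
#' pregnancies ending in live birth) mirror the Missouri-scale population the
#' simulator emulates.
#'
#' @return A named list of marginal-distribution constants.
#' @export
synth_marginals <- function() {
  list(
    age            = list(mean = 27, sd = 6, min = 15, max = 45),
    married        = 0.41,
    insurance_private = 0.55,
    race_black     = 0.15,
    hispanic       = 0.05,
    education_years = list(mean = 13.5, sd = 2.5, min = 8, max = 20),
    foreign_born   = 0.06,
    infertility_treatment = 0.02,
    parity         = list(lambda = 1.2),       # previous live births, Poisson
    multiple_birth = 0.03,
    prenatal_month = c(0.28, 0.30, 0.18, 0.10, 0.06, 0.04, 0.02, 0.01, 0.01),
    prenatal_visits = list(lambda = 11),
    smoked_before  = 0.16,
    bmi            = list(mean = 27, sd = 6, min = 15, max = 50),
    risk_any       = 0.12,
    prev_adverse   = 0.08,
    birthweight_g  = list(mean = 3300, sd = 550, min = 300, max = 6000),
    gest_lt39      = 0.35,
    breastfeeding  = 0.85,
    infant_male    = 0.51,
    father_college = 0.30,
    # five-category response splits conditional on the latent binary truth
    split_unintended = c(later = 0.70, never = 0.30),
    split_intended   = c(sooner = 0.30, then = 0.55, unsure = 0.15),
    # pregnancy-history (NSFG-like) generator
    pregnancies_per_woman = list(lambda = 1.7),
    unintended_share_pregnancies = 0.40,
    years = 2014:2016
  )
}

#' Ground truth for the synthetic vital-records simulator
#'
#' Bundles the true models and population parameters that fully determine
#' every generated table given a seed: the logit-scale coefficients of the
#' true intendedness model \eqn{f^*} and live-birth model \eqn{g^*}, the
#' baseline shares both are calibrated to, the geography size, and per-field
#' missingness rates. The generator calibrates each model's intercept by
#' root-finding so that the marginal share matches the stated baseline on the
#' realised covariates.
#'
#' @param intendedness_coefficients Named numeric vector, logit scale, over
#'   birth-record covariates. Defaults put the signal on marriage, private
#'   insurance, (centred) age, parity and prenatal-care month — the dominant
#'   predictors the method is designed to recover — and zero elsewhere.
#' @param livebirth_coefficients Named numeric vector, logit scale, over the
#'   pregnancy-history covariates; must include an `unintended` term (negative
#'   by default: unintended pregnancies are less likely to end in live birth).
#' @param baseline_unintended_share Fraction of births from unintended
#'   pregnancies, in (0,1). Default 0.34.
#' @param baseline_livebirth_share Fraction of pregnancies ending in a live
#'   birth, in (0,1). Default 0.71.
#' @param area_count Number of areas the geography is tiled into.
#' @param women_per_area Length-2 integer range for women aged 15-45 per area.
#' @param births_per_area Mean births per area over the whole window.
#' @param missingness_rates Named vector of per-field MCAR rates in [0,1).
#' @param area_unintended_share Optional numeric vector (length
#'   \code{area_count}): per-area target unintended shares. When supplied,
#'   heterogeneity is generated the way it arises in real vital records —
#'   each area's covariate composition (marriage, insurance, maternal age,
#'   parity) is tilted along a risk axis derived from its target share — and
#'   a small per-area intercept residual makes each area hit its target
#'   exactly. Because the differences are carried by observable covariates,
#'   a classifier fit on pooled data can recover the area ranking.
#' @param seed Integer seed; with it, the truth determines every table.
#'
#' @return An object of class \code{uisae_truth}.
#' @examples
#' tr <- ground_truth(area_count = 4, seed = 1)
#' tr$baseline_unintended_share
#' @export
ground_truth <- function(intendedness_coefficients = c(
                           married = -0.45, insurance_private = -0.36,
                           age_c = -0.035, parity = 0.15, prenatal_month = 0.08),
                         livebirth_coefficients = c(
                           unintended = -0.55, married = 0.30,
                           age_c = 0.01, parity = 0.05),
                         baseline_unintended_share = 0.34,
                         baseline_livebirth_share = 0.71,
                         area_count = 10L,
                         women_per_area = c(15000L, 36000L),
                         births_per_area = 4500,
                         missingness_rates = c(
                           prenatal_month = 0.05, bmi = 0.08,
                           education_years = 0.04, father_college = 0.15,
                           insurance_private = 0.02, smoked_before = 0.03),
                         area_unintended_share = NULL,
                         seed = 20140101L) {
  stopifnot(
    baseline_unintended_share > 0, baseline_unintended_share < 1,
    baseline_livebirth_share > 0, baseline_livebirth_share <= 1,
    area_count >= 1,
    all(missingness_rates >= 0), all(missingness_rates < 1),
    "unintended" %in% names(livebirth_coefficients)
  )
  if (!is.null(area_unintended_share)) {
    stopifnot(length(area_unintended_share) == area_count,
              all(area_unintended_share > 0), all(area_unintended_share < 1))
  }
  structure(list(
    intendedness_coefficients = intendedness_coefficients,
    livebirth_coefficients = livebirth_coefficients,
    baseline_unintended_share = baseline_unintended_share,
    baseline_livebirth_share = baseline_livebirth_share,
    area_count = as.integer(area_count),
    women_per_area = as.integer(women_per_area),
    births_per_area = births_per_area,
    missingness_rates = missingness_rates,
    area_unintended_share = area_unintended_share,
    marginals = synth_marginals(),
    seed = as.integer(seed)
  ), class = "uisae_truth")
}

# Evaluate code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Calibrate an intercept so mean(plogis(a + lp)) == target on realised lp.
calibrate_intercept <- function(lp, target) {
  if (target >= 1) return(Inf)
  f <- function(a) mean(stats::plogis(a + lp)) - target
  stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
}
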