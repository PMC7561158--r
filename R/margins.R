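#' Predictive margins (partial dependence) of a fitted classifier
#'
#' For each requested level of one feature, sets that feature to the level
#' for every row of the table, predicts, and summarises the distribution of
#' the row-level predictions: mean, 25th/50th/75th percentiles, and lower /
#' upper adjacent values (the box fences p25 - 1.5 IQR and p75 + 1.5 IQR,
#' clipped to the observed minimum and maximum of the predictions). All
#' summaries are on the percentage scale. This is the partial-dependence
#' construction behind box-and-whisker margin plots: it shows how predicted
#' unintended-pregnancy rates would shift if everyone had the characteristic,
#' averaging over all remaining covariates.
#'
#' @param model A \code{uisae_model}.
#' @param data Feature table to average over (imputed, or imputable by the
#'   model's frozen imputer).
#' @param feature Name of the feature to vary; must be a column of
#'   \code{data}.
#' @param levels Numeric vector of values to force the feature to.
#' @return A data.frame with one row per level: \code{feature},
#'   \code{level}, \code{mean}, \code{p25}, \code{p50}, \code{p75},
#'   \code{lower_adjacent}, \code{upper_adjacent} (percent).
#' @export
predictive_margins <- function(model, data, feature, levels) {
  stopifnot(inherits(model, "uisae_model"))
  if (!feature %in% names(data))
    stop("unknown feature: ", feature, call. = FALSE)
  ind <- paste0(feature, "_missing")
  out <- lapply(levels, function(v) {
    d <- data
    d[[feature]] <- v
    if (ind %in% names(d)) d[[ind]] <- 0   # the forced value is observed
    p <- 100 * predict(model, d)
    q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(feature = feature, level = v, mean = mean(p),
               p25 = q[1], p50 = q[2], p75 = q[3],
               lower_adjacent = max(min(p), q[1] - 1.5 * iqr),
               upper_adjacent = min(max(p), q[3] + 1.5 * iqr))
  })
  do.call(rbind, out)
}
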