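#' Survey-weighted c-statistic (area under the ROC curve)
#'
#' The weighted probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counting one half; each
#' positive-negative pair contributes the product of the two observation
#' weights. With unit weights this is the classical AUC / c-statistic.
#' Computed by a single pass over score-sorted groups, O(n log n), exactly
#' equal to brute-force enumeration over all pairs.
#'
#' @param scores Numeric vector of predicted probabilities (or any scores).
#' @param labels Binary vector (0/1) of outcomes, same length.
#' @param weights Positive observation weights; default unit.
#' @return The weighted c-statistic, a number in [0, 1].
#' @examples
#' weighted_cstat(c(0.9, 0.8, 0.3), c(1, 0, 1), c(1, 2, 1))  # 0.5
#' @export
weighted_cstat <- function(scores, labels, weights = rep(1, length(scores))) {
  n <- length(scores)
  stopifnot(length(labels) == n, length(weights) == n,
            all(weights > 0), all(labels %in% c(0, 1)))
  if (!any(labels == 1) || !any(labels == 0))
    stop("both outcome classes must be present to compute a c-statistic",
         call. = FALSE)
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]; w <- weights[ord]
  # collapse to unique score groups
  grp <- cumsum(c(TRUE, s[-1] != s[-n]))
  wpos <- as.vector(tapply(w * (y == 1), grp, sum))
  wneg <- as.vector(tapply(w * (y == 0), grp, sum))
  cumneg <- c(0, cumsum(wneg))[seq_along(wneg)]
  num <- sum(wpos * (cumneg + 0.5 * wneg))
  num / (sum(wpos) * sum(wneg))
}
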