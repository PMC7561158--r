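#' Gini (impurity) feature-importance report
#'
#' Normalised impurity-based importance shares for tree-ensemble families
#' (random forest: impurity importance; gradient boosting: gain). Shares are
#' nonnegative and sum to 1, so "the top five features account for 95\%"
#' style statements read directly off the cumulative share.
#'
#' @param model A \code{uisae_model} of a tree family.
#' @param top_k How many leading features the cumulative share covers.
#' @return A list of class \code{uisae_importance}: \code{table} (data.frame
#'   feature, share, ordered decreasing) and \code{top_k_share}.
#' @export
importance_report <- function(model, top_k = 5) {
  stopifnot(inherits(model, "uisae_model"))
  imp <- switch(model$family,
    random_forest = model$fit$variable.importance,
    gradient_boosting = {
      it <- xgboost::xgb.importance(model = model$fit)
      v <- stats::setNames(rep(0, length(model$features)), model$features)
      v[it$Feature] <- it$Gain
      v
    },
    stop("family `", model$family,
         "` does not expose impurity-based importances", call. = FALSE)
  )
  imp <- pmax(imp, 0)
  share <- imp / sum(imp)
  ord <- order(share, decreasing = TRUE)
  tab <- data.frame(feature = names(share)[ord],
                    share = unname(share[ord]))
  top_k <- min(top_k, nrow(tab))
  structure(list(table = tab,
                 top_k = top_k,
                 top_k_share = sum(tab$share[seq_len(top_k)])),
            class = "uisae_importance")
}

#' @method print uisae_importance
#' @export
print.uisae_importance <- function(x, ...) {
  cat("Gini importance (normalised shares)\n")
  top <- utils::head(x$table, 10)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-24s %6.3f\n", top$feature[i], top$share[i]))
  cat(sprintf("Top %d features account for %.1f%% of total importance\n",
              x$top_k, 100 * x$top_k_share))
  invisible(x)
}
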