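# Missing-data handling for the predictive models: missing binaries become 0,
# missing continuous values become the median observed in the FITTING table,
# and every originally-missing field gains a 0/1 indicator column. The
# medians are computed once on the fitting table and frozen, so applying a
# fitted model to a birth-record file reuses the training medians rather than
# recomputing them on the application file.

#' Fit the imputation state on a table
#'
#' Classifies each feature column as binary (observed values all in {0, 1})
#' or continuous, and freezes the median of the observed values of every
#' continuous column. Identifier-like character columns are ignored.
#'
#' @param data Data.frame of features (may contain NA).
#' @param exclude Character vector of column names to leave untouched.
#' @return An object of class \code{uisae_imputer}.
#' @export
fit_imputer <- function(data, exclude = character(0)) {
  cols <- setdiff(names(data), exclude)
  cols <- cols[vapply(data[cols], is.numeric, logical(1))]
  binary <- character(0); continuous <- character(0); medians <- numeric(0)
  for (cl in cols) {
    obs <- data[[cl]][!is.na(data[[cl]])]
    if (length(obs) == 0)
      stop("column `", cl, "` has no observed values; no median exists",
           call. = FALSE)
    if (all(obs %in% c(0, 1))) {
      binary <- c(binary, cl)
    } else {
      continuous <- c(continuous, cl)
      medians[cl] <- stats::median(obs)
    }
  }
  structure(list(binary = binary, continuous = continuous, medians = medians),
            class = "uisae_imputer")
}

#' Apply frozen imputation to a table
#'
#' Fills missing binaries with 0 and missing continuous values with the
#' frozen fitting-table median, appending one \code{<col>_missing} indicator
#' per handled column (1 where the value was originally missing). Complete
#' tables pass through unchanged apart from zero-valued indicators, and the
#' operation is idempotent: re-imputing an imputed table changes nothing.
#'
#' @param data Data.frame to impute.
#' @param imputer A [fit_imputer()] object; by default fitted on \code{data}
#'   itself.
#' @return The imputed data.frame with indicator columns appended.
#' @examples
#' df <- data.frame(a = c(1, NA, 0), b = c(2, 4, NA))
#' impute(df)
#' @export
impute <- function(data, imputer = fit_imputer(data)) {
  stopifnot(inherits(imputer, "uisae_imputer"))
  for (cl in c(imputer$binary, imputer$continuous)) {
    ind <- paste0(cl, "_missing")
    if (!cl %in% names(data)) next
    if (ind %in% names(data)) next   # already imputed: idempotence
    miss <- is.na(data[[cl]])
    data[[ind]] <- as.integer(miss)
    if (any(miss)) {
      fill <- if (cl %in% imputer$binary) 0 else unname(imputer$medians[cl])
      data[[cl]][miss] <- fill
    }
  }
  data
}

#' @method print uisae_imputer
#' @export
print.uisae_imputer <- function(x, ...) {
  cat(sprintf("Imputation state: %d binary (fill 0), %d continuous (frozen medians)\n",
              length(x$binary), length(x$continuous)))
  invisible(x)
}
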