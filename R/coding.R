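#' Code the five-category intendedness response to a binary outcome
#'
#' The survey asks how the woman felt just before becoming pregnant; the five
#' responses are coded here by the short labels \code{"later"} ("wanted to be
#' pregnant later"), \code{"sooner"}, \code{"then"}, \code{"never"} ("didn't
#' want to be pregnant then or at any time in the future") and
#' \code{"unsure"} ("wasn't sure what I wanted").
#'
#' Under the default scheme, \code{"later"} and \code{"never"} code to 1
#' (unintended) and the rest — including \code{"unsure"} — to 0, the
#' convention of the unintended-pregnancy literature. Two sensitivity
#' schemes are supported: \code{unsure_as_unintended} codes the unsure
#' response to 1, and \code{drop_unsure} excludes it (returned as
#' \code{NA}).
#'
#' @param raw_response Character vector of the five category labels.
#' @param coding_scheme One of \code{"unsure_as_not_unintended"} (default),
#'   \code{"unsure_as_unintended"}, \code{"drop_unsure"}.
#' @return Integer vector: 1 = unintended, 0 = not unintended, \code{NA} =
#'   excluded (only under \code{drop_unsure} for \code{"unsure"}).
#' @examples
#' code_intendedness(c("later", "unsure", "then"))
#' code_intendedness("unsure", "drop_unsure")
#' @export
code_intendedness <- function(raw_response,
                              coding_scheme = c("unsure_as_not_unintended",
                                                "unsure_as_unintended",
                                                "drop_unsure")) {
  coding_scheme <- match.arg(coding_scheme)
  categories <- c("later", "sooner", "then", "never", "unsure")
  bad <- setdiff(unique(raw_response), categories)
  if (length(bad))
    stop("unknown intendedness categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  y <- ifelse(raw_response %in% c("later", "never"), 1L, 0L)
  if (coding_scheme == "unsure_as_unintended") {
    y[raw_response == "unsure"] <- 1L
  } else if (coding_scheme == "drop_unsure") {
    y[raw_response == "unsure"] <- NA_integer_
  }
  y
}
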