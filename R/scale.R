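#' Ordered rating scale for expert grading
#'
#' A rating scale pairs ordered grade labels with strictly increasing numeric
#' values. The default is the five-grade importance scale used throughout the
#' package: grades from "very unimportant" to "very important" scored 1 to 5.
#' The numeric values are both the grade codes experts record and the
#' evaluation set against which membership vectors are defuzzified.
#'
#' @param labels Character vector of grade names, ordered from lowest to
#'   highest.
#' @param values Numeric vector of scores, one per label, strictly increasing.
#' @return An object of class `rating_scale` with elements `labels` and
#'   `values`.
#' @examples
#' rating_scale()
#' rating_scale(c("low", "high"), c(0, 1))
#' @export
rating_scale <- function(labels = c("very unimportant", "unimportant",
                                    "average", "important", "very important"),
                         values = seq_along(labels)) {
  if (!is.character(labels) || length(labels) < 2)
    stop_("a rating scale needs at least two character labels")
  if (length(values) != length(labels))
    stop_("scale has %d labels but %d values", length(labels), length(values))
  if (anyNA(values) || any(diff(values) <= 0))
    stop_("scale values must be strictly increasing")
  structure(list(labels = labels, values = as.numeric(values)),
            class = "rating_scale")
}

#' @export
print.rating_scale <- function(x, ...) {
  cat("Rating scale (", length(x$values), " grades):\n", sep = "")
  cat(paste0("  ", format(x$values), "  ", x$labels, collapse = "\n"), "\n")
  invisible(x)
}

n_grades <- function(scale) length(scale$values)
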