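#' Expert rating panel
#'
#' A panel stores one row per expert and one column per leaf indicator, with
#' entries taken from the rating scale's integer grade codes; missing cells
#' (an expert who did not rate an indicator) are `NA`. Optional expert
#' profiles (workplace, education, experience, sex) ride along, aligned to
#' rows.
#'
#' @param ratings Numeric matrix or data frame, experts x leaf indicators,
#'   with column names equal to leaf ids.
#' @param scale The [rating_scale()] the grades refer to.
#' @param profiles Optional data frame of expert metadata with one row per
#'   expert.
#' @return An object of class `expert_panel` with elements `ratings`
#'   (integer matrix), `scale` and `profiles`.
#' @seealso [load_panel()], [membership_matrix()]
#' @export
expert_panel <- function(ratings, scale = rating_scale(), profiles = NULL) {
  ratings <- as.matrix(ratings)
  if (is.null(colnames(ratings)))
    stop_("rating matrix must have leaf indicator ids as column names")
  storage.mode(ratings) <- "double"
  bad <- which(!is.na(ratings) & !(ratings %in% scale$values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("rating %s at row %d, column '%s' is not a valid grade code (%s)",
          format(ratings[bad[1, 1], bad[1, 2]]), bad[1, 1],
          colnames(ratings)[bad[1, 2]],
          paste(scale$values, collapse = ","))
  }
  if (!is.null(profiles)) {
    profiles <- as.data.frame(profiles, stringsAsFactors = FALSE)
    if (nrow(profiles) != nrow(ratings))
      stop_("profiles have %d rows but the panel has %d experts",
            nrow(profiles), nrow(ratings))
  }
  structure(list(ratings = ratings, scale = scale, profiles = profiles),
            class = "expert_panel")
}

#' @export
print.expert_panel <- function(x, ...) {
  cat(sprintf("Expert panel: %d experts x %d indicators (%.1f%% cells rated)\n",
              nrow(x$ratings), ncol(x$ratings),
              100 * mean(!is.na(x$ratings))))
  if (!is.null(x$profiles) && "workplace" %in% names(x$profiles)) {
    tb <- table(x$profiles$workplace)
    cat("Workplace strata:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname expert_panel
#' @param panel An object to test.
#' @export
n_experts <- function(panel) nrow(panel$ratings)

# profile columns recognized in panel CSVs
PROFILE_COLS <- c("person_id", "workplace", "education", "experience", "sex")

#' Read an expert panel from CSV
#'
#' The CSV has a header of leaf indicator ids, one row per expert, cells
#' holding integer grade codes or empty for a missing rating. Columns named
#' `person_id`, `workplace`, `education`, `experience` or `sex` are read as
#' expert profiles. Any other column that is not a leaf of `hierarchy` is
#' rejected; a column naming an internal (non-leaf) node is reported as such.
#'
#' @param path Path to the CSV file.
#' @param hierarchy The [indicator_hierarchy()] the ratings refer to.
#' @return An [expert_panel()] with columns ordered as in the hierarchy.
#' @export
load_panel <- function(path, hierarchy) {
  if (!file.exists(path)) stop_("panel not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  leaves <- hierarchy_leaves(hierarchy)
  prof_cols <- intersect(names(df), PROFILE_COLS)
  rating_cols <- setdiff(names(df), prof_cols)

  unknown <- setdiff(rating_cols, leaves)
  if (length(unknown)) {
    if (unknown[1] %in% hierarchy$nodes$id)
      stop_("column '%s' is an internal node, not a leaf indicator",
            unknown[1])
    stop_("unknown rating column '%s'", unknown[1])
  }
  missing_leaves <- setdiff(leaves, rating_cols)
  if (length(missing_leaves))
    stop_("panel is missing leaf column '%s'", missing_leaves[1])

  ratings <- as.matrix(df[, leaves, drop = FALSE])
  storage.mode(ratings) <- "double"
  profiles <- if (length(prof_cols)) df[, prof_cols, drop = FALSE] else NULL
  panel <- expert_panel(ratings, hierarchy$scale, profiles)
  message(sprintf("loaded %d experts x %d indicators from %s",
                  nrow(ratings), ncol(ratings), path))
  panel
}

#' Write an expert panel to CSV
#'
#' Inverse of [load_panel()]: profile columns first (if present), then one
#' column per leaf, empty cells for missing ratings.
#'
#' @param panel An [expert_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel$ratings)
  if (!is.null(panel$profiles)) out <- cbind(panel$profiles, out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
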