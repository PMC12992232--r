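#' Fuzzy membership matrix from an expert panel
#'
#' For each leaf indicator, the membership degree of a grade is the fraction
#' of responding experts who assigned that grade:
#' `r[leaf, grade] = n(leaf, grade) / n(leaf)`, where `n(leaf)` counts
#' non-missing ratings for that leaf. Columns are the grades in ascending
#' order; every row sums to one.
#'
#' @param panel An [expert_panel()].
#' @param hierarchy An [indicator_hierarchy()]; its leaf order fixes the row
#'   order.
#' @return A numeric matrix of class `membership_matrix` (leaves x grades)
#'   with attributes `counts` (respondents per leaf) and `scale`.
#' @examples
#' h <- indicator_hierarchy(data.frame(
#'   id = c("root", "L1"), label = c("goal", "leaf"),
#'   level = 1:2, parent = c(NA, "root")))
#' p <- expert_panel(matrix(c(3, 4, 4), 3, dimnames = list(NULL, "L1")))
#' membership_matrix(p, h)
#' @export
membership_matrix <- function(panel, hierarchy) {
  leaves <- hierarchy_leaves(hierarchy)
  if (!all(leaves %in% colnames(panel$ratings)))
    stop_("panel is missing leaf '%s'",
          setdiff(leaves, colnames(panel$ratings))[1])
  scale <- hierarchy$scale
  R <- matrix(0, length(leaves), n_grades(scale),
              dimnames = list(leaves, scale$labels))
  counts <- stats::setNames(integer(length(leaves)), leaves)
  for (leaf in leaves) {
    x <- panel$ratings[, leaf]
    x <- x[!is.na(x)]
    if (!length(x))
      stop_("leaf '%s' has zero responses; cannot estimate membership", leaf)
    counts[leaf] <- length(x)
    R[leaf, ] <- vapply(scale$values, function(v) mean(x == v), numeric(1))
  }
  as_membership_matrix(R, scale, counts)
}

#' Construct a membership matrix from given degrees
#'
#' Validates a leaves x grades matrix of membership degrees (nonnegative
#' rows summing to one within 1e-5, to accommodate values transcribed at
#' fixed printed precision). Degrees are stored verbatim; synthesis and
#' aggregation absorb any residual printed-precision roundoff.
#'
#' @param R Numeric matrix, rows named by leaf id.
#' @param scale The [rating_scale()] naming the grade columns.
#' @param counts Optional per-row respondent counts.
#' @return A `membership_matrix`.
#' @export
as_membership_matrix <- function(R, scale = rating_scale(), counts = NULL) {
  R <- as.matrix(R)
  if (ncol(R) != n_grades(scale))
    stop_("membership matrix has %d columns but the scale has %d grades",
          ncol(R), n_grades(scale))
  if (is.null(rownames(R))) stop_("membership rows must be named by leaf id")
  if (anyNA(R) || any(R < 0)) stop_("membership degrees must be nonnegative")
  rs <- rowSums(R)
  if (!near(rs, 1, 1e-5))
    stop_("membership row '%s' sums to %.6f, not 1",
          rownames(R)[which.max(abs(rs - 1))], rs[which.max(abs(rs - 1))])
  colnames(R) <- scale$labels
  structure(R, class = c("membership_matrix", class(matrix())),
            counts = counts, scale = scale)
}

#' @export
print.membership_matrix <- function(x, digits = 6, ...) {
  cat(sprintf("Membership matrix: %d indicators x %d grades\n",
              nrow(x), ncol(x)))
  m <- round(unclass(x), digits)
  attr(m, "counts") <- NULL; attr(m, "scale") <- NULL
  print(m)
  invisible(x)
}

#' Write / read a membership matrix as CSV
#'
#' Rows are leaf indicators (first column `indicator`), remaining columns the
#' grades in ascending order; degrees are written at 6 decimal places.
#'
#' @param R A `membership_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(R, path) {
  df <- data.frame(indicator = rownames(R),
                   round(unclass(R), 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fuzzy synthesis A = W . R
#'
#' Combines leaf membership rows into a group evaluation vector with the
#' weighted-average operator (ordinary matrix product): the group's degree
#' of each grade is the weight-weighted mean of its members' degrees. The
#' max-min composition used by some fuzzy-evaluation variants is available
#' via `operator = "maxmin"` for comparison; the weighted average is the
#' operator the scoring model `P = W . R . V` presumes.
#'
#' @param W A [weight_vector()] keyed by the rows of `R`.
#' @param R A `membership_matrix` (or plain matrix with matching row names).
#' @param operator "average" (default) or "maxmin".
#' @return An `evaluation_vector`: named numeric over the grades, summing to
#'   one.
#' @export
synthesize <- function(W, R, operator = c("average", "maxmin")) {
  operator <- match.arg(operator)
  W <- weight_vector(W)
  R <- as.matrix(R)
  if (!setequal(names(W), rownames(R)))
    stop_("weight keys do not match membership rows")
  Rm <- R[names(W), , drop = FALSE]
  A <- if (operator == "average") {
    as.numeric(as.numeric(W) %*% Rm)
  } else {
    # max-min: A_j = max_i min(w_i, r_ij)
    apply(pmin(matrix(as.numeric(W), nrow(Rm), ncol(Rm)), Rm), 2, max)
  }
  # rows at printed precision can leave a <=1e-5 residual; close it exactly
  evaluation_vector(stats::setNames(A / sum(A), colnames(R)))
}

#' Evaluation vector over the grades
#'
#' @param degrees Named nonnegative numeric vector over the grades, summing
#'   to one within 1e-6.
#' @return An `evaluation_vector`.
#' @export
evaluation_vector <- function(degrees) {
  x <- unlist(degrees)
  if (anyNA(x) || any(x < 0)) stop_("degrees must be nonnegative")
  if (!near(sum(x), 1, 1e-6))
    stop_("evaluation vector sums to %.8f, not 1", sum(x))
  structure(as.numeric(x), names = names(x), class = "evaluation_vector")
}

#' Defuzzify an evaluation vector to a scalar score
#'
#' The expectation of the grade values under the membership degrees:
#' `P = sum_j A_j * V_j`. With the default 1-5 scale this is the familiar
#' weighted mean score.
#'
#' @param A An `evaluation_vector` (or any vector of degrees summing to 1).
#' @param scale The [rating_scale()] supplying the grade values.
#' @return A single numeric score in `[min(values), max(values)]`.
#' @export
defuzzify <- function(A, scale = rating_scale()) {
  A <- evaluation_vector(A)
  if (length(A) != n_grades(scale))
    stop_("evaluation vector length %d does not match the %d-grade scale",
          length(A), n_grades(scale))
  sum(as.numeric(A) * scale$values)
}

#' Performance grade bands on the normalized score axis
#'
#' Scores are normalized to \[0, 1\] and bucketed into ordered bands. The
#' default five bands are poor \[0, 0.2), average \[0.2, 0.4), medium
#' \[0.4, 0.6), good \[0.6, 0.8) and excellent \[0.8, 1\]: each band includes
#' its lower bound and the top band also includes 1.
#'
#' @param labels Band names, lowest first.
#' @param breaks Increasing boundary vector of length `length(labels) + 1`
#'   spanning 0 to 1.
#' @return An object of class `grade_scheme`.
#' @export
grade_scheme <- function(labels = c("poor", "average", "medium", "good",
                                    "excellent"),
                         breaks = seq(0, 1, length.out = length(labels) + 1)) {
  if (length(breaks) != length(labels) + 1)
    stop_("need %d breaks for %d bands", length(labels) + 1, length(labels))
  if (breaks[1] != 0 || breaks[length(breaks)] != 1 || any(diff(breaks) <= 0))
    stop_("breaks must increase from 0 to 1")
  structure(list(labels = labels, breaks = breaks), class = "grade_scheme")
}

#' Assign grade band and bracketing scale labels to a score
#'
#' Reports (a) the performance band of the min-max normalized score under a
#' [grade_scheme()] and (b) the adjacent rating-scale labels bracketing the
#' raw score. A score exactly on a scale value returns that single label.
#'
#' @param score Numeric score within the scale's value range, or a
#'   `composite_score`.
#' @param scheme A [grade_scheme()].
#' @param scale The [rating_scale()].
#' @return List with `band` (band label), `labels` (one or two scale
#'   labels), and `normalized` (score mapped to \[0, 1\]).
#' @examples
#' assign_grade(3.6363)
#' @export
assign_grade <- function(score, scheme = grade_scheme(),
                         scale = rating_scale()) {
  if (inherits(score, "composite_score")) score <- score$score
  v <- scale$values
  if (score < v[1] - 1e-9 || score > v[length(v)] + 1e-9)
    stop_("score %.4f outside the scale range [%g, %g]",
          score, v[1], v[length(v)])
  norm <- (score - v[1]) / (v[length(v)] - v[1])
  norm <- min(max(norm, 0), 1)
  band_idx <- findInterval(norm, scheme$breaks, rightmost.closed = TRUE,
                           left.open = FALSE)
  band_idx <- min(max(band_idx, 1L), length(scheme$labels))

  exact <- which(abs(v - score) < 1e-9)
  labels <- if (length(exact)) {
    scale$labels[exact[1]]
  } else {
    lo <- max(which(v < score))
    c(scale$labels[lo], scale$labels[lo + 1])
  }
  list(band = scheme$labels[band_idx], labels = labels, normalized = norm)
}

#' Composite score for one node
#'
#' Bundles a node's defuzzified score with its evaluation vector, normalized
#' score and grade assignment.
#'
#' @param node_id Node id.
#' @param vector An `evaluation_vector`, or NULL for fixed-score aggregation
#'   where no grade distribution exists.
#' @param scale The [rating_scale()].
#' @param scheme The [grade_scheme()].
#' @param score Score to use when `vector` is NULL; ignored otherwise.
#' @return An object of class `composite_score` with fields `node_id`,
#'   `score`, `vector`, `normalized`, `grade_label` (band) and `bracket`
#'   (adjacent scale labels).
#' @export
composite_score <- function(node_id, vector = NULL, scale = rating_scale(),
                            scheme = grade_scheme(), score = NULL) {
  if (!is.null(vector)) {
    vector <- evaluation_vector(vector)
    score <- defuzzify(vector, scale)
  } else if (is.null(score)) {
    stop_("either an evaluation vector or a score is required")
  }
  g <- assign_grade(score, scheme, scale)
  structure(list(node_id = node_id, score = score, vector = vector,
                 normalized = g$normalized, grade_label = g$band,
                 bracket = g$labels),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  cat(sprintf("%s: score %.4f (normalized %.3f) - band '%s', %s\n",
              x$node_id, x$score, x$normalized, x$grade_label,
              if (length(x$bracket) == 1) sprintf("at '%s'", x$bracket)
              else sprintf("between '%s' and '%s'",
                           x$bracket[1], x$bracket[2])))
  invisible(x)
}

#' Bottom-up fuzzy aggregation of a hierarchy
#'
#' Computes a composite score for every node: a leaf's evaluation vector is
#' its membership row; an internal node's vector is the weighted synthesis
#' (`A = W . R`) of its children's vectors under the group's normalized
#' weights; scores are defuzzified against the hierarchy's scale. Weights
#' default to those stored in the hierarchy; supply `weights` as a named
#' list (parent id -> [weight_vector()] over its children) to override.
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param R A `membership_matrix` covering all leaves.
#' @param weights Optional named list of per-group weight vectors.
#' @param scheme A [grade_scheme()] for band assignment.
#' @return Named list of `composite_score`, one per node; the root entry is
#'   the overall evaluation.
#' @examples
#' fx <- jilin_fixture()
#' # score the government-regulation branch from its printed membership rows
#' sub <- subset_hierarchy(fx$hierarchy, "A1")
#' agg <- aggregate_hierarchy(sub, fx$membership_g)
#' agg$A1$score
#' @export
aggregate_hierarchy <- function(hierarchy, R, weights = NULL,
                                scheme = grade_scheme()) {
  leaves <- hierarchy_leaves(hierarchy)
  missing <- setdiff(leaves, rownames(R))
  if (length(missing))
    stop_("no membership row for leaf '%s'", missing[1])
  scale <- hierarchy$scale

  gw <- function(parent) {
    if (!is.null(weights)) {
      if (is.null(weights[[parent]]))
        stop_("no weight vector supplied for group '%s'", parent)
      weight_vector(weights[[parent]])
    } else {
      group_weights(hierarchy, parent)
    }
  }

  vectors <- list()
  node_vector <- function(id) {
    if (!is.null(vectors[[id]])) return(vectors[[id]])
    vec <- if (id %in% leaves) {
      evaluation_vector(R[id, ] / sum(R[id, ]))
    } else {
      kids <- hierarchy_children(hierarchy, id)
      kid_rows <- do.call(rbind, lapply(kids, function(k)
        as.numeric(node_vector(k))))
      rownames(kid_rows) <- kids
      colnames(kid_rows) <- scale$labels
      synthesize(gw(id), kid_rows)
    }
    vectors[[id]] <<- vec
    vec
  }

  out <- lapply(hierarchy$nodes$id, function(id)
    composite_score(id, node_vector(id), scale, scheme))
  stats::setNames(out, hierarchy$nodes$id)
}

#' Weighted aggregation of fixed sub-scores
#'
#' The fixed-score variant of hierarchy aggregation: given scalar scores for
#' a sibling group (e.g. published dimension synthesis scores) and the
#' group's weights, returns their weight-normalized sum as the parent's
#' composite score. No grade distribution is propagated.
#'
#' @param weights A [weight_vector()] (or named positive vector) over the
#'   group.
#' @param scores Named numeric scores aligned to the same keys.
#' @param node_id Id to attach to the result.
#' @param scale,scheme Scale and banding used for grade assignment.
#' @return A `composite_score` with `vector = NULL`.
#' @examples
#' fx <- jilin_fixture()
#' aggregate_fixed_scores(fx$weights_level2, fx$dimension_scores)$score
#' @export
aggregate_fixed_scores <- function(weights, scores, node_id = "root",
                                   scale = rating_scale(),
                                   scheme = grade_scheme()) {
  W <- weight_vector(weights)
  if (!setequal(names(W), names(scores)))
    stop_("score keys do not match weight keys")
  s <- unlist(scores)[names(W)]
  if (anyNA(s)) stop_("missing score")
  composite_score(node_id, vector = NULL, scale = scale, scheme = scheme,
                  score = sum(as.numeric(W) * s))
}

#' Restrict a hierarchy to one branch
#'
#' Returns the sub-hierarchy rooted at `id` (the node and all its
#' descendants), with `id` relabeled to level 1. Useful for scoring a single
#' criterion block.
#'
#' @param h An [indicator_hierarchy()].
#' @param id Id of the new root.
#' @return An [indicator_hierarchy()].
#' @export
subset_hierarchy <- function(h, id) {
  nd <- h$nodes
  if (!id %in% nd$id) stop_("unknown node id '%s'", id)
  keep <- id
  repeat {
    more <- nd$id[!is.na(nd$parent) & nd$parent %in% keep & !(nd$id %in% keep)]
    if (!length(more)) break
    keep <- c(keep, more)
  }
  sub <- nd[match(keep, nd$id), , drop = FALSE]
  shift <- sub$level[1] - 1L
  sub$level <- sub$level - shift
  sub$parent[sub$id == id] <- NA_character_
  sub$weight[sub$id == id] <- NA_real_
  indicator_hierarchy(sub, h$scale)
}
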