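#' Fit hierarchy weights by entropy, AHP, or their combination
#'
#' Fills in the weights of every sibling group of a hierarchy using the
#' chosen method:
#' \describe{
#'   \item{entropy}{Objective weights from a raw indicator matrix whose
#'     columns are the hierarchy's leaves ([entropy_weights()]). Leaf nodes
#'     receive their global entropy weight; an internal node receives the
#'     sum of its descendant leaves' weights, so group normalization
#'     reproduces the usual two-level table layout.}
#'   \item{ahp}{Subjective weights from the expert panel's mean ratings,
#'     via [likert_to_pairwise()] and [principal_weights()] per sibling
#'     group; a warning is raised for any group whose consistency ratio
#'     reaches 0.1.}
#'   \item{combined}{Per-group convex combination
#'     `alpha * AHP + (1 - alpha) * entropy` ([combine_weights()]).}
#' }
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param method "entropy", "ahp" or "combined".
#' @param panel An [expert_panel()] (required for ahp/combined).
#' @param raw A [raw_indicator_matrix()] with leaf columns (required for
#'   entropy/combined).
#' @param alpha Mixing coefficient for "combined" (1 = pure AHP).
#' @return List with `hierarchy` (weights set), `method`, and `details`
#'   (per-method diagnostics: the `entropy_weight_result` and/or the
#'   per-group `ahp_result`s).
#' @export
fit_weights <- function(hierarchy, method = c("entropy", "ahp", "combined"),
                        panel = NULL, raw = NULL, alpha = 0.5) {
  method <- match.arg(method)
  leaves <- hierarchy_leaves(hierarchy)
  internal <- unique(hierarchy$nodes$parent[!is.na(hierarchy$nodes$parent)])
  details <- list()

  entropy_groups <- NULL
  if (method %in% c("entropy", "combined")) {
    if (is.null(raw)) stop_("entropy weighting needs a raw indicator matrix")
    if (!inherits(raw, "raw_indicator_matrix"))
      raw <- raw_indicator_matrix(raw)
    if (!setequal(colnames(raw$values), leaves))
      stop_("raw matrix columns must be exactly the hierarchy leaves")
    ew <- entropy_weights(raw)
    details$entropy <- ew
    glob <- stats::setNames(as.numeric(ew$weights), names(ew$weights))
    # global weight of an internal node = sum over its descendant leaves
    node_glob <- function(id) {
      if (id %in% leaves) return(glob[[id]])
      sum(vapply(hierarchy_children(hierarchy, id), node_glob, numeric(1)))
    }
    entropy_groups <- lapply(internal, function(p) {
      kids <- hierarchy_children(hierarchy, p)
      weight_vector(stats::setNames(
        vapply(kids, node_glob, numeric(1)), kids))
    })
    names(entropy_groups) <- internal
  }

  ahp_groups <- NULL
  if (method %in% c("ahp", "combined")) {
    if (is.null(panel)) stop_("AHP weighting needs an expert panel")
    res <- ahp_weights_from_panel(panel, hierarchy)
    details$ahp <- res
    bad <- names(res)[!vapply(res, `[[`, logical(1), "consistent")]
    if (length(bad))
      warn_("judgment matrix for group '%s' fails the consistency test (CR >= 0.1)",
            bad[1])
    ahp_groups <- lapply(res, `[[`, "weights")
  }

  groups <- switch(method,
    entropy = entropy_groups,
    ahp = ahp_groups,
    combined = {
      g <- lapply(internal, function(p)
        combine_weights(ahp_groups[[p]], entropy_groups[[p]], alpha))
      stats::setNames(g, internal)
    })

  for (p in internal)
    hierarchy <- set_group_weights(hierarchy, p, groups[[p]])
  list(hierarchy = hierarchy, method = method, details = details)
}

#' Tabulate hierarchy weights as a report data frame
#'
#' One row per non-root node: id, label, level, parent, the group-normalized
#' weight, and the global weight (the product of group weights down the
#' path), mirroring the usual two-column weight-table layout.
#'
#' @param hierarchy An [indicator_hierarchy()] with weights set.
#' @param method Label written into the `method` column.
#' @return A data frame.
#' @export
weight_report <- function(hierarchy, method = "stored") {
  nd <- hierarchy$nodes
  internal <- unique(nd$parent[!is.na(nd$parent)])
  gw <- lapply(internal, function(p) group_weights(hierarchy, p))
  names(gw) <- internal
  global <- function(id) {
    p <- nd$parent[match(id, nd$id)]
    if (is.na(p)) return(1)
    as.numeric(gw[[p]])[match(id, names(gw[[p]]))] * global(p)
  }
  rows <- nd[nd$level > 1L, , drop = FALSE]
  data.frame(node = rows$id, label = rows$label, level = rows$level,
             parent = rows$parent, method = method,
             weight = vapply(rows$id, function(id) {
               p <- nd$parent[match(id, nd$id)]
               as.numeric(gw[[p]])[match(id, names(gw[[p]]))]
             }, numeric(1)),
             global_weight = vapply(rows$id, global, numeric(1)),
             row.names = NULL)
}
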