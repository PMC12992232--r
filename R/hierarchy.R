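#' Build an indicator hierarchy
#'
#' An indicator hierarchy is the factor set of a hierarchical evaluation: a
#' rooted tree of nodes with a single goal node (level 1), criterion nodes
#' (level 2), and leaf indicators (level 3 in the full three-level layout).
#' Nodes may carry weights; weights are interpreted group-wise, i.e. they are
#' normalized over each sibling group when used, so both globally scaled and
#' per-group weights round-trip unchanged.
#'
#' Structural rules enforced by the validator:
#' \itemize{
#'   \item node ids are unique, non-empty strings;
#'   \item exactly one root at level 1 with no parent;
#'   \item every non-root names a parent exactly one level above it;
#'   \item all childless nodes (the leaves) sit at the same, deepest level,
#'     so two-level (goal + indicators) and three-level trees are both valid
#'     but ragged trees are not;
#'   \item weights, where present, are nonnegative and complete within each
#'     sibling group.
#' }
#'
#' @param nodes A data frame with columns `id`, `label`, `level`, `parent`
#'   (NA for the root) and optionally `weight` and `direction`
#'   ("positive"/"negative", used by entropy weighting of raw indicator
#'   matrices; default positive).
#' @param scale A [rating_scale()].
#' @return An object of class `indicator_hierarchy`.
#' @seealso [load_hierarchy()], [group_weights()], [hierarchy_leaves()]
#' @export
indicator_hierarchy <- function(nodes, scale = rating_scale()) {
  req <- c("id", "label", "level", "parent")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes)))
    stop_("`nodes` must be a data frame with columns %s",
          paste(req, collapse = ", "))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  nodes$level <- as.integer(nodes$level)
  if (is.null(nodes$weight)) nodes$weight <- NA_real_
  nodes$weight <- as.numeric(nodes$weight)
  if (is.null(nodes$direction)) nodes$direction <- "positive"
  nodes$direction[is.na(nodes$direction)] <- "positive"

  h <- structure(list(nodes = nodes, scale = scale),
                 class = "indicator_hierarchy")
  validate_hierarchy(h)
  h
}

validate_hierarchy <- function(h) {
  nd <- h$nodes
  if (nrow(nd) < 2)
    stop_("hierarchy needs a root and at least one indicator node")
  if (any(is.na(nd$id) | nd$id == ""))
    stop_("empty node id")
  dup <- nd$id[duplicated(nd$id)]
  if (length(dup))
    stop_("duplicate node id: %s", dup[1])
  if (!all(nd$direction %in% c("positive", "negative")))
    stop_("direction must be 'positive' or 'negative'")

  roots <- nd$id[nd$level == 1L]
  if (length(roots) != 1L)
    stop_("hierarchy must have exactly one level-1 root, found %d",
          length(roots))
  if (!is.na(nd$parent[nd$id == roots]))
    stop_("root node '%s' must not have a parent", roots)

  for (i in seq_len(nrow(nd))) {
    if (nd$id[i] == roots) next
    p <- nd$parent[i]
    if (is.na(p) || p == "")
      stop_("node '%s': non-root node without a parent (orphan)", nd$id[i])
    if (p == nd$id[i])
      stop_("node '%s': parent is the node itself (orphan/cycle)", nd$id[i])
    j <- match(p, nd$id)
    if (is.na(j))
      stop_("node '%s': unknown parent '%s' (orphan)", nd$id[i], p)
    if (nd$level[j] != nd$level[i] - 1L)
      stop_("node '%s' at level %d has parent '%s' at level %d (level gap)",
            nd$id[i], nd$level[i], p, nd$level[j])
  }

  has_child <- nd$id %in% nd$parent
  leaves <- nd$id[!has_child]
  deepest <- max(nd$level)
  bad <- leaves[nd$level[match(leaves, nd$id)] != deepest]
  if (length(bad))
    stop_("node '%s' at level %d has no children but leaves sit at level %d",
          bad[1], nd$level[match(bad[1], nd$id)], deepest)

  # per-group weight completeness and sign
  for (p in unique(nd$parent[!is.na(nd$parent)])) {
    w <- nd$weight[nd$parent == p & !is.na(nd$parent)]
    if (all(is.na(w))) next
    if (anyNA(w))
      stop_("sibling group under '%s' has a partially set weight vector", p)
    if (any(w < 0))
      stop_("negative weight in sibling group under '%s'", p)
    if (sum(w) <= 0)
      stop_("weights under '%s' sum to zero", p)
  }
  invisible(h)
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("Indicator hierarchy: %d nodes (%s)\n", nrow(nd),
              paste(sprintf("%d at level %d", table(nd$level),
                            sort(unique(nd$level))), collapse = ", ")))
  cat(sprintf("Leaves: %s\n", paste(hierarchy_leaves(x), collapse = ", ")))
  invisible(x)
}

#' Hierarchy accessors
#'
#' `hierarchy_leaves()` returns leaf indicator ids in file order;
#' `hierarchy_root()` the root id; `hierarchy_children()` the child ids of a
#' node; `node_label()` a node's label.
#'
#' @param h An [indicator_hierarchy()].
#' @param id A node id.
#' @return Character vector of ids (or a single label).
#' @export
hierarchy_leaves <- function(h) {
  nd <- h$nodes
  nd$id[!(nd$id %in% nd$parent)]
}

#' @rdname hierarchy_leaves
#' @export
hierarchy_root <- function(h) h$nodes$id[h$nodes$level == 1L]

#' @rdname hierarchy_leaves
#' @export
hierarchy_children <- function(h, id) {
  nd <- h$nodes
  nd$id[!is.na(nd$parent) & nd$parent == id]
}

#' @rdname hierarchy_leaves
#' @export
node_label <- function(h, id) {
  j <- match(id, h$nodes$id)
  if (anyNA(j)) stop_("unknown node id '%s'", id[which(is.na(j))[1]])
  h$nodes$label[j]
}

#' Normalized weights of a sibling group
#'
#' Extracts the stored weights of the children of `parent_id` and normalizes
#' them to sum to one. Stored weights may be on any positive scale (e.g.
#' global weights whose block sums equal the parent weight); only their
#' ratios matter within a group.
#'
#' @param h An [indicator_hierarchy()] with weights set for the group.
#' @param parent_id Id of the parent node.
#' @return A [weight_vector()] named by child id.
#' @export
group_weights <- function(h, parent_id) {
  kids <- hierarchy_children(h, parent_id)
  if (!length(kids)) stop_("node '%s' has no children", parent_id)
  w <- h$nodes$weight[match(kids, h$nodes$id)]
  if (anyNA(w))
    stop_("missing weight for child of '%s'", parent_id)
  weight_vector(stats::setNames(w, kids))
}

#' Replace the weights of one sibling group
#'
#' @param h An [indicator_hierarchy()].
#' @param parent_id Id of the parent whose children are reweighted.
#' @param w A [weight_vector()] (or named numeric) keyed by the child ids.
#' @return The updated hierarchy.
#' @export
set_group_weights <- function(h, parent_id, w) {
  kids <- hierarchy_children(h, parent_id)
  if (!setequal(names(w), kids))
    stop_("weight keys do not match the children of '%s'", parent_id)
  h$nodes$weight[match(names(w), h$nodes$id)] <- as.numeric(w)
  validate_hierarchy(h)
  h
}

#' Read an indicator hierarchy from a YAML or JSON config
#'
#' The config holds a `nodes` list (fields `id`, `label`, `level`, `parent`,
#' optional `weight` and `direction`) and an optional `scale` block with
#' `labels` and `values`. The format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the config file.
#' @return A validated [indicator_hierarchy()].
#' @examples
#' cfg <- system.file("extdata", "jilin_hierarchy.yaml", package = "ahpfce")
#' h <- load_hierarchy(cfg)
#' hierarchy_leaves(h)
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop_("hierarchy config not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$nodes))
    stop_("config %s has no `nodes` block", path)
  nodes <- do.call(rbind, lapply(cfg$nodes, function(n) {
    if (is.null(n$id) || is.null(n$level))
      stop_("config node without id/level in %s", path)
    data.frame(id = as.character(n$id),
               label = as.character(n$label %||% n$id),
               level = as.integer(n$level),
               parent = as.character(n$parent %||% NA_character_),
               weight = as.numeric(n$weight %||% NA_real_),
               direction = as.character(n$direction %||% "positive"),
               stringsAsFactors = FALSE)
  }))
  scale <- if (!is.null(cfg$scale)) {
    rating_scale(unlist(cfg$scale$labels), unlist(cfg$scale$values))
  } else {
    rating_scale()
  }
  indicator_hierarchy(nodes, scale)
}

#' Write an indicator hierarchy config
#'
#' Inverse of [load_hierarchy()]; a written file loads back to an identical
#' hierarchy.
#'
#' @param h An [indicator_hierarchy()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  nd <- h$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    n <- list(id = nd$id[i], label = nd$label[i], level = nd$level[i])
    if (!is.na(nd$parent[i])) n$parent <- nd$parent[i]
    if (!is.na(nd$weight[i])) n$weight <- nd$weight[i]
    if (nd$direction[i] != "positive") n$direction <- nd$direction[i]
    n
  })
  cfg <- list(scale = list(labels = h$scale$labels, values = h$scale$values),
              nodes = nodes)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}
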