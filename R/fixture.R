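#' Bundled case study: provincial food-safety collaborative governance
#'
#' Returns the published Jilin Province food-safety collaborative-governance
#' assessment as a ready-made bundle: the 1/4/18-node indicator hierarchy
#' with entropy-derived weights at printed precision, the published
#' membership rows for the government-regulation (G) block, the four
#' dimension synthesis scores, and the characteristics of the 33-expert
#' consultation panel. All values are transcribed verbatim from the study's
#' published tables; nothing is re-derived.
#'
#' @return A list of class `jilin_fixture` with elements:
#' \describe{
#'   \item{hierarchy}{[indicator_hierarchy()] with all weights set.}
#'   \item{weights_level2}{[weight_vector()] over A1..A4.}
#'   \item{weights_level3}{Named numeric of the 18 leaf weights on their
#'     published global scale (each block sums to its dimension weight).}
#'   \item{membership_g}{`membership_matrix` of the five G-block rows.}
#'   \item{dimension_scores}{Named numeric, dimension synthesis scores
#'     (A1 = 4, A2 = 3, A3 = 3.5, A4 = 3.5).}
#'   \item{dimension_notes}{Named character, published grade descriptions.}
#'   \item{experts}{Data frame of the 33 expert profiles (workplace strata
#'     GRA/FPE/TTI/CO, education, experience years, sex).}
#' }
#' @examples
#' fx <- jilin_fixture()
#' aggregate_fixed_scores(fx$weights_level2, fx$dimension_scores)$score
#' @export
jilin_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "ahpfce",
                                 mustWork = TRUE)
  h <- load_hierarchy(ext("jilin_hierarchy.yaml"))

  w2 <- group_weights(h, hierarchy_root(h))
  leaves <- hierarchy_leaves(h)
  w3 <- stats::setNames(h$nodes$weight[match(leaves, h$nodes$id)], leaves)

  mg <- utils::read.csv(ext("jilin_membership_g.csv"), check.names = FALSE)
  R <- as.matrix(mg[, -1])
  rownames(R) <- mg$indicator
  counts <- stats::setNames(rep(17L, nrow(R)), rownames(R))
  R <- as_membership_matrix(R, h$scale, counts)

  ds <- utils::read.csv(ext("jilin_dimension_scores.csv"),
                        stringsAsFactors = FALSE)
  experts <- utils::read.csv(ext("jilin_experts.csv"),
                             stringsAsFactors = FALSE)

  structure(list(hierarchy = h,
                 weights_level2 = w2,
                 weights_level3 = w3,
                 membership_g = R,
                 dimension_scores = stats::setNames(ds$score, ds$node),
                 dimension_notes = stats::setNames(ds$description, ds$node),
                 experts = experts),
            class = "jilin_fixture")
}

#' @export
print.jilin_fixture <- function(x, ...) {
  cat("Provincial food-safety governance case study\n")
  cat(sprintf("  hierarchy: %d nodes, %d leaves; %d-expert panel\n",
              nrow(x$hierarchy$nodes), length(hierarchy_leaves(x$hierarchy)),
              nrow(x$experts)))
  cs <- aggregate_fixed_scores(x$weights_level2, x$dimension_scores)
  cat(sprintf("  composite (dimension-score mode): %.4f / %g\n",
              cs$score, max(x$hierarchy$scale$values)))
  invisible(x)
}
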