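#' Specification of a synthetic expert panel
#'
#' Describes how to simulate an expert Likert survey: each expert's rating
#' of a leaf is drawn independently from that leaf's consensus distribution
#' over the grades, and each cell is observed with the leaf's response rate
#' (otherwise missing). The consensus vectors are exactly the statistical
#' object the membership-matrix stage estimates, which makes parameter
#' recovery directly testable.
#'
#' @param n_experts Number of experts (rows).
#' @param leaves Character vector of leaf indicator ids.
#' @param consensus Either a single probability vector over the grades
#'   (recycled for every leaf) or a leaves x grades matrix of per-leaf grade
#'   distributions; each row must sum to one.
#' @param response_rate Probability that a given expert rates a given leaf,
#'   in (0, 1\]; scalar or one value per leaf.
#' @param strata Named workplace-category mix for the generated profiles
#'   (proportions or counts); default mirrors the bundled case study's
#'   15/8/6/4 split across regulatory agencies (GRA), producers (FPE),
#'   testing institutions (TTI) and consumer organizations (CO).
#' @param scale The [rating_scale()] ratings are drawn on.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @seealso [generate_panel()], [jilin_panel_spec()]
#' @export
panel_spec <- function(n_experts, leaves, consensus,
                       response_rate = 1,
                       strata = c(GRA = 15, FPE = 8, TTI = 6, CO = 4),
                       scale = rating_scale(), seed = 0) {
  if (!is_count(n_experts) || n_experts < 1)
    stop_("n_experts must be a positive integer")
  leaves <- as.character(leaves)
  if (!length(leaves) || anyDuplicated(leaves))
    stop_("leaves must be a non-empty set of unique ids")
  g <- n_grades(scale)
  if (is.matrix(consensus)) {
    if (nrow(consensus) != length(leaves) || ncol(consensus) != g)
      stop_("consensus matrix must be %d leaves x %d grades",
            length(leaves), g)
  } else {
    if (length(consensus) != g)
      stop_("consensus vector must have %d entries", g)
    consensus <- matrix(consensus, length(leaves), g, byrow = TRUE)
  }
  rownames(consensus) <- leaves
  if (anyNA(consensus) || any(consensus < 0) ||
      !near(rowSums(consensus), 1, 1e-6))
    stop_("every consensus vector must be nonnegative and sum to 1")
  response_rate <- rep(response_rate, length.out = length(leaves))
  if (any(response_rate <= 0) || any(response_rate > 1))
    stop_("response_rate must lie in (0, 1]")
  if (is.null(names(strata)) || any(strata < 0) || sum(strata) <= 0)
    stop_("strata must be a named nonnegative mix")
  structure(list(n_experts = as.integer(n_experts), leaves = leaves,
                 consensus = consensus, response_rate = response_rate,
                 strata = strata / sum(strata), scale = scale,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Default panel specification mirroring the bundled case study
#'
#' 33 experts rating the 18 leaf indicators of the bundled hierarchy, with
#' the 15/8/6/4 workplace strata of the published consultation panel. The
#' five G-block leaves use the published membership rows as consensus
#' distributions with a response rate of 17/33 (the published rows are
#' consistent with 17 respondents per G indicator); the remaining blocks use
#' smooth consensus profiles centred on their published dimension scores
#' (mean 3 for the E block, mean 3.5 for T and C) with full response.
#'
#' @param seed Integer seed.
#' @return A [panel_spec()].
#' @export
jilin_panel_spec <- function(seed = 0) {
  fx <- jilin_fixture()
  leaves <- hierarchy_leaves(fx$hierarchy)
  g <- n_grades(fx$hierarchy$scale)
  cons <- matrix(0, length(leaves), g, dimnames = list(leaves, NULL))
  g_rows <- unclass(fx$membership_g)
  cons[rownames(fx$membership_g), ] <- g_rows / rowSums(g_rows)
  e_row <- c(0.05, 0.20, 0.50, 0.20, 0.05)   # mean 3.0
  tc_row <- c(0.02, 0.08, 0.40, 0.38, 0.12)  # mean 3.5
  for (leaf in leaves) {
    block <- substr(leaf, 1, 1)
    if (block == "E") cons[leaf, ] <- e_row
    if (block %in% c("T", "C")) cons[leaf, ] <- tc_row
  }
  rr <- ifelse(substr(leaves, 1, 1) == "G", 17 / 33, 1)
  panel_spec(33, leaves, cons, response_rate = rr,
             scale = fx$hierarchy$scale, seed = seed)
}

#' Generate a synthetic expert panel
#'
#' Draws every rating from the leaf's consensus distribution, thins cells to
#' the leaf's response rate, and attaches synthetic expert profiles drawn
#' from the workplace strata. If thinning leaves an indicator with no
#' respondent, that leaf's responses are redrawn (bounded retries). The
#' output is deterministic given `spec$seed`.
#'
#' @param spec A [panel_spec()].
#' @param max_retries Redraw budget per leaf whose column ends up empty.
#' @return An [expert_panel()].
#' @examples
#' spec <- panel_spec(10, c("L1", "L2"), c(0, 0, 0.3, 0.5, 0.2), seed = 1)
#' generate_panel(spec)
#' @export
generate_panel <- function(spec, max_retries = 100) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_experts
  vals <- spec$scale$values
  withr::with_seed(spec$seed, {
    ratings <- matrix(NA_real_, n, length(spec$leaves),
                      dimnames = list(paste0("P", seq_len(n)), spec$leaves))
    for (j in seq_along(spec$leaves)) {
      for (try in seq_len(max_retries)) {
        x <- sample(vals, n, replace = TRUE, prob = spec$consensus[j, ])
        x[stats::runif(n) > spec$response_rate[j]] <- NA_real_
        if (any(!is.na(x))) break
        if (try == max_retries)
          stop_("leaf '%s': no respondents after %d redraws",
                spec$leaves[j], max_retries)
      }
      ratings[, j] <- x
    }
    # profiles: workplace by strata (largest-remainder counts), the rest drawn
    counts <- floor(spec$strata * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- spec$strata * n - counts
      top <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    workplace <- sample(rep(names(spec$strata), counts))
    profiles <- data.frame(
      person_id = rownames(ratings),
      workplace = workplace,
      education = sample(c("BA", "MA", "MS", "MMS", "PhD"), n, replace = TRUE,
                         prob = c(5, 9, 8, 5, 6)),
      experience = sample(5:19, n, replace = TRUE),
      sex = sample(c("F", "M"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    expert_panel(ratings, spec$scale, profiles)
  })
}

#' Specification of a synthetic raw indicator matrix
#'
#' Describes simulated observed indicator values for entropy weighting: each
#' indicator's column is drawn log-normally with `sdlog` equal to its
#' dispersion parameter, so dispersion directly controls how unequal the
#' column is across items — the property entropy weighting responds to. A
#' dispersion of 0 yields a constant column (the degenerate case handled by
#' the constant-column policy).
#'
#' @param n_items Number of items (rows), at least 2.
#' @param indicators Character vector of indicator ids.
#' @param dispersion Nonnegative spread parameter, scalar or one per
#'   indicator.
#' @param directions "positive"/"negative" per indicator.
#' @param seed Integer seed.
#' @return An object of class `raw_matrix_spec`.
#' @export
raw_matrix_spec <- function(n_items, indicators, dispersion = 1,
                            directions = "positive", seed = 0) {
  if (!is_count(n_items) || n_items < 2)
    stop_("n_items must be an integer >= 2")
  indicators <- as.character(indicators)
  if (!length(indicators) || anyDuplicated(indicators))
    stop_("indicators must be a non-empty set of unique ids")
  dispersion <- rep(dispersion, length.out = length(indicators))
  if (anyNA(dispersion) || any(dispersion < 0))
    stop_("dispersion must be nonnegative")
  structure(list(n_items = as.integer(n_items), indicators = indicators,
                 dispersion = dispersion,
                 directions = rep(directions, length.out = length(indicators)),
                 seed = as.integer(seed)),
            class = "raw_matrix_spec")
}

#' Generate a synthetic raw indicator matrix
#'
#' @param spec A [raw_matrix_spec()].
#' @return A [raw_indicator_matrix()], deterministic given `spec$seed`.
#' @examples
#' X <- generate_raw_matrix(raw_matrix_spec(20, c("a", "b"),
#'                                          dispersion = c(2, 0.2), seed = 1))
#' entropy_weights(X)$weights
#' @export
generate_raw_matrix <- function(spec) {
  stopifnot(inherits(spec, "raw_matrix_spec"))
  withr::with_seed(spec$seed, {
    V <- vapply(seq_along(spec$indicators), function(j)
      exp(stats::rnorm(spec$n_items, 0, spec$dispersion[j])),
      numeric(spec$n_items))
    colnames(V) <- spec$indicators
    raw_indicator_matrix(V, spec$directions)
  })
}
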