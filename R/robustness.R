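#' Weight-perturbation sensitivity of a composite score
#'
#' Multiplies the target's weight by `(1 + delta)`, renormalizes the whole
#' weight vector to sum to one, and recomputes the composite score as the
#' weighted sum of the fixed per-node scores. The renormalization is part of
#' the perturbation semantics: weights are shares, so inflating one share
#' deflates the others.
#'
#' @param weights A [weight_vector()] (or named positive vector).
#' @param scores Named numeric scores over the same keys.
#' @param target Key of the weight to perturb.
#' @param delta Signed relative perturbation (e.g. 0.10 for +10%); must
#'   exceed -1.
#' @return An object of class `sensitivity_result`: list with `target_node`,
#'   `delta`, `baseline_score`, `perturbed_score` and `change`
#'   (perturbed - baseline).
#' @examples
#' fx <- jilin_fixture()
#' sensitivity_perturb(fx$weights_level2, fx$dimension_scores, "A1", 0.10)
#' @export
sensitivity_perturb <- function(weights, scores, target, delta) {
  W <- weight_vector(weights)
  if (!target %in% names(W)) stop_("unknown target node '%s'", target)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      1 + delta <= 0)
    stop_("delta must be a single number greater than -1")
  s <- unlist(scores)
  if (!setequal(names(W), names(s)))
    stop_("score keys do not match weight keys")
  s <- s[names(W)]

  baseline <- sum(as.numeric(W) * s)
  w <- as.numeric(W)
  names(w) <- names(W)
  w[target] <- w[target] * (1 + delta)
  w <- w / sum(w)
  perturbed <- sum(w * s)
  structure(list(target_node = target, delta = delta,
                 baseline_score = baseline, perturbed_score = perturbed,
                 change = perturbed - baseline),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("%s %+.0f%%: %.4f -> %.4f (change %+.4f)\n",
              x$target_node, 100 * x$delta, x$baseline_score,
              x$perturbed_score, x$change))
  invisible(x)
}

#' Sensitivity sweep over targets and both perturbation signs
#'
#' Runs [sensitivity_perturb()] for `+delta` and `-delta` on each target and
#' reports every case plus the maximum absolute score change.
#'
#' @inheritParams sensitivity_perturb
#' @param targets Character vector of weight keys to perturb.
#' @return List with `cases` (list of `sensitivity_result`) and
#'   `max_abs_change`.
#' @examples
#' fx <- jilin_fixture()
#' sw <- sensitivity_sweep(fx$weights_level2, fx$dimension_scores,
#'                         c("A1", "A4"), 0.10)
#' sw$max_abs_change
#' @export
sensitivity_sweep <- function(weights, scores, targets, delta) {
  grid <- expand.grid(target = targets, d = c(delta, -delta),
                      stringsAsFactors = FALSE)
  cases <- lapply(seq_len(nrow(grid)), function(i)
    sensitivity_perturb(weights, scores, grid$target[i], grid$d[i]))
  list(cases = cases,
       max_abs_change = if (length(cases))
         max(vapply(cases, function(x) abs(x$change), numeric(1))) else 0)
}

#' Expert-resampling stability of the composite score
#'
#' Draws `n_groups` subpanels of experts without replacement (a fraction
#' `resample_fraction` of the panel per group), rebuilds the membership
#' matrix and the hierarchical composite score for each subpanel, and
#' reports the per-group scores together with the deviation rate
#' `max |group score - full score| / full score`. A draw that leaves some
#' leaf with zero responses is redrawn (up to `max_retries` per group). The
#' whole procedure is deterministic given `seed`.
#'
#' @param panel An [expert_panel()].
#' @param hierarchy An [indicator_hierarchy()] with weights (or supply
#'   `weights`).
#' @param weights Optional per-group weight list, as in
#'   [aggregate_hierarchy()].
#' @param n_groups Number of resampled groups (default 10).
#' @param resample_fraction Fraction of experts per group, in (0, 1\];
#'   default 0.8.
#' @param seed Integer seed driving all draws.
#' @param max_retries Redraw budget per group when a leaf loses all its
#'   respondents.
#' @return An object of class `stability_result`: list with `n_groups`,
#'   `resample_fraction`, `seed`, `full_score`, `group_scores` and
#'   `deviation_rate`.
#' @export
bootstrap_stability <- function(panel, hierarchy, weights = NULL,
                                n_groups = 10, resample_fraction = 0.8,
                                seed = 0, max_retries = 100) {
  if (!is_count(n_groups) || n_groups < 1)
    stop_("n_groups must be a positive integer")
  if (!is.numeric(resample_fraction) || resample_fraction <= 0 ||
      resample_fraction > 1)
    stop_("resample_fraction must lie in (0, 1]")
  n <- n_experts(panel)
  m <- max(1L, floor(resample_fraction * n))

  root <- hierarchy_root(hierarchy)
  full_score <- aggregate_hierarchy(
    hierarchy, membership_matrix(panel, hierarchy), weights)[[root]]$score

  group_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_groups), function(g) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(n, m)
        sub <- expert_panel(panel$ratings[idx, , drop = FALSE],
                            panel$scale,
                            if (!is.null(panel$profiles))
                              panel$profiles[idx, , drop = FALSE])
        R <- tryCatch(membership_matrix(sub, hierarchy),
                      error = function(e) NULL)
        if (!is.null(R))
          return(aggregate_hierarchy(hierarchy, R, weights)[[root]]$score)
      }
      stop_("group %d: could not draw a subpanel covering every leaf in %d tries",
            g, max_retries)
    }, numeric(1))
  })

  structure(list(n_groups = n_groups, resample_fraction = resample_fraction,
                 seed = seed, full_score = full_score,
                 group_scores = group_scores,
                 deviation_rate = max(abs(group_scores - full_score)) /
                   full_score),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Resampling stability: %d groups at fraction %.2f (seed %d)\n",
              x$n_groups, x$resample_fraction, x$seed))
  cat(sprintf("  full-panel score %.4f; group scores %.4f..%.4f\n",
              x$full_score, min(x$group_scores), max(x$group_scores)))
  cat(sprintf("  deviation rate %.4f (%.2f%%)\n",
              x$deviation_rate, 100 * x$deviation_rate))
  invisible(x)
}

#' Cronbach's alpha internal-consistency reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row totals))`,
#' with sample (n-1) variances, over the complete rows of a respondents x
#' items rating matrix (rows with any missing cell are dropped).
#'
#' @param items Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least 2 items and 2 complete respondents.
#' @return An object of class `reliability_result`: list with `alpha`,
#'   `k_items`, `n_respondents`.
#' @examples
#' cronbach_alpha(cbind(q1 = c(1, 2, 3, 4), q2 = c(2, 3, 4, 5)))
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  n <- nrow(items)
  if (k < 2) stop_("Cronbach's alpha needs at least 2 items")
  if (n < 2) stop_("Cronbach's alpha needs at least 2 complete respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var <= 0)
    stop_("alpha undefined: total-score variance is zero")
  alpha <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  structure(list(alpha = alpha, k_items = k, n_respondents = n),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d respondents)\n",
              x$alpha, x$k_items, x$n_respondents))
  invisible(x)
}
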