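#' Normalized weight vector over a sibling group
#'
#' Weights are nonnegative, named by node id, and normalized so they sum to
#' one; the constructor normalizes its input, so any positively scaled named
#' vector is accepted.
#'
#' @param x Named nonnegative numeric vector with at least one positive
#'   entry.
#' @return A `weight_vector` (named numeric summing to 1).
#' @export
weight_vector <- function(x) {
  if (inherits(x, "weight_vector")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop_("weights must be named by node id")
  if (anyNA(x) || any(x < 0)) stop_("weights must be nonnegative")
  s <- sum(x)
  if (s <= 0) stop_("weights sum to zero")
  structure(as.numeric(x) / s, names = names(x), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("Weights:\n")
  print(round(stats::setNames(as.numeric(x), names(x)), 6))
  invisible(x)
}

#' Combine two weight vectors
#'
#' Convex combination `alpha * w_a + (1 - alpha) * w_b`, renormalized. Used
#' to blend a subjective (AHP) and an objective (entropy) weighting of the
#' same sibling group.
#'
#' @param w_a,w_b [weight_vector()]s over the same key set.
#' @param alpha Mixing coefficient in \[0, 1\]; 1 returns `w_a`, 0 returns
#'   `w_b`.
#' @return A [weight_vector()].
#' @export
combine_weights <- function(w_a, w_b, alpha) {
  w_a <- weight_vector(w_a); w_b <- weight_vector(w_b)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop_("alpha must be a single number in [0, 1]")
  if (!setequal(names(w_a), names(w_b)))
    stop_("weight vectors have different key sets")
  wb <- as.numeric(w_b)[match(names(w_a), names(w_b))]
  weight_vector(stats::setNames(alpha * as.numeric(w_a) + (1 - alpha) * wb,
                                names(w_a)))
}

#' Raw indicator matrix for entropy weighting
#'
#' Holds observed indicator values, items (e.g. regions, years, schemes) in
#' rows and indicators in columns, with a per-indicator direction: for a
#' "negative" indicator smaller raw values are better and min-max
#' normalization is mirrored.
#'
#' @param values Numeric matrix (>= 2 rows, no missing entries) with
#'   indicator ids as column names.
#' @param directions "positive" or "negative", recycled over columns.
#' @return An object of class `raw_indicator_matrix`.
#' @export
raw_indicator_matrix <- function(values, directions = "positive") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (nrow(values) < 2) stop_("need at least 2 items (rows)")
  if (anyNA(values)) stop_("raw indicator matrix must not contain missing values")
  directions <- rep(directions, length.out = ncol(values))
  if (!all(directions %in% c("positive", "negative")))
    stop_("directions must be 'positive' or 'negative'")
  structure(list(values = values, directions = directions),
            class = "raw_indicator_matrix")
}

#' Min-max normalization of a raw indicator matrix
#'
#' Rescales each column to \[0, 1\]: `(x - min) / (max - min)` for positive
#' indicators and `(max - x) / (max - min)` for negative ones. A constant
#' column carries no ordering information; it is mapped to all 0.5 with a
#' warning, and [entropy_weights()] then assigns it entropy 1 (weight 0).
#'
#' @param X A [raw_indicator_matrix()] (a plain matrix is accepted and
#'   treated as all-positive directions).
#' @return Numeric matrix of the same shape with entries in \[0, 1\].
#' @export
minmax_normalize <- function(X) {
  if (!inherits(X, "raw_indicator_matrix")) X <- raw_indicator_matrix(X)
  V <- X$values
  Y <- V
  for (j in seq_len(ncol(V))) {
    rng <- range(V[, j])
    if (rng[1] == rng[2]) {
      warn_("indicator '%s' is constant; normalized to 0.5 (zero weight)",
            colnames(V)[j])
      Y[, j] <- 0.5
    } else if (X$directions[j] == "positive") {
      Y[, j] <- (V[, j] - rng[1]) / (rng[2] - rng[1])
    } else {
      Y[, j] <- (rng[2] - V[, j]) / (rng[2] - rng[1])
    }
  }
  Y
}

#' Entropy weight method
#'
#' Objective indicator weighting from the dispersion of observed values.
#' With `Y` the min-max normalized matrix over `n` items, the proportion of
#' item `i` in indicator `j` is `P_ij = Y_ij / sum_i(Y_ij)`, the information
#' entropy of indicator `j` is `E_j = -(1/ln n) * sum_i(P_ij ln P_ij)` (with
#' `0 ln 0 = 0`), and the weight is `W_j = (1 - E_j) / (k - sum(E))` over the
#' `k` indicators. Indicators whose values are more unequal across items have
#' lower entropy and receive larger weights.
#'
#' A constant column gets `E_j = 1` and hence weight 0. If every indicator is
#' perfectly uniform (all `E_j = 1`) no indicator discriminates and an error
#' is raised.
#'
#' @param X A [raw_indicator_matrix()] or plain numeric matrix.
#' @return An object of class `entropy_weight_result`: list with `normalized`
#'   (Y), `proportions` (P), `entropies` (E) and `weights` (a
#'   [weight_vector()]).
#' @examples
#' X <- raw_indicator_matrix(cbind(a = c(1, 2, 3), b = c(10, 11, 30)))
#' entropy_weights(X)$weights
#' @export
entropy_weights <- function(X) {
  if (!inherits(X, "raw_indicator_matrix")) X <- raw_indicator_matrix(X)
  Y <- minmax_normalize(X)
  n <- nrow(Y); k <- ncol(Y)
  P <- Y
  E <- numeric(k)
  constant <- apply(X$values, 2, function(v) min(v) == max(v))
  for (j in seq_len(k)) {
    cs <- sum(Y[, j])
    P[, j] <- if (cs > 0) Y[, j] / cs else 0
    if (constant[j]) {
      E[j] <- 1  # no information in a constant indicator
    } else {
      p <- P[, j]
      E[j] <- -sum(ifelse(p > 0, p * log(p), 0)) / log(n)
      E[j] <- min(max(E[j], 0), 1)  # clamp roundoff at the boundaries
    }
  }
  names(E) <- colnames(Y)
  denom <- k - sum(E)
  if (denom <= .Machine$double.eps * k)
    stop_("no discriminating information: all indicator entropies are 1")
  W <- (1 - E) / denom
  structure(list(normalized = Y, proportions = P, entropies = E,
                 weights = weight_vector(W)),
            class = "entropy_weight_result")
}

#' @export
print.entropy_weight_result <- function(x, ...) {
  cat(sprintf("Entropy weighting of %d indicators over %d items\n",
              ncol(x$normalized), nrow(x$normalized)))
  print(data.frame(entropy = round(x$entropies, 4),
                   weight = round(as.numeric(x$weights), 4)))
  invisible(x)
}

#' Pairwise comparison (judgment) matrix
#'
#' A positive reciprocal matrix on the Saaty 1-9 scale: unit diagonal,
#' `a[i,j] * a[j,i] = 1`, entries in \[1/9, 9\].
#'
#' @param entries Square numeric matrix of pairwise importance ratios.
#' @return An object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(entries) {
  entries <- as.matrix(entries)
  n <- nrow(entries)
  if (ncol(entries) != n || n < 1) stop_("judgment matrix must be square")
  if (anyNA(entries) || any(entries <= 0))
    stop_("judgment matrix entries must be positive")
  if (!near(diag(entries), 1, 1e-9))
    stop_("judgment matrix diagonal must be 1")
  if (!near(entries * t(entries), 1, 1e-9))
    stop_("judgment matrix must be reciprocal (a_ij * a_ji = 1)")
  if (any(entries < 1 / 9 - 1e-9) || any(entries > 9 + 1e-9))
    stop_("judgment matrix entries must lie in [1/9, 9]")
  structure(list(entries = entries), class = "pairwise_matrix")
}

# Saaty's random consistency index, n = 1..9
SAATY_RI <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' Map mean Likert ratings to a judgment matrix
#'
#' Converts per-item mean ratings on a 1-5 scale into a Saaty-scale pairwise
#' comparison matrix: the rounded mean difference `d = round(mean_i -
#' mean_j)`, clipped to \[-4, 4\], maps through `|d|` -> 1, 3, 5, 7, 9
#' (reciprocal for negative `d`). Equal means give equal importance (1); the
#' maximal 4-point spread maps to the Saaty extreme 9. The map is a stated
#' convention; pass a different odd-scale `map` to change it.
#'
#' @param mean_scores Named numeric vector of mean ratings, each in \[1, 5\].
#' @param map Length-5 increasing positive vector giving the Saaty value for
#'   absolute rounded differences 0..4.
#' @return A [pairwise_matrix()] keyed like `mean_scores`.
#' @examples
#' likert_to_pairwise(c(A = 4, B = 3, C = 2))$entries
#' @export
likert_to_pairwise <- function(mean_scores, map = c(1, 3, 5, 7, 9)) {
  m <- unlist(mean_scores)
  if (!length(m)) stop_("empty sibling group")
  if (anyNA(m) || any(m < 1) || any(m > 5))
    stop_("mean scores must lie in [1, 5]")
  if (length(map) != 5 || any(diff(map) <= 0) || any(map <= 0))
    stop_("map must be 5 increasing positive values")
  n <- length(m)
  A <- matrix(1, n, n, dimnames = list(names(m), names(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- round(m[i] - m[j])
    d <- max(min(d, 4), -4)
    A[i, j] <- if (d >= 0) map[d + 1] else 1 / map[-d + 1]
  }
  pairwise_matrix(A)
}

#' AHP principal-eigenvector weights with consistency check
#'
#' Estimates priority weights from a judgment matrix as the normalized
#' principal right eigenvector, computed by power iteration, and runs the
#' standard consistency test: `CI = (lambda_max - n) / (n - 1)`,
#' `CR = CI / RI(n)` with Saaty's random index table, accepting the matrix
#' when `CR < 0.1`. For `n <= 2` a reciprocal matrix is always consistent and
#' `CR` is defined as 0. A geometric-mean (row product) estimator is
#' available via `method = "geometric"`.
#'
#' @param M A [pairwise_matrix()] (or plain reciprocal matrix).
#' @param method "eigenvector" (default, power iteration) or "geometric".
#' @param tol Convergence tolerance on the weight vector (power iteration).
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `ahp_result`: list with `weights` (a
#'   [weight_vector()]), `lambda_max`, `ci`, `cr`, `consistent`, `n`.
#' @examples
#' M <- pairwise_matrix(rbind(c(1, 3, 5), c(1/3, 1, 3), c(1/5, 1/3, 1)))
#' principal_weights(M)
#' @export
principal_weights <- function(M, method = c("eigenvector", "geometric"),
                              tol = 1e-10, max_iter = 10000) {
  method <- match.arg(method)
  if (!inherits(M, "pairwise_matrix")) M <- pairwise_matrix(M)
  A <- M$entries
  n <- nrow(A)
  keys <- colnames(A) %||% paste0("k", seq_len(n))

  if (method == "geometric") {
    w <- apply(A, 1, function(r) exp(mean(log(r))))
    w <- w / sum(w)
  } else if (n == 1) {
    w <- 1
  } else {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w_new <- as.numeric(A %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < tol) {
        w <- w_new
        converged <- TRUE
        break
      }
      w <- w_new
    }
    if (!converged)
      stop_("power iteration did not converge in %d iterations", max_iter)
  }

  lambda_max <- if (n == 1) 1 else mean(as.numeric(A %*% w) / w)
  ci <- if (n >= 2) (lambda_max - n) / (n - 1) else 0
  cr <- if (n <= 2) 0 else {
    if (n > length(SAATY_RI))
      stop_("random index table covers n <= %d", length(SAATY_RI))
    ci / SAATY_RI[n]
  }
  structure(list(weights = weight_vector(stats::setNames(w, keys)),
                 lambda_max = lambda_max, ci = ci, cr = cr,
                 consistent = cr < 0.1, n = n),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("AHP weights (n = %d): %s\n", x$n,
              paste(sprintf("%s=%.4f", names(x$weights),
                            as.numeric(x$weights)), collapse = ", ")))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$ci, x$cr,
              if (x$consistent) "consistent, CR < 0.1" else "INCONSISTENT"))
  invisible(x)
}

#' AHP weights for every sibling group of a hierarchy, from panel means
#'
#' For each internal node, takes the panel's mean rating of each child (a
#' leaf's mean is its column mean over non-missing ratings; an internal
#' child's mean is the unweighted mean of its leaf means), maps the means to
#' a judgment matrix with [likert_to_pairwise()] and extracts
#' principal-eigenvector weights. All consistency ratios are checked.
#'
#' @param panel An [expert_panel()].
#' @param hierarchy An [indicator_hierarchy()].
#' @inheritParams likert_to_pairwise
#' @return Named list, one [principal_weights()] result per internal node id.
#' @export
ahp_weights_from_panel <- function(panel, hierarchy, map = c(1, 3, 5, 7, 9)) {
  leaves <- hierarchy_leaves(hierarchy)
  if (!all(leaves %in% colnames(panel$ratings)))
    stop_("panel does not cover all hierarchy leaves")
  leaf_means <- colMeans(panel$ratings[, leaves, drop = FALSE], na.rm = TRUE)
  node_mean <- function(id) {
    if (id %in% leaves) return(leaf_means[[id]])
    mean(vapply(hierarchy_children(hierarchy, id), node_mean, numeric(1)))
  }
  internal <- unique(hierarchy$nodes$parent[!is.na(hierarchy$nodes$parent)])
  out <- lapply(internal, function(p) {
    kids <- hierarchy_children(hierarchy, p)
    means <- stats::setNames(vapply(kids, node_mean, numeric(1)), kids)
    if (length(kids) == 1) {
      # single child: trivial unit weight, no comparison needed
      structure(list(weights = weight_vector(stats::setNames(1, kids)),
                     lambda_max = 1, ci = 0, cr = 0, consistent = TRUE,
                     n = 1L), class = "ahp_result")
    } else {
      principal_weights(likert_to_pairwise(means, map))
    }
  })
  stats::setNames(out, internal)
}
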