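# small hierarchies and panels built in code for the unit tests

# root -> B1 (x1, x2), B2 (y1); weights set everywhere
tiny_hierarchy <- function() {
  indicator_hierarchy(data.frame(
    id     = c("root", "B1", "B2", "x1", "x2", "y1"),
    label  = c("goal", "branch 1", "branch 2", "leaf x1", "leaf x2",
               "leaf y1"),
    level  = c(1, 2, 2, 3, 3, 3),
    parent = c(NA, "root", "root", "B1", "B1", "B2"),
    weight = c(NA, 0.6, 0.4, 0.5, 0.5, 1)))
}

# root -> single level-2 node -> single leaf (pass-through chain)
chain_hierarchy <- function() {
  indicator_hierarchy(data.frame(
    id = c("r", "m", "l"), label = c("goal", "mid", "leaf"),
    level = 1:3, parent = c(NA, "r", "m"), weight = c(NA, 1, 1)))
}

# panel with given rating columns on tiny_hierarchy's leaves
tiny_panel <- function(x1, x2 = x1, y1 = x1) {
  expert_panel(cbind(x1 = x1, x2 = x2, y1 = y1))
}

# a deterministic random panel over a hierarchy's leaves
random_panel <- function(hierarchy, n = 20, seed = 1) {
  leaves <- hierarchy_leaves(hierarchy)
  withr::with_seed(seed, {
    m <- matrix(sample(1:5, n * length(leaves), replace = TRUE),
                n, length(leaves), dimnames = list(NULL, leaves))
    expert_panel(m, hierarchy$scale)
  })
}

# independent brute-force implementation of the entropy-weight formulas,
# used as the oracle against entropy_weights()
entropy_oracle <- function(X, directions = rep("positive", ncol(X))) {
  n <- nrow(X); k <- ncol(X)
  Y <- X
  for (j in seq_len(k)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    Y[, j] <- if (hi == lo) 0.5
    else if (directions[j] == "positive") (X[, j] - lo) / (hi - lo)
    else (hi - X[, j]) / (hi - lo)
  }
  E <- numeric(k)
  for (j in seq_len(k)) {
    if (min(X[, j]) == max(X[, j])) { E[j] <- 1; next }
    s <- 0
    for (i in seq_len(n)) {
      p <- Y[i, j] / sum(Y[, j])
      if (p > 0) s <- s + p * log(p)
    }
    E[j] <- -s / log(n)
  }
  W <- (1 - E) / (k - sum(E))
  list(E = E, W = W)
}
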