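test_that("min-max normalization maps endpoints and mirrors negatives", {
  X <- raw_indicator_matrix(cbind(a = c(1, 2, 3), b = c(1, 2, 3)),
                            directions = c("positive", "negative"))
  Y <- minmax_normalize(X)
  expect_equal(Y[, "a"], c(0, 0.5, 1))
  expect_equal(Y[, "b"], c(1, 0.5, 0))
  expect_warning(
    Yc <- minmax_normalize(cbind(c = c(4, 4, 4))), "constant")
  expect_equal(unname(Yc[, 1]), c(0.5, 0.5, 0.5))
})

test_that("entropy weighting reproduces hand-computed entropies and weights", {
  # columns normalize to [0, .5, 1] and a constant; frozen oracle values
  X <- raw_indicator_matrix(cbind(a = c(1, 2, 3), b = c(7, 7, 7)))
  res <- suppressWarnings(entropy_weights(X))
  expect_equal(unname(res$entropies), c(0.5793802, 1), tolerance = 1e-6)
  expect_equal(unname(as.numeric(res$weights)), c(1, 0))
  expect_equal(sum(res$proportions[, "a"]), 1, tolerance = 1e-12)

  # two identical non-constant columns share the weight equally
  X2 <- entropy_weights(cbind(u = c(1, 3, 9), v = c(1, 3, 9)))
  expect_equal(unname(as.numeric(X2$weights)), c(0.5, 0.5))

  # a single non-constant indicator takes all the weight
  expect_equal(as.numeric(entropy_weights(cbind(s = c(2, 5, 1)))$weights), 1)

  # all-constant input carries no discriminating information
  expect_error(suppressWarnings(entropy_weights(cbind(a = c(1, 1), b = c(2, 2)))),
               "no discriminating information")
})

test_that("entropy weights agree with the brute-force oracle on random matrices", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n <- sample(3:6, 1); k <- sample(3:6, 1)
      X <- matrix(stats::runif(n * k, 1, 10), n, k,
                  dimnames = list(NULL, paste0("I", seq_len(k))))
      dirs <- sample(c("positive", "negative"), k, replace = TRUE)
      res <- entropy_weights(raw_indicator_matrix(X, dirs))
      orc <- entropy_oracle(
        # oracle works on the already-mirrored values
        vapply(seq_len(k), function(j)
          if (dirs[j] == "negative") -X[, j] else X[, j], numeric(n)))
      expect_equal(unname(res$entropies), orc$E, tolerance = 1e-12)
      expect_equal(unname(as.numeric(res$weights)), orc$W, tolerance = 1e-12)
      expect_equal(sum(as.numeric(res$weights)), 1, tolerance = 1e-9)
      expect_true(all(res$entropies >= 0 & res$entropies <= 1))
    }
  })
})

test_that("entropy weights are invariant to positive affine column transforms", {
  withr::with_seed(7, {
    X <- matrix(stats::runif(20, 0, 5), 5, 4)
    w1 <- as.numeric(entropy_weights(X)$weights)
    X2 <- X
    X2[, 2] <- 3.7 * X[, 2] + 11
    w2 <- as.numeric(entropy_weights(X2)$weights)
    expect_equal(w1, w2, tolerance = 1e-12)
  })
})

test_that("more concentrated normalized columns never lose entropy weight", {
  # a power transform sharpens the normalized column (endpoints fixed, so
  # min-max is a no-op) and concentrates its proportions on fewer items
  base <- c(0, 0.25, 0.5, 0.75, 1)
  other <- c(0, 0.9, 0.4, 0.2, 1)
  w_of <- function(gamma)
    as.numeric(entropy_weights(cbind(a = base^gamma, b = other))$weights)[1]
  ws <- vapply(c(1, 2, 4, 8), w_of, numeric(1))
  expect_true(all(diff(ws) >= -1e-12))
})

test_that("likert differences map onto the Saaty scale reciprocally", {
  expect_equal(likert_to_pairwise(c(a = 3, b = 3))$entries,
               matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  M <- likert_to_pairwise(c(a = 5, b = 1))$entries
  expect_equal(M["a", "b"], 9)
  expect_equal(M["b", "a"], 1 / 9)
  M3 <- likert_to_pairwise(c(a = 4, b = 3, c = 2))$entries
  expect_equal(unname(M3[upper.tri(M3)]), c(3, 5, 3))
  expect_error(likert_to_pairwise(numeric(0)), "empty")
  expect_error(likert_to_pairwise(c(a = 6, b = 2)), "\\[1, 5\\]")
})

test_that("judgment matrix validation enforces reciprocity and range", {
  expect_error(pairwise_matrix(rbind(c(1, 2), c(2, 1))), "reciprocal")
  expect_error(pairwise_matrix(rbind(c(2, 1), c(1, 1))), "diagonal")
  expect_error(pairwise_matrix(rbind(c(1, -2), c(-0.5, 1))), "positive")
  expect_error(pairwise_matrix(rbind(c(1, 12), c(1 / 12, 1))), "1/9")
})

test_that("principal-eigenvector weights match closed forms and eigen oracle", {
  # consistent 2x2: closed-form weights, CR defined as 0
  r2 <- principal_weights(rbind(c(1, 2), c(0.5, 1)))
  expect_equal(unname(as.numeric(r2$weights)), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  expect_identical(r2$cr, 0)
  expect_true(r2$consistent)

  # 3x3 cross-checked against the dense eigensolver
  M <- rbind(c(1, 3, 5), c(1 / 3, 1, 3), c(1 / 5, 1 / 3, 1))
  r3 <- principal_weights(M)
  e <- eigen(M)
  i <- which.max(Re(e$values))
  w_oracle <- Re(e$vectors[, i]); w_oracle <- w_oracle / sum(w_oracle)
  expect_equal(unname(as.numeric(r3$weights)), w_oracle, tolerance = 1e-8)
  expect_equal(r3$lambda_max, Re(e$values[i]), tolerance = 1e-8)
  expect_equal(r3$cr, (Re(e$values[i]) - 3) / 2 / 0.58, tolerance = 1e-6)
  expect_true(r3$consistent)
  expect_gte(r3$lambda_max, 3 - 1e-6)
})

test_that("consistent matrices built from known weights are recovered exactly", {
  withr::with_seed(11, {
    for (n in 3:6) {
      w <- stats::runif(n, 0.5, 3); w <- w / sum(w)
      A <- outer(w, w, "/")
      # clip to the admissible Saaty range before validating
      if (max(A) > 9) next
      r <- principal_weights(A)
      expect_equal(unname(as.numeric(r$weights)), w, tolerance = 1e-8)
      expect_equal(r$cr, 0, tolerance = 1e-8)
    }
  })
  # geometric-mean estimator agrees on a consistent matrix
  w <- c(0.5, 0.3, 0.2)
  rg <- principal_weights(outer(w, w, "/"), method = "geometric")
  expect_equal(unname(as.numeric(rg$weights)), w, tolerance = 1e-10)
})

test_that("combine_weights is a renormalized convex combination", {
  wa <- weight_vector(c(p = 0.6, q = 0.4))
  wb <- weight_vector(c(p = 0.2, q = 0.8))
  expect_equal(as.numeric(combine_weights(wa, wb, 1)), as.numeric(wa))
  expect_equal(as.numeric(combine_weights(wa, wb, 0)), as.numeric(wb))
  expect_equal(unname(as.numeric(combine_weights(wa, wb, 0.5))), c(0.4, 0.6))
  expect_error(combine_weights(wa, weight_vector(c(p = 1, z = 1)), 0.5),
               "key sets")
  expect_error(combine_weights(wa, wb, 1.5), "alpha")
})

test_that("fit_weights fills every sibling group by each method", {
  h <- tiny_hierarchy()
  withr::with_seed(5, {
    X <- raw_indicator_matrix(matrix(stats::runif(30, 1, 9), 10, 3,
                                     dimnames = list(NULL, c("x1", "x2", "y1"))))
    panel <- random_panel(h, n = 15)
  })
  for (m in c("entropy", "ahp")) {
    fit <- fit_weights(h, m, panel = panel, raw = X)
    for (p in c("root", "B1", "B2"))
      expect_equal(sum(as.numeric(group_weights(fit$hierarchy, p))), 1,
                   tolerance = 1e-9)
  }
  # combined endpoints: alpha = 1 is pure AHP
  fit_a <- fit_weights(h, "ahp", panel = panel)
  fit_c <- fit_weights(h, "combined", panel = panel, raw = X, alpha = 1)
  expect_equal(as.numeric(group_weights(fit_c$hierarchy, "B1")),
               as.numeric(group_weights(fit_a$hierarchy, "B1")),
               tolerance = 1e-12)
  # entropy: level-2 node weight is the sum of its leaves' global weights
  fit_e <- fit_weights(h, "entropy", raw = X)
  ew <- entropy_weights(X)$weights
  w2 <- group_weights(fit_e$hierarchy, "root")
  expect_equal(as.numeric(w2["B1"]), sum(as.numeric(ew[c("x1", "x2")])),
               tolerance = 1e-9)
})
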