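make_counts_panel <- function(counts, leaf = "l") {
  # a one-leaf panel whose grade counts are exactly `counts` (ascending)
  h <- indicator_hierarchy(data.frame(
    id = c("r", leaf), label = c("goal", "leaf"),
    level = 1:2, parent = c(NA, "r")))
  ratings <- matrix(rep(1:5, counts), ncol = 1, dimnames = list(NULL, leaf))
  list(hierarchy = h, panel = expert_panel(ratings))
}

test_that("membership degrees are response frequencies at printed precision", {
  # 17 raters, counts (0,0,5,11,1): the published G1 row to 6 dp
  cp <- make_counts_panel(c(0, 0, 5, 11, 1))
  R <- membership_matrix(cp$panel, cp$hierarchy)
  expect_equal(round(as.numeric(R[1, ]), 6),
               c(0, 0, 0.294118, 0.647059, 0.058824))
  expect_identical(unname(attr(R, "counts")), 17L)

  # counts (0,1,8,6,2): the published G2 row
  cp2 <- make_counts_panel(c(0, 1, 8, 6, 2))
  expect_equal(round(as.numeric(membership_matrix(cp2$panel, cp2$hierarchy)[1, ]), 6),
               c(0, 0.058824, 0.470588, 0.352941, 0.117647))

  # unanimous top grade is a point mass
  cp3 <- make_counts_panel(c(0, 0, 0, 0, 9))
  expect_equal(as.numeric(membership_matrix(cp3$panel, cp3$hierarchy)[1, ]),
               c(0, 0, 0, 0, 1))
})

test_that("membership estimation skips missing cells and flags empty leaves", {
  h <- tiny_hierarchy()
  p <- tiny_panel(c(3, NA, 4), c(5, 5, NA), c(NA, NA, NA))
  expect_error(membership_matrix(p, h), "'y1'.*zero responses")
  p2 <- tiny_panel(c(3, NA, 4), c(5, 5, NA), c(2, NA, NA))
  R <- membership_matrix(p2, h)
  expect_equal(unname(attr(R, "counts")), c(2L, 2L, 1L))
  expect_equal(as.numeric(R["x1", ]), c(0, 0, 0.5, 0.5, 0))
  expect_equal(rowSums(R), c(x1 = 1, x2 = 1, y1 = 1))
})

test_that("synthesis is the weighted average of membership rows", {
  R <- as_membership_matrix(rbind(a = c(1, 0, 0, 0, 0),
                                  b = c(0, 0, 0, 0, 1)))
  # single row: identity
  expect_equal(as.numeric(synthesize(weight_vector(c(a = 1)),
                                     R["a", , drop = FALSE])),
               c(1, 0, 0, 0, 0))
  # equal weights: plain average
  A <- synthesize(weight_vector(c(a = 1, b = 1)), R)
  expect_equal(as.numeric(A), c(0.5, 0, 0, 0, 0.5))
  expect_error(synthesize(weight_vector(c(a = 1, z = 1)), R), "keys")
  # max-min variant still yields a unit-sum vector
  expect_equal(sum(synthesize(weight_vector(c(a = 1, b = 3)), R,
                              operator = "maxmin")), 1, tolerance = 1e-12)
})

test_that("defuzzification is the expectation under the grade values", {
  expect_equal(defuzzify(c(0, 0, 0, 0, 1)), 5)
  expect_equal(defuzzify(rep(0.2, 5)), 3)
  g1 <- c(0, 0, 0.294118, 0.647059, 0.058824) /
    sum(c(0, 0, 0.294118, 0.647059, 0.058824))
  expect_equal(defuzzify(g1), 3.7647, tolerance = 1e-4)
})

test_that("dimension-score aggregation reproduces the published composite", {
  fx <- jilin_fixture()
  cs <- aggregate_fixed_scores(fx$weights_level2, fx$dimension_scores)
  expect_equal(round(cs$score, 2), 3.63)
  expect_equal(cs$score, 3.633914, tolerance = 1e-6)
  expect_identical(cs$grade_label, "good")
})

test_that("hierarchy aggregation matches a brute-force two-stage computation", {
  fx <- jilin_fixture()
  sub <- subset_hierarchy(fx$hierarchy, "A1")
  agg <- aggregate_hierarchy(sub, fx$membership_g)

  # independent oracle: explicit loops over the printed rows (read as
  # probability distributions, so normalized at full precision) and weights
  gw <- fx$weights_level3[paste0("G", 1:5)]
  gw <- gw / sum(gw)
  R <- unclass(fx$membership_g)
  R <- R / rowSums(R)
  A_oracle <- numeric(5)
  for (j in 1:5) for (i in 1:5) A_oracle[j] <- A_oracle[j] + gw[i] * R[i, j]
  score_oracle <- sum(A_oracle * (1:5))

  expect_equal(as.numeric(agg$A1$vector), A_oracle, tolerance = 1e-12)
  expect_equal(agg$A1$score, score_oracle, tolerance = 1e-12)
  expect_equal(agg$A1$score, 3.5718, tolerance = 1e-4)
  # leaf scores are their own rows' expectations
  expect_equal(agg$G1$score, sum(R[1, ] * (1:5)), tolerance = 1e-12)
})

test_that("a one-branch hierarchy passes the leaf score through unchanged", {
  h <- chain_hierarchy()
  R <- as_membership_matrix(rbind(l = c(0, 0.1, 0.2, 0.3, 0.4)))
  agg <- aggregate_hierarchy(h, R)
  expect_equal(agg$r$score, agg$l$score, tolerance = 1e-12)
  expect_equal(agg$r$score, defuzzify(c(0, 0.1, 0.2, 0.3, 0.4)))
  expect_error(aggregate_hierarchy(h, R[0, , drop = FALSE]),
               "no membership row")
})

test_that("grade assignment brackets scores and bands normalized values", {
  g <- assign_grade(3.6363)
  expect_identical(g$labels, c("average", "important"))
  expect_identical(g$band, "good")
  expect_equal(g$normalized, 0.659, tolerance = 1e-3)

  top <- assign_grade(5)
  expect_identical(top$labels, "very important")
  expect_identical(top$band, "excellent")
  bottom <- assign_grade(1)
  expect_identical(bottom$labels, "very unimportant")
  expect_identical(bottom$band, "poor")
  # bands are lower-inclusive
  expect_identical(assign_grade(1 + 4 * 0.2)$band, "average")
  expect_error(assign_grade(5.2), "outside")
})

test_that("membership, synthesis and aggregation conserve unit mass", {
  fx <- jilin_fixture()
  h <- fx$hierarchy
  for (seed in 1:3) {
    p <- random_panel(h, n = 12, seed = seed)
    R <- membership_matrix(p, h)
    expect_equal(unname(rowSums(R)), rep(1, 18), tolerance = 1e-6)
    agg <- aggregate_hierarchy(h, R)
    for (cs in agg) {
      expect_equal(sum(cs$vector), 1, tolerance = 1e-6)
      expect_gte(cs$score, 1); expect_lte(cs$score, 5)
      expect_gte(cs$normalized, 0); expect_lte(cs$normalized, 1)
    }
  }
})

test_that("raising one rating never lowers that leaf's score", {
  h <- tiny_hierarchy()
  base <- tiny_panel(c(3, 2, 4), c(1, 5, 2), c(2, 2, 3))
  s0 <- aggregate_hierarchy(h, membership_matrix(base, h))$x1$score
  for (new in 4:5) {
    up <- base
    up$ratings[1, "x1"] <- new
    s1 <- aggregate_hierarchy(h, membership_matrix(up, h))$x1$score
    expect_gte(s1, s0)
    s0 <- s1
  }
})

test_that("defuzzify after synthesis equals the weighted sum of row scores", {
  withr::with_seed(9, {
    for (rep in 1:5) {
      k <- sample(2:6, 1)
      R <- matrix(stats::rexp(5 * k), k, 5)
      R <- R / rowSums(R)
      rownames(R) <- paste0("n", seq_len(k))
      w <- weight_vector(stats::setNames(stats::runif(k, 0.1, 1),
                                         rownames(R)))
      lhs <- defuzzify(synthesize(w, as_membership_matrix(R)))
      rhs <- sum(as.numeric(w) *
                   apply(R, 1, function(r) sum(r * (1:5))))
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  })
})
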