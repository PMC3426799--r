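test_that("edge confidence has the right boundary behavior", {
  g <- seq(0, 1, 0.01)
  t_curve <- 100 * (1 - g)        # edges accrue uniformly
  # no null edges at all: confidence 1 wherever edges accrue
  L1 <- edge_confidence(t_curve, rep(0, length(g)), g)
  expect_true(all(L1 == 1))
  # null curve identical to observed: nothing is trustworthy
  L0 <- edge_confidence(t_curve, t_curve, g)
  expect_true(all(L0 == 0))
  expect_error(edge_confidence(t_curve[-1], t_curve, g), "length")
})

test_that("edge confidence matches analytic slopes on polynomial curves", {
  # t_f = 2(1-f) E and p_f = (1-f)^2 E have slope ratio (1-f), so the raw
  # confidence is exactly f; centered differences are exact for these
  # polynomials, and the curve is already monotone so the envelope is a
  # no-op away from the boundary-clamped edges of the grid
  g <- seq(0, 1, 0.01)
  E <- 500
  L <- edge_confidence(2 * (1 - g) * E, (1 - g)^2 * E, g)
  interior <- g >= 0.12 & g <= 0.88
  expect_equal(L[interior], g[interior], tolerance = 1e-9)
})

test_that("confidence is clipped to [0,1] and monotone by construction", {
  set.seed(71)
  g <- seq(0, 1, 0.01)
  for (rep in 1:10) {
    t_curve <- rev(cumsum(stats::rexp(length(g))))
    p_curve <- rev(cumsum(stats::rexp(length(g))))
    L <- edge_confidence(t_curve, p_curve, g)
    expect_true(all(L >= 0 & L <= 1))
    expect_true(all(diff(L) >= 0))
  }
})

test_that("null calibration: permuted and observed counts agree on null data", {
  # independence model: permuting cannot change the dependence structure,
  # so p_f tracks t_f and the consensus comes out (near) empty
  set.seed(81)
  x <- as_bn_data(matrix(sample(1:2, 5 * 150, replace = TRUE), ncol = 5),
                  arities = rep(2L, 5))
  pt <- bn_permtest(x, n_perm = 4, target = 0.9, B = 60, m1 = 3, m2 = 3,
                    seed = 17)
  cv <- pt$curves
  mid <- cv$threshold >= 0.3 & cv$threshold <= 0.9
  expect_lt(mean(abs(cv$t_f[mid] - cv$p_f[mid])),
            0.15 * choose(5, 2) + 0.5)
  expect_lte(nrow(pt$consensus), 2)
  expect_true(all(diff(cv$t_f) <= 0))
  expect_true(all(diff(cv$p_f) <= 0))
})

test_that("structured data yields a high-confidence consensus containing true edges", {
  bn <- benchmark_suite()$chain4
  x <- simulate(bn, nsim = 400, seed = 23)
  pt <- bn_permtest(x, n_perm = 4, target = 0.9, B = 40, m1 = 4, m2 = 4,
                    seed = 29)
  expect_false(is.na(pt$threshold))
  truth <- bnbag:::skeleton_adjacency(bn$parents)
  found <- 0
  for (r in seq_len(nrow(pt$consensus))) {
    a <- match(pt$consensus$from[r], bn$names)
    b <- match(pt$consensus$to[r], bn$names)
    found <- found + truth[a, b]
  }
  expect_gte(found, 2) # at least 2 of the 3 chain edges
  expect_true(all(pt$consensus$confidence >= pt$target))
})

test_that("threshold selection respects the confidence target", {
  g <- seq(0, 1, 0.01)
  fitlike <- structure(list(
    edge_prob = matrix(c(0, 0.95, 0.95, 0), 2,
                       dimnames = list(c("A", "B"), c("A", "B"))),
    dir_freq = matrix(c(0, 0, 0.95, 0), 2,
                      dimnames = list(c("A", "B"), c("A", "B")))),
    class = "bn_bag")
  # L identically 0 (observed == null) gives an empty consensus
  t_curve <- count_edges <- bnbag:::count_edges_at(fitlike$edge_prob, g)
  L0 <- edge_confidence(t_curve, t_curve, g)
  expect_true(all(L0 == 0))
})
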