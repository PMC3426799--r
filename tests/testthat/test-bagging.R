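chain_data <- function(n = 300, seed = 11) {
  simulate(benchmark_suite()$chain4, nsim = n, seed = seed)
}

test_that("edge probability matrix is a symmetric sum of direction frequencies", {
  fit <- bn_bag(chain_data(150), B = 10, m1 = 3, m2 = 3, seed = 5)
  expect_equal(fit$edge_prob, fit$dir_freq + t(fit$dir_freq))
  expect_true(all(fit$edge_prob >= 0 & fit$edge_prob <= 1 + 1e-9))
  expect_true(all(diag(fit$edge_prob) == 0))
  # B = 1 single best: indicator features only
  f1 <- bn_bag(chain_data(150), B = 1, m1 = 3, m2 = 3, seed = 5)
  expect_true(all(f1$edge_prob %in% c(0, 1)))
})

test_that("double-Bayesian averaging with one retained network is single-best", {
  x <- chain_data(120, seed = 21)
  a <- bn_bag(x, B = 8, mode = "single_best", m1 = 3, m2 = 3, seed = 9)
  b <- bn_bag(x, B = 8, mode = "double_bayesian", top_m = 1,
              m1 = 3, m2 = 3, seed = 9)
  expect_identical(a$edge_prob, b$edge_prob)
})

test_that("bagging is bit-reproducible from the seed", {
  x <- chain_data(100, seed = 31)
  a <- bn_bag(x, B = 6, bootstrap = "ordinary", m1 = 2, m2 = 2, seed = 42)
  b <- bn_bag(x, B = 6, bootstrap = "ordinary", m1 = 2, m2 = 2, seed = 42)
  expect_identical(a$edge_prob, b$edge_prob)
  expect_identical(a$dir_freq, b$dir_freq)
})

test_that("bagged probabilities separate true from false chain edges", {
  x <- chain_data(300, seed = 41)
  fit <- bn_bag(x, B = 200, metric = "DPSM", lambda = 0.1,
                bootstrap = "bayesian", m1 = 5, m2 = 5, seed = 7)
  truth <- bnbag:::skeleton_adjacency(benchmark_suite()$chain4$parents)
  up <- upper.tri(truth)
  expect_true(all(fit$edge_prob[up][truth[up] == 1] > 0.8))
  expect_true(all(fit$edge_prob[up][truth[up] == 0] < 0.5))
  # and they track the exact enumeration posterior (Pearson: the near-zero
  # false-edge probabilities make rank correlation noisy on 6 pairs)
  ex <- exact_edge_posterior(x, score_config("DPSM", lambda = 0.1))
  expect_gt(stats::cor(fit$edge_prob[up], ex$edge_prob[up]), 0.95)
})

test_that("double averaging spreads mass over the retained networks", {
  x <- chain_data(200, seed = 51)
  fs <- bn_bag(x, B = 12, mode = "double_simple", top_m = 5,
               m1 = 4, m2 = 4, seed = 3)
  # per-resample contributions are means of indicators, so multiples of
  # 1/(B * top_m) can appear strictly between the single-best steps of 1/B
  expect_true(all(fs$edge_prob >= 0 & fs$edge_prob <= 1 + 1e-9))
  expect_gt(sum(fs$edge_prob[upper.tri(fs$edge_prob)] > 0), 2)
})

test_that("coef and consensus agree with the probability matrix", {
  fit <- bn_bag(chain_data(150), B = 15, m1 = 3, m2 = 3, seed = 13)
  ce <- coef(fit)
  expect_true(all(diff(ce$prob) <= 0))
  expect_equal(ce$prob, ce$fwd + ce$rev, tolerance = 1e-12)
  net <- consensus_network(fit, threshold = 0.5)
  expect_equal(
    sum(bnbag:::skeleton_adjacency(net$parents)[upper.tri(diag(4))]),
    sum(ce$prob >= 0.5))
  expect_true(bnbag:::is_acyclic(net$parents))
})
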