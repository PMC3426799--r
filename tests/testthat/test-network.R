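test_that("topological order respects parents and detects cycles", {
  # empty graph: any permutation is valid
  ord <- topological_order(rep(list(integer(0)), 3))
  expect_setequal(ord, 1:3)
  # chain 1 -> 2 -> 3
  expect_equal(topological_order(list(integer(0), 1L, 2L)), 1:3)
  # 2-cycle
  expect_error(topological_order(list(2L, 1L)), "cycle")
  # longer cycle buried in a larger graph
  expect_error(topological_order(list(3L, 1L, 2L, c(1L, 2L))), "cycle")
  # agreement with igraph on random structures
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    parents <- lapply(seq_len(n), function(i) {
      cand <- setdiff(seq_len(n), i)
      sort(sample(cand, sample(0:min(2, length(cand)), 1)))
    })
    expect_equal(bnbag:::is_acyclic(parents), igraph_is_dag(parents))
  }
})

test_that("network construction validates CPTs and structure", {
  expect_error(bn_network(c(1, 2), list(integer(0), integer(0))), "arity")
  expect_error(bn_network(c(2, 2), list(2L, 1L),
                          cpts = list(matrix(0.5, 1, 2), matrix(0.5, 2, 2))),
               "cycle")
  expect_error(
    bn_network(c(2, 2), list(integer(0), 1L),
               cpts = list(matrix(c(0.5, 0.5), 1), rbind(c(0.8, 0.3), c(0.1, 0.9)))),
    "sum to 1")
  expect_error(bn_network(c(2, 2), list(1L, integer(0))), "own parent")
})

test_that("joint distribution of generated networks sums to one", {
  for (seed in c(3, 14, 159)) {
    bn <- random_bn(3, n_edges = 2, arities = c(2, 3, 2), seed = seed)
    states <- bnbag:::enumerate_states(bn$arities)
    expect_equal(sum(exp(bn_logprob(bn, states))), 1, tolerance = 1e-9)
  }
  # independent fair coins: every row has probability 1/4
  bn <- coin_pair_bn()
  expect_equal(bn_logprob(bn, c(1, 2)), log(0.25))
  # zero-probability entries give -Inf
  bn0 <- copy_chain_bn()
  expect_identical(bn_logprob(bn0, c(1, 2)), -Inf)
  expect_error(bn_logprob(bn0, matrix(c(1, NA), 1)), "incomplete|missing")
})

test_that("forward sampling matches the encoded distribution", {
  # single binary variable: empirical frequency within binomial 3-sigma
  bn1 <- bn_network(2, list(integer(0)), cpts = list(matrix(c(0.5, 0.5), 1)))
  x <- simulate(bn1, nsim = 10000, seed = 1)
  expect_lt(abs(mean(x[, 1] == 1) - 0.5), 0.02)
  # deterministic copy chain: Y always equals X
  xy <- simulate(copy_chain_bn(), nsim = 500, seed = 2)
  expect_true(all(xy[, 1] == xy[, 2]))
  # determinism contract
  bn <- benchmark_suite()$tree8
  expect_identical(simulate(bn, 100, seed = 9), simulate(bn, 100, seed = 9))
})

test_that("sampled marginals pass goodness of fit against enumeration", {
  bn <- random_bn(4, n_edges = 4, arities = c(2, 3, 2, 4), seed = 77)
  x <- simulate(bn, nsim = 50000, seed = 101)
  for (v in seq_len(4)) {
    expected <- enumerated_marginal(bn, v)
    observed <- tabulate(x[, v], nbins = bn$arities[v])
    pval <- stats::chisq.test(observed, p = expected)$p.value
    expect_gt(pval, 0.001)
  }
})
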