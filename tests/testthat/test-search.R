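make_xyz_data <- function(n = 80, seed = 12) {
  # X independent of Y; Z strongly driven by X
  with_seed <- bnbag:::with_seed
  with_seed(seed, {
    X <- sample(1:2, n, replace = TRUE)
    Y <- sample(1:2, n, replace = TRUE)
    Z <- ifelse(stats::runif(n) < 0.95, X, 3 - X)
    as_bn_data(cbind(X = X, Y = Y, Z = Z), arities = rep(2L, 3))
  })
}

test_that("candidate selection ranks single-edge family gains", {
  x <- make_xyz_data()
  scorer <- bnbag:::make_scorer(x, score_config("K2"))
  ctx <- attr(scorer, "ctx")
  empty <- rep(list(integer(0)), 3)
  cand <- bnbag:::.cpp_select_candidates(ctx, empty, 6L)
  # with k >= n-1 every node's candidates are simply the others
  expect_equal(cand, list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  for (i in 1:3) expect_false(i %in% cand[[i]])
  # with k = 1, Z's sole candidate must be X (the strong driver),
  # verified against exhaustive single-edge scoring
  cand1 <- bnbag:::.cpp_select_candidates(ctx, empty, 1L)
  gains <- vapply(1:2, function(j) scorer(3L, j), numeric(1))
  expect_equal(cand1[[3]], which.max(gains))
  expect_equal(cand1[[3]], 1L)
  # current parents are always retained on re-selection
  cand2 <- bnbag:::.cpp_select_candidates(ctx, list(integer(0), integer(0), 2L), 1L)
  expect_equal(cand2[[3]], 2L)
})

test_that("neighbor enumeration yields exactly the legal one-move graphs", {
  full_cand <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  empty <- rep(list(integer(0)), 3)
  nb <- bnbag:::structure_neighbors(empty, full_cand, k = 6)
  expect_length(nb, 6) # 3 * 2 ordered pairs
  keys <- vapply(nb, function(m) bnbag:::struct_key(m$parents), character(1))
  expect_false(bnbag:::struct_key(empty) %in% keys)
  expect_identical(anyDuplicated(keys), 0L)
  # chain 1 -> 2 -> 3: enumerate and cross-check against the igraph
  # acyclicity oracle applied to all one-move modifications
  chain <- list(integer(0), 1L, 2L)
  nb2 <- bnbag:::structure_neighbors(chain, full_cand, k = 6)
  for (m in nb2) expect_true(igraph_is_dag(m$parents))
  # 2 deletions + 2 reversals + 1 addition (1->3); the additions 3->1,
  # 2->1 and 3->2 would each close a cycle and must be filtered out
  expect_length(nb2, 2 + 2 + 1)
})

test_that("hill climbing stops at the enumeration optimum and caches visits", {
  x <- make_xyz_data(n = 50, seed = 3)
  cfg <- score_config("K2")
  best <- brute_force_best(x, cfg)
  scorer <- bnbag:::make_scorer(x, cfg)
  ctx <- attr(scorer, "ctx")
  cand <- bnbag:::.cpp_select_candidates(ctx, rep(list(integer(0)), 3), 2L)
  res <- bnbag:::.cpp_hill_climb(ctx, best$parents, cand, k = 2)
  expect_equal(res$parents, best$parents)
  expect_equal(res$score, best$score, tolerance = 1e-9)
  n1 <- bnbag:::.cpp_visited_n(ctx)
  bnbag:::.cpp_hill_climb(ctx, rep(list(integer(0)), 3), cand, k = 2)
  expect_gt(bnbag:::.cpp_visited_n(ctx), n1) # visited set grows across restarts
})

test_that("compiled family scorer agrees with the reference implementation", {
  set.seed(77)
  x <- as_bn_data(matrix(sample(1:3, 200, replace = TRUE), ncol = 4),
                  arities = rep(3L, 4))
  w <- runif(50, 0.1, 3)
  for (m in c("K2", "DPSM", "BDe", "BIC", "MDL")) {
    cfg <- score_config(m, lambda = 0.3, ess = 2)
    scorer <- bnbag:::make_scorer(x, cfg, weights = w)
    for (parents in list(integer(0), 2L, c(2L, 3L), c(2L, 3L, 4L))) {
      expect_equal(scorer(1L, parents),
                   family_log_score(family_counts(x, 1, parents, w), cfg),
                   tolerance = 1e-9, label = m)
    }
  }
})

test_that("sparse-candidate search attains the enumeration optimum on all metrics", {
  for (seed in c(5, 17)) {
    x <- make_xyz_data(n = 60, seed = seed)
    for (m in c("K2", "DPSM", "BDe", "BIC", "MDL")) {
      cfg <- score_config(m, lambda = 0.1)
      oracle <- brute_force_best(x, cfg)
      fit <- bn_search(x, cfg, search_config(m1 = 6, m2 = 6, seed = seed))
      expect_equal(fit$scores[1], oracle$score, tolerance = 1e-9,
                   label = sprintf("%s seed %d", m, seed))
    }
  }
})

test_that("search results are deterministic, ranked and structurally valid", {
  bn <- benchmark_suite()$chain4
  x <- simulate(bn, nsim = 150, seed = 4)
  scfg <- search_config(k = 2, m1 = 5, m2 = 5, seed = 99)
  f1 <- bn_search(x, score_config("DPSM", lambda = 1), scfg)
  f2 <- bn_search(x, score_config("DPSM", lambda = 1), scfg)
  expect_identical(f1$networks, f2$networks)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(diff(f1$scores) <= 0))
  keys <- vapply(f1$networks, bnbag:::struct_key, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  for (p in f1$networks) {
    expect_true(igraph_is_dag(p))
    expect_true(all(lengths(p) <= 2))
  }
  # never below the empty network (which is in the start list)
  empty_score <- bn_score(x, rep(list(integer(0)), 4),
                          score_config("DPSM", lambda = 1))
  expect_gte(f1$scores[1], empty_score)
})

test_that("search recovers a chain skeleton from moderate data", {
  bn <- benchmark_suite()$chain4
  hits <- 0
  n_rep <- 12
  for (s in seq_len(n_rep)) {
    x <- simulate(bn, nsim = 500, seed = 200 + s)
    fit <- bn_search(x, score_config("DPSM", lambda = 1),
                     search_config(m1 = 6, m2 = 6, seed = s))
    sk <- bnbag:::skeleton_adjacency(fit$networks[[1]])
    truth <- bnbag:::skeleton_adjacency(bn$parents)
    hits <- hits + identical(sk, truth)
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})
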