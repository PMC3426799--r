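# Expected value for the K2 parentless binary family with counts (1, 2):
# Gamma(2)/Gamma(2+3) * Gamma(1+1) * Gamma(1+2) = 1/24 * 1 * 2 = 1/12.
test_that("family counts accumulate weighted mass per configuration", {
  x <- as_bn_data(matrix(c(1L, 2L, 2L), ncol = 1), arities = 2L)
  fc <- family_counts(x, 1)
  expect_equal(fc$counts, matrix(c(1, 2), 1))
  fc_w <- family_counts(x, 1, weights = c(2, 0.5, 0.5))
  expect_equal(fc_w$counts, matrix(c(2, 1), 1))
  # conservation for an arbitrary family with parents
  set.seed(8)
  y <- as_bn_data(matrix(sample(1:3, 60, replace = TRUE), ncol = 3),
                  arities = c(3L, 3L, 3L))
  w <- runif(20)
  fc2 <- family_counts(y, 2, parents = c(1, 3), weights = w)
  expect_equal(sum(fc2$counts), sum(w), tolerance = 1e-12)
  expect_equal(fc2$nij, rowSums(fc2$counts))
  expect_error(family_counts(y, 2, parents = 2), "exclude")
})

test_that("K2 score matches the factorial product form", {
  x <- as_bn_data(matrix(c(1L, 2L, 2L), ncol = 1), arities = 2L)
  fc <- family_counts(x, 1)
  expect_equal(family_log_score(fc, score_config("K2")), log(1 / 12),
               tolerance = 1e-12)
  # integer-count agreement with the factorial reference on random families
  set.seed(21)
  for (rep in 1:10) {
    y <- as_bn_data(matrix(sample(1:2, 90, replace = TRUE), ncol = 3),
                    arities = c(2L, 2L, 2L))
    fc <- family_counts(y, 1, parents = c(2, 3))
    expect_equal(family_log_score(fc, score_config("K2")),
                 k2_factorial_reference(fc$counts), tolerance = 1e-9)
  }
})

test_that("DPSM with lambda = 1 equals K2 bitwise", {
  set.seed(31)
  x <- as_bn_data(matrix(sample(1:3, 120, replace = TRUE), ncol = 4),
                  arities = rep(3L, 4))
  w <- runif(30, 0.2, 2)
  for (i in 1:4) {
    fc <- family_counts(x, i, parents = setdiff(1:2, i), weights = w)
    expect_identical(family_log_score(fc, score_config("DPSM", lambda = 1)),
                     family_log_score(fc, score_config("K2")))
  }
})

test_that("BDe is likelihood-equivalent across edge orientations", {
  set.seed(41)
  x <- as_bn_data(matrix(sample(1:2, 100, replace = TRUE), ncol = 2),
                  arities = c(2L, 2L))
  cfg <- score_config("BDe", ess = 1)
  s_xy <- bn_score(x, list(integer(0), 1L), cfg)
  s_yx <- bn_score(x, list(2L, integer(0)), cfg)
  expect_equal(s_xy, s_yx, tolerance = 1e-9)
  # cross-check each family against the independent Dirichlet marginal
  fc <- family_counts(x, 2, parents = 1)
  expect_equal(family_log_score(fc, cfg),
               dirichlet_marginal_reference(fc$counts, 1 / (2 * 2)),
               tolerance = 1e-9)
  # and on a 3-variable Markov-equivalence class: X -> Y -> Z vs X <- Y <- Z
  z <- as_bn_data(matrix(sample(1:2, 150, replace = TRUE), ncol = 3),
                  arities = rep(2L, 3))
  s1 <- bn_score(z, list(integer(0), 1L, 2L), cfg)
  s2 <- bn_score(z, list(2L, 3L, integer(0)), cfg)
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("all metrics decompose over families", {
  set.seed(51)
  x <- as_bn_data(matrix(sample(1:2, 200, replace = TRUE), ncol = 4),
                  arities = rep(2L, 4))
  parents <- list(integer(0), 1L, c(1L, 2L), 3L)
  for (m in c("K2", "DPSM", "BDe", "BIC", "MDL")) {
    cfg <- score_config(m)
    total <- bn_score(x, parents, cfg)
    fam <- sum(vapply(1:4, function(i) {
      family_log_score(family_counts(x, i, parents[[i]]), cfg)
    }, numeric(1)))
    expect_equal(total, fam, tolerance = 1e-12, label = m)
    # adding one edge changes exactly one family term
    p2 <- parents; p2[[4]] <- c(2L, 3L)
    delta <- bn_score(x, p2, cfg) - total
    fdelta <- family_log_score(family_counts(x, 4, p2[[4]]), cfg) -
      family_log_score(family_counts(x, 4, parents[[4]]), cfg)
    expect_equal(delta, fdelta, tolerance = 1e-9, label = m)
  }
})

test_that("free parameter counts follow (r-1) * q", {
  expect_identical(free_parameters(rep(list(integer(0)), 3), c(2, 2, 2)), 3)
  # binary child with two binary parents contributes (2-1)*4 = 4
  expect_identical(free_parameters(list(integer(0), integer(0), c(1L, 2L)),
                                   c(2, 2, 2)), 1 + 1 + 4)
  # ternary child, one 4-state parent: (3-1)*4 = 8
  expect_identical(free_parameters(list(integer(0), 1L), c(4, 3)), 3 + 8)
})

test_that("BIC increasingly selects the true sparser structure as N grows", {
  truth <- copy_chain_bn()
  truth$cpts[[2]] <- rbind(c(0.85, 0.15), c(0.15, 0.85))
  hits <- function(N) {
    mean(vapply(1:20, function(s) {
      x <- simulate(truth, nsim = N, seed = 1000 + s)
      best <- brute_force_best(x, score_config("BIC"))$parents
      identical(bnbag:::skeleton_adjacency(best),
                bnbag:::skeleton_adjacency(truth$parents))
    }, logical(1)))
  }
  expect_gte(hits(400), hits(25))
  expect_gte(hits(400), 0.9)
})

test_that("MDL and BIC rank structures consistently when graph length is ignored", {
  # with equal parent-set sizes the DL(G) term cancels and MDL ordering
  # must match BIC ordering (both reduce to penalized likelihood)
  set.seed(61)
  x <- as_bn_data(matrix(sample(1:2, 120, replace = TRUE), ncol = 3),
                  arities = rep(2L, 3))
  s_mdl <- c(bn_score(x, list(integer(0), 1L, integer(0)), score_config("MDL")),
             bn_score(x, list(integer(0), 3L, integer(0)), score_config("MDL")))
  s_bic <- c(bn_score(x, list(integer(0), 1L, integer(0)), score_config("BIC")),
             bn_score(x, list(integer(0), 3L, integer(0)), score_config("BIC")))
  expect_identical(order(s_mdl), order(s_bic))
})
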