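# Shared fixtures and independent reference implementations used as
# oracles. These deliberately use different code paths (factorial product
# forms, direct per-configuration loops, igraph) than the package.

# Two independent fair binary coins.
coin_pair_bn <- function() {
  bn_network(c(2, 2), list(integer(0), integer(0)),
             cpts = list(matrix(c(0.5, 0.5), 1), matrix(c(0.5, 0.5), 1)))
}

# X -> Y with Y a deterministic copy of X.
copy_chain_bn <- function() {
  bn_network(c(2, 2), list(integer(0), 1L),
             cpts = list(matrix(c(0.5, 0.5), 1), rbind(c(1, 0), c(0, 1))))
}

# K2 family score via the factorial product form:
# prod_j [ (r-1)! / (N_ij + r - 1)! * prod_k N_ijk! ]   (integer counts)
k2_factorial_reference <- function(counts) {
  r <- ncol(counts)
  nij <- rowSums(counts)
  sum(lfactorial(r - 1) - lfactorial(nij + r - 1)) + sum(lfactorial(counts))
}

# Dirichlet-multinomial family marginal written as an explicit
# per-configuration loop over gamma-function ratios.
dirichlet_marginal_reference <- function(counts, alpha_jk) {
  total <- 0
  for (j in seq_len(nrow(counts))) {
    a0 <- alpha_jk * ncol(counts)
    total <- total + lgamma(a0) - lgamma(a0 + sum(counts[j, ]))
    for (k in seq_len(ncol(counts))) {
      total <- total + lgamma(alpha_jk + counts[j, k]) - lgamma(alpha_jk)
    }
  }
  total
}

# Acyclicity oracle via igraph.
igraph_is_dag <- function(parents) {
  edges <- do.call(rbind, lapply(seq_along(parents), function(i) {
    if (length(parents[[i]])) cbind(parents[[i]], i) else NULL
  }))
  if (is.null(edges)) return(TRUE)
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  igraph::is_dag(g)
}

# Enumerated marginal distribution of one variable by exhaustive summation
# of the joint over the full state space.
enumerated_marginal <- function(bn, var) {
  states <- bnbag:::enumerate_states(bn$arities)
  p <- exp(bn_logprob(bn, states))
  vapply(seq_len(bn$arities[var]), function(k) sum(p[states[, var] == k]),
         numeric(1))
}

# Brute-force best DAG over full enumeration, scoring each family directly.
brute_force_best <- function(x, config, weights = NULL) {
  dags <- enumerate_dags(ncol(x))
  scores <- vapply(dags, function(p) bn_score(x, p, config, weights),
                   numeric(1))
  list(parents = dags[[which.max(scores)]], score = max(scores))
}
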