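# Decomposable scoring metrics over weighted sufficient statistics.
#
# Every metric consumes only the weighted family counts N_ijk (mass of cases
# in which child i takes state k and its parents take joint configuration
# j), so a single code path serves the original data (unit weights), the
# ordinary bootstrap (integer multinomial weights) and the Bayesian
# bootstrap (continuous Dirichlet weights).

#' Scoring-metric configuration
#'
#' All metrics are returned as log-scores with the "higher is better"
#' convention (the penalized-likelihood metrics BIC and MDL are negated
#' accordingly).
#'
#' \describe{
#'   \item{K2 (UPSM)}{Bayesian-Dirichlet marginal likelihood with uniform
#'     prior counts \eqn{\alpha_{ijk} = 1}.}
#'   \item{DPSM}{the same with constant prior count
#'     \eqn{\alpha_{ijk} = \lambda}; small \eqn{\lambda} (default 0.1) is
#'     deliberately promiscuous, which works well under bagging.}
#'   \item{BDe}{likelihood-equivalent variant with
#'     \eqn{\alpha_{ijk} = N'/(r_i q_i)} where \eqn{N'} is the equivalent
#'     sample size.}
#'   \item{BIC}{maximized log-likelihood minus \eqn{(d/2)\log N} with
#'     \eqn{d = \sum_i (r_i - 1) q_i} free parameters.}
#'   \item{MDL}{negated total description length of graph, parameters and
#'     data (see the methods vignette for the adopted encoding).}
#' }
#'
#' @param metric one of \code{"DPSM"}, \code{"K2"}, \code{"BDe"},
#'   \code{"BIC"}, \code{"MDL"}.
#' @param lambda Dirichlet prior count for DPSM (> 0).
#' @param ess equivalent sample size \eqn{N'} for BDe (> 0).
#' @return a list of class \code{"bn_score_config"}.
#' @export
score_config <- function(metric = c("DPSM", "K2", "BDe", "BIC", "MDL"),
                         lambda = 0.1, ess = 1) {
  metric <- match.arg(metric)
  if (lambda <= 0) stop("lambda must be positive")
  if (ess <= 0) stop("ess must be positive")
  structure(list(metric = metric, lambda = lambda, ess = ess),
            class = "bn_score_config")
}

#' Weighted family sufficient statistics
#'
#' Computes the \eqn{q \times r} matrix of weighted counts
#' \eqn{N_{ijk} = \sum_{cases} w_r [X_i = k, U_i = j]} for one
#' child-parents family. Parent configurations are indexed in mixed-radix
#' order with the lowest-indexed parent varying fastest (the same
#' convention as the CPTs in [bn_network()]).
#'
#' @param x integer state matrix (see [as_bn_data()]).
#' @param child child variable index.
#' @param parents integer vector of parent indices (excluding the child).
#' @param weights nonnegative case weights; defaults to unit weights.
#' @param arities arities; taken from \code{attr(x, "arities")} by default.
#' @return a list of class \code{"family_counts"} with elements
#'   \code{counts} (\eqn{q \times r} matrix), \code{nij} (row sums),
#'   \code{child}, \code{parents}, \code{n_vars}, \code{N} (total weight
#'   mass).
#' @export
family_counts <- function(x, child, parents = integer(0), weights = NULL,
                          arities = NULL) {
  arities <- as.integer(arities %||% attr(x, "arities") %||% apply(x, 2, max))
  if (child %in% parents) stop("parents must exclude the child")
  weights <- weights %||% rep.int(1, nrow(x))
  parents <- sort(as.integer(parents))
  r <- arities[child]
  q <- if (length(parents)) prod(arities[parents]) else 1L
  j0 <- parent_config_index(x, parents, arities) - 1L
  cell <- j0 * r + x[, child]
  cnt <- numeric(q * r)
  s <- rowsum(weights, cell)
  cnt[as.integer(rownames(s))] <- s
  counts <- matrix(cnt, nrow = q, ncol = r, byrow = TRUE)
  structure(list(counts = counts, nij = rowSums(counts), child = child,
                 parents = parents, n_vars = ncol(x), N = sum(weights)),
            class = "family_counts")
}

#' Log-score of a single family
#'
#' @param fc a \code{family_counts} object.
#' @param config a [score_config()].
#' @return the family's contribution to the network log-score (higher is
#'   better for every metric).
#' @export
family_log_score <- function(fc, config = score_config()) {
  family_score_kernel(as.vector(t(fc$counts)), nrow(fc$counts),
                      ncol(fc$counts), length(fc$parents), fc$N, fc$n_vars,
                      config$metric, config$lambda, config$ess)
}

# Shared scoring kernel. `cnt` is the q*r count vector grouped by parent
# configuration (the r child states of configuration j are contiguous).
family_score_kernel <- function(cnt, q, r, n_parents, N, n_vars,
                                metric, lambda, ess) {
  if (metric == "K2" || metric == "DPSM" || metric == "BDe") {
    alpha <- if (metric == "K2") 1
             else if (metric == "DPSM") lambda
             else ess / (r * q)
    nij <- .colSums(cnt, r, q)
    # sum_j [ lgamma(r*alpha) - lgamma(r*alpha + N_ij) ]
    #   + sum_jk [ lgamma(alpha + N_ijk) - lgamma(alpha) ]
    q * lgamma(r * alpha) - sum(lgamma(r * alpha + nij)) +
      sum(lgamma(alpha + cnt)) - q * r * lgamma(alpha)
  } else {
    nij <- .colSums(cnt, r, q)
    pos <- cnt > 0
    nij_rep <- rep(nij, each = r)
    ll <- sum(cnt[pos] * log(cnt[pos] / nij_rep[pos])) # x log x -> 0 at 0
    d <- (r - 1) * q
    if (metric == "BIC") {
      ll - d / 2 * log(N)
    } else { # MDL: -(DL(G) + DL(Theta) + DL(D|G,Theta))
      dl_graph <- n_parents * log2(n_vars)
      dl_theta <- 0.5 * log2(N) * d
      dl_data <- -ll / log(2)
      -(dl_graph + dl_theta + dl_data)
    }
  }
}

#' Log-score of a network structure
#'
#' All five metrics are decomposable: the network score is the sum of the
#' family scores, so local search can rescore a single family per move.
#'
#' @param x integer state matrix.
#' @param structure a \code{bn} object or parents list (must be acyclic).
#' @param config a [score_config()].
#' @param weights optional case weights.
#' @param arities optional arities override.
#' @return total log-score (higher is better).
#' @export
bn_score <- function(x, structure, config = score_config(), weights = NULL,
                     arities = NULL) {
  parents <- if (inherits(structure, "bn")) structure$parents else structure
  topological_order(parents)
  sum(vapply(seq_along(parents), function(i) {
    family_log_score(family_counts(x, i, parents[[i]], weights, arities),
                     config)
  }, numeric(1)))
}

#' Number of free parameters of a structure
#'
#' \eqn{d = \sum_i (r_i - 1) q_i}: each family contributes one free
#' probability fewer than the child's arity for every parent configuration.
#'
#' @param structure a \code{bn} or parents list.
#' @param arities arities (taken from the \code{bn} if omitted).
#' @export
free_parameters <- function(structure, arities = NULL) {
  if (inherits(structure, "bn")) {
    arities <- structure$arities
    structure <- structure$parents
  }
  arities <- as.integer(arities)
  sum(vapply(seq_along(structure), function(i) {
    (arities[i] - 1) * prod(arities[structure[[i]]])
  }, numeric(1)))
}

# Memoizing family scorer bound to one (data, weights, config) context.
# Returned closure maps (child, parent vector) -> family log-score,
# computing each family at most once (the cache lives in the compiled
# search context, shared with the hill-climb inner loop). This cache is
# what makes rescoring during search incremental.
make_scorer <- function(x, config, weights = NULL, arities = NULL) {
  arities <- as.integer(arities %||% attr(x, "arities") %||% apply(x, 2, max))
  weights <- as.numeric(weights %||% rep.int(1, nrow(x)))
  code <- match(config$metric, c("K2", "DPSM", "BDe", "BIC", "MDL")) - 1L
  ctx <- .cpp_ctx_new(x, arities, weights, code, config$lambda, config$ess)
  f <- function(child, parents) {
    .cpp_family_score(ctx, child, as.integer(parents))
  }
  attr(f, "arities") <- arities
  attr(f, "ctx") <- ctx
  f
}
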