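# Generators for ground-truth networks, emulating the statistical shape of
# the classic discrete benchmarks (tens of nodes, 2-4 states per node) so
# the whole pipeline is testable without external downloads.

#' Generate a random ground-truth Bayesian network
#'
#' Draws a uniformly random topological order, adds the requested number of
#' edges uniformly among the slots compatible with the order and the
#' parent limit, and fills every CPT row with a draw from a symmetric
#' Dirichlet. Small concentrations (\code{alpha} well below 1) give
#' near-deterministic dependencies that are learnable from a few hundred
#' cases; \code{alpha = 1} gives uniform random rows.
#'
#' @param n_nodes number of variables.
#' @param n_edges number of directed edges; an error is raised when this
#'   exceeds what \code{max_parents} admits.
#' @param max_parents parent limit per node.
#' @param arities integer vector (recycled) or range sampled from
#'   \code{2:4} by default.
#' @param alpha symmetric Dirichlet concentration for CPT rows.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a \code{bn} with CPTs.
#' @examples
#' bn <- random_bn(6, n_edges = 6, seed = 42)
#' topological_order(bn)
#' @export
random_bn <- function(n_nodes, n_edges, max_parents = 4, arities = NULL,
                      alpha = 0.5, seed = 1) {
  with_seed(seed, {
    if (is.null(arities)) {
      arities <- sample(2:4, n_nodes, replace = TRUE)
    } else {
      arities <- rep_len(as.integer(arities), n_nodes)
    }
    ord <- sample.int(n_nodes)                 # ord[pos] = variable at pos
    pos <- match(seq_len(n_nodes), ord)        # pos[var] = position
    # admissible slots: (parent, child) with pos[parent] < pos[child]
    slots <- which(outer(pos, pos, `<`), arr.ind = TRUE)
    colnames(slots) <- c("parent", "child")
    cap <- sum(pmin(pos - 1, max_parents))     # capacity given the order
    if (n_edges > cap) {
      stop(sprintf("requested %d edges but at most %d are feasible", n_edges, cap))
    }
    parents <- rep(list(integer(0)), n_nodes)
    avail <- slots[sample.int(nrow(slots)), , drop = FALSE]
    added <- 0L
    for (e in seq_len(nrow(avail))) {
      if (added == n_edges) break
      ch <- avail[e, "child"]
      if (length(parents[[ch]]) >= max_parents) next
      parents[[ch]] <- sort.int(c(parents[[ch]], avail[e, "parent"]))
      added <- added + 1L
    }
    if (added < n_edges) {
      stop("could not place all edges under the parent limit; lower n_edges")
    }
    cpts <- lapply(seq_len(n_nodes), function(i) {
      q <- prod(arities[parents[[i]]])
      r <- arities[i]
      g <- matrix(stats::rgamma(q * r, shape = alpha), q, r)
      g / rowSums(g)
    })
    bn_network(arities, parents, cpts = cpts)
  })
}

#' Built-in benchmark networks
#'
#' A fixed suite of seeded ground-truth networks used throughout the tests
#' and examples:
#' \describe{
#'   \item{chain4}{4 binary variables in a chain X1 -> X2 -> X3 -> X4, each
#'     child copying its parent with probability 0.9.}
#'   \item{tree8}{8 variables (2-3 states) in a random tree (7 edges),
#'     near-deterministic CPTs.}
#'   \item{alarm_like_37}{a statistical look-alike of the classic 37-node
#'     medical-monitoring benchmark: 37 nodes, 46 edges, 2-4 states per
#'     node. The real benchmark's probabilities are not reproduced; supply
#'     the published network as a BIF file for exact comparisons.}
#' }
#' The same networks ship as BIF files under
#' \code{system.file("extdata", package = "bnbag")}; regenerating from the
#' recorded seeds reproduces those files exactly.
#'
#' @return named list of \code{bn} objects.
#' @export
benchmark_suite <- function() {
  chain4 <- bn_network(
    arities = c(2, 2, 2, 2),
    parents = list(integer(0), 1L, 2L, 3L),
    cpts = list(
      matrix(c(0.5, 0.5), 1),
      rbind(c(0.9, 0.1), c(0.1, 0.9)),
      rbind(c(0.9, 0.1), c(0.1, 0.9)),
      rbind(c(0.9, 0.1), c(0.1, 0.9))
    ))
  tree8 <- random_tree_bn(8, arities = c(2, 3), alpha = 0.25, seed = 208)
  alarm_like <- random_bn(37, n_edges = 46, max_parents = 3,
                          alpha = 0.35, seed = 3746)
  list(chain4 = chain4, tree8 = tree8, alarm_like_37 = alarm_like)
}

# Random tree-structured network: node i > 1 gets one parent among 1..i-1.
random_tree_bn <- function(n_nodes, arities = 2, alpha = 0.5, seed = 1) {
  with_seed(seed, {
    arities <- rep_len(as.integer(arities), n_nodes)
    parents <- c(list(integer(0)),
                 lapply(2:n_nodes, function(i) sample.int(i - 1L, 1L)))
    cpts <- lapply(seq_len(n_nodes), function(i) {
      q <- prod(arities[parents[[i]]])
      r <- arities[i]
      g <- matrix(stats::rgamma(q * r, shape = alpha), q, r)
      g / rowSums(g)
    })
    bn_network(arities, parents, cpts = cpts)
  })
}
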