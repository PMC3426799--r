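# Greedy hill-climbing with randomized restarts inside the sparse-candidate
# framework. Every structure visited during a search run is recorded in a
# global (per-run) visited set keyed by its canonical edge set, and no
# structure is ever rescored.

#' Search configuration
#'
#' @param k maximum number of parents per node and size of each node's
#'   candidate parent set.
#' @param c_rounds maximum number of candidate-set re-selection rounds per
#'   restart; re-selection also stops when a previously seen candidate set
#'   recurs.
#' @param m1 number of first-phase restarts (from random structures with at
#'   most two edges).
#' @param m2 number of second-phase restarts (from structures chosen at
#'   random among all those visited during the first phase).
#' @param retain number of distinct top-scoring networks reported.
#' @param seed integer seed making the whole search reproducible.
#' @export
search_config <- function(k = 6, c_rounds = 10, m1 = 25, m2 = 25,
                          retain = 10, seed = NULL) {
  stopifnot(k >= 1, c_rounds >= 1, m1 >= 1, m2 >= 1, retain >= 1)
  structure(list(k = as.integer(k), c_rounds = as.integer(c_rounds),
                 m1 = as.integer(m1), m2 = as.integer(m2),
                 retain = as.integer(retain), seed = seed),
            class = "bn_search_config")
}

# All legal single-move neighbors of `parents`, in deterministic order:
# child index, then move type (add < delete < reverse), then parent index.
# Each move is returned as list(parents = <new list>, changed = <children
# whose family changed>).
structure_neighbors <- function(parents, candidates, k) {
  n <- length(parents)
  out <- list()
  for (i in seq_len(n)) {
    pi <- parents[[i]]
    # additions
    if (length(pi) < k) {
      for (j in setdiff(candidates[[i]], pi)) {
        if (j == i) next
        new <- parents
        new[[i]] <- sort.int(c(pi, j))
        if (is_acyclic(new)) out[[length(out) + 1L]] <-
            list(parents = new, changed = i)
      }
    }
    # deletions (always acyclic)
    for (j in pi) {
      new <- parents
      new[[i]] <- setdiff(pi, j)
      out[[length(out) + 1L]] <- list(parents = new, changed = i)
    }
    # reversals: j -> i becomes i -> j
    for (j in pi) {
      if (!(i %in% candidates[[j]]) || length(parents[[j]]) >= k) next
      new <- parents
      new[[i]] <- setdiff(pi, j)
      new[[j]] <- sort.int(c(parents[[j]], i))
      if (is_acyclic(new)) out[[length(out) + 1L]] <-
          list(parents = new, changed = c(i, j))
    }
  }
  out
}

# Random structure with 0, 1 or 2 edges drawn from the candidate-respecting
# edge list (uniform over the edge count, then over edges; cycles between a
# pair are excluded by construction).
random_start <- function(candidates, n) {
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(candidates[[i]])) cbind(candidates[[i]], i) else NULL
  }))
  parents <- rep(list(integer(0)), n)
  if (is.null(edges) || !nrow(edges)) return(parents)
  ne <- sample.int(3L, 1L) - 1L
  ne <- min(ne, nrow(edges))
  if (ne > 0) {
    pick <- edges[sample.int(nrow(edges), ne), , drop = FALSE]
    for (e in seq_len(nrow(pick))) {
      p <- pick[e, 1]; ch <- pick[e, 2]
      if (p %in% parents[[ch]] || ch %in% parents[[p]]) next # skip 2-cycles
      parents[[ch]] <- sort.int(c(parents[[ch]], p))
    }
  }
  parents
}

#' Sparse-candidate greedy search for a high-scoring network
#'
#' Runs \code{m1} greedy hill-climbing searches started from random
#' structures with at most two edges, then \code{m2} further searches
#' started from structures chosen at random among everything visited during
#' the first phase. Within each restart, candidate parent sets are
#' re-selected after each local optimum (up to \code{c_rounds} times, or
#' until a previously seen candidate set recurs). No structure is ever
#' scored twice: a global visited set keyed by the canonical edge set is
#' shared across all restarts.
#'
#' @param data discrete data (anything accepted by [as_bn_data()]).
#' @param config a [score_config()].
#' @param search a [search_config()].
#' @param weights optional nonnegative case weights (bootstrap resamples are
#'   expressed this way).
#' @param arities optional arities override.
#' @return an object of class \code{"bn_search"}: list with \code{networks}
#'   (parents lists of the distinct top structures, best first),
#'   \code{scores}, \code{n_visited}, and the \code{names}/\code{arities}
#'   of the variables.
#' @examples
#' bn <- benchmark_suite()$chain4
#' x <- simulate(bn, nsim = 200, seed = 7)
#' fit <- bn_search(x, score_config("DPSM", lambda = 1),
#'                  search_config(m1 = 4, m2 = 4, seed = 1))
#' fit$scores[1]
#' @export
bn_search <- function(data, config = score_config(),
                      search = search_config(), weights = NULL,
                      arities = NULL) {
  x <- as_bn_data(data, arities = arities)
  if (is.null(search$seed)) bn_search_core(x, config, search, weights)
  else with_seed(search$seed, bn_search_core(x, config, search, weights))
}

# Search engine on canonical data; uses the current RNG state. The family
# scorer, visited set and hill-climb inner loop live in compiled code
# behind a per-run search context.
bn_search_core <- function(x, config, search, weights = NULL) {
  n <- ncol(x)
  k <- min(search$k, n - 1L)
  scorer <- make_scorer(x, config, weights)
  ctx <- attr(scorer, "ctx")
  empty <- rep(list(integer(0)), n)
  init_cand <- .cpp_select_candidates(ctx, empty, k)

  run_restart <- function(start) {
    cand <- .cpp_select_candidates(ctx, start, k)
    seen_cand <- struct_key(cand)
    cur <- start
    for (round in seq_len(search$c_rounds)) {
      res <- .cpp_hill_climb(ctx, cur, cand, k)
      cur <- res$parents
      cand <- .cpp_select_candidates(ctx, cur, k)
      ck <- struct_key(cand)
      if (ck %in% seen_cand) break
      seen_cand <- c(seen_cand, ck)
    }
  }

  for (m in seq_len(search$m1)) run_restart(random_start(init_cand, n))
  n_phase1 <- .cpp_visited_n(ctx)
  for (m in seq_len(search$m2)) {
    idx <- sample.int(n_phase1, 1L)
    run_restart(.cpp_visited_get(ctx, idx))
  }

  top <- .cpp_top_networks(ctx, search$retain)
  structure(
    list(networks = top$networks,
         scores = top$scores,
         n_visited = .cpp_visited_n(ctx),
         names = colnames(x), arities = attr(x, "arities"),
         config = config, search = search),
    class = "bn_search")
}

#' @export
print.bn_search <- function(x, ...) {
  cat(sprintf("Sparse-candidate search: %d structures visited\n", x$n_visited))
  cat(sprintf("Top score (%s): %.4f; %d networks retained\n",
              x$config$metric, x$scores[1], length(x$scores)))
  invisible(x)
}
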