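#' Bootstrap model averaging (bagging) of Bayesian-network edges
#'
#' The central fitting function of the package. For each of \code{B}
#' bootstrap resamples (ordinary multinomial or Bayesian Dirichlet case
#' weights), a high-scoring network is learned by sparse-candidate greedy
#' hill-climbing with randomized restarts, and the occurrence of every
#' directed edge is recorded. Averaging these indicators across resamples
#' yields the posterior probability of each edge feature; thresholding the
#' undirected sum (the probability that an edge is present in either
#' direction) gives the final consensus structure, most usefully via
#' [bn_permtest()].
#'
#' Three aggregation modes are available. \code{"single_best"} uses the
#' indicator features of the single best network of each resample (the
#' recommended default: averaging more networks per resample buys little
#' once the resample count is adequate). \code{"double_simple"} averages
#' indicators over the \code{top_m} distinct highest-scoring networks of
#' each resample; \code{"double_bayesian"} weights those networks in
#' proportion to \eqn{\exp(\mathrm{score})}, normalized within the resample.
#'
#' Reproducibility: resample \eqn{b} runs under a child seed derived
#' deterministically from \code{seed} and \eqn{b}, so results are invariant
#' to execution order.
#'
#' @param data discrete data: a data frame of factors, an integer state
#'   matrix, or the output of [simulate.bn()].
#' @param metric,lambda,ess scoring metric (see [score_config()]). The
#'   default, DPSM with \eqn{\lambda = 0.1}, is the configuration that
#'   performs best with Bayesian bagging on limited data.
#' @param bootstrap \code{"bayesian"} (default) or \code{"ordinary"}.
#' @param B number of bootstrap resamples (default 2500; see
#'   [required_resamples()] for the rationale — reduce for quick looks).
#' @param mode \code{"single_best"}, \code{"double_simple"} or
#'   \code{"double_bayesian"}.
#' @param top_m networks retained per resample for the double modes.
#' @param k,c_rounds,m1,m2 search parameters (see [search_config()]).
#' @param seed root seed for the whole run.
#' @param arities optional arities override.
#' @return an object of class \code{"bn_bag"} with components
#'   \code{edge_prob} (symmetric matrix of undirected edge probabilities),
#'   \code{dir_freq} (matrix of directed frequencies,
#'   \code{dir_freq[a, b]} = bagged frequency of the edge a -> b),
#'   \code{B}, \code{config}, \code{search}, \code{bootstrap}, \code{mode},
#'   \code{names}, \code{call}.
#' @examples
#' bn <- benchmark_suite()$chain4
#' x <- simulate(bn, nsim = 250, seed = 11)
#' fit <- bn_bag(x, B = 20, m1 = 3, m2 = 3, seed = 1)
#' fit
#' coef(fit)[1:3, ]
#' @seealso [bn_permtest()] for automatic threshold selection,
#'   [bn_eval()] for evaluation against a known network.
#' @export
bn_bag <- function(data, metric = "DPSM", lambda = 0.1, ess = 1,
                   bootstrap = c("bayesian", "ordinary"), B = 2500,
                   mode = c("single_best", "double_simple", "double_bayesian"),
                   top_m = 10, k = 6, c_rounds = 10, m1 = 25, m2 = 25,
                   seed = 1, arities = NULL) {
  bootstrap <- match.arg(bootstrap)
  mode <- match.arg(mode)
  stopifnot(B >= 1, top_m >= 1)
  x <- as_bn_data(data, arities = arities)
  n <- ncol(x)
  config <- score_config(metric, lambda = lambda, ess = ess)
  retain <- if (mode == "single_best") 1L else as.integer(top_m)
  scfg <- search_config(k = k, c_rounds = c_rounds, m1 = m1, m2 = m2,
                        retain = retain)

  dir_freq <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (b in seq_len(B)) {
    sb <- child_seed(seed, b)
    contrib <- with_seed(sb, {
      w <- bootstrap_weights(nrow(x), bootstrap)
      res <- bn_search_core(x, config, scfg, weights = w)
      resample_edge_features(res, mode, top_m, n)
    })
    dir_freq <- dir_freq + contrib
  }
  dir_freq <- dir_freq / B
  edge_prob <- dir_freq + t(dir_freq)

  structure(
    list(edge_prob = edge_prob, dir_freq = dir_freq, B = as.integer(B),
         config = config, search = scfg, bootstrap = bootstrap, mode = mode,
         top_m = as.integer(top_m), seed = seed, n_cases = nrow(x),
         names = colnames(x), arities = attr(x, "arities"),
         call = match.call()),
    class = "bn_bag")
}

# Directed-edge feature probabilities contributed by one resample.
resample_edge_features <- function(res, mode, top_m, n) {
  if (mode == "single_best") {
    return(parents_to_adjacency(res$networks[[1]]))
  }
  m <- min(top_m, length(res$networks))
  wts <- if (mode == "double_simple") {
    rep(1 / m, m)
  } else {
    s <- res$scores[seq_len(m)]
    w <- exp(s - max(s))
    w / sum(w)
  }
  a <- matrix(0, n, n)
  for (t in seq_len(m)) {
    a <- a + wts[t] * parents_to_adjacency(res$networks[[t]])
  }
  a
}

#' @export
print.bn_bag <- function(x, digits = 3, ...) {
  cat(sprintf("Bagged Bayesian-network edge probabilities (%s bootstrap, %s)\n",
              x$bootstrap, x$mode))
  cat(sprintf("  %d variables, %d cases, B = %d resamples, metric %s%s\n",
              length(x$names), x$n_cases, x$B, x$config$metric,
              if (x$config$metric == "DPSM")
                sprintf(" (lambda = %g)", x$config$lambda) else ""))
  ce <- coef(x)
  cat(sprintf("  edges with probability >= 0.5: %d (max %.*f)\n",
              sum(ce$prob >= 0.5), digits, max(ce$prob)))
  invisible(x)
}

#' Bagged edge probabilities as a ranked edge table
#'
#' @param object a \code{bn_bag} fit.
#' @param ... unused.
#' @return data frame with columns \code{from}, \code{to}, \code{prob}
#'   (undirected probability), \code{fwd}, \code{rev} (per-direction
#'   frequencies), sorted by decreasing probability.
#' @export
coef.bn_bag <- function(object, ...) {
  n <- length(object$names)
  idx <- which(upper.tri(object$edge_prob), arr.ind = TRUE)
  out <- data.frame(
    from = object$names[idx[, 1]], to = object$names[idx[, 2]],
    prob = object$edge_prob[idx],
    fwd = object$dir_freq[idx],
    rev = t(object$dir_freq)[idx],
    stringsAsFactors = FALSE)
  out[order(-out$prob, out$from, out$to), , drop = FALSE]
}

#' @export
summary.bn_bag <- function(object, threshold = 0.5, ...) {
  ce <- coef(object)
  structure(list(fit = object, edges = ce[ce$prob >= threshold, ],
                 threshold = threshold),
            class = "summary.bn_bag")
}

#' @export
print.summary.bn_bag <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nEdges with bagged probability >= %.2f:\n", x$threshold))
  if (nrow(x$edges)) {
    print(x$edges, row.names = FALSE, digits = 3)
  } else cat("  (none)\n")
  invisible(x)
}

#' Plot a bagged-edge fit
#'
#' Shows the sorted undirected edge probabilities (the "scree" of edge
#' support); most probabilities sit near 0 or 1, which is what makes
#' thresholding meaningful.
#'
#' @param x a \code{bn_bag} fit.
#' @param threshold optional threshold drawn as a horizontal line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bn_bag <- function(x, threshold = NULL, ...) {
  p <- sort(coef(x)$prob, decreasing = TRUE)
  graphics::plot(seq_along(p), p, type = "h", xlab = "edge rank",
                 ylab = "bagged edge probability", ylim = c(0, 1), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Consensus structure at a fixed threshold
#'
#' @param object a \code{bn_bag} fit.
#' @param threshold include every undirected edge with bagged probability
#'   \code{>= threshold}; each is oriented by its more frequent direction.
#' @return a structure-only \code{bn} object.
#' @export
consensus_network <- function(object, threshold = 0.5) {
  n <- length(object$names)
  parents <- rep(list(integer(0)), n)
  idx <- which(upper.tri(object$edge_prob) &
                 object$edge_prob >= threshold, arr.ind = TRUE)
  if (nrow(idx)) {
    for (e in seq_len(nrow(idx))) {
      a <- idx[e, 1]; b <- idx[e, 2]
      if (object$dir_freq[a, b] >= object$dir_freq[b, a]) {
        parents[[b]] <- sort.int(c(parents[[b]], a))
      } else {
        parents[[a]] <- sort.int(c(parents[[a]], b))
      }
    }
  }
  # orientation by majority direction can in principle create cycles;
  # break them by dropping one edge on each cycle
  while (!is_acyclic(parents)) {
    sk <- vapply(seq_len(n), function(i) length(parents[[i]]) > 0, logical(1))
    done <- FALSE
    for (i in which(sk)) {
      for (p in parents[[i]]) {
        trial <- parents
        trial[[i]] <- setdiff(parents[[i]], p)
        if (is_acyclic(trial)) { parents <- trial; done <- TRUE; break }
      }
      if (done) break
    }
    if (!done) break
  }
  bn_network(object$arities, parents, names = object$names)
}
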