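# Evaluation of learned edge probabilities against a known reference
# network. All comparisons are on the undirected skeleton: an edge is
# called present at threshold t when the sum of its bagged probabilities in
# both directions is >= t. The >= convention is applied everywhere.

#' Edge confusion counts at one threshold
#'
#' Classifies every unordered variable pair: a pair with probability
#' \code{>= t} is a true positive if the reference skeleton contains the
#' edge and a false positive otherwise; a pair below \code{t} is a false
#' negative if the reference contains it, else a true negative.
#'
#' @param P a \code{bn_bag} fit or a symmetric edge-probability matrix.
#' @param reference reference network: \code{bn}, parents list, or
#'   symmetric adjacency matrix.
#' @param t threshold in \eqn{[0,1]}.
#' @return named vector \code{c(TP, FP, FN, TN)}.
#' @export
edge_confusion <- function(P, reference, t) {
  P <- as_edge_matrix(P)
  ref <- as_skeleton(reference, nrow(P))
  if (!all(dim(ref) == dim(P))) stop("variable sets differ")
  up <- upper.tri(P)
  pred <- P[up] >= t
  truth <- ref[up] > 0
  c(TP = sum(pred & truth), FP = sum(pred & !truth),
    FN = sum(!pred & truth), TN = sum(!pred & !truth))
}

as_edge_matrix <- function(P) {
  if (inherits(P, "bn_bag")) P$edge_prob
  else if (is.matrix(P)) P
  else stop("P must be a bn_bag fit or a matrix")
}

as_skeleton <- function(reference, n) {
  if (is.matrix(reference)) reference else skeleton_adjacency(reference)
}

#' False-positive/false-negative tradeoff curve
#'
#' Evaluates [edge_confusion()] over a grid of thresholds. Lower curves are
#' better: for a fixed number of false positives, fewer true edges are
#' missed.
#'
#' @inheritParams edge_confusion
#' @param grid threshold grid (default 0 to 1 in steps of 0.01).
#' @return data frame of class \code{"bn_eval"} with columns
#'   \code{threshold, TP, FP, FN, TN, total} (total = FP + FN).
#' @export
bn_eval <- function(P, reference, grid = seq(0, 1, 0.01)) {
  rows <- t(vapply(grid, function(t) edge_confusion(P, reference, t),
                   numeric(4)))
  out <- data.frame(threshold = grid, rows)
  out$total <- out$FP + out$FN
  class(out) <- c("bn_eval", "data.frame")
  out
}

#' @export
plot.bn_eval <- function(x, which = c("tradeoff", "total"), ...) {
  which <- match.arg(which)
  if (which == "tradeoff") {
    graphics::plot(x$FP, x$FN, type = "b", xlab = "false positives",
                   ylab = "false negatives", ...)
  } else {
    graphics::plot(x$threshold, x$total, type = "l",
                   xlab = "threshold", ylab = "total errors (FP + FN)", ...)
  }
  invisible(x)
}

#' Replicated simulation experiment
#'
#' Draws \code{n_datasets} independent datasets from a ground-truth
#' network, runs [bn_bag()] on each under one or more configurations, and
#' averages the resulting evaluation curves pointwise across datasets —
#' the protocol used to compare scoring metrics and bagging variants on
#' benchmark networks.
#'
#' @param truth a \code{bn} with CPTs (ground truth).
#' @param n_datasets number of independent datasets.
#' @param n_cases cases per dataset.
#' @param configs named list of argument lists for [bn_bag()]; each entry
#'   is one configuration to compare.
#' @param grid evaluation threshold grid.
#' @param seed root seed. Dataset \eqn{d} is drawn and analysed under
#'   deterministically derived child seeds; a manifest of all child seeds
#'   is returned.
#' @return list of class \code{"bn_experiment"}: \code{curves} (named list
#'   of averaged \code{bn_eval} data frames), \code{per_dataset} (list of
#'   lists of individual curves), \code{seeds} (manifest).
#' @export
replicate_experiment <- function(truth, n_datasets, n_cases, configs,
                                 grid = seq(0, 1, 0.01), seed = 1) {
  stopifnot(n_datasets >= 1)
  if (is.null(names(configs))) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  ref <- skeleton_adjacency(truth)
  per <- vector("list", n_datasets)
  manifest <- data.frame(dataset = integer(0), data_seed = integer(0),
                         bag_seed = integer(0))
  for (d in seq_len(n_datasets)) {
    ds <- child_seed(seed, d, stream = 10)
    bs <- child_seed(seed, d, stream = 11)
    manifest <- rbind(manifest,
                      data.frame(dataset = d, data_seed = ds, bag_seed = bs))
    x <- simulate(truth, nsim = n_cases, seed = ds)
    per[[d]] <- lapply(configs, function(cf) {
      fit <- do.call(bn_bag, c(list(data = x, seed = bs), cf))
      bn_eval(fit, ref, grid)
    })
  }
  avg <- lapply(names(configs), function(nm) {
    mats <- lapply(per, function(p) as.matrix(p[[nm]][, -1]))
    m <- Reduce(`+`, mats) / n_datasets
    out <- data.frame(threshold = grid, m)
    class(out) <- c("bn_eval", "data.frame")
    out
  })
  names(avg) <- names(configs)
  structure(list(curves = avg, per_dataset = per, seeds = manifest,
                 n_datasets = n_datasets, n_cases = n_cases),
            class = "bn_experiment")
}

#' @export
print.bn_experiment <- function(x, ...) {
  cat(sprintf("Replicated experiment: %d datasets x %d cases\n",
              x$n_datasets, x$n_cases))
  for (nm in names(x$curves)) {
    cat(sprintf("  %-16s min total errors %.2f\n", nm,
                min(x$curves[[nm]]$total)))
  }
  invisible(x)
}
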