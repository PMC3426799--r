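# Permutation-based selection of the edge-inclusion threshold.
#
# Bagging a randomly permuted copy of the data (all columns shuffled
# independently, destroying every dependence while preserving marginals)
# yields edge frequencies for data known to contain no real edges. The
# number of permuted-data edges above a threshold is therefore a
# conservative estimate of the number of incorrect edges above that
# threshold in the unpermuted analysis.

# Number of undirected edges with bagged probability >= each grid value.
count_edges_at <- function(edge_prob, grid) {
  p <- edge_prob[upper.tri(edge_prob)]
  vapply(grid, function(f) sum(p >= f), numeric(1))
}

#' Edge confidence from observed and null edge-count curves
#'
#' At edge frequency \eqn{f}, the confidence that an edge appearing at that
#' frequency is real is estimated from the slopes of the total edge count
#' \eqn{t_f} and the permutation-null edge count \eqn{p_f}:
#' \deqn{L_f^{raw} = 1 - \Delta p_f / \Delta t_f,}
#' the fraction of edges accruing at frequency \eqn{f} not attributable to
#' the null. Neither curve is smooth, so each slope is the average of
#' centered finite differences over a range of widths. Raw values are
#' clipped to \eqn{[0,1]} (with confidence 0 where \eqn{\Delta t_f = 0})
#' and the isotonic upper envelope is applied so the confidence never
#' increases as the threshold decreases.
#'
#' @param t_curve,p_curve edge counts on the common threshold grid
#'   (unpermuted data and permutation-null average respectively).
#' @param grid increasing threshold grid in \eqn{[0,1]}.
#' @param widths smoothing widths (in threshold units) over which finite
#'   differences are averaged.
#' @return numeric vector of confidences \eqn{L_f} on the grid.
#' @examples
#' g <- seq(0, 1, 0.01)
#' edge_confidence(2 * (1 - g) * 100, (1 - g)^2 * 100, g)[c(21, 51, 81)]
#' @export
edge_confidence <- function(t_curve, p_curve, grid,
                            widths = c(0.02, 0.04, 0.06, 0.08, 0.10)) {
  if (length(t_curve) != length(grid) || length(p_curve) != length(grid)) {
    stop("curves and grid lengths differ")
  }
  ng <- length(grid)
  step <- if (ng > 1) grid[2] - grid[1] else 1
  # Above the top of the grid no edge can appear, so both curves are
  # extended with 0 there (an edge at frequency exactly 1 accrues at the
  # grid top); below the bottom they are constant.
  slope <- function(curve, i, h) {
    lo <- max(1L, i - h)
    hi <- i + h
    lo_f <- grid[lo]; lo_v <- curve[lo]
    if (hi <= ng) { hi_f <- grid[hi]; hi_v <- curve[hi] }
    else { hi_f <- grid[i] + h * step; hi_v <- 0 }
    if (hi_f == lo_f) return(0)
    (lo_v - hi_v) / (hi_f - lo_f) # >= 0: curves are non-increasing
  }
  raw <- numeric(ng)
  hs <- pmax(1L, as.integer(round(widths / step)))
  for (i in seq_len(ng)) {
    st <- mean(vapply(hs, function(h) slope(t_curve, i, h), numeric(1)))
    sp <- mean(vapply(hs, function(h) slope(p_curve, i, h), numeric(1)))
    raw[i] <- if (st <= 0) 0 else 1 - sp / st
  }
  raw <- pmin(1, pmax(0, raw))
  cummax(raw) # upper envelope: monotone non-decreasing in f
}

#' Permutation-null edge-count curve
#'
#' Bags each of \code{n_perm} independently permuted copies of the data and
#' averages, over permutations, the number of edges at or above every grid
#' threshold.
#'
#' @param data discrete data.
#' @param n_perm number of permutations (60 in the reference protocol;
#'   reduce for quick looks).
#' @param grid threshold grid.
#' @param seed root seed (permutation \eqn{j} uses a derived child seed).
#' @param ... arguments passed on to [bn_bag()] (metric, B, search
#'   parameters, bootstrap type).
#' @return list with \code{p_curve} (mean counts), \code{per_perm} (matrix
#'   of per-permutation counts, one column per permutation).
#' @export
permutation_null_curve <- function(data, n_perm = 60,
                                   grid = seq(0, 1, 0.01), seed = 1, ...) {
  stopifnot(n_perm >= 1)
  x <- as_bn_data(data)
  counts <- matrix(0, length(grid), n_perm)
  for (j in seq_len(n_perm)) {
    sj <- child_seed(seed, j, stream = 1)
    xp <- permute_data(x, seed = sj)
    fit <- bn_bag(xp, seed = child_seed(seed, j, stream = 2), ...)
    counts[, j] <- count_edges_at(fit$edge_prob, grid)
  }
  list(p_curve = rowMeans(counts), per_perm = counts)
}

#' Automatic threshold selection by permutation testing
#'
#' Fits (or reuses) a bagged model on the original data, estimates the
#' null edge-count curve from column-permuted copies, derives the edge
#' confidence \eqn{L_f} via [edge_confidence()], and selects the smallest
#' threshold whose confidence reaches \code{target}. Edges at or above the
#' selected threshold form the consensus edge set, each annotated with the
#' confidence at its own frequency.
#'
#' @param data discrete data.
#' @param fit optional \code{bn_bag} fit of \code{data} to reuse; when
#'   omitted one is fitted with the \code{...} arguments and
#'   \code{seed}.
#' @param n_perm number of data permutations.
#' @param target target edge confidence (default 0.9).
#' @param grid threshold grid (default 0 to 1 in steps of 0.01).
#' @param widths slope-smoothing widths for [edge_confidence()].
#' @param perm_B optional reduced resample count for the permutation runs
#'   (a cost knob; the permutation bagging otherwise reuses the same
#'   settings as the main fit).
#' @param seed root seed.
#' @param ... passed to [bn_bag()].
#' @return object of class \code{"bn_permtest"}: \code{curves} data frame
#'   (\code{threshold}, \code{t_f}, \code{p_f}, \code{d_f}, \code{L_f}),
#'   \code{threshold} (selected, or \code{NA} if no threshold attains the
#'   target), \code{consensus} edge data frame, \code{target},
#'   \code{fit}.
#' @examples
#' \donttest{
#' bn <- benchmark_suite()$chain4
#' x <- simulate(bn, nsim = 300, seed = 5)
#' pt <- bn_permtest(x, n_perm = 3, B = 25, m1 = 3, m2 = 3, seed = 1)
#' pt$threshold
#' }
#' @export
bn_permtest <- function(data, fit = NULL, n_perm = 60, target = 0.9,
                        grid = seq(0, 1, 0.01),
                        widths = c(0.02, 0.04, 0.06, 0.08, 0.10),
                        perm_B = NULL, seed = 1, ...) {
  stopifnot(target > 0, target <= 1)
  x <- as_bn_data(data)
  if (is.null(fit)) fit <- bn_bag(x, seed = child_seed(seed, 0), ...)
  args <- list(...)
  if (!is.null(perm_B)) args$B <- perm_B
  t_curve <- count_edges_at(fit$edge_prob, grid)
  null <- do.call(permutation_null_curve,
                  c(list(data = x, n_perm = n_perm, grid = grid,
                         seed = seed), args))
  p_curve <- null$p_curve
  L <- edge_confidence(t_curve, p_curve, grid, widths)

  ok <- which(L >= target & grid > 0)
  threshold <- if (length(ok)) grid[min(ok)] else NA_real_
  ce <- coef(fit)
  if (!is.na(threshold)) {
    cons <- ce[ce$prob >= threshold, , drop = FALSE]
    # confidence at each edge's own frequency: step function on the grid
    conf_at <- function(p) L[max(which(grid <= p))]
    cons$confidence <- vapply(cons$prob, conf_at, numeric(1))
  } else {
    cons <- ce[0, , drop = FALSE]
    cons$confidence <- numeric(0)
  }
  structure(
    list(curves = data.frame(threshold = grid, t_f = t_curve, p_f = p_curve,
                             d_f = t_curve - p_curve, L_f = L),
         threshold = threshold, consensus = cons, target = target,
         n_perm = n_perm, per_perm = null$per_perm, fit = fit,
         reduced_perm_B = !is.null(perm_B)),
    class = "bn_permtest")
}

#' @export
print.bn_permtest <- function(x, ...) {
  cat(sprintf("Permutation threshold selection (%d permutations%s)\n",
              x$n_perm,
              if (x$reduced_perm_B) ", reduced permutation B" else ""))
  if (is.na(x$threshold)) {
    cat(sprintf("  no threshold attains edge confidence %.2f; consensus is empty\n",
                x$target))
  } else {
    cat(sprintf("  selected threshold %.2f (target confidence %.2f)\n",
                x$threshold, x$target))
    cat(sprintf("  consensus edges: %d\n", nrow(x$consensus)))
  }
  invisible(x)
}

#' Plot threshold-selection curves
#'
#' Draws the total edge count, the permutation-null count, their difference
#' and (on the right axis) the edge confidence \eqn{L_f} as functions of
#' the threshold.
#'
#' @param x a \code{bn_permtest} object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.bn_permtest <- function(x, ...) {
  cv <- x$curves
  graphics::matplot(cv$threshold, cbind(cv$t_f, cv$p_f, pmax(cv$d_f, 0)),
                    type = "l", lty = 1, col = c("blue", "red", "orange"),
                    xlab = "edge frequency threshold",
                    ylab = "number of edges", ...)
  graphics::par(new = TRUE)
  graphics::plot(cv$threshold, cv$L_f, type = "l", col = "darkgreen",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("edge confidence", side = 4, line = 2)
  if (!is.na(x$threshold)) graphics::abline(v = x$threshold, lty = 2)
  graphics::legend("topright",
                   c("total edges", "null edges", "difference", "confidence"),
                   lty = c(1, 1, 1, 1),
                   col = c("blue", "red", "orange", "darkgreen"), bty = "n")
  invisible(x)
}
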