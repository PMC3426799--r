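#' Construct a discrete Bayesian network
#'
#' A Bayesian network over discrete variables is a directed acyclic graph
#' (DAG) together with one conditional probability table (CPT) per variable.
#' The joint distribution factorizes as the product of the conditionals
#' \eqn{P(X_1,\dots,X_n) = \prod_i P(X_i \mid U_i)} where \eqn{U_i} are the
#' parents of \eqn{X_i}.
#'
#' CPTs are stored as \eqn{q_i \times r_i} matrices: one row per joint parent
#' configuration (\eqn{q_i} = product of parent arities), one column per child
#' state. Parent configurations are indexed in mixed-radix order with the
#' lowest-indexed parent varying fastest; the same convention is used by the
#' scoring functions so sufficient statistics and CPTs always line up.
#'
#' @param arities integer vector of state counts \eqn{r_i \ge 2}, one per
#'   variable.
#' @param parents list of integer vectors, \code{parents[[i]]} giving the
#'   indices of the parents of variable \code{i}. Stored sorted.
#' @param cpts optional list of CPT matrices (\eqn{q_i \times r_i}, rows
#'   summing to 1). A network without CPTs is a bare structure and can be
#'   scored or evaluated but not sampled from.
#' @param names optional character vector of variable names.
#' @param levels optional list of state-label vectors, \code{levels[[i]]} of
#'   length \code{arities[i]}. Labels map to state indices by position.
#' @return an object of class \code{"bn"}.
#' @examples
#' # X -> Y, both binary, Y copies X with probability 0.9
#' bn <- bn_network(
#'   arities = c(2, 2), parents = list(integer(), 1L),
#'   cpts = list(matrix(c(0.5, 0.5), 1), rbind(c(0.9, 0.1), c(0.1, 0.9)))
#' )
#' simulate(bn, nsim = 5, seed = 1)
#' @seealso [simulate.bn()], [bn_logprob()], [read_bif()], [random_bn()]
#' @export
bn_network <- function(arities, parents, cpts = NULL, names = NULL,
                       levels = NULL) {
  n <- length(arities)
  arities <- as.integer(arities)
  if (any(arities < 2)) stop("every variable needs arity >= 2")
  if (length(parents) != n) stop("parents list length must match arities")
  parents <- lapply(parents, function(p) sort(as.integer(p)))
  if (is.null(names)) names <- paste0("X", seq_len(n))
  if (anyDuplicated(names)) stop("variable names must be unique")
  if (is.null(levels)) {
    levels <- lapply(arities, function(r) paste0("s", seq_len(r)))
  }
  if (any(lengths(levels) != arities)) {
    stop("state label count must equal arity for every variable")
  }
  obj <- structure(
    list(arities = arities, parents = parents, cpts = cpts,
         names = names, levels = levels),
    class = "bn"
  )
  validate_bn(obj)
  obj
}

#' @export
print.bn <- function(x, ...) {
  n <- length(x$arities)
  ne <- sum(lengths(x$parents))
  cat(sprintf("Discrete Bayesian network: %d variables, %d edges%s\n",
              n, ne, if (is.null(x$cpts)) " (structure only)" else ""))
  cat(sprintf("Arities: %s\n", paste(x$arities, collapse = " ")))
  invisible(x)
}

# Validates structural and distributional invariants; stops on violation.
validate_bn <- function(bn, tol = 1e-9) {
  n <- length(bn$arities)
  for (i in seq_len(n)) {
    p <- bn$parents[[i]]
    if (any(p == i)) stop(sprintf("variable %d is its own parent", i))
    if (length(p) && (any(p < 1) || any(p > n))) {
      stop(sprintf("invalid parent index for variable %d", i))
    }
  }
  topological_order(bn$parents) # raises on cycles
  if (!is.null(bn$cpts)) {
    if (length(bn$cpts) != n) stop("need one CPT per variable")
    for (i in seq_len(n)) {
      cpt <- bn$cpts[[i]]
      q <- prod(bn$arities[bn$parents[[i]]])
      if (nrow(cpt) != q || ncol(cpt) != bn$arities[i]) {
        stop(sprintf("CPT %d must be %d x %d", i, q, bn$arities[i]))
      }
      if (any(cpt < -tol) || any(cpt > 1 + tol)) {
        stop(sprintf("CPT %d has entries outside [0,1]", i))
      }
      if (any(abs(rowSums(cpt) - 1) > tol)) {
        stop(sprintf("CPT %d rows must sum to 1", i))
      }
    }
  }
  invisible(bn)
}

#' Topological ordering of a DAG
#'
#' Kahn's algorithm. Raises an error naming an edge on a cycle if the graph
#' is not acyclic; every other function in the package relies on this check.
#'
#' @param structure a \code{bn} object or a parents list.
#' @return integer vector ordering the variables so that every variable
#'   appears after all of its parents.
#' @export
topological_order <- function(structure) {
  parents <- if (inherits(structure, "bn")) structure$parents else structure
  n <- length(parents)
  indeg <- lengths(parents)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[[i]]) {
    children[[p]] <- c(children[[p]], i)
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    i <- left[1]
    p <- intersect(parents[[i]], left)[1]
    stop(sprintf("graph contains a cycle (through edge %d -> %d)", p, i))
  }
  out
}

# TRUE iff the parents list describes a DAG.
is_acyclic <- function(parents) {
  !inherits(try(topological_order(parents), silent = TRUE), "try-error")
}

# Mixed-radix parent-configuration index, 1-based; lowest-indexed parent
# varies fastest. `x` is an N x n integer state matrix (states 1..r_i).
parent_config_index <- function(x, parents, arities) {
  if (!length(parents)) return(rep.int(1L, nrow(x)))
  radix <- cumprod(c(1, arities[parents][-length(parents)]))
  as.integer(1 + (x[, parents, drop = FALSE] - 1) %*% radix)
}

#' Forward (ancestral) sampling from a Bayesian network
#'
#' Draws i.i.d. cases by sampling each variable in topological order
#' conditional on its already-sampled parents.
#'
#' @param object a \code{bn} with CPTs.
#' @param nsim number of cases to draw.
#' @param seed optional integer; if given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#' @param ... unused.
#' @return integer matrix (\code{nsim} rows, states coded 1..\eqn{r_i}) with
#'   variable names as column names and the state labels attached as the
#'   \code{"levels"} attribute.
#' @export
simulate.bn <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$cpts)) stop("network has no CPTs; cannot sample")
  draw <- function() {
    n <- length(object$arities)
    x <- matrix(0L, nsim, n, dimnames = list(NULL, object$names))
    for (i in topological_order(object$parents)) {
      cpt <- object$cpts[[i]]
      cfg <- parent_config_index(x, object$parents[[i]], object$arities)
      cum <- t(apply(cpt, 1, cumsum))
      u <- stats::runif(nsim)
      k <- 1L + rowSums(u > cum[cfg, , drop = FALSE])
      x[, i] <- pmin.int(k, object$arities[i])
    }
    attr(x, "levels") <- object$levels
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Joint log-probability of complete cases under a network
#'
#' @param bn a \code{bn} with CPTs.
#' @param x integer state matrix (or single row) with one column per
#'   variable; every entry must be a valid state index.
#' @return numeric vector of log joint probabilities, \code{-Inf} where a
#'   zero-probability CPT entry is hit.
#' @export
bn_logprob <- function(bn, x) {
  if (is.null(bn$cpts)) stop("network has no CPTs")
  if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1)
  n <- length(bn$arities)
  if (ncol(x) != n) stop("assignment must cover every variable")
  if (anyNA(x)) stop("incomplete assignment: missing values")
  for (i in seq_len(n)) {
    if (any(x[, i] < 1 | x[, i] > bn$arities[i])) {
      stop(sprintf("state out of range for variable %d", i))
    }
  }
  lp <- numeric(nrow(x))
  for (i in seq_len(n)) {
    cfg <- parent_config_index(x, bn$parents[[i]], bn$arities)
    lp <- lp + log(bn$cpts[[i]][cbind(cfg, x[, i])])
  }
  lp
}

# Enumerate the full state space as an integer matrix (small networks only;
# used by tests and exact-posterior oracles).
enumerate_states <- function(arities) {
  m <- as.matrix(expand.grid(lapply(arities, seq_len)))
  dimnames(m) <- NULL
  m
}
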