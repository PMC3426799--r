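#' Coerce a data set to the internal discrete representation
#'
#' Accepts a data frame of factors/characters/integers or an integer matrix
#' and returns an integer state matrix (states coded 1..\eqn{r_i}) with
#' variable names and state labels attached. Missing values are rejected:
#' all methods in this package assume complete data.
#'
#' @param data data frame or matrix of categorical observations.
#' @param bn optional \code{bn}; when given, columns are matched to the
#'   network's variables by name and labels are mapped to state indices by
#'   the network's declaration order.
#' @param arities optional integer vector overriding the inferred arities
#'   (useful when some states are unobserved in a small sample).
#' @return integer matrix with attributes \code{"levels"} (state labels) and
#'   \code{"arities"}.
#' @export
as_bn_data <- function(data, bn = NULL, arities = NULL) {
  if (anyNA(data)) stop("missing values are not supported (complete data required)")
  if (!is.null(bn)) {
    if (is.null(colnames(data)) && ncol(data) == length(bn$names)) {
      colnames(data) <- bn$names
    }
    if (!all(bn$names %in% colnames(data))) {
      stop("data columns do not match network variables")
    }
    data <- data[, bn$names, drop = FALSE]
    n <- ncol(data)
    x <- matrix(0L, nrow(data), n, dimnames = list(NULL, bn$names))
    for (i in seq_len(n)) {
      col <- data[, i]
      if (is.numeric(col) && all(col == as.integer(col))) {
        xi <- as.integer(col)
      } else {
        xi <- match(as.character(col), bn$levels[[i]])
        if (anyNA(xi)) stop(sprintf("unknown state label in column %s", bn$names[i]))
      }
      if (any(xi < 1 | xi > bn$arities[i])) {
        stop(sprintf("state out of range in column %s", bn$names[i]))
      }
      x[, i] <- xi
    }
    attr(x, "levels") <- bn$levels
    attr(x, "arities") <- bn$arities
    return(x)
  }
  if (is.matrix(data) && is.numeric(data)) {
    x <- data
    storage.mode(x) <- "integer"
    levs <- attr(data, "levels")
  } else {
    data <- as.data.frame(data)
    levs <- vector("list", ncol(data))
    x <- matrix(0L, nrow(data), ncol(data),
                dimnames = list(NULL, colnames(data)))
    for (i in seq_len(ncol(data))) {
      f <- factor(data[[i]])
      levs[[i]] <- levels(f)
      x[, i] <- as.integer(f)
    }
  }
  if (any(x < 1)) stop("states must be coded 1..r_i")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ar <- as.integer(arities %||% apply(x, 2, max))
  ar <- pmax(ar, 2L)
  attr(x, "levels") <- levs
  attr(x, "arities") <- ar
  x
}

#' Read a delimited table of discrete observations
#'
#' Thin wrapper over [utils::read.csv()]/[utils::read.delim()] followed by
#' [as_bn_data()]. The file must have a header row of variable names; states
#' may be labels (mapped via \code{bn} if given, otherwise by sorted factor
#' order) or 1-based integers.
#'
#' @param file path to a CSV or TSV file.
#' @param bn optional \code{bn} fixing the variable order and label mapping.
#' @param sep field separator; guessed from the file extension by default.
#' @inheritParams as_bn_data
#' @export
read_discrete_table <- function(file, bn = NULL, arities = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.tsv$|\\.txt$", file)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_bn_data(df, bn = bn, arities = arities)
}

#' Independently permute each column of a data set
#'
#' The permutation null used for threshold selection: every column's values
#' are shuffled independently, preserving each variable's marginal
#' distribution exactly while destroying all inter-variable dependence.
#'
#' @param x integer state matrix (see [as_bn_data()]).
#' @param seed optional seed for a reproducible permutation.
#' @return a matrix of the same shape and attributes.
#' @export
permute_data <- function(x, seed = NULL) {
  doit <- function() {
    out <- x
    for (i in seq_len(ncol(x))) out[, i] <- x[sample.int(nrow(x)), i]
    out
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}
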