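# BIF (Bayesian Interchange Format) reader and writer.
#
# Supports the common discrete subset: `variable` blocks declaring a
# discrete type with a state list, and `probability` blocks giving either a
# `table` row (no parents, or a flattened table) or one row per parent
# configuration written as "( state, state ) p1, p2, ...;". Parent
# configuration rows may appear in any order; states map to indices by
# declaration order in the variable block.

parse_numbers <- function(s) {
  z <- strsplit(trimws(s), "[,[:space:]]+")[[1]]
  as.numeric(z[nzchar(z)])
}

#' Read a discrete Bayesian network from a BIF file
#'
#' @param file path to a BIF file.
#' @return a \code{bn} object with CPTs.
#' @seealso [write_bif()]
#' @export
read_bif <- function(file) {
  txt <- paste(readLines(file, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)           # strip line comments
  names <- character(0); levels <- list()
  var_pat <- "variable\\s+([A-Za-z0-9_.-]+)\\s*\\{[^{]*type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}\\s*;?[^}]*\\}"
  m <- gregexpr(var_pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("no variable blocks found in BIF file")
  for (s in regmatches(txt, list(m))[[1]]) {
    parts <- regmatches(s, regexec(var_pat, s, perl = TRUE))[[1]]
    names <- c(names, parts[2])
    labs <- trimws(strsplit(parts[4], ",")[[1]])
    if (length(labs) != as.integer(parts[3])) {
      stop(sprintf("state count mismatch for variable %s", parts[2]))
    }
    levels <- c(levels, list(labs))
  }
  n <- length(names)
  arities <- lengths(levels)
  parents <- rep(list(integer(0)), n)
  cpts <- vector("list", n)

  prob_pat <- "probability\\s*\\(\\s*([A-Za-z0-9_.-]+)\\s*(\\|([^)]*))?\\)\\s*\\{([^}]*)\\}"
  pm <- gregexpr(prob_pat, txt, perl = TRUE)[[1]]
  if (pm[1] == -1) stop("no probability blocks found in BIF file")
  for (s in regmatches(txt, list(pm))[[1]]) {
    parts <- regmatches(s, regexec(prob_pat, s, perl = TRUE))[[1]]
    child <- match(parts[2], names)
    if (is.na(child)) stop(sprintf("probability block for unknown variable %s", parts[2]))
    pnames <- if (nzchar(trimws(parts[4]))) {
      trimws(strsplit(parts[4], ",")[[1]])
    } else character(0)
    pidx <- match(pnames, names)
    if (anyNA(pidx)) stop("unknown parent name in probability block")
    parents[[child]] <- sort(pidx)
    r <- arities[child]
    q <- prod(arities[parents[[child]]])
    cpt <- matrix(NA_real_, q, r)
    body <- parts[5]
    if (length(pidx) == 0 || grepl("\\btable\\b", body)) {
      nums <- parse_numbers(gsub("table|;", " ", body))
      if (length(nums) != q * r) stop("table length mismatch in BIF probability block")
      cpt[] <- matrix(nums, q, r, byrow = TRUE)
    } else {
      row_pat <- "\\(([^)]*)\\)\\s*([^;]*);"
      rm_ <- gregexpr(row_pat, body, perl = TRUE)[[1]]
      for (rs in regmatches(body, list(rm_))[[1]]) {
        rp <- regmatches(rs, regexec(row_pat, rs, perl = TRUE))[[1]]
        states <- trimws(strsplit(rp[2], ",")[[1]])
        # states are listed in the declared parent order; map to sorted order
        si <- integer(length(pidx))
        for (a in seq_along(pidx)) {
          si[a] <- match(states[a], levels[[pidx[a]]])
          if (is.na(si[a])) stop("unknown parent state label in BIF row")
        }
        ord <- order(pidx)
        sp <- sort(pidx)
        s_sorted <- si[ord]
        radix <- cumprod(c(1, arities[sp][-length(sp)]))
        j <- as.integer(1 + sum((s_sorted - 1) * radix))
        nums <- parse_numbers(rp[3])
        if (length(nums) != r) stop("probability row length mismatch")
        cpt[j, ] <- nums
      }
      if (anyNA(cpt)) stop("missing parent configurations in BIF probability block")
    }
    cpts[[child]] <- cpt
  }
  for (i in seq_len(n)) {
    if (is.null(cpts[[i]])) stop(sprintf("no probability block for variable %s", names[i]))
  }
  bn_network(arities, parents, cpts = cpts, names = names, levels = levels)
}

#' Write a Bayesian network to a BIF file
#'
#' Probabilities are written with 17 significant digits so a write/read
#' round trip reproduces the network bit-exactly.
#'
#' @param bn a \code{bn} with CPTs.
#' @param file output path (or \code{""} for stdout).
#' @param name network name recorded in the header.
#' @return the path, invisibly.
#' @export
write_bif <- function(bn, file, name = "network") {
  if (is.null(bn$cpts)) stop("network has no CPTs; nothing to write")
  fmt <- function(p) {
    s <- formatC(p, format = "g", digits = 17)
    sub("^\\s+", "", s)
  }
  out <- c(sprintf("network %s {", name), "}")
  n <- length(bn$arities)
  for (i in seq_len(n)) {
    out <- c(out,
      sprintf("variable %s {", bn$names[i]),
      sprintf("  type discrete [ %d ] { %s };", bn$arities[i],
              paste(bn$levels[[i]], collapse = ", ")),
      "}")
  }
  for (i in seq_len(n)) {
    p <- bn$parents[[i]]
    cpt <- bn$cpts[[i]]
    if (!length(p)) {
      out <- c(out,
        sprintf("probability ( %s ) {", bn$names[i]),
        sprintf("  table %s;", paste(fmt(cpt[1, ]), collapse = ", ")),
        "}")
    } else {
      hdr <- sprintf("probability ( %s | %s ) {", bn$names[i],
                     paste(bn$names[p], collapse = ", "))
      rows <- character(nrow(cpt))
      radix <- cumprod(c(1, bn$arities[p][-length(p)]))
      for (j in seq_len(nrow(cpt))) {
        states <- ((j - 1) %/% radix) %% bn$arities[p] + 1
        labs <- mapply(function(v, s) bn$levels[[v]][s], p, states)
        rows[j] <- sprintf("  ( %s ) %s;", paste(labs, collapse = ", "),
                           paste(fmt(cpt[j, ]), collapse = ", "))
      }
      out <- c(out, hdr, rows, "}")
    }
  }
  writeLines(out, file)
  invisible(file)
}
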