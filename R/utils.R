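# Internal helpers: reproducible seeding and structure hashing.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed for resample/restart/permutation streams.
# Arithmetic kept in doubles (< 2^53) and reduced below 2^31.
child_seed <- function(seed, index, stream = 0) {
  s <- (as.double(seed) %% 2147483647) * 1000003 +
    as.double(index) * 7919 + as.double(stream) * 104729
  as.integer(s %% 2147483629) + 1L
}

# Canonical key of a structure's edge set (parents stored sorted).
struct_key <- function(parents) {
  paste(vapply(seq_along(parents), function(i) {
    paste0(i, "<", paste(parents[[i]], collapse = ","))
  }, character(1)), collapse = ";")
}

# Directed adjacency matrix (a[parent, child] = 1) from a parents list.
parents_to_adjacency <- function(parents) {
  n <- length(parents)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) a[parents[[i]], i] <- 1
  a
}

# Undirected skeleton adjacency from a parents list or bn object.
skeleton_adjacency <- function(structure) {
  parents <- if (inherits(structure, "bn")) structure$parents else structure
  a <- parents_to_adjacency(parents)
  s <- a + t(a)
  s[s > 1] <- 1
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Insert value j into the sorted integer vector v (no duplicates expected).
insert_sorted <- function(v, j) {
  c(v[v < j], j, v[v > j])
}
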