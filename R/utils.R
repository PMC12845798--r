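# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_domain(...)
  invisible(TRUE)
}

# Map a function over every array leaf of a nested parameter list.
tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(x) tree_map(f, x)))
  f(tree)
}

# Zip two identically-shaped parameter trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

tree_leaves <- function(tree) {
  if (!is.list(tree)) return(list(tree))
  do.call(c, lapply(tree, tree_leaves))
}

n_params <- function(tree) sum(vapply(tree_leaves(tree), length, integer(1)))

sigmoid <- function(x) 1 / (1 + exp(-x))
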