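# Fixtures are built in code; nothing is read from disk.

# Integer-valued HU-like random slice: integer values make difference
# arithmetic exact, so offset/rotation invariances hold bit-for-bit.
rand_hu_slice <- function(n, seed) {
  set.seed(seed)
  matrix(as.numeric(sample(-1000:400, n * n, replace = TRUE)), n, n)
}

# Naive per-pixel riu2 code map assembled from the scalar building blocks
# (circular sampling -> thresholded code -> riu2 mapping); the oracle for
# the vectorized code-map route.
naive_codemap <- function(slice, config) {
  m <- config$margin
  nr <- nrow(slice); nc <- ncol(slice)
  out <- matrix(NA_integer_, nr - 2 * m, nc - 2 * m)
  for (r in (m + 1):(nr - m))
    for (c in (m + 1):(nc - m))
      out[r - m, c - m] <- riu2_map(lbp_code(slice, c(r, c), config), config$P)
  out
}

# Small linearly separable 2-feature toy set (8 points).
toy_separable <- function() {
  list(X = cbind(c(-4, -3, -2, -1, 1, 2, 3, 4),
                 c(0.3, -0.2, 0.5, -0.4, 0.1, -0.3, 0.2, -0.1)),
       y = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
}

# Feature-level dataset for search/evaluate tests: class-informative
# features without any image processing, so LOOCV loops stay fast.
feature_dataset <- function(n_per_class = 10, d = 5, shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + shift * y
  o <- sample.int(n)
  list(features = X[o, , drop = FALSE], labels = y[o])
}

# Shared phantom study set + feature cache for the end-to-end tests: built
# once per test run, reused across test files to avoid re-featurizing.
study_env <- new.env(parent = emptyenv())
study_dataset <- function() {
  if (is.null(study_env$ds))
    study_env$ds <- generate_dataset(phantom_spec(n_per_class = 20, seed = 42))
  study_env$ds
}
study_cache <- function() {
  if (is.null(study_env$cache))
    study_env$cache <- new.env(parent = emptyenv())
  study_env$cache
}

# Tree-walk assertions: every fitted tree respects the depth cap, the
# hessian floor on split-created leaves, and the positive-gain rule.
check_tree_constraints <- function(model) {
  pars <- model$params
  for (tree in model$trees) {
    depth_ok <- all(tree[, "depth"] <= pars$max_depth)
    internal <- tree[, "feature"] != 0
    gain_ok <- all(tree[internal, "gain"] > 0)
    leaves <- which(!internal)
    hess_ok <- all(vapply(leaves, function(i) {
      if (i == 1) TRUE  # an unsplit root is not bound by the child floor
      else tree[i, "hess_sum"] >= pars$min_child_weight
    }, logical(1)))
    if (!(depth_ok && gain_ok && hess_ok)) return(FALSE)
  }
  TRUE
}
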