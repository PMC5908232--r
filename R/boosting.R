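#' Gradient-tree-boosting hyperparameters
#'
#' The four tunable controls span the search ranges used for optimization:
#' `eta` (shrinkage) in `[0.2, 0.6]`, `max_depth` in `[1, 13]`,
#' `min_child_weight` (floor on a child's hessian sum) in `[1, 10]`,
#' `gamma_split` (minimum loss reduction to split) in `[0, 1]`. The number of
#' boosting rounds and the L2 leaf penalty are held fixed outside the search
#' space so trials are comparable. `n_rounds = 0` is allowed so the
#' base-score-only ensemble is constructible.
#'
#' @param eta shrinkage applied to each tree's output.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_child_weight minimum hessian sum in each child of a split.
#' @param gamma_split minimum loss reduction required to make a split.
#' @param n_rounds number of trees.
#' @param lambda_reg L2 penalty on leaf weights.
#' @return An object of class `gtb_params`.
#' @export
gtb_params <- function(eta = 0.3, max_depth = 6, min_child_weight = 1,
                       gamma_split = 0, n_rounds = 50, lambda_reg = 1.0) {
  stopifnot(eta >= 0.2, eta <= 0.6,
            max_depth >= 1, max_depth <= 13,
            min_child_weight >= 0, min_child_weight <= 10,
            gamma_split >= 0, gamma_split <= 1,
            n_rounds >= 0, lambda_reg >= 0)
  structure(list(eta = eta, max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight,
                 gamma_split = gamma_split, n_rounds = as.integer(n_rounds),
                 lambda_reg = lambda_reg),
            class = "gtb_params")
}

#' Gradient and hessian of the logistic loss
#'
#' For binary logistic loss at margin `m` with `p = sigmoid(m)`:
#' `g = p - y`, `h = p (1 - p)`.
#'
#' @param labels 0/1 vector.
#' @param margins current additive-model margins (log-odds scale).
#' @return List with numeric vectors `g` and `h`.
#' @export
grad_hess <- function(labels, margins) {
  stopifnot(all(labels %in% c(0, 1)), all(is.finite(margins)),
            length(labels) == length(margins))
  p <- sigmoid(margins)
  list(g = p - labels, h = p * (1 - p))
}

#' Best split of a node by exact greedy search
#'
#' Scans all features and all midpoints between consecutive distinct sorted
#' values; returns the split maximizing
#' `1/2 [GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda)] - gamma_split`,
#' or `NULL` if no candidate has positive gain or every candidate violates
#' the `min_child_weight` floor. Ties go to the lowest feature index, then
#' the lowest threshold.
#'
#' @param features n x d numeric matrix of the node's instances.
#' @param g,h per-instance gradients and hessians.
#' @param params a [gtb_params()].
#' @return `NULL`, or a list with `feature` (1-based column), `threshold`
#'   and `gain`.
#' @export
gtb_best_split <- function(features, g, h, params) {
  stopifnot(inherits(params, "gtb_params"), nrow(features) >= 2)
  res <- gtb_best_split_cpp(features, g, h, params$lambda_reg,
                            params$gamma_split, params$min_child_weight)
  if (!res$found) return(NULL)
  res$found <- NULL
  res
}

#' Fit a gradient-tree-boosting classifier
#'
#' Trees are grown depth-first under the depth, hessian-floor and gain
#' constraints; leaf weights are `-G/(H + lambda)`; after each round the
#' margins advance by `eta` times the tree output. The base score is the
#' log-odds of the training prevalence. Fitting is deterministic (no row or
#' column subsampling); `seed` is accepted for interface symmetry but unused.
#'
#' @param features n x d numeric matrix.
#' @param labels 0/1 vector with both classes present.
#' @param params a [gtb_params()].
#' @param seed ignored (fit is deterministic).
#' @return An object of class `cadx_gtb` with elements `trees` (one node
#'   matrix per round), `base`, `params`, `train_loss` (per-round mean
#'   training log loss) and `d` (feature dimension).
#' @export
fit_gtb <- function(features, labels, params = gtb_params(), seed = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(inherits(params, "gtb_params"), nrow(features) >= 2,
            length(labels) == nrow(features))
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class; cannot fit")
  fit <- gtb_fit_cpp(features, labels, params$eta, params$max_depth,
                     params$min_child_weight, params$gamma_split,
                     params$n_rounds, params$lambda_reg)
  structure(list(trees = fit$trees, base = fit$base, params = params,
                 train_loss = fit$train_loss, d = ncol(features)),
            class = "cadx_gtb")
}

#' Predicted malignancy probabilities
#'
#' @param model a fitted classifier (`cadx_gtb` or `cadx_svm`).
#' @param features numeric matrix with the training feature dimension.
#' @return Probabilities of class 1, strictly inside (0, 1).
#' @export
predict_proba <- function(model, features) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.cadx_gtb <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$d)
    stop("feature dimension ", ncol(features), " does not match training (",
         model$d, ")")
  m <- gtb_margin_cpp(model$trees, model$base, model$params$eta, features)
  sigmoid(m)
}

#' @export
print.cadx_gtb <- function(x, ...) {
  cat(sprintf("<cadx_gtb> %d trees, eta %.2f, max_depth %d, final train loss %.4f\n",
              length(x$trees), x$params$eta, x$params$max_depth,
              if (length(x$train_loss)) x$train_loss[length(x$train_loss)] else NA))
  invisible(x)
}

#' Serialize a boosting model to JSON
#'
#' @param model a `cadx_gtb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
gtb_to_json <- function(model, path) {
  obj <- list(base = model$base,
              params = unclass(model$params),
              train_loss = model$train_loss,
              trees = lapply(model$trees, function(M)
                as.data.frame(M, check.names = FALSE)),
              d = model$d)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a boosting model written by [gtb_to_json()]
#'
#' @param path JSON path.
#' @return A `cadx_gtb`.
#' @export
gtb_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(obj$trees, function(df) as.matrix(df))
  p <- obj$params
  params <- gtb_params(p$eta, p$max_depth, p$min_child_weight, p$gamma_split,
                       p$n_rounds, p$lambda_reg)
  structure(list(trees = trees, base = obj$base, params = params,
                 train_loss = obj$train_loss, d = obj$d),
            class = "cadx_gtb")
}
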