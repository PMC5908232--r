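#' RBF-SVM hyperparameters
#'
#' @param C soft-margin trade-off, in `[1e-5, 1e5]`.
#' @param gamma_rbf RBF kernel bandwidth `exp(-gamma ||u - v||^2)`, in
#'   `[1e-5, 1e5]`.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(C = 1, gamma_rbf = 1) {
  stopifnot(C >= 1e-5, C <= 1e5, gamma_rbf >= 1e-5, gamma_rbf <= 1e5)
  structure(list(C = C, gamma_rbf = gamma_rbf), class = "svm_params")
}

# Platt-style sigmoid calibration: fit (A, B) minimizing the cross-entropy of
# p = sigmoid(-(A f + B)) against the prior-corrected targets, on TRAINING
# decision values only (never on validation folds).
#' @noRd
platt_fit <- function(decision, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  t <- ifelse(labels == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  obj <- function(ab) {
    z <- ab[1] * decision + ab[2]
    -sum(t * stats::plogis(-z, log.p = TRUE) +
           (1 - t) * stats::plogis(z, log.p = TRUE))
  }
  fit <- optim(c(-1, log((n0 + 1) / (n1 + 1))), obj, method = "BFGS",
               control = list(maxit = 200))
  list(A = fit$par[1], B = fit$par[2])
}

#' Fit an RBF-kernel soft-margin SVM with probabilistic outputs
#'
#' The dual problem is solved by libsvm (via e1071) to tolerance 1e-3 with no
#' feature scaling (scale sensitivity is part of the model's behaviour, and
#' deliberately exposed). Probabilities come from a Platt-style sigmoid
#' fitted here to the training decision values.
#'
#' @param features n x d numeric matrix.
#' @param labels 0/1 vector with both classes present.
#' @param params an [svm_params()].
#' @return An object of class `cadx_svm`.
#' @export
fit_svm <- function(features, labels, params = svm_params()) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(inherits(params, "svm_params"), length(labels) == nrow(features))
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class; cannot fit")
  m <- e1071::svm(x = features, y = factor(labels, levels = c(0, 1)),
                  type = "C-classification", kernel = "radial",
                  cost = params$C, gamma = params$gamma_rbf,
                  scale = FALSE, tolerance = 1e-3, probability = FALSE)
  dv <- decision_values_raw(m, features)
  # libsvm orients decision values toward the first class it encounters;
  # normalize so positive values favor class "1"
  flip <- if (identical(attr(dv, "pair"), "0/1")) -1 else 1
  cal <- platt_fit(flip * as.numeric(dv), labels)
  structure(list(svm = m, A = cal$A, B = cal$B, flip = flip,
                 params = params, d = ncol(features)),
            class = "cadx_svm")
}

#' @noRd
decision_values_raw <- function(svm_model, features) {
  pr <- predict(svm_model, features, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  structure(dv[, 1], pair = colnames(dv)[1])
}

#' SVM decision values, oriented so larger favors class 1
#'
#' @param model a `cadx_svm`.
#' @param features numeric matrix with the training feature dimension.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, features) {
  stopifnot(inherits(model, "cadx_svm"))
  features <- as.matrix(features)
  if (ncol(features) != model$d)
    stop("feature dimension ", ncol(features), " does not match training (",
         model$d, ")")
  model$flip * as.numeric(decision_values_raw(model$svm, features))
}

#' @rdname predict_proba
#' @export
predict_proba.cadx_svm <- function(model, features) {
  f <- decision_values(model, features)
  p <- stats::plogis(-(model$A * f + model$B))
  clip_prob(p, .Machine$double.xmin)
}

#' @rdname predict_proba
#' @export
predict_proba_svm <- function(model, features) predict_proba.cadx_svm(model, features)

#' @export
print.cadx_svm <- function(x, ...) {
  cat(sprintf("<cadx_svm> C %.3g, gamma %.3g, %d support vectors\n",
              x$params$C, x$params$gamma_rbf, nrow(x$svm$SV)))
  invisible(x)
}
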