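#' ROC AUC (Mann-Whitney form)
#'
#' AUC is the fraction of (positive, negative) pairs with the positive
#' scored higher, counting ties as half; computed via midranks, it equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param labels 0/1 vector containing both classes.
#' @param scores numeric scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a probability threshold
#'
#' @param labels 0/1 vector.
#' @param scores predicted probabilities.
#' @param threshold scores `>= threshold` predict class 1 (default 0.5).
#' @return Fraction of correct predictions.
#' @export
accuracy <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  mean(as.integer(scores >= threshold) == labels)
}

#' Points of the empirical ROC curve
#'
#' Sweeps the unique score values as thresholds (descending), yielding
#' `n_unique + 1` points from (0, 0) to (1, 1), monotone in both
#' coordinates.
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `fpr`, `tpr`.
#' @export
roc_curve_points <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), sum(labels) > 0, sum(1 - labels) > 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  data.frame(
    fpr = c(0, vapply(thr, function(t) mean(neg >= t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(pos >= t), numeric(1))))
}

#' @noRd
trapezoid_area <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Repeated hyperparameter search with LOOCV evaluation
#'
#' Runs the search `n_repeats` times (repeat r uses seed `base_seed + r`);
#' each repeat takes the best trial's held-out probabilities and computes
#' AUC and accuracy from them (no refit on the full data — the evaluated
#' predictions are exactly the cross-validated ones that defined the loss).
#'
#' @param algorithm `"svm"` or `"gtb"`.
#' @param dataset a `cadx_dataset` (or precomputed `features`/`labels` list).
#' @param n_trials trials per search.
#' @param search `"tpe"` or `"random"`.
#' @param n_repeats number of repeated searches to average over.
#' @param base_seed integer; repeat r is seeded with `base_seed + r`.
#' @param space search space (defaults to the algorithm's standard space).
#' @param K folds for the objective (`NULL` = leave-one-out).
#' @param cache feature-cache environment (created if `NULL`).
#' @return An object of class `repeat_summary`: `per_repeat` data.frame
#'   (seed, loss, auc, accuracy), their `means`, and metadata.
#' @export
run_experiment <- function(algorithm, dataset, n_trials,
                           search = c("tpe", "random"), n_repeats = 10,
                           base_seed = 0, space = NULL, K = NULL,
                           cache = NULL) {
  search <- match.arg(search)
  stopifnot(n_repeats >= 1, n_trials >= 1)
  if (is.null(space))
    space <- if (identical(algorithm, "svm")) svm_search_space()
             else gtb_search_space()
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  objective <- function(theta) cv_objective(algorithm, theta, dataset,
                                            K = K, cache = cache)
  runner <- if (search == "tpe") tpe_search else random_search
  rows <- vector("list", n_repeats)
  best_records <- vector("list", n_repeats)
  histories <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    hist <- runner(space, objective, n_trials, seed = base_seed + r)
    histories[[r]] <- hist
    best <- best_trial(hist)
    best_records[[r]] <- best
    rows[[r]] <- data.frame(repeat_index = r, seed = base_seed + r,
                            loss = best$loss,
                            auc = roc_auc(best$labels, best$probs),
                            accuracy = accuracy(best$labels, best$probs))
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(algorithm = algorithm, search = search,
                 n_trials = as.integer(n_trials),
                 per_repeat = per_repeat,
                 means = colMeans(per_repeat[, c("loss", "auc", "accuracy")]),
                 best_records = best_records, histories = histories),
            class = "repeat_summary")
}

#' Summary table in the layout of the study report
#'
#' One row per (algorithm, search, number of trials): mean validation loss,
#' AUC and accuracy over the repeats.
#'
#' @param object a `repeat_summary` (or list of them).
#' @param ... unused.
#' @return A `data.frame` with columns `algorithm`, `search`, `n_trials`,
#'   `validation_loss`, `auc`, `accuracy`.
#' @export
summary.repeat_summary <- function(object, ...) {
  data.frame(algorithm = object$algorithm, search = object$search,
             n_trials = object$n_trials,
             validation_loss = unname(object$means["loss"]),
             auc = unname(object$means["auc"]),
             accuracy = unname(object$means["accuracy"]))
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %s + %s search, %d trials x %d repeats\n",
              x$algorithm, x$search, x$n_trials, nrow(x$per_repeat)))
  cat(sprintf("  mean validation loss %.4f, mean AUC %.4f, mean accuracy %.4f\n",
              x$means["loss"], x$means["auc"], x$means["accuracy"]))
  invisible(x)
}

#' Write experiment results to disk
#'
#' JSON with per-repeat and mean loss/AUC/accuracy, a CSV table mirroring
#' the one-row-per-setting report layout, and the best repeat's ROC points
#' as CSV.
#'
#' @param results a `repeat_summary` or list of them.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (inherits(results, "repeat_summary")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    lapply(results, function(s) list(
      algorithm = s$algorithm, search = s$search, n_trials = s$n_trials,
      per_repeat = s$per_repeat, means = as.list(s$means))),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  tab <- do.call(rbind, lapply(results, summary))
  write.csv(tab, file.path(dir, "results_table.csv"), row.names = FALSE)
  best <- results[[1]]$best_records[[which.max(results[[1]]$per_repeat$auc)]]
  write.csv(roc_curve_points(best$labels, best$probs),
            file.path(dir, "roc_points.csv"), row.names = FALSE)
  invisible(dir)
}
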