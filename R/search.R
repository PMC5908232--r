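#' Hyperparameter search-space dimensions
#'
#' A search space is a named list of dimensions: continuous (optionally
#' log-uniform), uniform integer, or categorical. Priors are uniform on the
#' stated scale.
#'
#' @param name dimension name.
#' @param lower,upper range bounds.
#' @param log if `TRUE`, the prior (and the Parzen model) live in log space.
#' @param choices categorical values.
#' @return A dimension object of class `search_dim`.
#' @export
dim_uniform <- function(name, lower, upper, log = FALSE) {
  stopifnot(lower < upper, !log || lower > 0)
  structure(list(name = name, kind = "continuous", lower = lower,
                 upper = upper, log = log), class = "search_dim")
}

#' @rdname dim_uniform
#' @export
dim_integer <- function(name, lower, upper) {
  structure(list(name = name, kind = "integer", lower = as.integer(lower),
                 upper = as.integer(upper), log = FALSE), class = "search_dim")
}

#' @rdname dim_uniform
#' @export
dim_categorical <- function(name, choices) {
  structure(list(name = name, kind = "categorical", choices = choices),
            class = "search_dim")
}

#' Assemble a search space
#'
#' @param ... `search_dim` objects.
#' @return An object of class `search_space` (a named list of dimensions).
#' @export
search_space <- function(...) {
  dims <- list(...)
  stopifnot(all(vapply(dims, inherits, logical(1), "search_dim")))
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, class = "search_space")
}

#' Search space for the SVM pipeline
#'
#' `C` and `gamma_rbf` log-uniform over `[1e-5, 1e5]`; the texture
#' parameters `R` in `{7, 8}` and `P` in `{40, 48}` are searched jointly
#' with the classifier parameters.
#' @return A [search_space()].
#' @export
svm_search_space <- function() {
  search_space(dim_uniform("C", 1e-5, 1e5, log = TRUE),
               dim_uniform("gamma_rbf", 1e-5, 1e5, log = TRUE),
               dim_categorical("R", c(7, 8)),
               dim_categorical("P", c(40, 48)))
}

#' Search space for the gradient-tree-boosting pipeline
#'
#' `eta` uniform `[0.2, 0.6]`, `max_depth` integer `[1, 13]`,
#' `min_child_weight` integer `[1, 10]`, `gamma_split` uniform `[0, 1]`,
#' plus the texture parameters `R` in `{7, 8}` and `P` in `{40, 48}`.
#' @return A [search_space()].
#' @export
gtb_search_space <- function() {
  search_space(dim_uniform("eta", 0.2, 0.6),
               dim_integer("max_depth", 1, 13),
               dim_integer("min_child_weight", 1, 10),
               dim_uniform("gamma_split", 0, 1),
               dim_categorical("R", c(7, 8)),
               dim_categorical("P", c(40, 48)))
}

#' Draw one parameter point from the space prior
#'
#' @param space a [search_space()].
#' @return Named list theta; uses the current RNG stream.
#' @export
sample_space <- function(space) {
  theta <- lapply(space, function(d) {
    switch(d$kind,
      continuous = if (d$log) exp(runif(1, log(d$lower), log(d$upper)))
                   else runif(1, d$lower, d$upper),
      integer = sample(d$lower:d$upper, 1),
      categorical = d$choices[[sample.int(length(d$choices), 1)]])
  })
  theta
}

#' Is a parameter point inside the space?
#'
#' @param space a [search_space()].
#' @param theta named list.
#' @return Logical scalar.
#' @export
theta_in_space <- function(space, theta) {
  all(vapply(space, function(d) {
    v <- theta[[d$name]]
    if (is.null(v)) return(FALSE)
    switch(d$kind,
      continuous = v >= d$lower && v <= d$upper,
      integer = v >= d$lower && v <= d$upper && v == round(v),
      categorical = v %in% d$choices)
  }, logical(1)))
}

#' Deterministic stratified K folds
#'
#' Round-robin assignment within each class so every training set keeps both
#' classes whenever each class has at least 2 members.
#' @noRd
make_folds <- function(labels, K = NULL) {
  n <- length(labels)
  if (is.null(K) || K >= n) return(as.list(seq_len(n)))  # LOOCV
  fold <- integer(n)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- rep_len(seq_len(K), length(idx))
  }
  split(seq_len(n), fold)
}

#' Cross-validated black-box objective for one parameter point
#'
#' Features are (re)computed with theta's texture parameters `(R, P)`; for
#' each fold the classifier is trained on the remaining samples and the
#' held-out probabilities are recorded. The loss is the mean binary log loss
#' over all held-out predictions (probabilities clipped at
#' `[1e-15, 1 - 1e-15]`), with leave-one-out folds by default.
#'
#' @param algorithm `"svm"`, `"gtb"`, or a function
#'   `function(train_x, train_y, test_x, theta)` returning held-out
#'   probabilities (used for stubs in tests).
#' @param theta named parameter list. For `"svm"`: `C`, `gamma_rbf`; for
#'   `"gtb"`: `eta`, `max_depth`, `min_child_weight`, `gamma_split`; both
#'   take `R`, `P` when `dataset` holds patches.
#' @param dataset a `cadx_dataset` of patches, or a list with precomputed
#'   `features` and `labels`.
#' @param K number of folds (`NULL` = leave-one-out).
#' @param cache optional environment for feature memoization (see
#'   [featurize_dataset()]).
#' @param index trial index stored in the record.
#' @return A `trial_record`: list with `theta`, `loss`, `probs`, `labels`,
#'   `index`.
#' @export
cv_objective <- function(algorithm, theta, dataset, K = NULL, cache = NULL,
                         index = NA_integer_) {
  if (inherits(dataset, "cadx_dataset")) {
    cfg <- lbp_config(theta$R, theta$P)
    X <- featurize_dataset(dataset, cfg, cache = cache)
    y <- dataset$labels
  } else {
    X <- as.matrix(dataset$features)
    y <- as.integer(dataset$labels)
  }
  folds <- make_folds(y, K)
  probs <- rep(NA_real_, length(y))
  fit_predict <- if (is.function(algorithm)) {
    algorithm
  } else if (algorithm == "gtb") {
    params <- gtb_params(eta = theta$eta, max_depth = theta$max_depth,
                         min_child_weight = theta$min_child_weight,
                         gamma_split = theta$gamma_split)
    function(tx, ty, vx, th) predict_proba(fit_gtb(tx, ty, params), vx)
  } else if (algorithm == "svm") {
    params <- svm_params(C = theta$C, gamma_rbf = theta$gamma_rbf)
    function(tx, ty, vx, th) predict_proba(fit_svm(tx, ty, params), vx)
  } else stop("unknown algorithm: ", algorithm)
  for (f in folds) {
    tr <- setdiff(seq_along(y), f)
    if (length(unique(y[tr])) < 2)
      stop("fold training set is single-class; need >= 2 samples per class")
    probs[f] <- fit_predict(X[tr, , drop = FALSE], y[tr],
                            X[f, , drop = FALSE], theta)
  }
  structure(list(theta = theta, loss = log_loss(y, probs), probs = probs,
                 labels = y, index = index),
            class = "trial_record")
}

#' @noRd
new_history <- function(records) {
  losses <- vapply(records, `[[`, numeric(1), "loss")
  structure(list(records = records, losses = losses,
                 best_index = if (length(losses)) which.min(losses) else NA),
            class = "trial_history")
}

#' Best trial of a history (earliest wins ties)
#'
#' @param history a `trial_history`.
#' @return The best `trial_record`.
#' @export
best_trial <- function(history) history$records[[history$best_index]]

#' @export
print.trial_history <- function(x, ...) {
  cat(sprintf("<trial_history> %d trials, best loss %.4f (trial %d)\n",
              length(x$records), min(x$losses), x$best_index))
  invisible(x)
}

#' Random search over a parameter space
#'
#' Draws `n_trials` independent points from the space prior and evaluates
#' the objective at each. Reproducible under `seed`.
#'
#' @param space a [search_space()].
#' @param objective function of theta returning a `trial_record` or a bare
#'   numeric loss.
#' @param n_trials number of evaluations (>= 1).
#' @param seed integer seed controlling all draws.
#' @return A `trial_history`.
#' @export
random_search <- function(space, objective, n_trials, seed = 0) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    records <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      theta <- sample_space(space)
      records[[i]] <- as_record(objective(theta), theta, i)
    }
    new_history(records)
  })
}

#' @noRd
as_record <- function(res, theta, i) {
  if (inherits(res, "trial_record")) { res$index <- i; return(res) }
  if (is.numeric(res) && length(res) == 1) {
    if (!is.finite(res) || res < 0) stop("objective returned an invalid loss")
    return(structure(list(theta = theta, loss = as.numeric(res), probs = NULL,
                          labels = NULL, index = i), class = "trial_record"))
  }
  stop("objective must return a trial_record or a numeric loss")
}

# ---- Tree Parzen Estimator ------------------------------------------------

# Per-dimension Parzen density: mixture of truncated Gaussians centred at the
# observed values, plus one uniform prior component (weight 1/(m+1)) that
# keeps exploration alive. Bandwidths use the larger adjacent-spacing
# heuristic per point, clipped to [range/min_bandwidth_div, range].
#' @noRd
parzen_continuous <- function(obs, lower, upper, min_bandwidth_div) {
  rng <- upper - lower
  m <- length(obs)
  if (m == 1) bw <- rng / 2 else {
    o <- order(obs); s <- obs[o]
    gap_lo <- c(s[1] - lower, diff(s))
    gap_hi <- c(diff(s), upper - s[m])
    bw <- numeric(m); bw[o] <- pmax(gap_lo, gap_hi)
  }
  bw <- pmin(pmax(bw, rng / min_bandwidth_div), rng)
  dens <- function(x) {
    v <- vapply(seq_len(m), function(k) {
      z <- pnorm((upper - obs[k]) / bw[k]) - pnorm((lower - obs[k]) / bw[k])
      dnorm((x - obs[k]) / bw[k]) / (bw[k] * max(z, 1e-12))
    }, numeric(length(x)))
    gauss <- if (length(x) == 1) sum(v) else rowSums(matrix(v, nrow = length(x)))
    (gauss + 1 / rng) / (m + 1)
  }
  draw <- function() {
    k <- sample.int(m + 1, 1)
    if (k > m) return(runif(1, lower, upper))    # prior component
    plo <- pnorm((lower - obs[k]) / bw[k]); phi <- pnorm((upper - obs[k]) / bw[k])
    x <- obs[k] + bw[k] * qnorm(runif(1, plo, phi))
    min(max(x, lower), upper)
  }
  list(dens = dens, draw = draw)
}

#' @noRd
parzen_categorical <- function(obs, choices) {
  counts <- vapply(choices, function(ch) sum(vapply(obs, identical, logical(1), ch)),
                   numeric(1))
  p <- (counts + 1) / (length(obs) + length(choices))  # add-one smoothing
  list(p = p, choices = choices,
       dens = function(ch) p[which(vapply(choices, identical, logical(1), ch))],
       draw = function() choices[[sample.int(length(choices), 1, prob = p)]])
}

#' @noRd
dim_bounds <- function(d) {
  if (d$kind == "integer") c(d$lower - 0.5, d$upper + 0.5)
  else if (d$log) log(c(d$lower, d$upper))
  else c(d$lower, d$upper)
}

#' @noRd
dim_to_internal <- function(d, v) {
  if (d$kind == "integer") as.numeric(v) else if (d$log) log(v) else as.numeric(v)
}

#' @noRd
dim_from_internal <- function(d, x) {
  if (d$kind == "integer") as.integer(min(max(round(x), d$lower), d$upper))
  else if (d$log) exp(x) else x
}

#' Suggest the next parameter point with a Tree Parzen Estimator
#'
#' With fewer than `n_startup` completed trials the prior is sampled.
#' Otherwise the lowest-loss `min(ceil(gamma_q * sqrt(n)), 25)` trials (ties
#' by trial order) form the good set and the remainder the rest; factorized
#' Parzen densities `l(x)` (good) and `g(x)` (rest) are built per dimension
#' (continuous: truncated-Gaussian mixtures, log-uniform dimensions modelled
#' in log space, integers as rounded continuous; categoricals: smoothed
#' category frequencies); `n_candidates` draws from `l` are scored and the
#' candidate maximizing `l(x)/g(x)` is returned.
#'
#' @param space a [search_space()].
#' @param history a `trial_history` (may be empty or `NULL`).
#' @param n_startup trials before the Parzen model kicks in.
#' @param gamma_q good-set schedule coefficient (the good set holds the best
#'   `ceil(gamma_q * sqrt(n))` trials, capped at 25).
#' @param n_candidates candidate draws from `l`.
#' @param min_bandwidth_div bandwidth floor divisor (bandwidths are clipped
#'   below by `range/min_bandwidth_div`).
#' @return Named list theta; uses the current RNG stream.
#' @export
tpe_suggest <- function(space, history = NULL, n_startup = 10, gamma_q = 0.25,
                        n_candidates = 24, min_bandwidth_div = 100) {
  n <- if (is.null(history)) 0 else length(history$records)
  if (n < n_startup) return(sample_space(space))
  ord <- order(history$losses, seq_len(n))
  # good-set size follows the sqrt schedule of the reference estimator:
  # a constant fraction over-dilutes l(x) with mediocre trials as the
  # history grows, which measurably traps the search in secondary basins
  n_good <- max(1, min(ceiling(gamma_q * sqrt(n)), 25))
  good <- lapply(history$records[ord[seq_len(n_good)]], `[[`, "theta")
  rest_idx <- ord[-seq_len(n_good)]
  if (!length(rest_idx)) rest_idx <- ord  # degenerate split: all trials tied
  rest <- lapply(history$records[rest_idx], `[[`, "theta")

  models <- lapply(space, function(d) {
    if (d$kind == "categorical") {
      list(l = parzen_categorical(lapply(good, `[[`, d$name), d$choices),
           g = parzen_categorical(lapply(rest, `[[`, d$name), d$choices))
    } else {
      b <- dim_bounds(d)
      gv <- vapply(good, function(th) dim_to_internal(d, th[[d$name]]), numeric(1))
      rv <- vapply(rest, function(th) dim_to_internal(d, th[[d$name]]), numeric(1))
      list(l = parzen_continuous(gv, b[1], b[2], min_bandwidth_div),
           g = parzen_continuous(rv, b[1], b[2], min_bandwidth_div))
    }
  })

  # The Parzen model factorizes over dimensions, so the candidate maximizing
  # l/g over the drawn set is assembled dimension by dimension.
  theta <- list()
  for (d in space) {
    mod <- models[[d$name]]
    best_x <- NULL; best_score <- -Inf
    for (k in seq_len(n_candidates)) {
      if (d$kind == "categorical") {
        x <- mod$l$draw()
        score <- log(mod$l$dens(x)) - log(mod$g$dens(x))
      } else {
        x <- mod$l$draw()
        score <- log(max(mod$l$dens(x), 1e-300)) -
          log(max(mod$g$dens(x), 1e-300))
      }
      if (score > best_score) { best_score <- score; best_x <- x }
    }
    theta[[d$name]] <- if (d$kind == "categorical") best_x
                       else dim_from_internal(d, best_x)
  }
  theta
}

#' Sequential TPE search over a parameter space
#'
#' As [random_search()], but after `n_startup` prior draws each point comes
#' from [tpe_suggest()] conditioned on the history so far.
#'
#' @inheritParams random_search
#' @inheritParams tpe_suggest
#' @return A `trial_history`.
#' @export
tpe_search <- function(space, objective, n_trials, seed = 0, n_startup = 10,
                       gamma_q = 0.25, n_candidates = 24,
                       min_bandwidth_div = 100) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    records <- list()
    for (i in seq_len(n_trials)) {
      theta <- tpe_suggest(space, new_history(records), n_startup, gamma_q,
                           n_candidates, min_bandwidth_div)
      records[[i]] <- as_record(objective(theta), theta, i)
    }
    new_history(records)
  })
}

#' Persist a trial history as JSON lines
#'
#' One record per line: `{"index": i, "theta": {...}, "loss": ...}`.
#'
#' @param history a `trial_history`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  lines <- vapply(history$records, function(r)
    jsonlite::toJSON(list(index = r$index, theta = r$theta, loss = r$loss),
                     auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines trial history written by [write_history()]
#'
#' Held-out probabilities are not persisted; records carry `theta` and
#' `loss` only.
#'
#' @param path JSONL path.
#' @return A `trial_history`.
#' @export
read_history <- function(path) {
  records <- lapply(readLines(path), function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    structure(list(theta = as.list(obj$theta), loss = obj$loss, probs = NULL,
                   labels = NULL, index = obj$index), class = "trial_record")
  })
  new_history(records)
}
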