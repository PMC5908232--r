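test_that("logistic gradients and hessians follow the second-order expansion", {
  gh <- grad_hess(c(1, 0), c(0, 0))
  expect_equal(gh$g, c(-0.5, 0.5))
  expect_equal(gh$h, c(0.25, 0.25))
  sat <- grad_hess(c(1, 0), c(40, -40))
  expect_true(all(abs(sat$g) < 1e-15))
  expect_true(all(sat$h < 1e-15))
  expect_error(grad_hess(c(1, 0), c(Inf, 0)))
})

test_that("exact greedy split search maximizes the regularized gain", {
  pars <- gtb_params(min_child_weight = 0, gamma_split = 0, lambda_reg = 1)
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  g <- c(1, 0.5, -0.5, -1); h <- rep(1, 4)
  s <- gtb_best_split(X, g, h, pars)
  # hand evaluation: threshold 2.5 gives GL=1.5,HL=2,GR=-1.5,HR=2
  expect_equal(s$feature, 1)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 0.5 * (1.5^2 / 3 + 1.5^2 / 3 - 0))
  # no distinct values -> no split
  expect_null(gtb_best_split(matrix(1, 4, 1), g, h, pars))
  # gamma above any achievable gain -> no split
  pars_g <- gtb_params(min_child_weight = 0, gamma_split = 1, lambda_reg = 1)
  expect_null(gtb_best_split(X, g / 10, h, pars_g))
  # min_child_weight can forbid otherwise-best splits
  pars_m <- gtb_params(min_child_weight = 2, gamma_split = 0, lambda_reg = 1)
  s2 <- gtb_best_split(X, g, h, pars_m)
  expect_equal(s2$threshold, 2.5)  # only split with both child hessians >= 2
})

test_that("training loss is non-increasing and a separable toy is learned", {
  toy <- toy_separable()
  m <- fit_gtb(toy$X, toy$y,
               gtb_params(eta = 0.6, max_depth = 3, min_child_weight = 0,
                          gamma_split = 0, n_rounds = 20))
  expect_true(all(diff(m$train_loss) <= 1e-12))
  expect_equal(mean((predict_proba(m, toy$X) >= 0.5) == toy$y), 1)

  # monotone descent holds across the whole search range
  set.seed(5)
  X <- matrix(rnorm(200), 40, 5)
  y <- as.integer(X[, 1] + rnorm(40) > 0)
  for (pars in list(gtb_params(0.2, 1, 1, 0, 30),
                    gtb_params(0.6, 13, 1, 0.5, 30),
                    gtb_params(0.4, 6, 5, 1, 30))) {
    mm <- fit_gtb(X, y, pars)
    expect_true(all(diff(mm$train_loss) <= 1e-12))
    expect_true(check_tree_constraints(mm))
  }
})

test_that("depth-1 models are stumps and match a squared-error split oracle", {
  set.seed(6)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c(0L, 1L), 4)  # balanced -> round-1 hessians all equal 0.25
  m <- fit_gtb(X, y, gtb_params(eta = 0.3, max_depth = 1, min_child_weight = 0,
                                gamma_split = 0, n_rounds = 5, lambda_reg = 0))
  for (tree in m$trees)
    expect_lte(sum(tree[, "feature"] != 0), 1)

  # brute-force oracle: the stump split maximizing squared-error reduction on
  # the round-1 gradients (equal hessians make the two criteria coincide)
  g <- rep(0.5, 8); g[y == 1] <- -0.5
  best <- list(red = -Inf)
  for (j in 1:2) {
    vals <- sort(unique(X[, j]))
    for (k in seq_len(length(vals) - 1)) {
      thr <- (vals[k] + vals[k + 1]) / 2
      L <- X[, j] < thr
      red <- sum((g - mean(g))^2) -
        sum((g[L] - mean(g[L]))^2) - sum((g[!L] - mean(g[!L]))^2)
      if (red > best$red) best <- list(red = red, feature = j, thr = thr)
    }
  }
  tree1 <- m$trees[[1]]
  expect_equal(unname(tree1[1, "feature"]), best$feature)
  expect_equal(unname(tree1[1, "threshold"]), best$thr)
})

test_that("predictions are the sigmoid margin and the base score is the prior", {
  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  y <- as.integer(runif(20) < 0.35)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  m0 <- fit_gtb(X, y, gtb_params(n_rounds = 0))
  expect_equal(unname(predict_proba(m0, X)), rep(mean(y), 20))

  m <- fit_gtb(X, y, gtb_params(n_rounds = 10))
  p <- predict_proba(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict_proba(m, X))
  expect_error(predict_proba(m, X[, 1:2]), "dimension")
  expect_error(fit_gtb(X, rep(1L, 20), gtb_params()), "single class")
})

test_that("the independent reference booster reproduces our predictions", {
  skip_if_not_installed("xgboost")
  set.seed(10)
  n <- 60; d <- 8
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(n, sd = 0.5) > 0)
  pars <- gtb_params(eta = 0.3, max_depth = 4, min_child_weight = 2,
                     gamma_split = 0, n_rounds = 30, lambda_reg = 1)
  ours <- predict_proba(fit_gtb(X, y, pars), X)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.3, max_depth = 4,
                  min_child_weight = 2, gamma = 0, lambda = 1,
                  base_score = mean(y), tree_method = "exact", nthread = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 30, verbose = 0)
  theirs <- predict(bst, xgboost::xgb.DMatrix(X, label = y))
  expect_lt(max(abs(ours - theirs)), 1e-5)
})

test_that("models survive a JSON round trip bit-for-bit in behaviour", {
  td <- withr::local_tempdir()
  set.seed(8)
  X <- matrix(rnorm(80), 20, 4)
  y <- as.integer(X[, 1] > 0)
  m <- fit_gtb(X, y, gtb_params(eta = 0.4, max_depth = 4, n_rounds = 12))
  f <- file.path(td, "model.json")
  gtb_to_json(m, f)
  m2 <- gtb_from_json(f)
  expect_equal(predict_proba(m2, X), predict_proba(m, X), tolerance = 1e-15)
  expect_equal(m2$base, m$base)
})
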