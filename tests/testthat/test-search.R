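test_that("space sampling stays within every dimension's range", {
  for (space in list(svm_search_space(), gtb_search_space())) {
    with_seed(1, {
      for (i in 1:100) expect_true(theta_in_space(space, sample_space(space)))
    })
  }
  sp <- gtb_search_space()
  with_seed(2, {
    th <- sample_space(sp)
    expect_true(th$max_depth == round(th$max_depth))
    expect_true(th$R %in% c(7, 8) && th$P %in% c(40, 48))
  })
})

test_that("the LOOCV objective scores stubs at their closed-form losses", {
  # feature 1 encodes the label; a stub reading it is a perfect predictor
  fd <- list(features = cbind(rep(c(0, 1), each = 5), rnorm(10)),
             labels = rep(c(0L, 1L), each = 5))
  perfect <- function(tx, ty, vx, th) vx[, 1]
  rec <- cv_objective(perfect, list(), fd)
  expect_lt(rec$loss, 1e-12)
  half <- function(tx, ty, vx, th) rep(0.5, nrow(vx))
  expect_equal(cv_objective(half, list(), fd)$loss, log(2))
  # a wrong "probability 0" prediction is clipped, not infinite
  wrong <- function(tx, ty, vx, th) 1 - vx[, 1]
  expect_true(is.finite(cv_objective(wrong, list(), fd)$loss))
})

test_that("no held-out sample reaches its own fold's training set", {
  # unique-id probe: feature 1 is a per-sample id; the stub answers 0.99
  # only if the held-out id leaked into training, else 0.5
  n <- 12
  fd <- list(features = cbind(seq_len(n), rnorm(n)),
             labels = rep(c(0L, 1L), n / 2))
  probe <- function(tx, ty, vx, th) {
    if (any(vx[, 1] %in% tx[, 1])) 0.99 else 0.5
  }
  rec <- cv_objective(probe, list(), fd)
  expect_equal(rec$loss, log(2))  # never leaked
  # training sets always have n-1 rows and both classes
  size_probe <- function(tx, ty, vx, th) {
    stopifnot(nrow(tx) == n - 1, length(unique(ty)) == 2)
    rep(0.5, nrow(vx))
  }
  expect_silent(cv_objective(size_probe, list(), fd))
})

test_that("feature caching does not change the objective", {
  ds <- generate_dataset(phantom_spec(n_per_class = 2, seed = 5))
  th <- list(eta = 0.4, max_depth = 3, min_child_weight = 1,
             gamma_split = 0.2, R = 7, P = 40)
  cache <- new.env(parent = emptyenv())
  r1 <- cv_objective("gtb", th, ds, cache = cache)
  r2 <- cv_objective("gtb", th, ds, cache = cache)  # cache hit
  r3 <- cv_objective("gtb", th, ds)                 # no cache
  expect_identical(r1$loss, r2$loss)
  expect_identical(r1$loss, r3$loss)
  expect_true(exists("R=7,P=40", envir = cache))
})

test_that("random search is seeded, in-range, and prefix-monotone in its best", {
  sp <- gtb_search_space()
  obj <- function(th) th$eta + th$gamma_split  # deterministic toy loss
  h1 <- random_search(sp, obj, 10, seed = 3)
  expect_length(h1$records, 10)
  expect_true(all(vapply(h1$records, function(r)
    theta_in_space(sp, r$theta), logical(1))))
  h2 <- random_search(sp, obj, 10, seed = 3)
  expect_identical(h1$losses, h2$losses)
  # the best over a growing prefix never worsens
  expect_true(all(diff(cummin(h1$losses)) <= 0))
  h5 <- random_search(sp, obj, 5, seed = 3)
  expect_identical(h5$losses, h1$losses[1:5])
  expect_gte(best_trial(h5)$loss, best_trial(h1)$loss)
  expect_error(random_search(sp, obj, 0, seed = 1))
})

test_that("TPE suggestions are in-range from any history shape", {
  sp <- gtb_search_space()
  with_seed(4, {
    expect_true(theta_in_space(sp, tpe_suggest(sp, NULL)))
    # all-equal losses: the count-based split still yields a valid point
    obj_const <- function(th) 1
    h <- random_search(sp, obj_const, 15, seed = 4)
    for (i in 1:5) {
      th <- tpe_suggest(sp, h)
      expect_true(theta_in_space(sp, th))
      expect_true(is.numeric(th$eta) && th$max_depth == round(th$max_depth))
    }
  })
})

test_that("TPE concentrates on a 1-D quadratic better than random search", {
  sp <- search_space(dim_uniform("x", 0, 1))
  obj <- function(th) (th$x - 0.3)^2
  err <- vapply(1:20, function(s) {
    c(abs(best_trial(tpe_search(sp, obj, 40, seed = s))$theta$x - 0.3),
      abs(best_trial(random_search(sp, obj, 40, seed = s))$theta$x - 0.3))
  }, numeric(2))
  expect_lt(median(err[1, ]), median(err[2, ]))
})

test_that("TPE histories are seeded and reproducible", {
  sp <- svm_search_space()
  obj <- function(th) log10(th$C)^2 + log10(th$gamma_rbf)^2
  h1 <- tpe_search(sp, obj, 15, seed = 9)
  h2 <- tpe_search(sp, obj, 15, seed = 9)
  expect_length(h1$records, 15)
  expect_identical(h1$losses, h2$losses)
  expect_true(all(vapply(h1$records, function(r)
    theta_in_space(sp, r$theta), logical(1))))
  expect_true(all(diff(cummin(h1$losses)) <= 0))
})

test_that("label permutation yields chance-level or pessimistic AUC, never optimistic", {
  fd <- feature_dataset(n_per_class = 10, d = 4, shift = 3, seed = 6)
  set.seed(7)
  fd$labels <- sample(fd$labels)  # break the feature-label link
  sp <- gtb_search_space()
  cacheless <- function(th) cv_objective("gtb", th, fd)
  h <- random_search(sp, cacheless, 8, seed = 8)
  best <- best_trial(h)
  expect_gte(best$loss, 0)
  expect_lte(roc_auc(best$labels, best$probs), 0.65)
})

test_that("histories round-trip through JSON lines", {
  td <- withr::local_tempdir()
  sp <- gtb_search_space()
  h <- random_search(sp, function(th) th$eta, 6, seed = 11)
  f <- file.path(td, "hist.jsonl")
  write_history(h, f)
  back <- read_history(f)
  expect_equal(back$losses, h$losses)
  expect_equal(back$best_index, h$best_index)
  expect_equal(back$records[[3]]$theta$max_depth,
               h$records[[3]]$theta$max_depth)
})
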