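test_that("riu2 mapping counts circular transitions correctly", {
  expect_identical(riu2_map(0, 8), 0L)                   # all zeros
  expect_identical(riu2_map(2^8 - 1, 8), 8L)             # all ones
  expect_identical(riu2_map(strtoi("00001111", base = 2), 8), 4L)  # U = 2
  expect_identical(riu2_map(strtoi("01010101", base = 2), 8), 9L)  # U = 8
  # uniform patterns of every weight map to their bit count
  for (k in 0:7) expect_identical(riu2_map(2^k - 1, 8), k)
  expect_error(riu2_map(2^8, 8))
})

test_that("the naive LBP code implements thresholded circular sampling", {
  cfg <- lbp_config(1, 4)
  # constant neighborhood: s(0) = 1 for every sample
  expect_equal(lbp_code(matrix(7, 5, 5), c(3, 3), cfg), 2^4 - 1)
  # neighbors in angle order [6, 4, 5, 2] around center 5 -> bits 1,0,1,0
  S <- matrix(0, 3, 3)
  S[2, 2] <- 5; S[3, 2] <- 6; S[2, 3] <- 4; S[1, 2] <- 5; S[2, 1] <- 2
  expect_equal(lbp_code(S, c(2, 2), cfg), 5)
  # center strictly above all neighbors -> code 0
  P <- matrix(1, 5, 5); P[3, 3] <- 10
  expect_equal(lbp_code(P, c(3, 3), cfg), 0)
  expect_error(lbp_code(S, c(1, 2), cfg), "border")
})

test_that("circular sampling hits lattice neighbors exactly and interpolates bilinearly", {
  cfg <- lbp_config(1, 4)
  S <- matrix(as.numeric(1:25), 5, 5)
  nb <- sample_neighbors(S, c(3, 3), cfg)
  expect_identical(nb, c(S[4, 3], S[3, 4], S[2, 3], S[3, 2]))
  expect_equal(sample_neighbors(matrix(3.5, 7, 7), c(4, 4), lbp_config(2, 8)),
               rep(3.5, 8))
  # off-lattice sample against the closed-form bilinear formula on a 2x2 cell
  set.seed(11)
  M <- matrix(rnorm(49), 7, 7)
  cfg3 <- lbp_config(1.5, 8)       # sample 1 at (1.5/sqrt(2), 1.5/sqrt(2))
  nb3 <- sample_neighbors(M, c(4, 4), cfg3)
  fr <- 1.5 * cos(pi / 4) - 1; fc <- 1.5 * sin(pi / 4) - 1
  hand <- M[4, 4] +
    ((1 - fr) * (1 - fc) * (M[5, 5] - M[4, 4]) +
     fr * (1 - fc) * (M[6, 5] - M[4, 4]) +
     (1 - fr) * fc * (M[5, 6] - M[4, 4]) +
     fr * fc * (M[6, 6] - M[4, 4]))
  expect_equal(nb3[2], hand, tolerance = 1e-12)
})

test_that("vectorized code maps equal the naive per-pixel oracle", {
  for (cfg in list(lbp_config(1, 8), lbp_config(7, 40))) {
    for (seed in 1:3) {
      S <- rand_hu_slice(2 * cfg$margin + 6, seed)
      fast <- lbp_slice(S, cfg)
      expect_identical(matrix(as.integer(fast), nrow(fast)),
                       naive_codemap(S, cfg))
    }
  }
})

test_that("valid region excludes the ceiling(R) margin", {
  expect_equal(dim(lbp_slice(matrix(0, 64, 64), lbp_config(7, 40))), c(50, 50))
  expect_equal(dim(lbp_slice(matrix(0, 64, 64), lbp_config(8, 48))), c(48, 48))
  expect_error(lbp_slice(matrix(0, 14, 14), lbp_config(7, 40)), "small")
})

test_that("codes are invariant to intensity offsets and 90-degree rotation", {
  cfg <- lbp_config(7, 40)
  S <- rand_hu_slice(32, 21)
  base <- lbp_slice(S, cfg)
  expect_identical(base, lbp_slice(S + 150, cfg))       # monotone offset
  rot <- lbp_slice(t(S[nrow(S):1, ]), cfg)              # 90-degree rotation
  expect_identical(tabulate(as.vector(base) + 1L, cfg$P + 2),
                   tabulate(as.vector(rot) + 1L, cfg$P + 2))
})

test_that("LBP-TOP concatenates three normalized orientation histograms", {
  const <- volume_patch(array(-800, c(64, 64, 64)))
  for (cfg in list(lbp_config(7, 40), lbp_config(8, 48))) {
    v <- lbp_top(const, cfg)
    expect_length(v, 3 * (cfg$P + 2))
    for (b in 0:2) {
      block <- v[b * (cfg$P + 2) + seq_len(cfg$P + 2)]
      expect_equal(sum(block), 1)
      expect_equal(unname(block[cfg$P + 1]), 1)  # all mass in bin P
    }
  }

  set.seed(31)
  arr <- array(sample(-1000:200, 64^3, replace = TRUE) + 0, c(64, 64, 64))
  cfg <- lbp_config(7, 40)
  v <- lbp_top(arr, cfg)
  expect_true(all(v >= 0))
  expect_equal(as.vector(tapply(v, rep(1:3, each = cfg$P + 2), sum)),
               rep(1, 3), tolerance = 1e-12)
  # pooling over an axis is order-free: permuting z slices fixes the XY block
  perm <- sample(64)
  v2 <- lbp_top(arr[, , perm], cfg)
  expect_equal(v[1:(cfg$P + 2)], v2[1:(cfg$P + 2)])
})

test_that("feature matrices round-trip through TSV plus sidecar", {
  td <- withr::local_tempdir()
  cfg <- lbp_config(7, 40)
  set.seed(41)
  X <- matrix(runif(4 * 126), 4, 126)
  f <- file.path(td, "feat.tsv")
  write_features(X, c(0, 1, 0, 1), paste0("p", 1:4), cfg, f)
  back <- read_features(f)
  expect_equal(unname(back$features), unname(X), tolerance = 1e-12)
  expect_identical(back$labels, c(0L, 1L, 0L, 1L))
  expect_identical(back$config$P, 40L)
  expect_identical(back$config$R, 7)
})

test_that("the P-divisible-by-4 and positive-radius constraints are enforced", {
  expect_error(lbp_config(0, 8))
  expect_error(lbp_config(1, 6))
  expect_error(lbp_config(1, 2))
})
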