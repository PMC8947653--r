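test_that("score maps have the input shape and unit range", {
  w <- small_network()
  set.seed(12)
  Ch <- matrix(rnorm(48 * 40), 48, 40)
  Dh <- matrix(rnorm(48 * 40), 48, 40)
  M <- feature_detect(w, Ch, Dh)
  expect_identical(dim(M), dim(Ch))
  expect_gte(min(M), 0); expect_lte(max(M), 1)
  expect_error(feature_detect(w, Ch, matrix(0, 40, 48)), "identical")
  expect_error(feature_detect(w, matrix(0, 8, 8), matrix(0, 8, 8)), ">= 16")
})

# Textured image with discriminative content in every 16x16 block (flat
# regions would score near 0.5, since neither side is sharper there).
make_textured <- function(seed, n = 64) {
  set.seed(seed)
  tex <- medfuse:::gaussian_blur(matrix(stats::rnorm(n * n), n, n), 0.6)
  pmin(pmax(0.5 + 0.2 * tex / stats::sd(tex), 0), 1)
}

test_that("the score map favors the sharper band on either side", {
  w <- full_network()
  sharp <- make_textured(30)
  blurred <- medfuse:::gaussian_blur(sharp, 2.5)
  expect_gt(mean(feature_detect(w, sharp, blurred)), 0.7)
  expect_lt(mean(feature_detect(w, blurred, sharp)), 0.3)
})

test_that("initial segmentation thresholds strictly at one half", {
  M <- matrix(c(0.6, 0.5, 0.0, 0.50001), 2, 2)
  B <- initial_segment(M)
  expect_equal(B[1, 1], 1)   # M > 0.5
  expect_equal(B[2, 1], 0)   # exactly 0.5 goes to the 'otherwise' branch
  expect_equal(B[1, 2], 0)
  expect_equal(B[2, 2], 1)
  expect_equal(initial_segment(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(initial_segment(matrix(2, 4, 4)), "0, 1")
})

test_that("consistency verification removes singletons, keeps structures", {
  allones <- matrix(1, 32, 32)
  expect_equal(consistency_verify(allones), allones)
  B <- matrix(0, 64, 64); B[30, 30] <- 1
  expect_equal(consistency_verify(B), matrix(0, 64, 64))
  half <- matrix(0, 32, 32); half[, 17:32] <- 1
  cv <- consistency_verify(half)
  changed_cols <- which(colSums(cv != half) > 0)
  expect_true(all(abs(changed_cols - 16.5) <= 4))  # only a boundary band
  expect_error(consistency_verify(matrix(0.5, 8, 8)), "binary")
})

test_that("consistency verification matches the majority-vote oracle", {
  for (s in 1:5) {
    set.seed(400 + s)
    B <- (matrix(runif(24 * 24), 24, 24) > 0.4) * 1
    expect_equal(consistency_verify(B), oracle_majority(B))
  }
})

test_that("verification is idempotent on structured maps", {
  half <- matrix(0, 32, 32); half[, 17:32] <- 1
  v1 <- consistency_verify(half)
  expect_equal(consistency_verify(v1), v1)
})

test_that("guided refinement preserves constants and matches the textbook filter", {
  expect_equal(refine_decision(matrix(0.3, 16, 16), matrix(0.8, 16, 16)),
               matrix(0.3, 16, 16))
  set.seed(17)
  for (s in 1:3) {
    set.seed(500 + s)
    p <- (matrix(runif(32 * 32), 32, 32) > 0.5) * 1
    I <- matrix(runif(32 * 32), 32, 32)
    expect_lt(max(abs(refine_decision(p, I, 4, 0.1) - oracle_guided(p, I, 4, 0.1))),
              1e-6)
  }
})

test_that("guided filter softens steps and limits to a double box mean", {
  I <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32)
  p <- matrix(0, 32, 32); p[, 17:32] <- 1
  d <- refine_decision(p, I, 4, 0.1)
  near <- d[, 14:19]
  expect_true(any(near > 0 & near < 1))
  d2 <- refine_decision(p, I, 4, 1e6)
  expect_lt(max(abs(d2 - oracle_box_mean(oracle_box_mean(p, 4), 4))), 1e-4)
})

test_that("compositing obeys the convex-combination identities", {
  set.seed(23)
  Ch <- matrix(rnorm(100), 10, 10)
  Dh <- matrix(rnorm(100), 10, 10)
  expect_equal(fuse_hf(matrix(1, 10, 10), Ch, Dh), Ch)
  expect_equal(fuse_hf(matrix(0, 10, 10), Ch, Dh), Dh)
  expect_equal(fuse_hf(matrix(0.5, 10, 10), matrix(2, 10, 10), matrix(4, 10, 10)),
               matrix(3, 10, 10))
  Dm <- matrix(runif(100), 10, 10)
  expect_equal(fuse_hf(Dm, Ch, Ch), Ch)                  # agreement identity
  Fh <- fuse_hf(Dm, Ch, Dh)
  expect_true(all(Fh >= pmin(Ch, Dh) - 1e-12 & Fh <= pmax(Ch, Dh) + 1e-12))
  expect_error(fuse_hf(matrix(2, 10, 10), Ch, Dh), "0, 1")
  expect_error(fuse_hf(Dm, Ch, matrix(0, 5, 5)), "identical")
})

test_that("fusing a band with its blurred copy keeps the sharp band's energy", {
  w <- full_network()
  img <- make_textured(41)
  sharp <- lsist_decompose(img, 1, 4)$high[[1]][[2]]
  blurred <- medfuse:::gaussian_blur(sharp, 2)
  M <- feature_detect(w, sharp, blurred)
  Dm <- refine_decision(consistency_verify(initial_segment(M)), img)
  fused <- fuse_hf(Dm, sharp, blurred)
  expect_gt(sum(fused^2) / sum(sharp^2), 0.95)
  expect_lt(sum(fused^2) / sum(sharp^2), 1.05)
})
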