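rand_img <- function(seed, n = 48) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

test_that("perfect fusions score perfectly", {
  A <- rand_img(1)
  expect_lt(abs(qfab(A, A, A) - 1), 1e-6)
  expect_lt(abs(nfab(A, A, A)), 1e-6)
  expect_equal(crr(A, A, A), 1)
})

test_that("a constant fused image transfers almost no edges", {
  A <- rand_img(2); B <- rand_img(3)
  expect_lt(qfab(A, B, matrix(0.5, 48, 48)), 0.05)
})

test_that("degenerate source/fused combinations behave consistently", {
  A <- rand_img(4)
  expect_equal(qfab(A, A, A), qfab(A, A, A))
  expect_error(qfab(matrix(0.2, 8, 8), matrix(0.2, 8, 8), A[1:8, 1:8]),
               "constant")
  expect_error(crr(matrix(0.2, 8, 8), A[1:8, 1:8], A[1:8, 1:8]), "constant")
  expect_error(qfab(A, A, A[1:8, 1:8]), "identical")
})

test_that("anticorrelated fusion gives CRR of -1", {
  A <- rand_img(5)
  expect_equal(crr(A, A, 1 - A), -1)
})

test_that("averaging independent fields gives CRR near 1/sqrt(2)", {
  vals <- vapply(1:20, function(s) {
    set.seed(600 + s)
    A <- matrix(runif(64 * 64), 64, 64)
    B <- matrix(runif(64 * 64), 64, 64)
    crr(A, B, (A + B) / 2)
  }, numeric(1))
  # cor(A, (A+B)/2) -> 1/sqrt(2) for iid fields; 20 replicates average out
  expect_lt(abs(mean(vals) - 1 / sqrt(2)), 3 * stats::sd(vals) / sqrt(20) + 0.01)
})

test_that("average gradient matches closed forms and scales linearly", {
  expect_equal(avg_gradient(matrix(0.7, 16, 16)), 0)
  W <- 64
  ramp <- matrix(rep((0:(W - 1)) / (W - 1), each = W), W, W)
  expect_lt(abs(avg_gradient(ramp) - 1 / ((W - 1) * sqrt(2))), 1e-9)
  A <- 0.25 + 0.25 * rand_img(6)       # doubling stays inside [0, 1]
  expect_equal(avg_gradient(2 * A), 2 * avg_gradient(A))
})

test_that("sourceless checkerboard edges raise the artifact measure", {
  n <- 64
  A <- matrix(rep(seq(0.3, 0.7, length.out = n), each = n), n, n)
  A <- A + 0.02 * rand_img(7, n)       # mild texture so weights are nonzero
  # 2x2-block checkerboard: strong injected edges that Sobel responds to
  # (a period-1 checker sits at Nyquist and is nulled by the Sobel smoothing)
  blk <- (-1)^(floor((0:(n - 1)) / 2))
  checker <- 0.25 * outer(blk, blk)
  F1 <- pmin(pmax(A + checker, 0), 1)
  expect_gt(nfab(A, A, F1), 0.3)
  expect_gte(nfab(A, A, F1), 0)
  expect_lte(nfab(A, A, F1), 1)
})

test_that("all metrics are invariant under simultaneous circular shifts", {
  A <- rand_img(8); B <- rand_img(9)
  F1 <- (A + B) / 2
  As <- circ_shift(A, 7, 11); Bs <- circ_shift(B, 7, 11)
  Fs <- circ_shift(F1, 7, 11)
  expect_equal(qfab(As, Bs, Fs), qfab(A, B, F1), tolerance = 0.02)
  expect_equal(nfab(As, Bs, Fs), nfab(A, B, F1), tolerance = 0.02)
  expect_equal(crr(As, Bs, Fs), crr(A, B, F1), tolerance = 1e-12)
  expect_equal(avg_gradient(Fs), avg_gradient(F1), tolerance = 0.02)
})

test_that("high edge transfer implies low artifact content on identity fusions", {
  A <- rand_img(10)
  expect_gt(qfab(A, A, A), 0.99)
  expect_lt(nfab(A, A, A), 0.01)
})
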