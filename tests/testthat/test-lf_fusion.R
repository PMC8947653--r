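test_that("local energy matches direct summation on simple fields", {
  cfg <- energy_config()
  expect_equal(local_energy(matrix(2, 6, 6), cfg), matrix(36, 6, 6))
  expect_equal(local_energy(matrix(0, 6, 6), cfg), matrix(0, 6, 6))
  L <- matrix(0, 5, 5); L[3, 3] <- 1
  En <- local_energy(L, cfg)
  expected <- matrix(0, 5, 5); expected[2:4, 2:4] <- 1
  expect_equal(En, expected)
})

test_that("salience hits its closed-form values", {
  set.seed(4)
  LC <- matrix(rnorm(100), 10, 10)
  expect_equal(salience(LC, LC), matrix(1, 10, 10))
  expect_equal(salience(LC, matrix(0, 10, 10)), matrix(0, 10, 10))
  # LD = 2 LC: 2*sum(2 c^2) / (sum c^2 + sum 4 c^2) = 4/5
  expect_equal(salience(LC, 2 * LC), matrix(0.8, 10, 10))
  expect_true(all(abs(salience(LC, matrix(rnorm(100), 10, 10))) <= 1 + 1e-12))
})

test_that("identical bands fuse to themselves", {
  set.seed(5)
  LC <- matrix(rnorm(64), 8, 8)
  expect_equal(fuse_lf(LC, LC), LC)
})

test_that("fusion agrees exactly with the per-pixel oracle on random bands", {
  cfg <- energy_config()
  n_avg <- 0; n_sel <- 0
  for (s in 1:100) {
    set.seed(s)
    LC <- matrix(rnorm(64), 8, 8)
    # alternate between correlated (averaging) and anti-correlated (selection)
    LD <- if (s %% 2) LC + 0.2 * matrix(rnorm(64), 8, 8)
          else -LC + 0.1 * matrix(rnorm(64), 8, 8)
    got <- fuse_lf(LC, LD, cfg)
    expect_identical(got, oracle_fuse_lf(LC, LD))
    S <- salience(LC, LD, cfg = cfg)
    n_avg <- n_avg + sum(S > cfg$threshold)
    n_sel <- n_sel + sum(S <= cfg$threshold)
  }
  expect_gt(n_avg, 0)   # both rule branches exercised
  expect_gt(n_sel, 0)
})

test_that("anti-correlated bands select the higher-energy coefficient", {
  set.seed(6)
  LC <- matrix(rnorm(64), 8, 8)
  LD <- -LC
  got <- fuse_lf(LC, LD)
  expect_true(all(got == LC | got == LD))
  expect_identical(got, oracle_fuse_lf(LC, LD))
})

test_that("degenerate alpha_max = 1 collapses averaging to selection", {
  set.seed(7)
  LC <- matrix(rnorm(64), 8, 8)
  LD <- LC + 0.1 * matrix(rnorm(64), 8, 8)
  cfg <- energy_config(alpha_min = 0, alpha_max = 1)
  got <- fuse_lf(LC, LD, cfg)
  EnC <- local_energy(LC, cfg); EnD <- local_energy(LD, cfg)
  expect_equal(got, ifelse(EnC >= EnD, LC, LD))
})

test_that("fused values stay within the pointwise band envelope", {
  for (s in 1:10) {
    set.seed(200 + s)
    LC <- matrix(rnorm(100), 10, 10)
    LD <- LC + 0.3 * matrix(rnorm(100), 10, 10)
    got <- fuse_lf(LC, LD)
    expect_true(all(got >= pmin(LC, LD) - 1e-12))
    expect_true(all(got <= pmax(LC, LD) + 1e-12))
  }
})

test_that("swapping arguments only matters at energy ties", {
  set.seed(9)
  LC <- matrix(rnorm(144), 12, 12)
  LD <- matrix(rnorm(144), 12, 12)
  f1 <- fuse_lf(LC, LD)
  f2 <- fuse_lf(LD, LC)
  EnC <- local_energy(LC); EnD <- local_energy(LD)
  neq <- EnC != EnD
  expect_equal(f1[neq], f2[neq])
})

test_that("invalid configurations are rejected", {
  expect_error(energy_config(alpha_min = 0.4, alpha_max = 0.7), "equal 1")
  expect_error(energy_config(threshold = 1.5), "threshold")
  expect_error(energy_config(template = matrix(1, 2, 2)), "3x3")
  expect_error(fuse_lf(matrix(0, 4, 4), matrix(0, 5, 5)), "identical dim")
})
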