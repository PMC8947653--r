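test_that("constant images carry no high-pass energy", {
  p <- lsist_decompose(matrix(0.7, 64, 64), 2, c(4, 4))
  expect_lt(max(abs(unlist(p$high))), 1e-8)
  expect_equal(p$low, matrix(0.7, 64, 64), tolerance = 1e-10)
})

test_that("decompose/reconstruct round trip is tight across sizes and depths", {
  for (n in c(64, 96, 128)) {
    for (S in c(2, 3, 4)) {
      set.seed(n + S)
      x <- matrix(runif(n * n), n, n)
      dirs <- switch(as.character(S),
                     "2" = c(4, 8), "3" = c(8, 8, 16), "4" = c(4, 8, 8, 16))
      xr <- lsist_reconstruct(lsist_decompose(x, S, dirs))
      expect_lt(max(abs(x - xr)), 1e-4)
    }
  }
})

test_that("sub-bands commute with circular shifts", {
  set.seed(21)
  x <- matrix(runif(64 * 64), 64, 64)
  p <- lsist_decompose(x, 3, c(8, 8, 16))
  ps <- lsist_decompose(circ_shift(x, 5, 9), 3, c(8, 8, 16))
  expect_lt(max(abs(ps$low - circ_shift(p$low, 5, 9))), 1e-6)
  for (s in 1:3) for (d in seq_along(p$high[[s]]))
    expect_lt(max(abs(ps$high[[s]][[d]] - circ_shift(p$high[[s]][[d]], 5, 9))),
              1e-6)
})

test_that("the transform is linear", {
  set.seed(8)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- matrix(runif(64 * 64), 64, 64)
  px <- lsist_decompose(x, 2, c(4, 4))
  py <- lsist_decompose(y, 2, c(4, 4))
  comb <- px
  comb$low <- 2 * px$low - 3 * py$low
  for (s in 1:2) for (d in 1:4)
    comb$high[[s]][[d]] <- 2 * px$high[[s]][[d]] - 3 * py$high[[s]][[d]]
  expect_equal(lsist_reconstruct(comb),
               2 * lsist_reconstruct(px) - 3 * lsist_reconstruct(py),
               tolerance = 1e-10)
})

test_that("low-band-only pyramids reconstruct their constant", {
  p <- lsist_decompose(matrix(0.4, 64, 64), 2, c(4, 4))
  for (s in 1:2) for (d in 1:4) p$high[[s]][[d]] <- matrix(0, 64, 64)
  expect_equal(lsist_reconstruct(p), matrix(0.4, 64, 64), tolerance = 1e-8)
})

test_that("directional windows partition unity on every scale", {
  fb <- build_shear_filter_bank(64, 96, 3, c(8, 8, 16))
  for (s in 1:3) {
    pou <- Reduce(`+`, lapply(fb$windows[[s]], function(w) w^2))
    expect_lt(max(abs(pou - 1)), 1e-6)
  }
})

test_that("two-direction banks give half-plane wedges swapped by rotation", {
  fb <- build_shear_filter_bank(64, 64, 1, 2)
  W1 <- fb$windows[[1]][[1]]; W2 <- fb$windows[[1]][[2]]
  d <- abs(W2 - t(W1))
  d[1, 1] <- 0                      # DC assigned to the first wedge
  d[33, ] <- 0; d[, 33] <- 0        # Nyquist line is symmetrized separately
  expect_lt(max(d), 1e-10)
})

test_that("angular profiles agree across grid sizes", {
  fb1 <- build_shear_filter_bank(64, 64, 1, 8)
  fb2 <- build_shear_filter_bank(128, 128, 1, 8)
  # corresponding normalized frequencies: (i, j) on 64 maps to (2i, 2j) on 128
  idx1 <- cbind(c(9, 5, 3, 13), c(3, 9, 13, 5))       # assorted off-axis bins
  idx2 <- (idx1 - 1) * 2 + 1
  for (d in 1:8)
    expect_equal(fb1$windows[[1]][[d]][idx1], fb2$windows[[1]][[d]][idx2],
                 tolerance = 1e-3)
})

test_that("band energies sum exactly to the image energy (tight frame)", {
  set.seed(77)
  x <- matrix(runif(96 * 96), 96, 96)
  p <- lsist_decompose(x, 3, c(8, 8, 16))
  e <- sum(p$low^2) +
    sum(vapply(unlist(p$high, recursive = FALSE),
               function(b) sum(b^2), numeric(1)))
  ratio <- e / sum(x^2)
  expect_gte(ratio, 1 - 1e-10)
  expect_lt(ratio, 1 + 1e-10)
})

test_that("oriented gratings concentrate energy in the nearest wedges", {
  n <- 128
  co <- matrix(rep(0:(n - 1), each = n), n, n)
  ro <- matrix(rep(0:(n - 1), n), n, n)
  for (th in c(0, pi / 4, pi / 2)) {
    g <- sin(2 * pi * 0.2 * (cos(th) * co + sin(th) * ro))
    p <- lsist_decompose(g, 3, c(8, 8, 16))
    en <- vapply(unlist(p$high, recursive = FALSE),
                 function(b) sum(b^2), numeric(1))
    expect_gt(sum(sort(en, decreasing = TRUE)[1:2]) / sum(en), 0.8)
  }
})

test_that("invalid direction counts and shapes are rejected", {
  x <- matrix(runif(64 * 64), 64, 64)
  expect_error(lsist_decompose(x, 2, c(3, 4)), "power of 2")
  expect_error(lsist_decompose(x, 2, c(4, 4, 4)), "per scale")
  p <- lsist_decompose(x, 2, c(4, 4))
  p$high[[1]][[1]] <- matrix(0, 32, 32)
  expect_error(lsist_reconstruct(p), "mismatch")
})
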