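# Two-branch (shared-weight) convolutional classifier for sharp-versus-blurred
# patch pairs, and its fully-convolutional application to whole sub-bands.
#
# Branch architecture (fixed): conv 3x3/stride 1 with 64, then 128 filters,
# one 2x2/stride 2 max-pool, conv 3x3 with 256 filters, ReLU after each
# convolution, then a 4x4 average pool collapsing each receptive field to a
# 256-vector. The two branches share one copy of the weights; their features
# are concatenated (512) and a linear 2-way soft-max head scores which input
# holds the sharper content. With valid convolutions this gives each output
# unit a 16x16 receptive field at stride 2, so the same weights score 16x16
# training patches (one unit) and arbitrary-size bands (a dense score map).
# No fully connected layers are used.
#
# Everything runs on base-R array slicing plus BLAS matrix products; training
# is plain SGD with momentum and weight decay on the soft-max cross-entropy,
# fully deterministic under the configuration seed.

#' Network and training configuration
#'
#' Architecture constants (filter counts 64/128/256, 3x3 kernels, stride 1,
#' one 2x2/2 max-pool, 512 concatenated features, 2-way soft-max) are fixed;
#' this object carries the training hyperparameters.
#'
#' @param learning_rate SGD step size (constant schedule).
#' @param epochs number of passes over the training split.
#' @param batch_size pairs per SGD step.
#' @param momentum classical momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param seed integer seed fixing initialization and shuffling.
#' @return object of class `network_config`.
#' @export
network_config <- function(learning_rate = 0.01, epochs = 10,
                           batch_size = 128, momentum = 0.9,
                           weight_decay = 1e-5, seed = 1) {
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(conv_filters = c(64L, 128L, 256L), kernel = 3L, stride = 1L,
                 pool = 2L, learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, momentum = momentum,
                 weight_decay = weight_decay, seed = seed),
            class = "network_config")
}

# He-normal initialization; weights stored as (3, 3, Cin, Cout) arrays.
init_weights <- function(cfg) {
  conv <- function(cin, cout) {
    list(W = array(stats::rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                   dim = c(3, 3, cin, cout)),
         b = numeric(cout))
  }
  nf <- cfg$conv_filters
  list(conv1 = conv(1, nf[1]), conv2 = conv(nf[1], nf[2]),
       conv3 = conv(nf[2], nf[3]),
       head = list(W = matrix(stats::rnorm(2 * nf[3] * 2, 0,
                                           sqrt(1 / (2 * nf[3]))),
                              2 * nf[3], 2),
                   b = numeric(2)))
}

# x: (H, W, N, Cin) -> (H-2, W-2, N, Cout). Compiled im2col gather plus one
# GEMM per convolution; the column matrix is cached for backward when `keep`.
conv_fwd <- function(x, layer, keep = FALSE) {
  d <- dim(x)
  Xcol <- cpp_im2col(x, d[1], d[2], d[3], d[4])
  Y <- Xcol %*% flat_kernel(layer$W)
  Y <- Y + rep(layer$b, each = nrow(Y))
  dim(Y) <- c(d[1] - 2L, d[2] - 2L, d[3], dim(layer$W)[4])
  list(out = Y, Xcol = if (keep) Xcol else NULL, in_dim = d)
}

# (3, 3, Cin, Cout) kernel -> (9*Cin, Cout) matrix matching the im2col
# column order (offset-major, channel-minor).
flat_kernel <- function(W) {
  d <- dim(W)
  Wm <- aperm(W, c(3, 1, 2, 4))           # (Cin, kh, kw, Cout)
  dim(Wm) <- c(9L * d[3], d[4])
  Wm
}

unflat_kernel <- function(Wm, Cin, Cout) {
  dim(Wm) <- c(Cin, 3L, 3L, Cout)
  aperm(Wm, c(2, 3, 1, 4))
}

conv_bwd <- function(dY, layer, cache, need_dX = TRUE) {
  d <- cache$in_dim
  Cin <- d[4]; Cout <- dim(layer$W)[4]
  dYm <- dY; dim(dYm) <- c((d[1] - 2L) * (d[2] - 2L) * d[3], Cout)
  dW <- unflat_kernel(crossprod(cache$Xcol, dYm), Cin, Cout)
  dX <- NULL
  if (need_dX) {
    dXcol <- tcrossprod(dYm, flat_kernel(layer$W))
    dX <- cpp_col2im(dXcol, d[1], d[2], d[3], d[4])
  }
  list(dX = dX, dW = dW, db = colSums(dYm))
}

# 2x2/stride-2 max-pool (odd trailing row/col dropped); argmax tie goes to
# the first candidate in scan order for deterministic gradient routing.
pool_fwd <- function(x) {
  d <- dim(x)
  p <- cpp_maxpool(x, d[1], d[2], d[3], d[4])
  list(out = p$out, argmax = p$argmax, in_dim = d)
}

pool_bwd <- function(dM, cache) {
  d <- cache$in_dim
  cpp_maxpool_bwd(dM, cache$argmax, d[1], d[2], d[3], d[4])
}

relu_fwd <- function(x) pmax(x, 0)

# One shared-weight branch. x: (H, W, N, 1). Returns per-position features
# after the 4x4 stride-1 average pool: (P, Q, N, 256).
branch_fwd <- function(x, wts, keep = FALSE) {
  c1 <- conv_fwd(x, wts$conv1, keep)
  r1 <- relu_fwd(c1$out)
  c2 <- conv_fwd(r1, wts$conv2, keep)
  r2 <- relu_fwd(c2$out)
  p  <- pool_fwd(r2)
  c3 <- conv_fwd(p$out, wts$conv3, keep)
  r3 <- relu_fwd(c3$out)
  d <- dim(r3)
  f <- cpp_avgpool4(r3, d[1], d[2], d[3], d[4])
  list(feat = f, c1 = c1, r1 = r1, c2 = c2, r2 = r2, p = p, c3 = c3, r3 = r3)
}

branch_bwd <- function(dfeat, wts, cache) {
  d <- dim(cache$r3)
  P <- dim(dfeat)[1]; Q <- dim(dfeat)[2]
  dr3 <- array(0, dim = d)
  g <- dfeat / 16
  for (dh in 0:3) for (dw in 0:3)
    dr3[dh + seq_len(P), dw + seq_len(Q), , ] <-
      dr3[dh + seq_len(P), dw + seq_len(Q), , , drop = FALSE] + g
  dr3 <- dr3 * (cache$r3 > 0)
  b3 <- conv_bwd(dr3, wts$conv3, cache$c3)
  dp <- pool_bwd(b3$dX, cache$p)
  dp <- dp * (cache$r2 > 0)
  b2 <- conv_bwd(dp, wts$conv2, cache$c2)
  dr1 <- b2$dX * (cache$r1 > 0)
  b1 <- conv_bwd(dr1, wts$conv1, cache$c1, need_dX = FALSE)
  list(grads = list(conv1 = list(W = b1$dW, b = b1$db),
                    conv2 = list(W = b2$dW, b = b2$db),
                    conv3 = list(W = b3$dW, b = b3$db)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward both patches of each pair through the shared branch (stacked as one
# batch of 2N), then the concatenated head. Patches are (ps, ps, N) arrays.
pair_forward <- function(pa, pb, wts, keep = FALSE) {
  N <- dim(pa)[3]
  x <- array(c(pa, pb), dim = c(dim(pa)[1], dim(pa)[2], 2L * N, 1L))
  br <- branch_fwd(x, wts, keep)
  stopifnot(dim(br$feat)[1] == 1L, dim(br$feat)[2] == 1L)
  feats <- matrix(br$feat, 2L * N, dim(br$feat)[4])
  Fcat <- cbind(feats[seq_len(N), , drop = FALSE],
                feats[N + seq_len(N), , drop = FALSE])
  logits <- sweep(Fcat %*% wts$head$W, 2, wts$head$b, `+`)
  list(logits = logits, Fcat = Fcat, br = br, N = N)
}

sgd_update <- function(wts, grads, vel, cfg, scale) {
  for (ly in c("conv1", "conv2", "conv3", "head")) {
    for (pn in c("W", "b")) {
      g <- grads[[ly]][[pn]] * scale
      if (pn == "W") g <- g + cfg$weight_decay * wts[[ly]][[pn]]
      vel[[ly]][[pn]] <- cfg$momentum * vel[[ly]][[pn]] - cfg$learning_rate * g
      wts[[ly]][[pn]] <- wts[[ly]][[pn]] + vel[[ly]][[pn]]
    }
  }
  list(wts = wts, vel = vel)
}

#' Train the Siamese sharp/blur classifier
#'
#' Minimizes soft-max cross-entropy of pair labels with SGD (momentum,
#' weight decay) on an 80% split, reporting accuracy on the held-out 20%.
#' Fully deterministic given `cfg$seed` (initialization and shuffling come
#' from one seeded stream). `epochs = 0` returns the untrained initialization
#' (useful as a chance-level reference).
#'
#' @param patches a `patch_pair_set` from [generate_patch_pairs()] with at
#'   least 500 pairs of size >= 16.
#' @param cfg a [network_config()].
#' @return object of class `network_weights`: the shared branch and head
#'   parameters plus `training` metadata (final training loss, held-out
#'   accuracy, seed).
#' @export
train_network <- function(patches, cfg = network_config()) {
  if (!inherits(patches, "patch_pair_set"))
    stop("patches must be a patch_pair_set", call. = FALSE)
  if (patches$patch_size < 16) stop("patch size must be >= 16", call. = FALSE)
  n <- length(patches$label)
  if (n < 500) stop("need at least 500 pairs", call. = FALSE)

  with_seed(cfg$seed, {
    wts <- init_weights(cfg)
    vel <- rapply(wts, function(p) p * 0, how = "replace")
    idx <- sample.int(n)
    n_hold <- floor(0.2 * n)
    hold <- idx[seq_len(n_hold)]
    train <- idx[-seq_len(n_hold)]
    final_loss <- NA_real_

    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(train)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        pa <- patches$patch_a[, , bi, drop = FALSE]
        pb <- patches$patch_b[, , bi, drop = FALSE]
        y <- patches$label[bi]
        fw <- pair_forward(pa, pb, wts, keep = TRUE)
        p <- softmax_rows(fw$logits)
        m <- length(bi)
        # class 1 = "patch_a sharper" in column 2 (0-based class id + 1)
        py <- p[cbind(seq_len(m), y + 1L)]
        losses <- c(losses, -mean(log(pmax(py, 1e-12))))
        dlog <- p
        dlog[cbind(seq_len(m), y + 1L)] <- dlog[cbind(seq_len(m), y + 1L)] - 1
        dlog <- dlog / m
        gh <- list(W = crossprod(fw$Fcat, dlog), b = colSums(dlog))
        dF <- tcrossprod(dlog, wts$head$W)
        nf <- ncol(dF) / 2L
        dfeats <- rbind(dF[, seq_len(nf), drop = FALSE],
                        dF[, nf + seq_len(nf), drop = FALSE])
        dfeat <- array(dfeats, dim = c(1L, 1L, 2L * m, nf))
        bb <- branch_bwd(dfeat, wts, fw$br)
        grads <- c(bb$grads, list(head = gh))
        up <- sgd_update(wts, grads, vel, cfg, scale = 1)
        wts <- up$wts; vel <- up$vel
      }
      final_loss <- mean(losses)
    }

    acc <- holdout_accuracy(wts, patches, hold)
    structure(list(conv1 = wts$conv1, conv2 = wts$conv2, conv3 = wts$conv3,
                   head = wts$head, cfg = cfg,
                   training = list(final_loss = final_loss,
                                   holdout_accuracy = acc,
                                   n_holdout = n_hold, seed = cfg$seed)),
              class = "network_weights")
  })
}

holdout_accuracy <- function(wts, patches, hold) {
  correct <- 0L
  for (start in seq(1, length(hold), by = 256)) {
    bi <- hold[start:min(start + 255, length(hold))]
    fw <- pair_forward(patches$patch_a[, , bi, drop = FALSE],
                       patches$patch_b[, , bi, drop = FALSE], wts)
    pred <- max.col(fw$logits, ties.method = "first") - 1L
    correct <- correct + sum(pred == patches$label[bi])
  }
  correct / length(hold)
}

#' Save / load network weights
#'
#' Single-file checkpoint (RDS) embedding the configuration and seed.
#' @param weights a `network_weights` object.
#' @param path file path.
#' @return `load_network` returns the `network_weights` object.
#' @export
save_network <- function(weights, path) {
  stopifnot(inherits(weights, "network_weights"))
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  w <- readRDS(path)
  if (!inherits(w, "network_weights")) stop("not a network checkpoint", call. = FALSE)
  w
}
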