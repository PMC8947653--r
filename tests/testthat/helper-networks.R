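# Trained networks are expensive; train once per session and share.
.net_cache <- new.env(parent = emptyenv())

# Full-scale classifier: 5000 pairs, 10 epochs (the evaluation conditions).
full_network <- function() {
  if (is.null(.net_cache$full)) {
    patches <- generate_patch_pairs(5000, 16, c(1, 3), seed = 1)
    .net_cache$full <- train_network(patches,
                                     network_config(epochs = 10, seed = 11))
  }
  .net_cache$full
}

# Small classifier for cheap contract tests that only need trained-ish weights.
small_network <- function() {
  if (is.null(.net_cache$small)) {
    patches <- generate_patch_pairs(600, 16, c(1, 3), seed = 7)
    .net_cache$small <- train_network(patches,
                                      network_config(epochs = 2, seed = 4))
  }
  .net_cache$small
}
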