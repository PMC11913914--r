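# Tiny encoder-decoder segmentation backbone.
#
# Architecture (channels C, default 4):
#   conv 3x3 (1 -> C) + ReLU            at full resolution
#   2x2 mean-pool                       -> half resolution
#   conv 3x3 (C -> C) + ReLU            at half resolution
#   nearest-neighbour 2x upsample       -> full resolution
#   channel concat with the full-resolution features (2C)
#   conv 1x1 (2C -> 1)                  -> per-pixel logit
#
# The skip connection gives the classifier both fine detail and pooled
# context (effective receptive field ~10 px). All tensors are (H, W, C, B)
# column-major arrays; the 3x3 convolutions run through compiled kernels.
# Backbones are looked up through a small registry so alternative
# architectures can be plugged in behind the same training loop.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

meanpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1, d[1], by = 2)
  o2 <- seq(1, d[2], by = 2)
  (x[o1, o2, , , drop = FALSE] + x[o1 + 1, o2, , , drop = FALSE] +
     x[o1, o2 + 1, , , drop = FALSE] + x[o1 + 1, o2 + 1, , , drop = FALSE]) / 4
}

# Backward of meanpool2: spread the gradient uniformly over each 2x2 block.
meanpool2_bwd <- function(dy, full_dim) {
  up <- upsample2(dy)
  up / 4
}

upsample2 <- function(x) {
  d <- dim(x)
  r <- rep(seq_len(d[1]), each = 2)
  c <- rep(seq_len(d[2]), each = 2)
  x[r, c, , , drop = FALSE]
}

# Backward of nearest-neighbour upsample: sum each 2x2 block.
upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], by = 2)
  o2 <- seq(1, d[2], by = 2)
  dy[o1, o2, , , drop = FALSE] + dy[o1 + 1, o2, , , drop = FALSE] +
    dy[o1, o2 + 1, , , drop = FALSE] + dy[o1 + 1, o2 + 1, , , drop = FALSE]
}

# He-normal initialisation under the current RNG stream.
tiny_unet_init <- function(channels) {
  C <- channels
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  list(W1 = array(he(9 * 1, 9 * C), c(3, 3, 1, C)),
       b1 = rep(0, C),
       W2 = array(he(9 * C, 9 * C * C), c(3, 3, C, C)),
       b2 = rep(0, C),
       W3 = matrix(he(2 * C, 2 * C), 2 * C, 1),
       b3 = 0)
}

# Forward pass. x: (H, W, 1, B). Returns logits (H, W, B) and, optionally,
# the activation cache needed for the backward pass.
tiny_unet_forward <- function(weights, x, keep_cache = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; B <- d[4]
  if (H %% 2 != 0 || W %% 2 != 0) {
    stop_ennseg("tiny_unet requires even image dimensions, got ",
                H, "x", W, class = "ennseg_shape_error")
  }
  C <- length(weights$b1)
  a1 <- conv3x3_fwd(x, dim(x), weights$W1, weights$b1)
  r1 <- relu(a1)
  p <- meanpool2(r1)
  a2 <- conv3x3_fwd(p, dim(p), weights$W2, weights$b2)
  r2 <- relu(a2)
  u <- upsample2(r2)
  # channel concat (r1 | u) -> (H, W, 2C, B), flattened for the 1x1 conv
  cat_mat <- cbind(matrix(aperm(r1, c(1, 2, 4, 3)), ncol = C),
                   matrix(aperm(u, c(1, 2, 4, 3)), ncol = C))
  logits <- cat_mat %*% weights$W3 + weights$b3
  logits <- array(logits, c(H, W, B))
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits,
       cache = list(x = x, a1 = a1, r1 = r1, p = p, a2 = a2, r2 = r2,
                    cat_mat = cat_mat, H = H, W = W, B = B, C = C))
}

# Backward pass from dL/dlogits (H, W, B); returns gradients for every
# weight tensor.
tiny_unet_backward <- function(weights, cache, dlogits) {
  H <- cache$H; W <- cache$W; B <- cache$B; C <- cache$C
  dl_mat <- matrix(dlogits, ncol = 1)
  dW3 <- crossprod(cache$cat_mat, dl_mat)
  db3 <- sum(dl_mat)
  dcat <- dl_mat %*% t(weights$W3)  # (H*W*B) x 2C
  to4 <- function(m) aperm(array(m, c(H, W, B, C)), c(1, 2, 4, 3))
  dr1 <- to4(dcat[, seq_len(C), drop = FALSE])
  du <- to4(dcat[, C + seq_len(C), drop = FALSE])
  dr2 <- upsample2_bwd(du)
  da2 <- dr2 * (cache$a2 > 0)
  gw2 <- conv3x3_bwd_weight(cache$p, dim(cache$p), da2, C)
  dp <- conv3x3_bwd_input(da2, dim(da2), weights$W2, C)
  dr1 <- dr1 + meanpool2_bwd(dp, c(H, W))
  da1 <- dr1 * (cache$a1 > 0)
  gw1 <- conv3x3_bwd_weight(cache$x, dim(cache$x), da1, C)
  list(W1 = gw1$dw, b1 = gw1$db, W2 = gw2$dw, b2 = gw2$db,
       W3 = dW3, b3 = db3)
}

backbone_registry <- function(name) {
  switch(name,
    tiny_unet = list(init = tiny_unet_init, forward = tiny_unet_forward,
                     backward = tiny_unet_backward),
    stop_ennseg("backbone '", name, "' is not available in this package; ",
                "available: tiny_unet", class = "ennseg_value_error"))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-slice standardisation: zero mean, unit variance on the raw stored
# intensities; the model's fixed input normalisation rule.
standardize_slice <- function(pixels) {
  s <- stats::sd(as.vector(pixels))
  if (!is.finite(s) || s < 1e-8) s <- 1
  (pixels - mean(pixels)) / s
}
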