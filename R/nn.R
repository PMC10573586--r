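# Minimal 3-D convolutional network engine.
#
# No deep-learning framework ships with this R toolchain, so the small
# network the package needs is implemented here: 3-D convolution via
# BLAS-backed im2col, ELU, dense layers, nearest-neighbour upsampling, a
# sigmoid score head, manual reverse-mode differentiation (including
# gradients with respect to the *input*, required for saliency maps) and an
# Adam optimizer. Everything is double precision and deterministic given
# the R RNG state at initialization.
#
# Shape conventions: convolutional tensors are arrays (x, y, z, C, B);
# dense activations are matrices (features, B).

.he_init <- function(n_out, n_in, fan_in) {
  matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / fan_in)), n_out, n_in)
}

# ---- layer constructors ----------------------------------------------------

.layer_conv3d <- function(in_dim, c_out, k = 3L, stride = 1L, pad = 1L) {
  sp <- in_dim[1:3]; c_in <- in_dim[4]
  out_sp <- (sp + 2L * pad - k) %/% stride + 1L
  if (any(out_sp < 1L)) {
    stop("conv3d: downsampling collapses an axis below 1 (input ",
         paste(sp, collapse = "x"), ")", call. = FALSE)
  }
  kc <- k^3 * c_in
  P <- sp + 2L * pad
  # im2col gather indices: one column per output position, rows = kernel
  # offsets x input channels, addressing the zero-padded sample volume
  o <- expand.grid(x = (0:(out_sp[1] - 1)) * stride,
                   y = (0:(out_sp[2] - 1)) * stride,
                   z = (0:(out_sp[3] - 1)) * stride)
  ker <- expand.grid(dx = 0:(k - 1), dy = 0:(k - 1), dz = 0:(k - 1),
                     c = 0:(c_in - 1))
  X <- outer(ker$dx, o$x, "+")
  Y <- outer(ker$dy, o$y, "+")
  Z <- outer(ker$dz, o$z, "+")
  idx <- X + P[1] * (Y + P[2] * (Z + P[3] * ker$c)) + 1
  list(type = "conv3d",
       W = .he_init(c_out, kc, kc), b = numeric(c_out),
       k = k, stride = stride, pad = pad,
       in_dim = in_dim, out_dim = c(out_sp, c_out),
       P = P, idx = as.integer(idx), n_out_pos = nrow(o), kc = kc)
}

.layer_dense <- function(n_in, n_out) {
  list(type = "dense", W = .he_init(n_out, n_in, n_in), b = numeric(n_out),
       in_dim = n_in, out_dim = n_out)
}

.layer_elu <- function() list(type = "elu")
.layer_sigmoid <- function() list(type = "sigmoid")
.layer_flatten <- function(in_dim) {
  list(type = "flatten", in_dim = in_dim, out_dim = prod(in_dim))
}
.layer_unflatten <- function(out_dim) {
  list(type = "unflatten", in_dim = prod(out_dim), out_dim = out_dim)
}
.layer_upsample <- function(in_dim, factor) {
  list(type = "upsample", factor = as.integer(factor), in_dim = in_dim,
       out_dim = c(in_dim[1:3] * factor, in_dim[4]))
}

# ---- forward / backward ----------------------------------------------------

.conv_forward <- function(layer, X) {
  d <- dim(X); B <- d[5]
  P <- layer$P; c_in <- layer$in_dim[4]
  pad <- layer$pad
  Xp <- array(0, c(P, c_in, B))
  Xp[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), , ] <- X
  dim(Xp) <- c(prod(P) * c_in, B)
  cols <- Xp[layer$idx, , drop = FALSE]
  dim(cols) <- c(layer$kc, layer$n_out_pos * B)
  Y <- layer$W %*% cols + layer$b
  o <- layer$out_dim
  out <- aperm(array(Y, c(o[4], o[1], o[2], o[3], B)), c(2, 3, 4, 1, 5))
  list(out = out, cache = list(cols = cols, B = B))
}

.conv_backward <- function(layer, cache, dOut) {
  o <- layer$out_dim; B <- cache$B
  dY <- aperm(dOut, c(4, 1, 2, 3, 5))
  dim(dY) <- c(o[4], layer$n_out_pos * B)
  dW <- tcrossprod(dY, cache$cols)
  db <- rowSums(dY)
  dcols <- crossprod(layer$W, dY)
  dim(dcols) <- c(layer$kc * layer$n_out_pos, B)
  rs <- rowsum(dcols, group = layer$idx)
  P <- layer$P; c_in <- layer$in_dim[4]; pad <- layer$pad
  dXp <- matrix(0, prod(P) * c_in, B)
  dXp[as.integer(rownames(rs)), ] <- rs
  dim(dXp) <- c(P, c_in, B)
  sp <- layer$in_dim[1:3]
  dX <- dXp[pad + seq_len(sp[1]), pad + seq_len(sp[2]), pad + seq_len(sp[3]),
            , , drop = FALSE]
  list(dX = dX, grads = list(W = dW, b = db))
}

.layer_forward <- function(layer, X) {
  switch(layer$type,
    conv3d = .conv_forward(layer, X),
    dense = list(out = layer$W %*% X + layer$b, cache = list(X = X)),
    elu = {
      out <- X
      neg <- X < 0
      out[neg] <- expm1(X[neg])
      list(out = out, cache = list(out = out, neg = neg))
    },
    sigmoid = {
      out <- stats::plogis(X)
      list(out = out, cache = list(out = out))
    },
    flatten = {
      B <- dim(X)[5]
      Y <- X; dim(Y) <- c(layer$out_dim, B)
      list(out = Y, cache = list(B = B))
    },
    unflatten = {
      B <- ncol(X)
      Y <- X; dim(Y) <- c(layer$out_dim, B)
      list(out = Y, cache = list(B = B))
    },
    upsample = {
      f <- layer$factor
      d <- layer$in_dim
      out <- X[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f),
               rep(seq_len(d[3]), each = f), , , drop = FALSE]
      list(out = out, cache = NULL)
    },
    stop("unknown layer type ", layer$type)
  )
}

.layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
    conv3d = .conv_backward(layer, cache, dOut),
    dense = list(dX = crossprod(layer$W, dOut),
                 grads = list(W = tcrossprod(dOut, cache$X),
                              b = rowSums(dOut))),
    elu = {
      g <- dOut
      g[cache$neg] <- g[cache$neg] * (cache$out[cache$neg] + 1)
      list(dX = g, grads = NULL)
    },
    sigmoid = list(dX = dOut * cache$out * (1 - cache$out), grads = NULL),
    flatten = {
      dX <- dOut; dim(dX) <- c(layer$in_dim, cache$B)
      list(dX = dX, grads = NULL)
    },
    unflatten = {
      dX <- dOut; dim(dX) <- c(layer$in_dim, cache$B)
      list(dX = dX, grads = NULL)
    },
    upsample = {
      f <- layer$factor
      d <- layer$in_dim
      dX <- array(0, c(d, dim(dOut)[5]))
      for (ox in seq_len(f)) for (oy in seq_len(f)) for (oz in seq_len(f)) {
        dX <- dX + dOut[seq(ox, by = f, length.out = d[1]),
                        seq(oy, by = f, length.out = d[2]),
                        seq(oz, by = f, length.out = d[3]), , , drop = FALSE]
      }
      list(dX = dX, grads = NULL)
    },
    stop("unknown layer type ", layer$type)
  )
}

# Forward through a layer list. Returns the final output and (optionally)
# the per-layer caches needed for the backward pass.
.net_forward <- function(layers, X, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    fw <- .layer_forward(layers[[i]], X)
    X <- fw$out
    if (want_cache) caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

# Backward from layer `from` down to the input. Returns per-layer weight
# gradients and the gradient with respect to the network input.
.net_backward <- function(layers, caches, dOut, from = length(layers)) {
  grads <- vector("list", length(layers))
  for (i in seq(from, 1)) {
    bw <- .layer_backward(layers[[i]], caches[[i]], dOut)
    grads[i] <- list(bw$grads) # [[<-]] with NULL would drop the slot
    dOut <- bw$dX
  }
  list(grads = grads, dX = dOut)
}

.net_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) 0 else length(l$W) + length(l$b)
  }, numeric(1)))
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers) {
  list(t = 0, m = lapply(layers, function(l) {
    if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0)
  }), v = lapply(layers, function(l) {
    if (is.null(l$W)) NULL else list(W = l$W * 0, b = l$b * 0)
  }))
}

.adam_step <- function(layers, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, trainable = rep(TRUE, length(layers))) {
  opt$t <- opt$t + 1
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$W) || is.null(grads[[i]]) || !trainable[i]) next
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      opt$m[[i]][[p]] <- beta1 * opt$m[[i]][[p]] + (1 - beta1) * g
      opt$v[[i]][[p]] <- beta2 * opt$v[[i]][[p]] + (1 - beta2) * g^2
      mhat <- opt$m[[i]][[p]] / corr1
      vhat <- opt$v[[i]][[p]] / corr2
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, opt = opt)
}

# Stack a list of patches (arrays or chiasm_patch) into a (x,y,z,1,B) batch.
.stack_patches <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 3) {
    patches <- list(patches)
  }
  if (is.array(patches) && length(dim(patches)) == 4) {
    d <- dim(patches)
    dim(patches) <- c(d[1:3], 1, d[4])
    return(patches)
  }
  if (is.array(patches) && length(dim(patches)) == 5) {
    return(patches)
  }
  arrs <- lapply(patches, .patch_array)
  d <- dim(arrs[[1]])
  out <- array(0, c(d, 1, length(arrs)))
  for (i in seq_along(arrs)) out[, , , 1, i] <- arrs[[i]]
  out
}
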