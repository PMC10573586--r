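# The two-component chiasm classifier: a 3-D convolutional encoder
# (pretrainable as an autoencoder on chiasm-excluded patches) and a dense
# classification head emitting a score in [0,1], 0 = control, 1 = albinism.

#' Encoder configuration
#'
#' The default is a compact 3-block 3-D convolutional encoder (channels
#' 8/16/32, 3^3 kernels, stride-2 downsampling, 64-dimensional latent) —
#' small enough for CPU training on 4608-voxel patches. The nonlinearity is
#' ELU (smooth, so saliency gradients stay informative everywhere). Every
#' dimension is exposed here so alternatives are one config away.
#'
#' @param n_blocks Number of conv+downsample blocks (`>= 1`).
#' @param channels_per_block Output channels per block.
#' @param kernel Odd kernel size in voxels.
#' @param downsample_factor Spatial stride per block.
#' @param latent_dim Latent vector length.
#' @param nonlinearity Only `"elu"` is implemented.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(n_blocks = 3, channels_per_block = c(8, 16, 32),
                           kernel = 3, downsample_factor = 2,
                           latent_dim = 64, nonlinearity = "elu") {
  stopifnot(n_blocks >= 1, length(channels_per_block) == n_blocks,
            kernel %% 2 == 1, downsample_factor >= 1, latent_dim >= 1)
  nonlinearity <- match.arg(nonlinearity, "elu")
  structure(list(n_blocks = as.integer(n_blocks),
                 channels_per_block = as.integer(channels_per_block),
                 kernel = as.integer(kernel),
                 downsample_factor = as.integer(downsample_factor),
                 latent_dim = as.integer(latent_dim),
                 nonlinearity = nonlinearity),
            class = "encoder_config")
}

# Build the encoder layer list for the fixed patch grid; errors if
# downsampling collapses an axis below one voxel.
.build_encoder_layers <- function(config, geometry = patch_geometry()) {
  sp <- geometry$dims
  layers <- list()
  c_in <- 1L
  for (b in seq_len(config$n_blocks)) {
    conv <- .layer_conv3d(c(sp, c_in), config$channels_per_block[b],
                          k = config$kernel,
                          stride = config$downsample_factor,
                          pad = (config$kernel - 1L) %/% 2L)
    layers <- c(layers, list(conv, .layer_elu()))
    sp <- conv$out_dim[1:3]
    c_in <- conv$out_dim[4]
  }
  layers <- c(layers, list(.layer_flatten(c(sp, c_in)),
                           .layer_dense(prod(sp) * c_in, config$latent_dim)))
  list(layers = layers, spatial = sp, channels = c_in)
}

#' Build an untrained autoencoder
#'
#' Encoder per `config`; decoder mirrors it with nearest-neighbour
#' upsampling and stride-1 convolutions, ending in a linear single-channel
#' reconstruction of the input patch. Weight initialization is reproducible
#' under `seed`; the parameter count is a pure function of `config`.
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `chiasm_autoencoder`.
#' @export
build_autoencoder <- function(config = encoder_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  geom <- patch_geometry()
  enc <- .build_encoder_layers(config)
  sp <- enc$spatial
  f <- config$downsample_factor
  if (!all(sp * f^config$n_blocks == geom$dims)) {
    stop("build_autoencoder: config does not reconstruct the ",
         paste(geom$dims, collapse = "x"),
         " grid (encoder output ", paste(sp, collapse = "x"), ")",
         call. = FALSE)
  }
  dec <- list(.layer_dense(config$latent_dim, prod(sp) * enc$channels),
              .layer_elu(),
              .layer_unflatten(c(sp, enc$channels)))
  c_in <- enc$channels
  chans <- rev(c(1L, config$channels_per_block))[-1] # next channels, ending 1
  for (b in seq_len(config$n_blocks)) {
    up_in <- c(sp * f^(b - 1), c_in)
    dec <- c(dec, list(.layer_upsample(up_in, f)))
    # only the coarsest decoder convolution uses the full kernel; finer
    # scales use 1x1x1 after upsampling — k^3 kernels at fine scales
    # dominate CPU time while only the encoder is reused downstream
    kk <- if (b == 1L) config$kernel else 1L
    conv <- .layer_conv3d(c(up_in[1:3] * f, c_in), chans[b],
                          k = kk, stride = 1L, pad = (kk - 1L) %/% 2L)
    dec <- c(dec, list(conv))
    if (b < config$n_blocks) dec <- c(dec, list(.layer_elu()))
    c_in <- chans[b]
  }
  structure(list(kind = "autoencoder",
                 layers = c(enc$layers, dec),
                 n_encoder_layers = length(enc$layers),
                 config = config, seed = as.integer(seed)),
            class = "chiasm_autoencoder")
}

#' Extract the encoder from an autoencoder or classifier
#'
#' @param model A `chiasm_autoencoder` or `chiasm_classifier`.
#' @return A `chiasm_encoder` (layer list + config).
#' @export
get_encoder <- function(model) {
  stopifnot(inherits(model, c("chiasm_autoencoder", "chiasm_classifier")))
  structure(list(layers = model$layers[seq_len(model$n_encoder_layers)],
                 config = model$config),
            class = "chiasm_encoder")
}

#' Build a classifier from an encoder
#'
#' The classification head is a two-layer dense network over the latent
#' vector with a logistic output, so the score is always in [0,1]
#' (0 = control, 1 = albinism). Encoder weights are copied from the
#' supplied encoder (trained or fresh).
#'
#' @param encoder A `chiasm_encoder`, `chiasm_autoencoder` (its encoder is
#'   used), or an [encoder_config()] (a fresh encoder is initialized).
#' @param head_config List with `hidden` (hidden units, default 16).
#' @param seed Seed for head (and fresh-encoder) initialization.
#' @return A `chiasm_classifier`.
#' @export
build_classifier <- function(encoder = encoder_config(),
                             head_config = list(hidden = 16), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  if (inherits(encoder, "encoder_config")) {
    enc <- .build_encoder_layers(encoder)
    enc_layers <- enc$layers
    config <- encoder
  } else if (inherits(encoder, "chiasm_autoencoder")) {
    enc_layers <- encoder$layers[seq_len(encoder$n_encoder_layers)]
    config <- encoder$config
  } else if (inherits(encoder, "chiasm_encoder")) {
    enc_layers <- encoder$layers
    config <- encoder$config
  } else {
    stop("build_classifier: unsupported encoder object", call. = FALSE)
  }
  latent <- config$latent_dim
  hidden <- if (is.null(head_config$hidden)) 16L else head_config$hidden
  head <- list(.layer_elu(),
               .layer_dense(latent, hidden), .layer_elu(),
               .layer_dense(hidden, 1L), .layer_sigmoid())
  structure(list(kind = "cnn",
                 layers = c(enc_layers, head),
                 n_encoder_layers = length(enc_layers),
                 config = config, head_config = list(hidden = hidden),
                 seed = as.integer(seed)),
            class = "chiasm_classifier")
}

#' Degenerate score models for testing and XAI nulls
#'
#' `constant_score_model()` ignores its input entirely (the XAI null
#' model: every attribution method must return zero maps on it).
#' `linear_score_model()` computes `plogis(sum(weights * x) + bias)`, a
#' model whose attributions have closed forms, used as an oracle.
#'
#' @param score Constant score in [0,1].
#' @return A `chiasm_classifier` of the respective kind.
#' @export
constant_score_model <- function(score = 0.5) {
  stopifnot(score >= 0, score <= 1)
  structure(list(kind = "constant", score = score),
            class = "chiasm_classifier")
}

#' @rdname constant_score_model
#' @param weights Patch-shaped array of linear weights.
#' @param bias Scalar intercept.
#' @export
linear_score_model <- function(weights, bias = 0) {
  stopifnot(is.array(weights))
  structure(list(kind = "linear", weights = weights, bias = bias),
            class = "chiasm_classifier")
}

#' Predict albinism scores
#'
#' Deterministic in inference mode; the batched call equals the
#' concatenation of single-patch calls. The score is interpreted as
#' P(albinism); 1 - score is P(control).
#'
#' @param model A `chiasm_classifier`.
#' @param patches A single patch ([patch_volume()] or 3-D array), a list of
#'   patches, or a 4-D array with samples in the last dimension.
#' @return Numeric vector of scores in [0,1], one per patch, in order.
#' @export
predict_score <- function(model, patches) {
  stopifnot(inherits(model, "chiasm_classifier"))
  X <- .stack_patches(patches)
  if (!all(is.finite(X))) {
    stop("predict_score: non-finite voxel values in input", call. = FALSE)
  }
  d <- dim(X)
  geom <- patch_geometry()
  if (!identical(d[1:3], as.integer(geom$dims))) {
    stop("predict_score: patches must have shape ",
         paste(geom$dims, collapse = "x"), ", got ",
         paste(d[1:3], collapse = "x"), call. = FALSE)
  }
  B <- d[5]
  switch(model$kind,
    constant = rep(model$score, B),
    linear = {
      Xm <- matrix(X, ncol = B)
      as.numeric(stats::plogis(crossprod(Xm, as.vector(model$weights)) +
                                 model$bias))
    },
    cnn = as.numeric(.net_forward(model$layers, X)$out)
  )
}

# Score and its gradient with respect to the input patch; the differentiable
# core behind saliency and gradient-x-input maps.
.score_with_grad <- function(model, patch) {
  x <- .patch_array(patch)
  d <- dim(x)
  switch(model$kind,
    constant = list(score = model$score, grad = array(0, d)),
    linear = {
      s <- predict_score(model, x)
      list(score = s,
           grad = array(as.vector(model$weights) * s * (1 - s), d))
    },
    cnn = {
      X <- .stack_patches(x)
      fw <- .net_forward(model$layers, X, want_cache = TRUE)
      bw <- .net_backward(model$layers, fw$caches, matrix(1, 1, 1))
      g <- bw$dX
      dim(g) <- d
      if (!all(is.finite(g))) {
        stop("saliency: non-finite gradient", call. = FALSE)
      }
      list(score = as.numeric(fw$out), grad = g)
    }
  )
}

#' Number of trainable parameters
#'
#' @param model A `chiasm_autoencoder` or `chiasm_classifier`.
#' @return Integer parameter count (pure function of the configuration).
#' @export
n_parameters <- function(model) {
  if (!is.null(model$kind) && model$kind %in% c("constant", "linear")) {
    return(0L)
  }
  as.integer(.net_n_params(model$layers))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the weights, the full
#' configuration and the training seed, written with R serialization
#' (version 3, gzip).
#'
#' @param model Model object.
#' @param path Destination file.
#' @return `path` / the restored model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
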