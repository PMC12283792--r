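# The decoder network: feature-reduction conv, five dilated-conv encoder
# stages with max-pool downsampling and skip saves, five decoder stages with
# skip concatenation + learnable transposed-conv (or fixed linear) upsampling,
# and a 1x1 output head. Forward and backward passes are written out by hand;
# the convolution/pooling kernels live in src/nnops.cpp. Activations are
# (channels, time, batch) arrays throughout.

#' Decoder network configuration
#'
#' Defaults follow the reference recipe: widths `(64, 64, 128, 256, 512, 512)`
#' (reduction output then five encoder stages), encoder kernels
#' `(7, 7, 5, 5, 5)` with the sawtooth dilation pattern `(1, 2, 3, 1, 2)`,
#' a kernel-3 reduction conv, dropout 0.1 and five finger outputs. Decoder
#' widths mirror the encoder in reverse and decoder kernels reuse the mirrored
#' encoder kernels; skip concatenation therefore doubles the feature axis at
#' every decoder stage.
#'
#' @param in_features flattened input feature count `c * f`.
#' @param layer_dims 6 widths: reduction output + 5 encoder stage outputs.
#' @param kernel_sizes 5 encoder kernel sizes (odd).
#' @param dilations 5 encoder dilation rates.
#' @param reduction_kernel reduction conv kernel size (odd).
#' @param dropout dropout rate in `[0, 1)`.
#' @param n_outputs number of decoded trajectories (5 fingers).
#' @param upsample `"transposed"` (learnable, kernel 2 stride 2) or `"linear"`
#'   (fixed x2 interpolation; the upsampling ablation).
#' @param dilation_enabled if `FALSE` all dilations are 1 (the dilation
#'   ablation); kernels are unchanged.
#' @return list of class `decoder_config`.
#' @export
decoder_config <- function(in_features,
                           layer_dims = c(64, 64, 128, 256, 512, 512),
                           kernel_sizes = c(7, 7, 5, 5, 5),
                           dilations = c(1, 2, 3, 1, 2),
                           reduction_kernel = 3,
                           dropout = 0.1,
                           n_outputs = 5,
                           upsample = c("transposed", "linear"),
                           dilation_enabled = TRUE) {
  upsample <- match.arg(upsample)
  stopifnot(in_features >= 1, length(layer_dims) == 6,
            length(kernel_sizes) == 5, length(dilations) == 5,
            all(layer_dims > 0), all(kernel_sizes > 0), all(dilations > 0),
            dropout >= 0, dropout < 1, n_outputs >= 1)
  if (any(c(kernel_sizes, reduction_kernel) %% 2 == 0))
    stop("kernel sizes must be odd for 'same' padding")
  if (!dilation_enabled) dilations <- rep(1L, 5)
  structure(list(in_features = as.integer(in_features),
                 layer_dims = as.integer(layer_dims),
                 kernel_sizes = as.integer(kernel_sizes),
                 dilations = as.integer(dilations),
                 reduction_kernel = as.integer(reduction_kernel),
                 dropout = dropout, n_outputs = as.integer(n_outputs),
                 upsample = upsample, dilation_enabled = dilation_enabled),
            class = "decoder_config")
}

# decoder stage widths implied by a config (mirror of the encoder, reversed)
.decoder_plan <- function(cfg) {
  d <- cfg$layer_dims
  enc_out <- d[2:6]                       # encoder stage outputs = skip widths
  dec_out <- c(rev(enc_out)[-1], d[1])    # (512,256,128,64) then 64
  dec_in <- c(enc_out[5] + enc_out[5],    # bottleneck concat with skip 5
              dec_out[1:4] + rev(enc_out)[2:5])
  list(dec_in = dec_in, dec_out = dec_out,
       dec_kernels = rev(cfg$kernel_sizes))
}

.he_uniform <- function(n_out, fan_in_cols) {
  bound <- sqrt(6 / fan_in_cols)
  matrix(stats::runif(n_out * fan_in_cols, -bound, bound), n_out, fan_in_cols)
}

#' Build a decoder network
#'
#' Assembles the parameter set for the configured network with fan-in-scaled
#' uniform initialization under the given seed.
#'
#' @param cfg a [decoder_config()].
#' @param seed RNG seed for the initialization (recorded on the model).
#' @return object of class `decoder_net` (list: `config`, `params`, `seed`).
#' @export
build_decoder <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "decoder_config"))
  set.seed(seed)
  d <- cfg$layer_dims
  p <- list()
  p$red.W <- .he_uniform(d[1], cfg$in_features * cfg$reduction_kernel)
  p$red.b <- numeric(d[1])
  enc_in <- d[1:5]; enc_out <- d[2:6]
  for (k in 1:5) {
    p[[sprintf("enc%d.W", k)]] <- .he_uniform(enc_out[k],
                                              enc_in[k] * cfg$kernel_sizes[k])
    p[[sprintf("enc%d.b", k)]] <- numeric(enc_out[k])
    p[[sprintf("enc%d.g", k)]] <- rep(1, enc_out[k])
    p[[sprintf("enc%d.be", k)]] <- numeric(enc_out[k])
  }
  plan <- .decoder_plan(cfg)
  for (k in 1:5) {
    p[[sprintf("dec%d.W", k)]] <- .he_uniform(plan$dec_out[k],
                                              plan$dec_in[k] * plan$dec_kernels[k])
    p[[sprintf("dec%d.b", k)]] <- numeric(plan$dec_out[k])
    p[[sprintf("dec%d.g", k)]] <- rep(1, plan$dec_out[k])
    p[[sprintf("dec%d.be", k)]] <- numeric(plan$dec_out[k])
    if (cfg$upsample == "transposed") {
      p[[sprintf("dec%d.upW", k)]] <- .he_uniform(plan$dec_out[k],
                                                  plan$dec_out[k] * 2)
      p[[sprintf("dec%d.upb", k)]] <- numeric(plan$dec_out[k])
    }
  }
  p$head.W <- .he_uniform(cfg$n_outputs, d[1])
  p$head.b <- numeric(cfg$n_outputs)
  structure(list(config = cfg, params = p, seed = seed),
            class = "decoder_net")
}

#' Count learnable parameters
#'
#' @param model a `decoder_net`.
#' @return total number of learnable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "decoder_net"))
  sum(vapply(model$params, length, integer(1)))
}

#' Per-layer parameter ledger
#'
#' @param model a `decoder_net`.
#' @return data.frame with one row per parameter tensor: `param`, `shape`,
#'   `n`.
#' @export
parameter_ledger <- function(model) {
  stopifnot(inherits(model, "decoder_net"))
  data.frame(
    param = names(model$params),
    shape = vapply(model$params, function(x)
      paste(if (is.matrix(x)) dim(x) else length(x), collapse = "x"),
      character(1)),
    n = vapply(model$params, length, integer(1)),
    row.names = NULL)
}

#' @export
print.decoder_net <- function(x, ...) {
  cfg <- x$config
  cat("1-D dilated-conv encoder / transposed-conv decoder\n")
  cat(sprintf("  input features: %d; widths: %s\n", cfg$in_features,
              paste(cfg$layer_dims, collapse = ", ")))
  cat(sprintf("  encoder kernels: %s; dilations: %s\n",
              paste(cfg$kernel_sizes, collapse = ", "),
              paste(cfg$dilations, collapse = ", ")))
  cat(sprintf("  upsampling: %s; dropout: %g; outputs: %d\n",
              cfg$upsample, cfg$dropout, cfg$n_outputs))
  cat(sprintf("  parameters: %s (init seed %d)\n",
              format(count_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

#' Encoder receptive field at the bottleneck
#'
#' Standard receptive-field recurrence through the reduction conv, the five
#' encoder convs and the five poolings: a conv with kernel `k` and dilation
#' `d` adds `(k - 1) * d * jump`, a x2 pool adds `jump` and doubles the jump.
#'
#' @param cfg a [decoder_config()].
#' @return receptive field in input frames (integer).
#' @export
receptive_field <- function(cfg) {
  stopifnot(inherits(cfg, "decoder_config"))
  rf <- 1; jump <- 1
  rf <- rf + (cfg$reduction_kernel - 1) * jump
  for (k in 1:5) {
    rf <- rf + (cfg$kernel_sizes[k] - 1) * cfg$dilations[k] * jump
    rf <- rf + jump          # max-pool 2
    jump <- jump * 2
  }
  as.integer(rf)
}

# ---- elementwise / normalization layers (C++-backed) -----------------------

.layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- .layernorm_fwd_cpp(x, gamma, beta, eps)
  list(y = r$y, cache = list(xhat = r$xhat, inv = r$inv, gamma = gamma))
}

.layernorm_bwd <- function(gy, cache) {
  .layernorm_bwd_cpp(gy, cache$xhat, cache$inv, cache$gamma)
}

.gelu_fwd <- function(x) list(y = .gelu_fwd_cpp(x), cache = x)
.gelu_bwd <- function(gy, x) .gelu_bwd_cpp(gy, x)

.dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  list(y = x * mask, mask = mask)
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[1:da[1], , ] <- a
  out[da[1] + (1:db[1]), , ] <- b
  out
}

# conv -> layernorm -> GELU -> dropout
.block_fwd <- function(x, W, b, gamma, beta, k, dil, dropout, train) {
  z <- .conv1d_fwd(x, W, b, k, dil)
  ln <- .layernorm_fwd(z, gamma, beta)
  ge <- .gelu_fwd(ln$y)
  dr <- .dropout_fwd(ge$y, dropout, train)
  list(y = dr$y, cache = list(x = x, ln = ln$cache, gelu_x = ge$cache,
                              mask = dr$mask, k = k, dil = dil))
}

.block_bwd <- function(gy, W, cache) {
  if (!is.null(cache$mask)) gy <- gy * cache$mask
  gy <- .gelu_bwd(gy, cache$gelu_x)
  ln <- .layernorm_bwd(gy, cache$ln)
  cv <- .conv1d_bwd(cache$x, W, ln$gx, cache$k, cache$dil)
  list(gx = cv$gx, gW = cv$gW, gb = as.numeric(cv$gb),
       ggamma = ln$ggamma, gbeta = ln$gbeta)
}

#' Forward pass of the decoder network
#'
#' Maps a batch of flattened spectrogram windows `(c*f, l, B)` to finger
#' trajectories `(5, l, B)`. The time length `l` must be divisible by 32 (it
#' is halved by each of the five encoder poolings; the bottleneck has length
#' `l / 32`). In evaluation mode (`train = FALSE`) the pass is deterministic;
#' in training mode dropout draws from the R RNG.
#'
#' @param model a `decoder_net`.
#' @param x input array `(in_features, l, B)` (a matrix is treated as B = 1).
#' @param train enable dropout.
#' @param with_cache keep intermediate activations for [net_backward()].
#' @return if `with_cache`, list `(y, cache)`; else the output array
#'   `(n_outputs, l, B)`.
#' @export
net_forward <- function(model, x, train = FALSE, with_cache = FALSE) {
  stopifnot(inherits(model, "decoder_net"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  cfg <- model$config
  if (d[1] != cfg$in_features)
    stop("shape error at feature-reduction layer: expected ",
         cfg$in_features, " input features, got ", d[1])
  if (d[2] %% 32 != 0)
    stop("shape error: window length ", d[2], " is not divisible by 32")
  p <- model$params
  cache <- list(x = x)
  h <- .conv1d_fwd(x, p$red.W, p$red.b, cfg$reduction_kernel, 1L)
  skips <- vector("list", 5)
  enc_caches <- vector("list", 5)
  pool_caches <- vector("list", 5)
  for (k in 1:5) {
    blk <- .block_fwd(h, p[[sprintf("enc%d.W", k)]], p[[sprintf("enc%d.b", k)]],
                      p[[sprintf("enc%d.g", k)]], p[[sprintf("enc%d.be", k)]],
                      cfg$kernel_sizes[k], cfg$dilations[k], cfg$dropout, train)
    pl <- .maxpool2_fwd(blk$y)
    enc_caches[[k]] <- blk$cache
    pool_caches[[k]] <- list(idx = pl$idx, t_in = dim(blk$y)[2])
    h <- pl$y
    skips[[k]] <- h                       # pooled copy saved for the skip path
  }
  plan <- .decoder_plan(cfg)
  dec_caches <- vector("list", 5)
  up_caches <- vector("list", 5)
  for (k in 1:5) {
    xc <- .concat_ch(h, skips[[6 - k]])
    blk <- .block_fwd(xc, p[[sprintf("dec%d.W", k)]], p[[sprintf("dec%d.b", k)]],
                      p[[sprintf("dec%d.g", k)]], p[[sprintf("dec%d.be", k)]],
                      plan$dec_kernels[k], 1L, cfg$dropout, train)
    dec_caches[[k]] <- c(blk$cache, list(split_at = dim(h)[1]))
    if (cfg$upsample == "transposed") {
      up_caches[[k]] <- blk$y
      h <- .convT1d_fwd(blk$y, p[[sprintf("dec%d.upW", k)]],
                        p[[sprintf("dec%d.upb", k)]])
    } else {
      h <- .linup2_fwd(blk$y)
    }
  }
  y <- .conv1d_fwd(h, p$head.W, p$head.b, 1L, 1L)
  if (!with_cache) return(y)
  cache$enc <- enc_caches; cache$pool <- pool_caches
  cache$dec <- dec_caches; cache$up <- up_caches
  cache$head_in <- h
  list(y = y, cache = cache)
}

#' Backward pass of the decoder network
#'
#' Given the cache from `net_forward(..., with_cache = TRUE)` and the loss
#' gradient with respect to the output, returns gradients for every parameter
#' (named as in `model$params`).
#'
#' @param model a `decoder_net`.
#' @param cache forward cache.
#' @param gy gradient array `(n_outputs, l, B)`.
#' @return named list of gradients.
#' @export
net_backward <- function(model, cache, gy) {
  cfg <- model$config
  p <- model$params
  plan <- .decoder_plan(cfg)
  g <- list()
  hv <- .conv1d_bwd(cache$head_in, p$head.W, gy, 1L, 1L)
  g$head.W <- hv$gW; g$head.b <- as.numeric(hv$gb)
  gh <- hv$gx
  gskips <- vector("list", 5)             # gradient w.r.t. each saved skip
  for (k in 5:1) {
    if (cfg$upsample == "transposed") {
      up <- .convT1d_bwd(cache$up[[k]], p[[sprintf("dec%d.upW", k)]], gh)
      g[[sprintf("dec%d.upW", k)]] <- up$gW
      g[[sprintf("dec%d.upb", k)]] <- as.numeric(up$gb)
      gh <- up$gx
    } else {
      gh <- .linup2_bwd(gh)
    }
    blk <- .block_bwd(gh, p[[sprintf("dec%d.W", k)]], cache$dec[[k]])
    g[[sprintf("dec%d.W", k)]] <- blk$gW
    g[[sprintf("dec%d.b", k)]] <- blk$gb
    g[[sprintf("dec%d.g", k)]] <- blk$ggamma
    g[[sprintf("dec%d.be", k)]] <- blk$gbeta
    sp <- cache$dec[[k]]$split_at
    gh <- blk$gx[1:sp, , , drop = FALSE]
    gsk <- blk$gx[(sp + 1):dim(blk$gx)[1], , , drop = FALSE]
    ki <- 6 - k
    gskips[[ki]] <- if (is.null(gskips[[ki]])) gsk else gskips[[ki]] + gsk
  }
  # gh is now the gradient at the bottleneck (= pooled output of encoder 5),
  # which also received a skip gradient.
  for (k in 5:1) {
    gpool <- gh + gskips[[k]]
    gblk_y <- .maxpool2_bwd(gpool, cache$pool[[k]]$idx, cache$pool[[k]]$t_in)
    blk <- .block_bwd(gblk_y, p[[sprintf("enc%d.W", k)]], cache$enc[[k]])
    g[[sprintf("enc%d.W", k)]] <- blk$gW
    g[[sprintf("enc%d.b", k)]] <- blk$gb
    g[[sprintf("enc%d.g", k)]] <- blk$ggamma
    g[[sprintf("enc%d.be", k)]] <- blk$gbeta
    gh <- blk$gx
  }
  rv <- .conv1d_bwd(cache$x, p$red.W, gh, cfg$reduction_kernel, 1L)
  g$red.W <- rv$gW; g$red.b <- as.numeric(rv$gb)
  g
}
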