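test_that("configuration validates the architecture contract", {
  cfg <- decoder_config(640)
  expect_equal(cfg$layer_dims, c(64L, 64L, 128L, 256L, 512L, 512L))
  expect_equal(cfg$kernel_sizes, c(7L, 7L, 5L, 5L, 5L))
  expect_equal(cfg$dilations, c(1L, 2L, 3L, 1L, 2L))
  expect_equal(cfg$dropout, 0.1)
  expect_error(decoder_config(640, layer_dims = c(64, 64)), "length")
  expect_error(decoder_config(640, kernel_sizes = c(6, 7, 5, 5, 5)), "odd")
  expect_error(decoder_config(640, dropout = 1))
  # disabling dilation flattens the rates
  expect_equal(decoder_config(640, dilation_enabled = FALSE)$dilations,
               rep(1L, 5))
})

test_that("forward maps (B, c*f, l) to (B, 5, l) with an l/32 bottleneck", {
  net <- build_decoder(tiny_config(), seed = 2)
  x <- array(0, c(6, 256, 2))
  y <- net_forward(net, x)
  expect_equal(dim(y), c(5, 256, 2))
  expect_true(all(is.finite(y)))
  # bottleneck length: cached activations at the deepest skip
  fw <- net_forward(net, x, with_cache = TRUE)
  expect_equal(dim(fw$cache$dec[[1]]$x)[2], 256 / 32)
  # skip concatenation doubles the feature axis at every decoder stage
  for (k in 1:5)
    expect_equal(dim(fw$cache$dec[[k]]$x)[1],
                 2 * fw$cache$dec[[k]]$split_at)
  # length-preservation holds across window lengths
  for (l in c(32, 64, 128)) {
    expect_equal(dim(net_forward(net, array(rnorm(6 * l), c(6, l, 1))))[2], l)
  }
  expect_error(net_forward(net, array(0, c(6, 100, 1))), "divisible")
  expect_error(net_forward(net, array(0, c(7, 32, 1))), "feature")
})

test_that("evaluation-mode forward is deterministic; dropout breaks ties in train mode", {
  cfg <- decoder_config(6, layer_dims = c(4, 4, 6, 6, 8, 8), dropout = 0.3)
  net <- build_decoder(cfg, seed = 3)
  x <- array(rnorm(6 * 64 * 2), c(6, 64, 2))
  expect_identical(net_forward(net, x), net_forward(net, x))
  set.seed(31); y1 <- net_forward(net, x, train = TRUE)
  set.seed(32); y2 <- net_forward(net, x, train = TRUE)
  expect_gt(max(abs(y1 - y2)), 0)
  # zero input yields the bias-only response, identical for any zero input
  z1 <- net_forward(net, array(0, c(6, 64, 2)))
  z2 <- net_forward(net, array(0, c(6, 64, 2)))
  expect_identical(z1, z2)
  expect_identical(z1[, , 1], z1[, , 2])
})

test_that("parameter count equals the closed-form ledger", {
  # independent closed-form sum written out layer by layer
  cf <- 10
  dims <- c(4, 4, 6, 6, 8, 8)
  cfg <- decoder_config(cf, layer_dims = dims,
                        kernel_sizes = c(7, 7, 5, 5, 5))
  net <- build_decoder(cfg, seed = 1)
  enc_in <- dims[1:5]; enc_out <- dims[2:6]
  expected <- cf * dims[1] * 3 + dims[1]                  # reduction conv
  for (k in 1:5)
    expected <- expected + enc_in[k] * enc_out[k] * cfg$kernel_sizes[k] +
      enc_out[k] + 2 * enc_out[k]                         # conv + layernorm
  dec_out <- c(8, 6, 6, 4, 4)
  dec_in <- 2 * c(8, 8, 6, 6, 4)
  dec_k <- c(5, 5, 5, 7, 7)
  for (k in 1:5)
    expected <- expected + dec_in[k] * dec_out[k] * dec_k[k] + dec_out[k] +
      2 * dec_out[k] +                                    # conv + layernorm
      dec_out[k] * dec_out[k] * 2 + dec_out[k]            # transposed conv
  expected <- expected + dims[1] * 5 + 5                  # 1x1 head
  expect_equal(count_parameters(net), expected)
  # invariant to batch size and window length by construction; ledger agrees
  lg <- parameter_ledger(net)
  expect_equal(sum(lg$n), expected)
  # single conv layer closed form: 4 -> 8, kernel 3
  w <- lg[lg$param == "red.W", "n"] + lg[lg$param == "red.b", "n"]
  expect_equal(w, cf * 4 * 3 + 4)
})

test_that("dilation strictly enlarges the encoder receptive field", {
  cfg_dil <- decoder_config(640)
  cfg_flat <- decoder_config(640, dilation_enabled = FALSE)
  expect_gt(receptive_field(cfg_dil), receptive_field(cfg_flat))
  expect_type(receptive_field(cfg_dil), "integer")
})

test_that("analytic gradients match numerical differentiation", {
  net <- build_decoder(tiny_config(), seed = 5)
  set.seed(51)
  x <- array(rnorm(6 * 32 * 2), c(6, 32, 2))
  y <- array(rnorm(5 * 32 * 2), c(5, 32, 2))
  fw <- net_forward(net, x, with_cache = TRUE)
  ls <- combined_loss(fw$y, y, lambda = 1, with_grad = TRUE)
  g <- net_backward(net, fw$cache, ls$grad)
  eps <- 1e-5
  for (nm in c("red.W", "enc2.W", "enc3.g", "dec2.W", "dec4.upW", "head.b")) {
    i <- 1 + (length(net$params[[nm]]) - 1) %/% 2
    np <- net
    np$params[[nm]][i] <- np$params[[nm]][i] + eps
    lp <- combined_loss(net_forward(np, x), y, 1)
    np$params[[nm]][i] <- np$params[[nm]][i] - 2 * eps
    lm <- combined_loss(net_forward(np, x), y, 1)
    num <- (lp - lm) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("every parameter receives gradient somewhere (no dead branches)", {
  for (ups in c("transposed", "linear")) {
    net <- build_decoder(tiny_config(upsample = ups), seed = 6)
    set.seed(61)
    x <- array(rnorm(6 * 32 * 3), c(6, 32, 3))
    y <- array(rnorm(5 * 32 * 3), c(5, 32, 3))
    fw <- net_forward(net, x, with_cache = TRUE)
    ls <- combined_loss(fw$y, y, 1, with_grad = TRUE)
    g <- net_backward(net, fw$cache, ls$grad)
    expect_setequal(names(g), names(net$params))
    for (nm in names(g))
      expect_gt(max(abs(g[[nm]])), 0)
  }
})

test_that("the linear-upsampling ablation keeps the shape contract", {
  net <- build_decoder(tiny_config(upsample = "linear"), seed = 7)
  y <- net_forward(net, array(rnorm(6 * 64), c(6, 64, 1)))
  expect_equal(dim(y), c(5, 64, 1))
  expect_false(any(grepl("upW", names(net$params))))
})
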