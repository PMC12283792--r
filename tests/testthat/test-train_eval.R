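test_that("cosine similarity handles the canonical cases", {
  v <- c(1, 2, 3)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_warning(r <- cosine_similarity(c(0, 0), v[1:2]), "zero-norm")
  expect_equal(r, 0)
})

test_that("pearson_r matches a from-definition two-pass oracle and is affine invariant", {
  x <- 1:10
  expect_equal(pearson_r(x, 3 * x + 2), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(21)
  for (i in 1:50) {
    a <- rnorm(40); b <- rnorm(40)
    # two-pass oracle straight from the definition
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b), num / den, tolerance = 1e-10)
    # affine invariance with sign flip
    expect_equal(pearson_r(a, 2.5 * b + 1), pearson_r(a, b), tolerance = 1e-12)
    expect_equal(pearson_r(a, -2.5 * b + 1), -pearson_r(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), 1:5), "zero-variance")
})

test_that("combined loss is zero at the optimum and reduces to MSE at lambda 0", {
  set.seed(22)
  p <- array(rnorm(5 * 32 * 3), c(5, 32, 3))
  expect_equal(combined_loss(p, p, lambda = 1), 0)
  t <- array(rnorm(5 * 32 * 3), c(5, 32, 3))
  expect_equal(combined_loss(p, t, lambda = 0), mean((p - t)^2),
               tolerance = 1e-12)
  # collinear prediction: cosine term vanishes, loss is pure MSE
  expect_equal(combined_loss(2 * t, t, lambda = 1), mean(t^2),
               tolerance = 1e-12)
  expect_gte(combined_loss(p, t, lambda = 1), 0)
  expect_error(combined_loss(p, t[, 1:2, ]), "shape mismatch")
})

test_that("loss gradient matches numerical differentiation", {
  set.seed(23)
  p <- array(rnorm(5 * 8 * 2), c(5, 8, 2))
  t <- array(rnorm(5 * 8 * 2), c(5, 8, 2))
  gr <- combined_loss(p, t, lambda = 0.7, with_grad = TRUE)$grad
  eps <- 1e-6
  for (probe in list(c(1, 1, 1), c(3, 5, 2), c(5, 8, 1))) {
    pp <- p; pp[probe[1], probe[2], probe[3]] <- pp[probe[1], probe[2], probe[3]] + eps
    pm <- p; pm[probe[1], probe[2], probe[3]] <- pm[probe[1], probe[2], probe[3]] - eps
    num <- (combined_loss(pp, t, 0.7) - combined_loss(pm, t, 0.7)) / (2 * eps)
    expect_equal(gr[probe[1], probe[2], probe[3]], num, tolerance = 1e-5)
  }
})

test_that("short training runs reduce the loss and are seed-reproducible", {
  pair <- tiny_pair(t_frames = 160)
  ds <- make_windows(pair$spec, pair$fingers, window_config(32, 8))
  net <- build_decoder(tiny_config(in_features = 12), seed = 9)
  cfg <- train_config(lr = 2e-3, batch_size = 8, max_epochs = 4, seed = 9)
  tr1 <- train_decoder(net, ds, NULL, cfg)
  expect_lt(tr1$history$train_loss[4], tr1$history$train_loss[1])
  tr2 <- train_decoder(net, ds, NULL, cfg)
  expect_equal(tr1$history$train_loss, tr2$history$train_loss,
               tolerance = 1e-12)
})

test_that("training with a large cosine weight raises the cosine term of predictions", {
  pair <- tiny_pair(t_frames = 160)
  ds <- make_windows(pair$spec, pair$fingers, window_config(32, 8))
  net <- build_decoder(tiny_config(in_features = 12), seed = 10)
  x <- window_inputs(ds); y <- window_targets(ds)
  mean_cos <- function(m) {
    p <- net_forward(m, x)
    cs <- 0
    for (s in seq_len(dim(p)[3])) for (f in 1:5)
      cs <- cs + sum(p[f, , s] * y[f, , s]) /
        (sqrt(sum(p[f, , s]^2)) * sqrt(sum(y[f, , s]^2)))
    cs / (5 * dim(p)[3])
  }
  before <- mean_cos(net)
  tr <- train_decoder(net, ds, NULL,
                      train_config(lr = 2e-3, lambda = 20, batch_size = 8,
                                   max_epochs = 5, seed = 10))
  expect_gt(mean_cos(tr$model), before)
})

test_that("evaluation stitches windows and reports per-finger correlations", {
  pair <- tiny_pair(t_frames = 320)
  net <- build_decoder(tiny_config(in_features = 12), seed = 12)
  ev <- evaluate_decoder(net, pair$spec, pair$fingers, "tile", l = 32)
  expect_s3_class(ev, "eval_report")
  expect_length(ev$per_finger_r, 5)
  expect_true(all(abs(ev$per_finger_r) <= 1, na.rm = TRUE))
  expect_equal(ev$mean_r, mean(ev$per_finger_r, na.rm = TRUE))
  expect_equal(ev$n_test_samples, 320)
  # zero-variance truth is reported undefined, excluded from the mean
  f2 <- pair$fingers; f2[3, ] <- 0.5
  expect_warning(ev2 <- evaluate_decoder(net, pair$spec, f2, "tile", l = 32),
                 "zero-variance")
  expect_true(is.na(ev2$per_finger_r[3]))
  expect_false(is.na(ev2$mean_r))
})

test_that("a degenerate one-cell ablation grid reduces to train + evaluate", {
  cfg <- synth_config(n_channels = 10, duration = 30, seed = 30,
                      channels_per_finger = 2)
  traj <- generate_trajectories(cfg)
  ecog <- generate_ecog(traj, cfg)
  n_tr <- 20 * cfg$fs
  rec_tr <- raw_recording(ecog[, 1:n_tr], traj[, 1:(20 * 25)], subject_id = "tr")
  rec_te <- raw_recording(ecog[, (n_tr + 1):ncol(ecog)],
                          traj[, (20 * 25 + 1):ncol(traj)], subject_id = "te")
  tbl <- run_ablation(rec_tr, rec_te,
                      variants = list(list(name = "cell", stride = 16)),
                      pre_cfg = preprocess_config(n_freqs = 8),
                      train_cfg = train_config(batch_size = 8, max_epochs = 1,
                                               steps_per_epoch = 5, seed = 1),
                      layer_dims = c(8, 8, 12, 12, 16, 16),
                      l = 64, max_steps = 5)
  expect_equal(nrow(tbl), 1)
  expect_true(is.na(tbl$error[1]))
  expect_true(is.finite(tbl$mean_r[1]))
  # failures are recorded per cell, not raised
  tbl2 <- run_ablation(rec_tr, rec_te,
                       variants = list(list(name = "bad", wavelet = "nope")),
                       pre_cfg = preprocess_config(n_freqs = 8),
                       train_cfg = train_config(max_epochs = 1, seed = 1),
                       layer_dims = c(8, 8, 12, 12, 16, 16), l = 64)
  expect_false(is.na(tbl2$error[1]))
})
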