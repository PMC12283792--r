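# Training loop (Adam, combined MSE + cosine loss), Pearson-correlation
# evaluation and the ablation harness.

#' Training configuration
#'
#' Defaults follow the reference recipe where one is stated (learning rate
#' 8.42e-5, L2 weight decay 1e-6); the remainder are desk-scale choices:
#' equal loss weighting (`lambda = 1`), batch size 64, up to 40 epochs with
#' early stopping on validation mean Pearson r (patience 5), and a
#' chronological 90/10 train/validation split to avoid temporal leakage.
#'
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty coefficient (added to the gradient).
#' @param lambda weight of the cosine-similarity term in the loss.
#' @param batch_size windows per optimization step.
#' @param max_epochs epoch cap.
#' @param steps_per_epoch optional cap on optimization steps per epoch (a
#'   random subset of windows is visited); `NULL` visits every window.
#' @param patience early-stopping patience in epochs (on validation mean r).
#' @param val_fraction chronological validation fraction in (0, 1).
#' @param seed RNG seed covering initialization, data order and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 8.42e-5, weight_decay = 1e-6, lambda = 1,
                         batch_size = 64, max_epochs = 40,
                         steps_per_epoch = NULL, patience = 5,
                         val_fraction = 0.1, seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, lambda >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, weight_decay = weight_decay, lambda = lambda,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 steps_per_epoch = steps_per_epoch,
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine similarity of two vectors
#'
#' `x . y / (||x|| ||y||)`, in `[-1, 1]`. If either vector has zero norm the
#' similarity is undefined; 0 is returned with a warning so losses built on
#' it stay finite.
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("zero-norm vector in cosine similarity; returning 0")
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Pearson correlation coefficient
#'
#' Covariance of `x` and `y` normalized by their standard deviations.
#' Invariant to positive affine rescaling of either argument. Zero-variance
#' input is an error (the correlation is undefined, not 0).
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero-variance input")
  sum(xc * yc) / (sx * sy)
}

# Mean cosine similarity over (sample, finger) along the time axis, plus its
# gradient w.r.t. pred. Zero-norm pairs contribute similarity 0, gradient 0.
.cosine_term <- function(pred, target) {
  d <- dim(pred)
  n_pairs <- d[1] * d[3]
  csum <- 0
  grad <- array(0, d)
  for (s in seq_len(d[3])) {
    for (f in seq_len(d[1])) {
      p <- pred[f, , s]; t <- target[f, , s]
      np <- sqrt(sum(p^2)); nt <- sqrt(sum(t^2))
      if (np == 0 || nt == 0) next
      cs <- sum(p * t) / (np * nt)
      csum <- csum + cs
      grad[f, , s] <- t / (np * nt) - cs * p / np^2
    }
  }
  list(mean = csum / n_pairs, grad = grad / n_pairs)
}

#' Combined MSE + cosine-similarity loss
#'
#' `MSE(pred, target) + lambda * (1 - mean cosine similarity)`, the cosine
#' term computed per (sample, finger) along the window's time axis, so the
#' loss penalizes both numerical error and misalignment of the trajectory's
#' direction of change. Equals plain MSE at `lambda = 0` and is 0 iff
#' `pred == target` (for `lambda >= 0`).
#'
#' @param pred,target arrays `(5, l, B)` (or any equal 3-D shape).
#' @param lambda cosine term weight.
#' @param with_grad also return the gradient w.r.t. `pred`.
#' @return scalar loss, or list `(loss, grad)` if `with_grad`.
#' @export
combined_loss <- function(pred, target, lambda = 1, with_grad = FALSE) {
  if (!identical(dim(pred), dim(target)))
    stop("shape mismatch: pred ", paste(dim(pred), collapse = "x"),
         " vs target ", paste(dim(target), collapse = "x"))
  diff <- pred - target
  mse <- mean(diff^2)
  if (lambda > 0) {
    ct <- .cosine_term(pred, target)
    loss <- mse + lambda * (1 - ct$mean)
  } else {
    loss <- mse
  }
  if (!with_grad) return(loss)
  grad <- 2 * diff / length(diff)
  if (lambda > 0) grad <- grad - lambda * ct$grad
  list(loss = loss, grad = grad)
}

# One Adam step over the flat named parameter list. `state` carries m, v, t.
.adam_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]] + weight_decay * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.mean_val_r <- function(pred, target) {
  # per-finger r over the concatenated validation windows; zero-variance
  # fingers are skipped
  rs <- c()
  for (f in seq_len(dim(pred)[1])) {
    p <- as.vector(pred[f, , ]); t <- as.vector(target[f, , ])
    if (stats::sd(t) == 0 || stats::sd(p) == 0) next
    rs <- c(rs, pearson_r(p, t))
  }
  if (length(rs) == 0) return(NA_real_)
  mean(rs)
}

#' Train a decoder network
#'
#' Minibatch Adam on the combined MSE + cosine loss, fully seeded (data
#' order and dropout; initialization is seeded in [build_decoder()]). Logs
#' per-epoch training loss, validation loss and validation mean Pearson r,
#' and retains the parameters of the best validation epoch.
#'
#' @param model a `decoder_net` from [build_decoder()].
#' @param train_ds,val_ds `windowed_dataset`s ([make_windows()]); `val_ds`
#'   may be `NULL` to train without validation-based early stopping.
#' @param cfg a [train_config()].
#' @param max_steps optional global cap on optimization steps.
#' @param verbose print one line per epoch.
#' @return list of class `decoder_training`: `model` (best weights),
#'   `history` (data.frame epoch/train_loss/val_loss/val_r), `steps`.
#' @export
train_decoder <- function(model, train_ds, val_ds = NULL,
                          cfg = train_config(), max_steps = Inf,
                          verbose = FALSE) {
  stopifnot(inherits(model, "decoder_net"),
            inherits(train_ds, "windowed_dataset"))
  if (train_ds$n < 1) stop("empty training dataset")
  set.seed(cfg$seed)
  params <- model$params
  state <- list(m = list(), v = list(), t = 0)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_r = numeric())
  best_r <- -Inf; best_params <- params; stale <- 0; steps <- 0
  val_x <- NULL
  if (!is.null(val_ds) && val_ds$n > 0) {
    val_x <- window_inputs(val_ds)
    val_y <- window_targets(val_ds)
  }
  for (epoch in seq_len(cfg$max_epochs)) {
    order <- sample.int(train_ds$n)
    n_steps <- ceiling(train_ds$n / cfg$batch_size)
    if (!is.null(cfg$steps_per_epoch))
      n_steps <- min(n_steps, cfg$steps_per_epoch)
    epoch_loss <- 0
    steps_this_epoch <- 0
    for (b in seq_len(n_steps)) {
      if (steps >= max_steps) break
      i0 <- (b - 1) * cfg$batch_size + 1
      idx <- order[i0:min(i0 + cfg$batch_size - 1, train_ds$n)]
      x <- window_inputs(train_ds, idx)
      y <- window_targets(train_ds, idx)
      model$params <- params
      fw <- net_forward(model, x, train = TRUE, with_cache = TRUE)
      ls <- combined_loss(fw$y, y, cfg$lambda, with_grad = TRUE)
      if (!is.finite(ls$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             " step ", b)
      grads <- net_backward(model, fw$cache, ls$grad)
      upd <- .adam_step(params, grads, state, cfg$lr, cfg$weight_decay)
      params <- upd$params; state <- upd$state
      epoch_loss <- epoch_loss + ls$loss
      steps <- steps + 1
      steps_this_epoch <- steps_this_epoch + 1
    }
    if (steps_this_epoch == 0) break
    epoch_loss <- epoch_loss / steps_this_epoch
    val_loss <- NA_real_; val_r <- NA_real_
    if (!is.null(val_x)) {
      model$params <- params
      vp <- net_forward(model, val_x, train = FALSE)
      val_loss <- combined_loss(vp, val_y, cfg$lambda)
      val_r <- .mean_val_r(vp, val_y)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_loss = val_loss, val_r = val_r))
    if (verbose)
      message(sprintf("epoch %d: train %.5f, val %.5f, val r %.3f",
                      epoch, epoch_loss, val_loss, val_r))
    if (!is.null(val_x) && is.finite(val_r)) {
      if (val_r > best_r) {
        best_r <- val_r; best_params <- params; stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= cfg$patience) break
      }
    } else {
      best_params <- params
    }
    if (steps >= max_steps) break
  }
  model$params <- if (is.finite(best_r)) best_params else params
  structure(list(model = model, history = history, steps = steps,
                 config = cfg),
            class = "decoder_training")
}

#' @export
print.decoder_training <- function(x, ...) {
  h <- x$history
  cat(sprintf("decoder training: %d epochs, %d steps\n", nrow(h), x$steps))
  cat(sprintf("  train loss %.5f -> %.5f\n", h$train_loss[1],
              h$train_loss[nrow(h)]))
  if (any(is.finite(h$val_r)))
    cat(sprintf("  best validation mean r: %.3f\n",
                max(h$val_r, na.rm = TRUE)))
  invisible(x)
}

#' Evaluate a trained decoder on an aligned test spectrogram
#'
#' Segments the test span into windows (non-overlapping tiles by default),
#' runs the forward pass, stitches the windowed predictions back into a
#' continuous trajectory and computes the per-finger Pearson correlation over
#' the full stitched span. Fingers whose true trace has zero variance are
#' reported as `NA` and excluded from the mean with a warning.
#'
#' @param model a `decoder_net` (or a `decoder_training`, whose best model is
#'   used).
#' @param spec test [ecog_spectrogram()] at the model's input rate.
#' @param fingers `5 x T` true trajectories aligned with `spec`.
#' @param stitch_mode `"tile"` (stride = window length) or `"overlap_mean"`
#'   (dense stride-`stride` windows, averaged).
#' @param l window length.
#' @param stride stride for `"overlap_mean"` (ignored for `"tile"`).
#' @return object of class `eval_report`: `per_finger_r` (named, length 5),
#'   `mean_r`, `n_test_samples`, `predictions`, `truth`.
#' @export
evaluate_decoder <- function(model, spec, fingers,
                             stitch_mode = c("tile", "overlap_mean"),
                             l = 256, stride = 32) {
  stitch_mode <- match.arg(stitch_mode)
  if (inherits(model, "decoder_training")) model <- model$model
  stopifnot(inherits(model, "decoder_net"),
            inherits(spec, "ecog_spectrogram"))
  T_full <- dim(spec$values)[3]
  stopifnot(ncol(fingers) == T_full)
  s <- if (stitch_mode == "tile") l else stride
  T_use <- if (stitch_mode == "tile") (T_full %/% l) * l else T_full
  if (T_use < l) stop("test span (", T_full, " frames) shorter than window")
  spec_use <- spec
  spec_use$values <- spec$values[, , 1:T_use, drop = FALSE]
  ds <- make_windows(spec_use, fingers[, 1:T_use, drop = FALSE],
                     window_config(l, s))
  preds <- array(0, c(5, l, ds$n))
  bs <- 16
  for (i0 in seq(1, ds$n, by = bs)) {
    idx <- i0:min(i0 + bs - 1, ds$n)
    preds[, , idx] <- net_forward(model, window_inputs(ds, idx),
                                  train = FALSE)
  }
  yhat <- stitch_predictions(preds, ds$starts, T_use, stitch_mode)
  truth <- fingers[, 1:T_use, drop = FALSE]
  per_r <- stats::setNames(rep(NA_real_, 5), FINGER_NAMES)
  for (f in 1:5) {
    if (stats::sd(truth[f, ]) == 0) {
      warning("finger '", FINGER_NAMES[f],
              "' has zero-variance truth; correlation undefined")
      next
    }
    if (stats::sd(yhat[f, ]) == 0) {
      warning("finger '", FINGER_NAMES[f],
              "' has constant prediction; correlation undefined")
      next
    }
    per_r[f] <- pearson_r(yhat[f, ], truth[f, ])
  }
  structure(list(per_finger_r = per_r,
                 mean_r = mean(per_r, na.rm = TRUE),
                 n_test_samples = T_use,
                 predictions = yhat, truth = truth),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("decoder evaluation (", x$n_test_samples, " frames)\n", sep = "")
  for (f in names(x$per_finger_r))
    cat(sprintf("  %-7s r = %s\n", f,
                ifelse(is.na(x$per_finger_r[f]), "undefined",
                       sprintf("%.3f", x$per_finger_r[f]))))
  cat(sprintf("  mean    r = %.3f\n", x$mean_r))
  invisible(x)
}

#' Ablation / stride experiment harness
#'
#' Trains and evaluates one model per variant on a shared train/test pair
#' with shared seeds, varying the wavelet family, the dilation switch, the
#' upsampling mode and the training window stride. Per-variant failures are
#' recorded and the grid continues.
#'
#' @param rec_train,rec_test [raw_recording()]s; `rec_test` must carry finger
#'   truth.
#' @param variants list of variant descriptors, each a list with any of
#'   `name`, `wavelet` ("morlet", "haar", "daubechies", "symlet"),
#'   `dilation` (logical), `upsample` ("transposed"/"linear"),
#'   `stride` (training stride).
#' @param pre_cfg a [preprocess_config()].
#' @param train_cfg a [train_config()] (the shared seed lives here).
#' @param layer_dims,l model widths and window length.
#' @param max_steps per-variant training step cap.
#' @return data.frame: one row per variant with `name`, `wavelet`,
#'   `dilation`, `upsample`, `stride`, `mean_r`, per-finger r columns, and
#'   `error` (NA on success).
#' @export
run_ablation <- function(rec_train, rec_test, variants,
                         pre_cfg = preprocess_config(),
                         train_cfg = train_config(),
                         layer_dims = c(64, 64, 128, 256, 512, 512),
                         l = 256, max_steps = Inf) {
  stopifnot(ncol(rec_test$fingers) > 0)
  cache <- new.env(parent = emptyenv())
  get_pre <- function(wavelet) {
    key <- wavelet
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- if (wavelet == "morlet") {
      list(train = preprocess_recording(rec_train, pre_cfg),
           test = preprocess_recording(rec_test, pre_cfg))
    } else {
      pre_alt <- function(rec) {
        params <- morlet_params(pre_cfg$f_lo, pre_cfg$f_hi, pre_cfg$n_freqs,
                                pre_cfg$n_cycles)
        x <- normalize_channels(rec$ecog)
        x <- bandpass_filter(x, rec$fs_ecog, pre_cfg$f_lo, pre_cfg$f_hi,
                             pre_cfg$bp_order)
        x <- notch_filter(x, rec$fs_ecog, pre_cfg$line_freq,
                          pre_cfg$harmonics, pre_cfg$notch_q)
        spec <- alt_wavelet_spectrogram(x, rec$fs_ecog, wavelet, params,
                                        rec$channel_ids)
        spec <- downsample_time(spec, pre_cfg$out_fs)
        fing <- interpolate_fingers(rec$fingers, pre_cfg$out_fs,
                                    rec$fs_glove)
        tt <- min(dim(spec$values)[3], ncol(fing))
        spec$values <- spec$values[, , 1:tt, drop = FALSE]
        list(spec = spec, fingers = fing[, 1:tt, drop = FALSE])
      }
      list(train = pre_alt(rec_train), test = pre_alt(rec_test))
    }
    cache[[key]] <- res
    res
  }
  rows <- list()
  for (v in variants) {
    name <- if (!is.null(v$name)) v$name else paste0("variant", length(rows) + 1)
    wavelet <- if (!is.null(v$wavelet)) v$wavelet else "morlet"
    dilation <- if (!is.null(v$dilation)) v$dilation else TRUE
    upsample <- if (!is.null(v$upsample)) v$upsample else "transposed"
    stride <- if (!is.null(v$stride)) v$stride else 1
    row <- data.frame(name = name, wavelet = wavelet, dilation = dilation,
                      upsample = upsample, stride = stride,
                      mean_r = NA_real_, thumb = NA_real_, index = NA_real_,
                      middle = NA_real_, ring = NA_real_, little = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      pre <- get_pre(wavelet)
      tt <- dim(pre$train$spec$values)[3]
      n_val <- max(l, floor(tt * train_cfg$val_fraction))
      cut <- tt - n_val
      sp_tr <- pre$train$spec
      sp_tr$values <- sp_tr$values[, , 1:cut, drop = FALSE]
      sp_va <- pre$train$spec
      sp_va$values <- sp_va$values[, , (cut + 1):tt, drop = FALSE]
      ds_tr <- make_windows(sp_tr, pre$train$fingers[, 1:cut, drop = FALSE],
                            window_config(l, stride))
      ds_va <- make_windows(sp_va,
                            pre$train$fingers[, (cut + 1):tt, drop = FALSE],
                            window_config(l, l))
      cf <- dim(pre$train$spec$values)[1] * dim(pre$train$spec$values)[2]
      net <- build_decoder(decoder_config(cf, layer_dims = layer_dims,
                                          upsample = upsample,
                                          dilation_enabled = dilation),
                           seed = train_cfg$seed)
      tr <- train_decoder(net, ds_tr, ds_va, train_cfg, max_steps = max_steps)
      evaluate_decoder(tr, pre$test$spec, pre$test$fingers, "tile", l = l)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$error <- conditionMessage(res)
    } else {
      row$mean_r <- res$mean_r
      row[, FINGER_NAMES] <- as.list(res$per_finger_r)
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
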