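# High-level modelling interface: one fitting function returning a classed
# fit with the usual accessor methods, wrapping the window / build / train /
# evaluate pipeline.

#' Fit a finger-flexion decoder to an aligned spectrogram / trajectory pair
#'
#' The front door of the package: takes a preprocessed recording (an
#' [ecog_spectrogram()] at 100 Hz with its aligned `5 x T` trajectory
#' matrix), splits it chronologically into training and validation spans,
#' segments both into sliding windows, builds the dilated-conv
#' encoder-decoder and trains it with Adam on the combined MSE + cosine
#' loss. Returns a classed fit with `print`, `summary`, `predict`, `plot`,
#' `coef` and `residuals` methods.
#'
#' @param spec an [ecog_spectrogram()] (typically from
#'   [preprocess_recording()]).
#' @param fingers `5 x T` trajectory matrix aligned with `spec`.
#' @param window_length,stride sliding-window geometry for training.
#' @param config a [decoder_config()]; `NULL` builds the default for the
#'   spectrogram's `c * f` feature count.
#' @param train a [train_config()].
#' @param max_steps optional global cap on optimization steps.
#' @param verbose print per-epoch progress.
#' @return object of class `ecog_decoder`.
#' @export
ecog_decoder <- function(spec, fingers, window_length = 256, stride = 1,
                         config = NULL, train = train_config(),
                         max_steps = Inf, verbose = FALSE) {
  stopifnot(inherits(spec, "ecog_spectrogram"))
  d <- dim(spec$values)
  stopifnot(ncol(fingers) == d[3])
  if (is.null(config)) config <- decoder_config(d[1] * d[2])
  tt <- d[3]
  n_val <- max(window_length, floor(tt * train$val_fraction))
  cut <- tt - n_val
  if (cut < window_length)
    stop("series too short (", tt, " frames) for window length ",
         window_length, " plus a validation span")
  sp_tr <- spec; sp_tr$values <- spec$values[, , 1:cut, drop = FALSE]
  sp_va <- spec; sp_va$values <- spec$values[, , (cut + 1):tt, drop = FALSE]
  ds_tr <- make_windows(sp_tr, fingers[, 1:cut, drop = FALSE],
                        window_config(window_length, stride))
  ds_va <- make_windows(sp_va, fingers[, (cut + 1):tt, drop = FALSE],
                        window_config(window_length, window_length))
  net <- build_decoder(config, seed = train$seed)
  tr <- train_decoder(net, ds_tr, ds_va, train, max_steps = max_steps,
                      verbose = verbose)
  val_eval <- evaluate_decoder(tr$model, sp_va,
                               fingers[, (cut + 1):tt, drop = FALSE],
                               "tile", l = window_length)
  structure(list(net = tr$model, history = tr$history, steps = tr$steps,
                 config = config, train_config = train,
                 window_length = window_length, stride = stride,
                 n_train_frames = cut, n_val_frames = n_val,
                 val_eval = val_eval, freqs = spec$freqs,
                 channel_ids = spec$channel_ids),
            class = "ecog_decoder")
}

#' @export
print.ecog_decoder <- function(x, ...) {
  cat("ECoG finger-flexion decoder fit\n")
  cat(sprintf("  %d training frames, %d validation frames, window %d stride %d\n",
              x$n_train_frames, x$n_val_frames, x$window_length, x$stride))
  cat(sprintf("  %d optimization steps, %d epochs logged\n",
              x$steps, nrow(x$history)))
  cat(sprintf("  validation mean r: %.3f\n", x$val_eval$mean_r))
  invisible(x)
}

#' @export
summary.ecog_decoder <- function(object, ...) {
  cat("ECoG finger-flexion decoder fit\n\n")
  print(object$net)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  cat("\nHeld-out validation span:\n")
  print(object$val_eval)
  invisible(object)
}

#' Predict finger trajectories from a new spectrogram
#'
#' @param object an `ecog_decoder` fit.
#' @param newdata an [ecog_spectrogram()] with the same `c * f` feature
#'   count as the fit.
#' @param stitch_mode `"tile"` or `"overlap_mean"` (see
#'   [stitch_predictions()]).
#' @param stride stride for `"overlap_mean"`.
#' @param ... unused.
#' @return `5 x T'` matrix of decoded trajectories (`T'` is the covered
#'   span: `floor(T / l) * l` frames for `"tile"`).
#' @export
predict.ecog_decoder <- function(object, newdata,
                                 stitch_mode = c("tile", "overlap_mean"),
                                 stride = 32, ...) {
  stitch_mode <- match.arg(stitch_mode)
  stopifnot(inherits(newdata, "ecog_spectrogram"))
  l <- object$window_length
  d <- dim(newdata$values)
  T_use <- if (stitch_mode == "tile") (d[3] %/% l) * l else d[3]
  if (T_use < l) stop("spectrogram shorter than one window")
  sp <- newdata
  sp$values <- newdata$values[, , 1:T_use, drop = FALSE]
  ds <- make_windows(sp, matrix(0, 5, T_use),
                     window_config(l, if (stitch_mode == "tile") l else stride))
  starts <- ds$starts
  if (stitch_mode == "overlap_mean" && max(starts) + l < T_use)
    starts <- c(starts, T_use - l)    # tail window so every frame is covered
  preds <- array(0, c(5, l, length(starts)))
  bs <- 16
  for (i0 in seq(1, length(starts), by = bs)) {
    idx <- i0:min(i0 + bs - 1, length(starts))
    xb <- array(0, c(nrow(ds$features), l, length(idx)))
    for (j in seq_along(idx))
      xb[, , j] <- ds$features[, (starts[idx[j]] + 1):(starts[idx[j]] + l)]
    preds[, , idx] <- net_forward(object$net, xb, train = FALSE)
  }
  out <- stitch_predictions(preds, starts, T_use, stitch_mode)
  rownames(out) <- FINGER_NAMES
  out
}

#' @export
coef.ecog_decoder <- function(object, ...) object$net$params

#' @export
residuals.ecog_decoder <- function(object, ...) {
  object$val_eval$truth - object$val_eval$predictions
}

#' Plot a decoder fit
#'
#' Two panels: the training / validation loss curves, and the held-out
#' validation span with decoded and true trajectories overlaid for each
#' finger.
#'
#' @param x an `ecog_decoder` fit.
#' @param ... unused.
#' @export
plot.ecog_decoder <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", main = "training curves")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  ev <- x$val_eval
  t_axis <- seq_len(ncol(ev$truth))
  graphics::matplot(t_axis, t(ev$truth + 1.2 * (4:0)), type = "l", lty = 1,
                    col = "grey50", xlab = "validation frame",
                    ylab = "flexion (offset per finger)",
                    main = sprintf("validation decode, mean r = %.2f",
                                   ev$mean_r))
  graphics::matlines(t_axis, t(ev$predictions + 1.2 * (4:0)), lty = 1,
                     col = "firebrick")
  invisible(x)
}
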