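# Overlapping sliding-window segmentation of aligned spectrogram / trajectory
# pairs, and stitching of windowed predictions back to a continuous trace.
#
# Feature flattening is channel-major: feature index = (channel - 1) * n_freqs
# + frequency, i.e. all frequencies of channel 1, then channel 2, ... This
# order is recorded in the dataset object and relied on by the model's
# feature-reduction layer.

#' Sliding-window configuration
#'
#' @param l window length in frames (default 256; the decoder halves the time
#'   axis five times, so `l` must be divisible by 32).
#' @param s stride between window starts in frames (default 1, the densest
#'   overlap).
#' @return list of class `window_config`.
#' @export
window_config <- function(l = 256, s = 1) {
  stopifnot(l >= 1, s >= 1, l %% 1 == 0, s %% 1 == 0)
  if (l %% 32 != 0)
    stop("window length l must be divisible by 32 (five halvings), got ", l)
  structure(list(l = as.integer(l), s = as.integer(s)),
            class = "window_config")
}

#' Number of sliding windows
#'
#' The count law for a window of length `l` sliding with stride `s` over `T`
#' frames: `N = floor((T - l) / s) + 1`.
#'
#' @param T total number of aligned frames.
#' @param l window length.
#' @param s stride.
#' @return integer window count (always >= 1).
#' @export
count_windows <- function(T, l, s) {
  stopifnot(l >= 1, s >= 1)
  if (T < l)
    stop("zero windows: series length T = ", T, " is shorter than the window l = ", l)
  as.integer((T - l) %/% s + 1)
}

#' Segment an aligned spectrogram / trajectory pair into training windows
#'
#' Produces the model's sample set: window `i` (1-based) covers frames
#' `start_i + 1 .. start_i + l` with `start_i = (i - 1) * s` (starts are kept
#' 0-based). Inputs are stored once as the flattened `(c * f) x T` feature
#' matrix; individual windows are materialized on demand by
#' [window_inputs()] / [window_targets()], which keeps dense stride-1 datasets
#' affordable.
#'
#' @param spec an [ecog_spectrogram()].
#' @param fingers `5 x T` trajectory matrix aligned with `spec`.
#' @param cfg a [window_config()].
#' @return An object of class `windowed_dataset` with elements `features`
#'   (`(c*f) x T`), `targets` (`5 x T`), `starts` (0-based), `l`, `s`, `n`,
#'   `n_channels`, `n_freqs`.
#' @export
make_windows <- function(spec, fingers, cfg = window_config()) {
  stopifnot(inherits(spec, "ecog_spectrogram"), inherits(cfg, "window_config"))
  d <- dim(spec$values)
  if (ncol(fingers) != d[3])
    stop("misaligned lengths: spectrogram has ", d[3], " frames but fingers ",
         ncol(fingers))
  n <- count_windows(d[3], cfg$l, cfg$s)
  # channel-major flattening: row (ch-1)*F + f  <=>  aperm to (f, c, t)
  features <- matrix(aperm(spec$values, c(2, 1, 3)), d[1] * d[2], d[3])
  structure(list(features = features, targets = fingers,
                 starts = as.integer((seq_len(n) - 1) * cfg$s),
                 l = cfg$l, s = cfg$s, n = n,
                 n_channels = d[1], n_freqs = d[2]),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("windowed dataset: %d windows of (%d features x %d frames), stride %d\n",
              x$n, nrow(x$features), x$l, x$s))
  cat(sprintf("  features = %d channels x %d frequencies (channel-major)\n",
              x$n_channels, x$n_freqs))
  invisible(x)
}

#' Materialize window inputs / targets
#'
#' @param ds a `windowed_dataset`.
#' @param idx window indices (1-based).
#' @return `window_inputs()`: array `(c*f) x l x length(idx)`;
#'   `window_targets()`: array `5 x l x length(idx)`.
#' @export
window_inputs <- function(ds, idx = seq_len(ds$n)) {
  stopifnot(inherits(ds, "windowed_dataset"), all(idx >= 1), all(idx <= ds$n))
  out <- array(0, c(nrow(ds$features), ds$l, length(idx)))
  for (j in seq_along(idx)) {
    s0 <- ds$starts[idx[j]]
    out[, , j] <- ds$features[, (s0 + 1):(s0 + ds$l)]
  }
  out
}

#' @rdname window_inputs
#' @export
window_targets <- function(ds, idx = seq_len(ds$n)) {
  stopifnot(inherits(ds, "windowed_dataset"), all(idx >= 1), all(idx <= ds$n))
  out <- array(0, c(5, ds$l, length(idx)))
  for (j in seq_along(idx)) {
    s0 <- ds$starts[idx[j]]
    out[, , j] <- ds$targets[, (s0 + 1):(s0 + ds$l)]
  }
  out
}

#' Stitch windowed predictions back into a continuous trajectory
#'
#' `"tile"` expects non-overlapping windows (stride = length) that exactly
#' cover `[0, T)` and concatenates them; `"overlap_mean"` averages, at every
#' frame, all window predictions covering that frame (all frames must be
#' covered).
#'
#' @param window_preds array `5 x l x N` of per-window predictions.
#' @param starts 0-based window start offsets (as in a `windowed_dataset`).
#' @param T total output length in frames.
#' @param mode `"tile"` or `"overlap_mean"`.
#' @return `5 x T` matrix.
#' @export
stitch_predictions <- function(window_preds, starts, T,
                               mode = c("tile", "overlap_mean")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(window_preds)) == 3, dim(window_preds)[1] == 5)
  l <- dim(window_preds)[2]
  n <- dim(window_preds)[3]
  stopifnot(length(starts) == n)
  if (mode == "tile") {
    expected <- seq(0, T - l, by = l)
    if (T %% l != 0 || !identical(as.integer(sort(starts)), as.integer(expected)))
      stop("coverage gap: tile mode needs non-overlapping windows exactly tiling [0, ",
           T, ")")
    out <- matrix(0, 5, T)
    for (j in seq_len(n))
      out[, (starts[j] + 1):(starts[j] + l)] <- window_preds[, , j]
    out
  } else {
    acc <- matrix(0, 5, T)
    cnt <- numeric(T)
    for (j in seq_len(n)) {
      sl <- (starts[j] + 1):(starts[j] + l)
      acc[, sl] <- acc[, sl] + window_preds[, , j]
      cnt[sl] <- cnt[sl] + 1
    }
    if (any(cnt == 0))
      stop("coverage gap: ", sum(cnt == 0), " frame(s) covered by no window")
    sweep(acc, 2, cnt, "/")
  }
}
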