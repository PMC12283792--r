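# Signal path: trajectory upsampling, channel normalization, band-pass +
# notch filtering, Morlet wavelet spectrogram, temporal downsampling to the
# common 100 Hz rate. All ECoG arrays are (channels x time).

#' Morlet analysis parameters
#'
#' Center frequencies are log-uniformly spaced over `[f_lo, f_hi]` (endpoints
#' included). The Gaussian envelope width of each wavelet is
#' `sigma(f) = n_cycles / (2 * pi * f)` seconds, so every wavelet carries the
#' same number of oscillation cycles and bandwidth scales with frequency.
#' Each sampled wavelet is normalized to unit L2 norm so amplitudes are
#' comparable across frequencies.
#'
#' @param f_lo,f_hi analysis band edges in Hz (defaults 40 and 300, the
#'   decoding band for movement-related high-gamma activity).
#' @param n_freqs number of center frequencies on the log grid.
#' @param n_cycles cycles per wavelet; scalar or one value per frequency.
#' @return An object of class `morlet_params` with elements `freqs`,
#'   `n_cycles` and `sigma` (seconds, per frequency).
#' @export
morlet_params <- function(f_lo = 40, f_hi = 300, n_freqs = 40, n_cycles = 7) {
  stopifnot(f_lo > 0, f_hi > f_lo, n_freqs >= 2)
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n_freqs))
  freqs[1] <- f_lo; freqs[n_freqs] <- f_hi   # pin endpoints exactly
  if (length(n_cycles) == 1) n_cycles <- rep(n_cycles, n_freqs)
  stopifnot(length(n_cycles) == n_freqs, all(n_cycles > 0))
  sigma <- n_cycles / (2 * pi * freqs)
  structure(list(freqs = freqs, n_cycles = n_cycles, sigma = sigma),
            class = "morlet_params")
}

#' 3D wavelet amplitude spectrogram container
#'
#' @param values non-negative array `(channel, frequency, time)`.
#' @param fs sampling rate of the time axis in Hz.
#' @param freqs center frequencies in Hz.
#' @param channel_ids channel labels.
#' @param kind `"amplitude"` or `"power"`.
#' @return An object of class `ecog_spectrogram`.
#' @export
ecog_spectrogram <- function(values, fs, freqs, channel_ids = NULL,
                             kind = "amplitude") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[2] == length(freqs))
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrogram values must be finite and non-negative")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(dim(values)[1]))
  structure(list(values = values, fs = fs, freqs = freqs,
                 channel_ids = as.character(channel_ids), kind = kind),
            class = "ecog_spectrogram")
}

#' @export
print.ecog_spectrogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ECoG %s spectrogram: %d channels x %d frequencies x %d frames @ %g Hz\n",
              x$kind, d[1], d[2], d[3], x$fs))
  cat(sprintf("  frequency grid: %.1f-%.1f Hz (log-spaced)\n",
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Upsample finger trajectories by cubic interpolation
#'
#' Raises the dataglove sampling rate (25 Hz) to the spectrogram frame rate
#' (default 100 Hz) with a cubic spline that passes through every original
#' sample. The output has exactly `n * target_fs / fs_in` samples, so the last
#' few frames beyond the final knot are cubic extrapolations.
#'
#' @param fingers numeric matrix `5 x n` at `fs_in` Hz.
#' @param target_fs target rate; must be an integer multiple of `fs_in`.
#' @param fs_in input rate (default 25).
#' @return numeric matrix `5 x (n * target_fs / fs_in)`.
#' @export
interpolate_fingers <- function(fingers, target_fs = 100, fs_in = 25) {
  stopifnot(is.matrix(fingers), nrow(fingers) == 5)
  n <- ncol(fingers)
  if (n < 4)
    stop("insufficient data: cubic interpolation needs at least 4 samples, got ", n)
  ratio <- target_fs / fs_in
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("target_fs must be an integer multiple of fs_in")
  ratio <- round(ratio)
  m <- n * ratio
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- (seq_len(m) - 1) / target_fs
  out <- matrix(0, 5, m)
  for (i in 1:5) {
    sf <- stats::splinefun(t_in, fingers[i, ], method = "fmm")
    out[i, ] <- sf(t_out)
  }
  out
}

#' Normalize ECoG channels
#'
#' Per channel: subtract the mean, divide by the standard deviation, then
#' subtract the median of the standardized trace, so every channel leaves with
#' zero median and unit scale. The trailing median step makes channels with
#' skewed amplitude distributions comparable across brain regions.
#'
#' @param ecog numeric matrix `channels x time` with at least 2 samples.
#' @return matrix of the same shape; every row has median exactly 0.
#' @export
normalize_channels <- function(ecog) {
  stopifnot(is.matrix(ecog), ncol(ecog) >= 2)
  m <- rowMeans(ecog)
  s <- apply(ecog, 1, stats::sd)
  bad <- which(s <= 0 | !is.finite(s))
  if (length(bad) > 0)
    stop("zero-variance channel(s): ", paste(bad, collapse = ", "),
         " - drop them before normalizing")
  z <- (ecog - m) / s
  z - apply(z, 1, stats::median)
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' ([signal::filtfilt()]) so no group delay shifts the signal relative to the
#' finger trajectories. Defaults select the 40-300 Hz movement-decoding band.
#'
#' @param ecog numeric matrix `channels x time`.
#' @param fs sampling rate in Hz.
#' @param lo,hi band edges in Hz; `hi` must be below the Nyquist rate.
#' @param order Butterworth order (per band edge).
#' @return filtered matrix, same shape.
#' @export
bandpass_filter <- function(ecog, fs, lo = 40, hi = 300, order = 4) {
  stopifnot(is.matrix(ecog), lo > 0, hi > lo)
  if (hi >= fs / 2)
    stop("design error: upper edge ", hi, " Hz is not below Nyquist (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- ecog
  for (i in seq_len(nrow(ecog)))
    out[i, ] <- signal::filtfilt(bf, ecog[i, ])
  out
}

# RBJ-cookbook biquad notch at f0 with quality factor q, as (b, a).
.notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Zero-phase notch comb for power-line interference
#'
#' Removes the mains frequency and its harmonics with narrow biquad notches
#' (quality factor `q`, default 30) applied forward-backward. Harmonics at or
#' above Nyquist are skipped with a warning.
#'
#' @param ecog numeric matrix `channels x time`.
#' @param fs sampling rate in Hz.
#' @param line line frequency in Hz (60 for the competition data).
#' @param harmonics harmonic frequencies in Hz; default `2..5 * line`.
#' @param q notch quality factor (center frequency / -3 dB bandwidth).
#' @return filtered matrix, same shape.
#' @export
notch_filter <- function(ecog, fs, line = 60, harmonics = NULL, q = 30) {
  stopifnot(is.matrix(ecog))
  if (is.null(harmonics)) harmonics <- line * (2:5)
  f0s <- c(line, harmonics)
  keep <- f0s < fs / 2
  if (any(!keep)) {
    warning("skipping notch frequencies at/above Nyquist: ",
            paste(f0s[!keep], collapse = ", "), " Hz")
    f0s <- f0s[keep]
  }
  out <- ecog
  for (f0 in f0s) {
    bq <- .notch_biquad(f0, fs, q)
    for (i in seq_len(nrow(out)))
      out[i, ] <- signal::filtfilt(signal::Arma(b = bq$b, a = bq$a), out[i, ])
  }
  out
}

# Sampled, unit-L2 Morlet wavelet kernels and their FFTs on a shared padded
# length. Returns kernel FFTs wrapped so circular multiplication gives
# "same"-aligned convolution at indices 1..t.
.morlet_kernel_ffts <- function(params, fs, t) {
  hw <- ceiling(5 * params$sigma * fs)        # half-width: 5 sigma support
  if (any(2 * hw + 1 > t))
    stop("wavelet support (", max(2 * hw + 1), " samples) exceeds signal ",
         "length (", t, "); use a shorter n_cycles or a longer signal")
  lp <- stats::nextn(t + 2 * max(hw), 2)
  kffts <- vector("list", length(params$freqs))
  for (j in seq_along(params$freqs)) {
    f <- params$freqs[j]; s <- params$sigma[j]; h <- hw[j]
    tt <- (-h:h) / fs
    psi <- exp(-tt^2 / (2 * s^2)) * exp(2i * pi * f * tt)
    psi <- psi / sqrt(sum(Mod(psi)^2))        # A: unit L2 norm
    kp <- complex(lp)
    kp[1:(h + 1)] <- psi[(h + 1):(2 * h + 1)] # center + causal half at 0
    if (h > 0) kp[(lp - h + 1):lp] <- psi[1:h]
    kffts[[j]] <- stats::fft(kp)
  }
  list(kffts = kffts, lp = lp)
}

# Amplitude rows (n_freqs x t) for one channel given precomputed kernel FFTs;
# optionally block-means the time axis by `factor` before returning.
.morlet_channel <- function(x, kinfo, factor = 1L) {
  t <- length(x)
  xf <- stats::fft(c(x, numeric(kinfo$lp - t)))
  nf <- length(kinfo$kffts)
  tout <- if (factor > 1L) t %/% factor else t
  out <- matrix(0, nf, tout)
  for (j in seq_len(nf)) {
    w <- stats::fft(xf * kinfo$kffts[[j]], inverse = TRUE)[1:t] / kinfo$lp
    a <- Mod(w)
    if (factor > 1L) {
      a <- a[1:(tout * factor)]
      dim(a) <- c(factor, tout)
      a <- colMeans(a)
    }
    out[j, ] <- a
  }
  out
}

#' Morlet wavelet amplitude spectrogram
#'
#' Convolves every channel with complex Morlet wavelets
#' `psi_f(t) = A exp(-t^2 / (2 sigma^2)) exp(2 pi i f t)` on the log-spaced
#' frequency grid of `params` and returns the amplitude `|W|` (or power
#' `|W|^2`). Convolution is FFT-based and "same"-aligned, so the time axis
#' equals the input's.
#'
#' @param ecog numeric matrix `channels x time` (normalize and filter first).
#' @param fs sampling rate in Hz.
#' @param params a [morlet_params()].
#' @param power if `TRUE` return `|W|^2` instead of `|W|`.
#' @param channel_ids optional channel labels.
#' @return An [ecog_spectrogram()] at the input rate `fs`.
#' @export
morlet_spectrogram <- function(ecog, fs, params = morlet_params(),
                               power = FALSE, channel_ids = NULL) {
  stopifnot(is.matrix(ecog), inherits(params, "morlet_params"))
  t <- ncol(ecog)
  kinfo <- .morlet_kernel_ffts(params, fs, t)
  nc <- nrow(ecog); nf <- length(params$freqs)
  values <- array(0, c(nc, nf, t))
  for (c in seq_len(nc))
    values[c, , ] <- .morlet_channel(ecog[c, ], kinfo)
  if (power) values <- values^2
  ecog_spectrogram(values, fs, params$freqs, channel_ids,
                   kind = if (power) "power" else "amplitude")
}

#' Downsample a spectrogram's time axis by block averaging
#'
#' Reduces the frame rate by `fs / out_fs` (must be an integer) by averaging
#' consecutive non-overlapping blocks, which anti-aliases the amplitude
#' envelope; trailing frames that do not fill a block are dropped, so the
#' output length is `floor(t / factor)`.
#'
#' @param spec an [ecog_spectrogram()].
#' @param out_fs target frame rate in Hz (default 100).
#' @return An [ecog_spectrogram()] at `out_fs`.
#' @export
downsample_time <- function(spec, out_fs = 100) {
  stopifnot(inherits(spec, "ecog_spectrogram"))
  factor <- spec$fs / out_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop("fs (", spec$fs, ") must be an integer multiple of out_fs (",
         out_fs, ")")
  factor <- round(factor)
  if (factor == 1) return(spec)
  d <- dim(spec$values)
  tout <- d[3] %/% factor
  v <- spec$values[, , 1:(tout * factor), drop = FALSE]
  m <- matrix(v, d[1] * d[2], tout * factor)
  acc <- matrix(0, d[1] * d[2], tout)
  for (j in seq_len(factor))
    acc <- acc + m[, seq(j, by = factor, length.out = tout), drop = FALSE]
  out <- array(acc / factor, c(d[1], d[2], tout))
  ecog_spectrogram(out, out_fs, spec$freqs, spec$channel_ids, spec$kind)
}

#' Preprocessing configuration
#'
#' @param f_lo,f_hi,n_freqs,n_cycles Morlet grid, see [morlet_params()].
#' @param line_freq mains frequency in Hz.
#' @param harmonics notch harmonics (default `2..5 * line_freq`).
#' @param out_fs common output frame rate in Hz.
#' @param power output `|W|^2` instead of `|W|`.
#' @param bp_order band-pass Butterworth order.
#' @param notch_q notch quality factor.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(f_lo = 40, f_hi = 300, n_freqs = 40,
                              n_cycles = 7, line_freq = 60, harmonics = NULL,
                              out_fs = 100, power = FALSE, bp_order = 4,
                              notch_q = 30) {
  structure(list(f_lo = f_lo, f_hi = f_hi, n_freqs = n_freqs,
                 n_cycles = n_cycles, line_freq = line_freq,
                 harmonics = harmonics, out_fs = out_fs, power = power,
                 bp_order = bp_order, notch_q = notch_q),
            class = "preprocess_config")
}

#' Preprocess a recording into an aligned spectrogram / trajectory pair
#'
#' Runs the full signal path: per-channel normalization, 40-300 Hz band-pass,
#' line-noise notch comb, Morlet wavelet amplitudes, block-mean downsampling
#' to `out_fs`; finger trajectories are cubically upsampled to the same rate.
#' Both outputs are truncated to the shorter common length so their time axes
#' align frame for frame.
#'
#' @param rec a [raw_recording()].
#' @param cfg a [preprocess_config()].
#' @return list with elements `spec` (an [ecog_spectrogram()] at `out_fs`) and
#'   `fingers` (`5 x t` matrix at `out_fs`, or `5 x 0` if the recording has no
#'   glove data).
#' @export
preprocess_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(cfg, "preprocess_config"))
  params <- morlet_params(cfg$f_lo, cfg$f_hi, cfg$n_freqs, cfg$n_cycles)
  x <- normalize_channels(rec$ecog)
  x <- bandpass_filter(x, rec$fs_ecog, cfg$f_lo, cfg$f_hi, cfg$bp_order)
  x <- notch_filter(x, rec$fs_ecog, cfg$line_freq, cfg$harmonics, cfg$notch_q)
  factor <- rec$fs_ecog / cfg$out_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("fs_ecog must be an integer multiple of out_fs")
  factor <- as.integer(round(factor))
  t <- ncol(x)
  kinfo <- .morlet_kernel_ffts(params, rec$fs_ecog, t)
  tout <- t %/% factor
  values <- array(0, c(nrow(x), cfg$n_freqs, tout))
  for (c in seq_len(nrow(x)))   # stream per channel: keeps memory at O(output)
    values[c, , ] <- .morlet_channel(x[c, ], kinfo, factor)
  if (cfg$power) values <- values^2
  spec <- ecog_spectrogram(values, cfg$out_fs, params$freqs, rec$channel_ids,
                           kind = if (cfg$power) "power" else "amplitude")
  if (ncol(rec$fingers) > 0) {
    fing <- interpolate_fingers(rec$fingers, cfg$out_fs, rec$fs_glove)
    tt <- min(dim(spec$values)[3], ncol(fing))
    spec$values <- spec$values[, , 1:tt, drop = FALSE]
    fing <- fing[, 1:tt, drop = FALSE]
  } else {
    fing <- matrix(numeric(0), 5, 0)
  }
  list(spec = spec, fingers = fing)
}

# ---- alternative mother wavelets (ablation only) ---------------------------

# Orthonormal low-pass decomposition filters, sum = sqrt(2).
.wavelet_filters <- list(
  haar = c(1, 1) / sqrt(2),
  daubechies = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
                 -0.02798376941698385, -0.18703481171888114,
                 0.030841381835986965, 0.032883011666982945,
                 -0.010597401784997278),
  symlet = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427)
)

# Wavelet function psi on a dyadic grid via the cascade algorithm, plus its
# dominant frequency in cycles per natural-time unit.
.cascade_psi <- function(h, n_iter = 8) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # QMF high-pass
  psi <- g
  for (i in seq_len(n_iter)) {
    up <- numeric(2 * length(psi)); up[seq(1, length(up), 2)] <- psi
    psi <- sqrt(2) * stats::convolve(up, rev(h), type = "open")
  }
  dt <- (length(h) - 1) / length(psi)     # grid spacing in natural time
  nfft <- stats::nextn(4 * length(psi), 2)
  spec <- Mod(stats::fft(c(psi, numeric(nfft - length(psi)))))[1:(nfft / 2)]
  fc <- (which.max(spec) - 1) / nfft / dt
  list(psi = psi, dt = dt, fc = fc)
}

#' Spectrogram with an alternative (real, compactly supported) mother wavelet
#'
#' Continuous wavelet transform with Haar, Daubechies (db4) or Symlet (sym4)
#' mother wavelets on the same log frequency grid, for the wavelet-family
#' ablation. The wavelet function is built by the cascade algorithm, dilated
#' so its dominant frequency hits each target frequency, L2-normalized and
#' convolved "same"; the absolute coefficient value is returned. The output
#' honours the `(channel, frequency, time)` axes contract so the downstream
#' model is unchanged.
#'
#' @param ecog numeric matrix `channels x time`.
#' @param fs sampling rate in Hz.
#' @param family `"haar"`, `"daubechies"` or `"symlet"`.
#' @param params a [morlet_params()] (only its frequency grid is used).
#' @param channel_ids optional channel labels.
#' @return An [ecog_spectrogram()] at the input rate `fs`.
#' @export
alt_wavelet_spectrogram <- function(ecog, fs,
                                    family = c("haar", "daubechies", "symlet"),
                                    params = morlet_params(),
                                    channel_ids = NULL) {
  family <- match.arg(family)
  stopifnot(is.matrix(ecog))
  cas <- .cascade_psi(.wavelet_filters[[family]])
  t_nat <- (seq_along(cas$psi) - 1) * cas$dt
  t <- ncol(ecog)
  nf <- length(params$freqs)
  values <- array(0, c(nrow(ecog), nf, t))
  for (j in seq_len(nf)) {
    f <- params$freqs[j]
    scale <- cas$fc * fs / f                 # kernel samples per natural unit
    klen <- max(2L, floor(max(t_nat) * scale) + 1L)
    if (klen > t)
      stop("wavelet support exceeds signal length at ", round(f, 1), " Hz")
    k <- stats::approx(t_nat, cas$psi, xout = (seq_len(klen) - 1) / scale,
                       rule = 2)$y
    k <- k / sqrt(sum(k^2))
    half <- (klen - 1) %/% 2
    for (c in seq_len(nrow(ecog))) {
      full <- stats::convolve(ecog[c, ], rev(k), type = "open")
      values[c, j, ] <- abs(full[(half + 1):(half + t)])
    }
  }
  ecog_spectrogram(values, fs, params$freqs, channel_ids, kind = "amplitude")
}

#' Save / load a spectrogram in the package's HDF5 container
#'
#' @param spec an [ecog_spectrogram()].
#' @param path `.h5` path.
#' @return `save_spectrogram()` returns `path` invisibly; `load_spectrogram()`
#'   returns an [ecog_spectrogram()].
#' @export
save_spectrogram <- function(spec, path) {
  stopifnot(inherits(spec, "ecog_spectrogram"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(spec$values, path, "values")
  rhdf5::h5write(spec$freqs, path, "freqs")
  rhdf5::h5write(spec$fs, path, "fs")
  rhdf5::h5write(spec$channel_ids, path, "channel_ids")
  rhdf5::h5write(spec$kind, path, "kind")
  invisible(path)
}

#' @rdname save_spectrogram
#' @export
load_spectrogram <- function(path) {
  if (!file.exists(path)) stop("spectrogram file not found: ", path)
  g <- function(k) rhdf5::h5read(path, k)
  ecog_spectrogram(g("values"), as.numeric(g("fs")), as.numeric(g("freqs")),
                   as.character(g("channel_ids")), as.character(g("kind")))
}
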