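# Shared tiny fixtures, built once per test run.

# FFT amplitude at one frequency (used as the independent filter oracle)
fft_amplitude <- function(x, fs, f) {
  n <- length(x)
  k <- round(f * n / fs)
  2 * Mod(stats::fft(x))[k + 1] / n
}

# analytic-signal amplitude envelope via the FFT method
hilbert_envelope <- function(x) {
  n <- length(x)
  sp <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(sp * h, inverse = TRUE) / n)
}

# tiny network configuration used across model tests
tiny_config <- function(in_features = 6, dropout = 0, ...) {
  decoder_config(in_features = in_features, layer_dims = c(4, 4, 6, 6, 8, 8),
                 dropout = dropout, ...)
}

# a small spectrogram + trajectory pair with learnable band structure
tiny_pair <- function(t_frames = 640, n_channels = 2, n_freqs = 6,
                      seed = 11) {
  set.seed(seed)
  vals <- array(abs(stats::rnorm(n_channels * n_freqs * t_frames, 1, 0.1)),
                c(n_channels, n_freqs, t_frames))
  fingers <- matrix(0, 5, t_frames)
  tt <- seq_len(t_frames)
  for (f in 1:5) fingers[f, ] <- 0.5 + 0.4 * sin(2 * pi * tt / (40 + 17 * f))
  # plant each finger's trace into one (channel, freq) envelope
  for (f in 1:5) {
    ch <- (f - 1) %% n_channels + 1
    fr <- (f - 1) %% n_freqs + 1
    vals[ch, fr, ] <- vals[ch, fr, ] + fingers[f, ]
  }
  list(spec = ecog_spectrogram(vals, 100, seq(40, 300, length.out = n_freqs)),
       fingers = fingers)
}
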