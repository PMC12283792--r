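test_that("cubic trajectory interpolation passes through knots and reproduces cubics", {
  # constant trace
  const <- matrix(0.7, 5, 20)
  up <- interpolate_fingers(const, 100, 25)
  expect_equal(dim(up), c(5, 80))
  expect_equal(up, matrix(0.7, 5, 80), tolerance = 1e-12)
  # knot recovery at stride-4 positions
  set.seed(4)
  f <- matrix(runif(5 * 25), 5, 25)
  up <- interpolate_fingers(f, 100, 25)
  expect_equal(up[, seq(1, 100, by = 4)], f, tolerance = 1e-9)
  # a cubic polynomial is reproduced exactly between (and beyond) knots:
  # oracle = direct polynomial evaluation on the fine grid
  t25 <- (0:24) / 25
  poly <- function(t) 0.3 - 1.2 * t + 0.8 * t^2 + 0.5 * t^3
  f <- matrix(rep(poly(t25), each = 5), 5, byrow = FALSE)
  f <- rbind(poly(t25), poly(t25), poly(t25), poly(t25), poly(t25))
  up <- interpolate_fingers(f, 100, 25)
  t100 <- (0:99) / 100
  expect_equal(up[1, ], poly(t100), tolerance = 1e-10)
  # too few samples is an explicit error
  expect_error(interpolate_fingers(matrix(1, 5, 3), 100, 25), "4 samples")
  expect_error(interpolate_fingers(matrix(1, 5, 10), 110, 25), "multiple")
})

test_that("channel normalization is z-score then median removal", {
  x <- matrix(c(1, 2, 3, 4, 5), 1)
  out <- normalize_channels(x)
  expect_equal(stats::median(out[1, ]), 0)
  # symmetric input: the median step is a no-op on the z-scores
  xs <- matrix(c(-2, -1, 0, 1, 2), 1)
  zs <- (xs - mean(xs)) / stats::sd(xs)
  expect_equal(normalize_channels(xs)[1, ], zs[1, ])
  # random Gaussian channels: brute-force recomputation of the two steps
  set.seed(5)
  g <- matrix(rnorm(3 * 500), 3)
  out <- normalize_channels(g)
  for (i in 1:3) {
    z <- (g[i, ] - mean(g[i, ])) / stats::sd(g[i, ])
    expect_equal(out[i, ], z - stats::median(z), tolerance = 1e-12)
    expect_equal(stats::median(out[i, ]), 0)
    expect_equal(stats::sd(out[i, ]), 1, tolerance = 1e-12)
  }
  # zero-variance channel is named
  bad <- rbind(rnorm(10), rep(2, 10))
  expect_error(normalize_channels(bad), "2")
})

test_that("band-pass keeps 100 Hz within 3 dB and kills 10 Hz by 20 dB", {
  fs <- 1000
  tt <- (0:(4 * fs - 1)) / fs
  tone <- function(f) matrix(sin(2 * pi * f * tt), 1)
  y100 <- bandpass_filter(tone(100), fs)
  ratio100 <- fft_amplitude(y100[1, ], fs, 100) / fft_amplitude(tone(100)[1, ], fs, 100)
  expect_gt(20 * log10(ratio100), -3)
  y10 <- bandpass_filter(tone(10), fs)
  ratio10 <- fft_amplitude(y10[1, ], fs, 10) / fft_amplitude(tone(10)[1, ], fs, 10)
  expect_lt(20 * log10(ratio10), -20)
  expect_equal(bandpass_filter(matrix(0, 1, 1000), fs),
               matrix(0, 1, 1000))
  expect_error(bandpass_filter(tone(10), fs, hi = 600), "Nyquist")
})

test_that("notch comb attenuates 60 Hz >= 20 dB and spares 90 Hz within 3 dB", {
  fs <- 1000
  tt <- (0:(4 * fs - 1)) / fs
  tone <- function(f) matrix(sin(2 * pi * f * tt), 1)
  y60 <- notch_filter(tone(60), fs)
  r60 <- fft_amplitude(y60[1, ], fs, 60) / fft_amplitude(tone(60)[1, ], fs, 60)
  expect_lt(20 * log10(r60), -20)
  y90 <- notch_filter(tone(90), fs)
  r90 <- fft_amplitude(y90[1, ], fs, 90) / fft_amplitude(tone(90)[1, ], fs, 90)
  expect_gt(20 * log10(r90), -3)
  expect_equal(notch_filter(matrix(0, 1, 500), fs), matrix(0, 1, 500))
  # harmonics at/above Nyquist are skipped with a warning
  expect_warning(notch_filter(tone(90), 500, line = 60,
                              harmonics = c(120, 300)), "Nyquist")
})

test_that("Morlet parameters pin the endpoints and sigma follows n_cycles/(2 pi f)", {
  p <- morlet_params(40, 300, 40, 7)
  expect_equal(p$freqs[1], 40)
  expect_equal(p$freqs[40], 300)
  expect_true(all(diff(p$freqs) > 0))
  expect_true(all(diff(p$sigma) < 0))
  # direct evaluation: f = 100, n_cycles = 7
  expect_equal(7 / (2 * pi * 100), 0.011140846, tolerance = 1e-6)
  pf <- morlet_params(100, 200, 5, 7)
  expect_equal(pf$sigma[1], 7 / (2 * pi * 100), tolerance = 1e-12)
})

test_that("Morlet spectrogram is frequency-selective with the analytic Gaussian profile", {
  fs <- 1000
  params <- morlet_params(40, 300, 20, 7)
  tt <- (0:(3 * fs - 1)) / fs
  mid <- 800:2200   # central region, away from edge transients
  for (j in c(1, 7, 14, 20)) {
    f0 <- params$freqs[j]
    x <- matrix(cos(2 * pi * f0 * tt), 1)
    sp <- morlet_spectrogram(x, fs, params)
    prof <- rowMeans(sp$values[1, , mid])
    expect_equal(which.max(prof), j)
    # analytic response of the unit-L2 Morlet filter to a cosine:
    # amp(f) = 0.5 * sqrt(2 sqrt(pi) sigma fs) * exp(-(2 pi sigma)^2 (f - f0)^2 / 2)
    pred <- 0.5 * sqrt(2 * sqrt(pi) * params$sigma * fs) *
      exp(-(2 * pi * params$sigma)^2 * (params$freqs - f0)^2 / 2)
    for (nb in c(j - 1, j + 1)) {
      if (nb < 1 || nb > 20) next
      expect_equal(prof[nb] / prof[j], pred[nb] / pred[j], tolerance = 0.05)
    }
  }
})

test_that("Morlet spectrogram is linear in amplitude and zero on zero input", {
  fs <- 1000
  params <- morlet_params(40, 300, 8, 7)
  expect_equal(max(morlet_spectrogram(matrix(0, 2, 2000), fs, params)$values), 0)
  set.seed(6)
  x <- matrix(rnorm(2000), 1)
  a <- morlet_spectrogram(x, fs, params)$values
  b <- morlet_spectrogram(3.5 * x, fs, params)$values
  expect_equal(b, 3.5 * a, tolerance = 1e-9)
  # power switch squares the amplitude
  pw <- morlet_spectrogram(x, fs, params, power = TRUE)$values
  expect_equal(pw, a^2, tolerance = 1e-12)
  # wavelet support longer than the signal is a descriptive error
  expect_error(morlet_spectrogram(matrix(rnorm(100), 1), fs, params),
               "n_cycles")
})

test_that("time downsampling is the block mean", {
  set.seed(7)
  vals <- array(abs(rnorm(2 * 3 * 1000)), c(2, 3, 1000))
  sp <- ecog_spectrogram(vals, 1000, c(50, 100, 200))
  dn <- downsample_time(sp, 100)
  expect_equal(dim(dn$values), c(2, 3, 100))
  expect_equal(dn$fs, 100)
  # brute-force oracle over each 10-sample block
  for (idx in list(c(1, 1, 1), c(2, 3, 100), c(1, 2, 37))) {
    blk <- vals[idx[1], idx[2], ((idx[3] - 1) * 10 + 1):(idx[3] * 10)]
    expect_equal(dn$values[idx[1], idx[2], idx[3]], mean(blk))
  }
  # constants stay constant; trailing partial blocks are dropped
  cs <- ecog_spectrogram(array(2.5, c(1, 2, 1005)), 1000, c(50, 100))
  cd <- downsample_time(cs, 100)
  expect_equal(dim(cd$values)[3], 100)
  expect_true(all(cd$values == 2.5))
  expect_error(downsample_time(sp, 300), "integer multiple")
})

test_that("full preprocessing aligns spectrogram and trajectories and tracks a planted envelope", {
  # 80 Hz carrier amplitude-modulated by a known slow envelope
  fs <- 1000
  dur <- 24
  n <- dur * fs
  tt <- (0:(n - 1)) / fs
  env <- 0.55 + 0.45 * sin(2 * pi * tt / 6)
  set.seed(8)
  ecog <- rbind(env * sin(2 * pi * 80 * tt) + 0.1 * rnorm(n),
                rnorm(n))
  fingers <- matrix(0.2, 5, dur * 25)
  fingers[1, ] <- env[seq(1, n, by = 40)]
  fingers <- fingers + matrix(rnorm(5 * dur * 25, 0, 1e-3), 5)  # avoid zero variance
  rec <- raw_recording(ecog, fingers, fs, 25)
  out <- preprocess_recording(rec, preprocess_config(n_freqs = 16))
  expect_equal(dim(out$spec$values)[3], ncol(out$fingers))
  expect_equal(out$spec$fs, 100)
  f_sel <- which(abs(out$spec$freqs - 80) < 10)
  energy <- colMeans(out$spec$values[1, f_sel, , drop = FALSE][1, , ])
  expect_gt(stats::cor(energy, out$fingers[1, ]), 0.8)
})

test_that("alternative mother wavelets honour the axes contract", {
  fs <- 1000
  params <- morlet_params(40, 300, 6, 7)
  z <- matrix(0, 2, 1500)
  for (fam in c("haar", "daubechies", "symlet")) {
    sp <- alt_wavelet_spectrogram(z, fs, fam, params)
    expect_equal(dim(sp$values), c(2, 6, 1500))
    expect_equal(max(sp$values), 0)
  }
  set.seed(9)
  x <- matrix(rnorm(2 * 1500), 2)
  sp <- alt_wavelet_spectrogram(x, fs, "daubechies", params)
  expect_equal(dim(sp$values), c(2, 6, 1500))
  expect_true(all(is.finite(sp$values)) && all(sp$values >= 0))
  expect_error(alt_wavelet_spectrogram(x, fs, "coiflet", params))
})

test_that("spectrogram HDF5 container round-trips", {
  set.seed(10)
  sp <- ecog_spectrogram(array(abs(rnorm(60)), c(2, 3, 10)), 100,
                         c(50, 100, 200), c("a", "b"))
  p <- withr::local_tempfile(fileext = ".h5")
  save_spectrogram(sp, p)
  back <- load_spectrogram(p)
  expect_equal(back$values, sp$values)
  expect_equal(back$freqs, sp$freqs)
  expect_equal(back$fs, 100)
  expect_identical(back$channel_ids, c("a", "b"))
})
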