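test_that("trajectories follow the cue paradigm with 3-5 bumps per cue", {
  cfg <- synth_config(duration = 40, seed = 17)
  traj <- generate_trajectories(cfg)
  expect_equal(dim(traj), c(5, 40 * 25))
  expect_true(all(traj >= 0 & traj <= 1))
  # zero duration gives an empty matrix
  expect_equal(ncol(generate_trajectories(synth_config(duration = 0, seed = 1))),
               0)
  # block b cues finger ((b-1) mod 5) + 1: cued finger peaks above the rest
  for (bl in 1:10) {
    finger <- (bl - 1) %% 5 + 1
    sel <- seq.int((bl - 1) * 4 * 25 + 1, length.out = 2 * 25)
    peaks <- apply(traj[, sel], 1, max)
    expect_equal(which.max(peaks), finger)
    expect_gt(peaks[finger], max(peaks[-finger]))
    # bump count oracle: count upward crossings of the half-max level
    x <- traj[finger, sel]
    lev <- max(x) / 2
    crossings <- sum(diff(x > lev) == 1)
    expect_gte(crossings, 3)
    expect_lte(crossings, 5)
  }
})

test_that("assigned channels carry a trajectory-locked band envelope", {
  cfg <- synth_config(duration = 30, seed = 18)
  traj <- generate_trajectories(cfg)
  ecog <- generate_ecog(traj, cfg)
  expect_equal(dim(ecog), c(16, 30 * 1000))
  # zero trajectories leave noise only: no extra band power on channel 1
  z <- generate_ecog(matrix(0, 5, 30 * 25), cfg)
  band_power <- function(x, band) {
    y <- bandpass_filter(matrix(x, 1), cfg$fs, band[1], band[2])
    mean(y^2)
  }
  expect_gt(band_power(ecog[1, ], cfg$bands[[1]]) /
              band_power(z[1, ], cfg$bands[[1]]), 3)
  # Hilbert-envelope oracle: the band envelope tracks the trajectory
  traj_hi <- interpolate_fingers(traj, 1000, 25)
  for (f in c(1, 4)) {
    ch <- (f - 1) * cfg$channels_per_finger + 1
    nb <- bandpass_filter(matrix(ecog[ch, ], 1), cfg$fs,
                          cfg$bands[[f]][1], cfg$bands[[f]][2])
    env <- hilbert_envelope(nb[1, ])
    # smooth the envelope to the trajectory's time scale
    env <- stats::filter(env, rep(1 / 200, 200), sides = 2)
    ok <- !is.na(env)
    expect_gt(stats::cor(env[ok], traj_hi[f, ok]), 0.7)
  }
})

test_that("line interference dominates before the notch and dies after", {
  cfg <- synth_config(duration = 20, seed = 19)
  traj <- generate_trajectories(cfg)
  ecog <- generate_ecog(traj, cfg)
  amp_pre <- fft_amplitude(ecog[1, ], cfg$fs, 60)
  neighbors <- mean(c(fft_amplitude(ecog[1, ], cfg$fs, 55),
                      fft_amplitude(ecog[1, ], cfg$fs, 65)))
  expect_gt(20 * log10(amp_pre / neighbors), 20)
  post <- notch_filter(ecog[1, , drop = FALSE], cfg$fs)
  amp_post <- fft_amplitude(post[1, ], cfg$fs, 60)
  expect_gt(20 * log10(amp_pre / amp_post), 20)
})

test_that("fixtures split 2:1, round-trip through the loader, and are seed-stable", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(duration = 30, seed = 20)
  fx <- make_fixture(cfg, dir)
  expect_equal(ncol(fx$rec_train$ecog), 20 * 1000)
  expect_equal(ncol(fx$rec_test$ecog), 10 * 1000)
  rec <- load_competition_recording(fx$train, "train")
  expect_equal(rec$ecog, fx$rec_train$ecog)
  expect_equal(rec$fingers, fx$rec_train$fingers)
  rec_te <- load_competition_recording(fx$test, "test")
  expect_equal(rec_te$ecog, fx$rec_test$ecog)
  # same seed, bit-identical files
  dir2 <- withr::local_tempdir()
  fx2 <- make_fixture(cfg, dir2)
  expect_identical(readBin(fx$train, "raw", 1e6)[-(1:128)],
                   readBin(fx2$train, "raw", 1e6)[-(1:128)])  # header has a timestamp
  expect_identical(fx$rec_train$ecog, fx2$rec_train$ecog)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(bands = list(c(70, 88), c(90, 108), c(110, 128),
                                         c(130, 148), c(150, 320))))
  expect_error(synth_config(n_channels = 4))
  expect_error(synth_config(pink_amp = -1))
})
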