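# Synthetic ECoG-like recordings with known band-power -> trajectory
# coupling. The generator emulates the cued finger-movement paradigm: a 2 s
# cue (the cued finger flexes 3-5 times) followed by a 2 s rest, cycling
# through the five fingers. Each finger is assigned a disjoint carrier band
# inside the high-gamma range and a set of channels; an assigned channel is
# band-limited carrier noise amplitude-modulated by that finger's upsampled
# trajectory, plus pink noise, a 60 Hz line component and a small shared
# Gaussian term. Fingers are thereby separable along the frequency axis,
# which lets modest networks succeed at desk scale.

#' Synthetic recording configuration
#'
#' @param n_channels number of ECoG channels (default 16; channels
#'   `2 * finger - 1` and `2 * finger` carry finger `finger`, the rest are
#'   noise-only with the default assignment).
#' @param fs ECoG sampling rate in Hz.
#' @param duration total recording length in seconds (default 120).
#' @param cue_len,rest_len cue / rest block lengths in seconds (2 s each).
#' @param glove_fs trajectory sampling rate in Hz.
#' @param bands list of 5 carrier bands `(lo, hi)` in Hz, disjoint, inside
#'   the 40-300 Hz analysis band (defaults span 70-170 Hz).
#' @param channels_per_finger channels assigned to each finger.
#' @param mod_depth amplitude-modulation depth: the carrier gain is
#'   `mod_depth * trajectory`, so a fully rested finger contributes no
#'   carrier at all.
#' @param pink_amp,line_amp,noise_amp amplitudes of the pink-noise, 60 Hz
#'   line and shared white-noise terms, relative to unit carrier power.
#' @param line_freq mains frequency in Hz.
#' @param seed RNG seed; the fixture is bit-identical under a fixed seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16, fs = 1000, duration = 120,
                         cue_len = 2, rest_len = 2, glove_fs = 25,
                         bands = list(c(70, 88), c(90, 108), c(110, 128),
                                      c(130, 148), c(150, 168)),
                         channels_per_finger = 2, mod_depth = 1.5,
                         pink_amp = 0.5, line_amp = 1, noise_amp = 0.2,
                         line_freq = 60, seed = 1L) {
  stopifnot(n_channels >= 5 * channels_per_finger, length(bands) == 5,
            pink_amp >= 0, line_amp >= 0, noise_amp >= 0, mod_depth > 0)
  for (b in bands)
    stopifnot(length(b) == 2, b[1] < b[2], b[1] >= 40, b[2] <= 300)
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 duration = duration, cue_len = cue_len, rest_len = rest_len,
                 glove_fs = glove_fs, bands = bands,
                 channels_per_finger = as.integer(channels_per_finger),
                 mod_depth = mod_depth, pink_amp = pink_amp,
                 line_amp = line_amp, noise_amp = noise_amp,
                 line_freq = line_freq, seed = as.integer(seed)),
            class = "synth_config")
}

# raised-cosine bump of unit peak on [0, 1]
.bump <- function(u) 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))

#' Generate cued finger-flexion trajectories
#'
#' For each cue block the cued finger (cycling thumb..little) performs 3-5
#' smooth raised-cosine flexion bumps; all other fingers stay near baseline
#' with a small smooth drift. Values lie in `[0, 1]`.
#'
#' @param cfg a [synth_config()].
#' @return `5 x (duration * glove_fs)` matrix at `glove_fs` Hz.
#' @export
generate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$glove_fs)
  out <- matrix(0, 5, n)
  if (n == 0) return(out)
  tt <- (seq_len(n) - 1) / cfg$glove_fs
  # baseline drift: slow random sinusoids, small amplitude
  for (f in 1:5) {
    ph <- stats::runif(1, 0, 2 * pi)
    per <- stats::runif(1, 20, 40)
    out[f, ] <- 0.05 + 0.02 * sin(2 * pi * tt / per + ph)
  }
  block <- cfg$cue_len + cfg$rest_len
  n_blocks <- floor(cfg$duration / block)
  for (bl in seq_len(n_blocks)) {
    finger <- (bl - 1) %% 5 + 1
    t0 <- (bl - 1) * block
    nb <- sample(3:5, 1)
    amp <- stats::runif(nb, 0.75, 1)
    for (j in seq_len(nb)) {
      b0 <- t0 + (j - 1) * cfg$cue_len / nb
      sel <- tt >= b0 & tt < b0 + cfg$cue_len / nb
      u <- (tt[sel] - b0) / (cfg$cue_len / nb)
      out[finger, sel] <- out[finger, sel] + amp[j] * .bump(u)
    }
  }
  pmin(pmax(out, 0), 1)
}

# pink (1/f amplitude) noise via spectral shaping of white noise
.pink_noise <- function(n) {
  white <- stats::rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))               # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                 # mirror for negative frequencies
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

# band-limited unit-variance carrier noise
.band_carrier <- function(n, fs, band) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / stats::sd(y)
}

#' Generate synthetic ECoG from finger trajectories
#'
#' Each channel assigned to finger `f` carries band-limited carrier noise in
#' that finger's band, amplitude-modulated by the finger's trajectory
#' (upsampled to `fs`; gain `mod_depth * trajectory`), so movement raises
#' that band's amplitude envelope exactly as high-gamma power rises with
#' movement in cortical recordings, and zero trajectories leave pure noise.
#' All channels additionally receive pink noise, a 60 Hz line component with
#' per-channel phase and a small shared Gaussian term; unassigned channels
#' are noise-only.
#'
#' @param trajectories `5 x n_glove` matrix at `glove_fs` Hz (from
#'   [generate_trajectories()]).
#' @param cfg a [synth_config()].
#' @return `n_channels x (duration * fs)` numeric matrix.
#' @export
generate_ecog <- function(trajectories, cfg) {
  stopifnot(inherits(cfg, "synth_config"), nrow(trajectories) == 5)
  set.seed(cfg$seed + 1L)
  n <- round(cfg$duration * cfg$fs)
  if (n == 0) return(matrix(0, cfg$n_channels, 0))
  traj_hi <- interpolate_fingers(trajectories, cfg$fs, cfg$glove_fs)
  traj_hi <- pmin(pmax(traj_hi, 0), 1)[, 1:n, drop = FALSE]
  tt <- (seq_len(n) - 1) / cfg$fs
  shared <- stats::rnorm(n)
  out <- matrix(0, cfg$n_channels, n)
  assign_map <- rep(0L, cfg$n_channels)
  for (f in 1:5) {
    chs <- (f - 1) * cfg$channels_per_finger + seq_len(cfg$channels_per_finger)
    assign_map[chs] <- f
  }
  for (ch in seq_len(cfg$n_channels)) {
    x <- cfg$pink_amp * .pink_noise(n) +
      cfg$line_amp * sin(2 * pi * cfg$line_freq * tt +
                           stats::runif(1, 0, 2 * pi)) +
      cfg$noise_amp * shared
    f <- assign_map[ch]
    if (f > 0) {
      carrier <- .band_carrier(n, cfg$fs, cfg$bands[[f]])
      x <- x + (cfg$mod_depth * traj_hi[f, ]) * carrier
    }
    out[ch, ] <- x
  }
  out
}

#' Write a synthetic train/test fixture pair
#'
#' Generates one recording under `cfg`, splits it chronologically 2:1 into
#' train and test, and writes MATLAB containers readable by
#' [load_competition_recording()] (`train_data`/`train_dg` and
#' `test_data`, with `test_dg` included when `include_test_labels` so the
#' synthetic test split can be scored).
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @param include_test_labels write the withheld test trajectories too.
#' @return list with `train` and `test` file paths and the full
#'   [raw_recording()]s, invisibly.
#' @export
make_fixture <- function(cfg, dir, include_test_labels = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- generate_trajectories(cfg)
  ecog <- generate_ecog(traj, cfg)
  n <- ncol(ecog)
  n_train <- round(n * 2 / 3)
  n_train <- (n_train %/% cfg$fs) * cfg$fs          # cut on a whole second
  g_train <- n_train / cfg$fs * cfg$glove_fs
  train_path <- file.path(dir, "synthetic_train.mat")
  test_path <- file.path(dir, "synthetic_test.mat")
  # competition layout is time-major
  write_mat(list(train_data = t(ecog[, 1:n_train, drop = FALSE]),
                 train_dg = t(traj[, 1:g_train, drop = FALSE])),
            train_path)
  test_vars <- list(test_data = t(ecog[, (n_train + 1):n, drop = FALSE]))
  if (include_test_labels)
    test_vars$test_dg <- t(traj[, (g_train + 1):ncol(traj), drop = FALSE])
  write_mat(test_vars, test_path)
  rec_train <- raw_recording(ecog[, 1:n_train, drop = FALSE],
                             traj[, 1:g_train, drop = FALSE],
                             cfg$fs, cfg$glove_fs, "synthetic_train")
  rec_test <- raw_recording(ecog[, (n_train + 1):n, drop = FALSE],
                            traj[, (g_train + 1):ncol(traj), drop = FALSE],
                            cfg$fs, cfg$glove_fs, "synthetic_test")
  invisible(list(train = train_path, test = test_path,
                 rec_train = rec_train, rec_test = rec_test))
}
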