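# Canonical in-memory recording representation and on-disk containers.
#
# Arrays are channel-major throughout the package: ECoG is (n_channels x
# n_time) and finger trajectories are (5 x n_time). The public competition
# release stores both time-major, so the loader transposes.

FINGER_NAMES <- c("thumb", "index", "middle", "ring", "little")

#' Construct a raw paired ECoG / dataglove recording
#'
#' The canonical container for one subject's recording: an ECoG matrix
#' (channels x time, typically 1 kHz) paired with five finger-flexion
#' trajectories (5 x time, typically 25 Hz) from a data glove. The finger
#' matrix may have zero columns for a test split whose labels are withheld.
#'
#' @param ecog numeric matrix, `n_channels x n_time_ecog`.
#' @param fingers numeric matrix, `5 x n_time_glove` (possibly 0 columns).
#' @param fs_ecog ECoG sampling rate in Hz.
#' @param fs_glove dataglove sampling rate in Hz.
#' @param subject_id subject label.
#' @param channel_ids channel labels; row `i` of `ecog` is always
#'   `channel_ids[i]` (the loader never reorders channels).
#' @param provider_bandpass optional length-2 vector recording the acquisition
#'   band-pass applied by the data provider (metadata only; not re-applied).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(ecog, fingers, fs_ecog = 1000, fs_glove = 25,
                          subject_id = "subject", channel_ids = NULL,
                          provider_bandpass = NULL) {
  stopifnot(is.matrix(ecog), is.numeric(ecog), nrow(ecog) >= 1)
  if (!all(is.finite(ecog)))
    stop("validation error: ECoG contains non-finite values")
  stopifnot(is.matrix(fingers), is.numeric(fingers))
  if (nrow(fingers) != 5)
    stop("fingers must have exactly 5 rows (thumb..little); got ",
         nrow(fingers))
  if (ncol(fingers) > 0 && !all(is.finite(fingers)))
    stop("validation error: finger trajectories contain non-finite values")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(ecog)))
  stopifnot(length(channel_ids) == nrow(ecog))
  if (ncol(fingers) > 0) {
    dur_e <- ncol(ecog) / fs_ecog
    dur_g <- ncol(fingers) / fs_glove
    if (abs(dur_e - dur_g) > 1 / fs_glove + 1e-9)
      stop("ECoG duration (", dur_e, " s) and glove duration (", dur_g,
           " s) disagree by more than one glove sample period")
  }
  structure(
    list(ecog = ecog, fingers = fingers, fs_ecog = fs_ecog,
         fs_glove = fs_glove, subject_id = subject_id,
         channel_ids = as.character(channel_ids),
         provider_bandpass = provider_bandpass),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("ECoG recording '", x$subject_id, "'\n", sep = "")
  cat(sprintf("  ecog:    %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$ecog), ncol(x$ecog), x$fs_ecog,
              ncol(x$ecog) / x$fs_ecog))
  if (ncol(x$fingers) > 0) {
    cat(sprintf("  fingers: 5 x %d samples @ %g Hz (%.1f s)\n",
                ncol(x$fingers), x$fs_glove, ncol(x$fingers) / x$fs_glove))
  } else {
    cat("  fingers: withheld (test split)\n")
  }
  if (!is.null(x$provider_bandpass))
    cat(sprintf("  provider band-pass: %g-%g Hz\n",
                x$provider_bandpass[1], x$provider_bandpass[2]))
  invisible(x)
}

#' Load a BCI Competition IV dataset 4 recording from a MAT-file
#'
#' Reads the competition's MATLAB v5 containers. Matrices stored time-major
#' (as in the public release) are transposed so the channel/finger axis comes
#' first. The provider's 0.15-200 Hz acquisition band-pass is recorded as
#' metadata only.
#'
#' @param path path to the `.mat` file.
#' @param split `"train"` (ECoG + dataglove required) or `"test"` (dataglove
#'   optional; absent labels give a 5 x 0 finger matrix).
#' @param var_names names of the MATLAB variables; defaults match the public
#'   release (`train_data`/`train_dg`/`test_data`, with `test_dg` accepted for
#'   fixtures that carry test labels).
#' @param subject_id subject label; defaults to the file name.
#' @return A [raw_recording()].
#' @export
load_competition_recording <- function(path, split = c("train", "test"),
                                       var_names = list(train_data = "train_data",
                                                        train_dg = "train_dg",
                                                        test_data = "test_data",
                                                        test_dg = "test_dg"),
                                       subject_id = NULL) {
  split <- match.arg(split)
  vars <- read_mat(path)
  data_key <- if (split == "train") var_names$train_data else var_names$test_data
  dg_key <- if (split == "train") var_names$train_dg else var_names$test_dg
  if (is.null(vars[[data_key]]))
    stop("format error: '", path, "' lacks expected ECoG variable '",
         data_key, "'")
  ecog <- vars[[data_key]]
  if (anyNA(ecog))
    stop("validation error: ECoG variable '", data_key, "' contains NaN/NA")
  # competition files are time-major (samples x channels)
  if (nrow(ecog) > ncol(ecog)) ecog <- t(ecog)
  fingers <- vars[[dg_key]]
  if (is.null(fingers)) {
    if (split == "train")
      stop("format error: '", path, "' lacks expected dataglove variable '",
           dg_key, "'")
    fingers <- matrix(numeric(0), nrow = 5, ncol = 0)
  } else {
    if (!(5 %in% dim(fingers)))
      stop("format error: dataglove variable '", dg_key,
           "' has no axis of length 5")
    if (nrow(fingers) != 5) fingers <- t(fingers)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.mat$", "", basename(path))
  raw_recording(ecog, fingers, fs_ecog = 1000, fs_glove = 25,
                subject_id = subject_id,
                provider_bandpass = c(0.15, 200))
}

#' Save / load a recording in the package's HDF5 container
#'
#' Lossless round trip of arrays, rates and labels. Layout: datasets `ecog`
#' (channels x time) and `fingers` (5 x time), with `fs_ecog`, `fs_glove`,
#' `subject_id`, `channel_ids` and (optionally) `provider_bandpass` stored
#' alongside.
#'
#' @param rec a [raw_recording()].
#' @param path output / input path (`.h5`).
#' @return `save_recording()` returns `path` invisibly; `load_recording()`
#'   returns a [raw_recording()].
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (file.exists(path)) unlink(path)
  tryCatch({
    rhdf5::h5createFile(path)
    rhdf5::h5write(rec$ecog, path, "ecog")
    if (ncol(rec$fingers) > 0)  # HDF5 zero-extent datasets are awkward; absence encodes "withheld"
      rhdf5::h5write(rec$fingers, path, "fingers")
    rhdf5::h5write(rec$fs_ecog, path, "fs_ecog")
    rhdf5::h5write(rec$fs_glove, path, "fs_glove")
    rhdf5::h5write(rec$subject_id, path, "subject_id")
    rhdf5::h5write(rec$channel_ids, path, "channel_ids")
    if (!is.null(rec$provider_bandpass))
      rhdf5::h5write(rec$provider_bandpass, path, "provider_bandpass")
  }, error = function(e) {
    stop("failed to write recording to '", path, "': ", conditionMessage(e))
  })
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  vars <- tryCatch(rhdf5::h5ls(path)$name,
                   error = function(e)
                     stop("failed to read recording from '", path, "': ",
                          conditionMessage(e)))
  need <- c("ecog", "fs_ecog", "fs_glove", "subject_id", "channel_ids")
  missing <- setdiff(need, vars)
  if (length(missing) > 0)
    stop("recording container '", path, "' lacks dataset(s): ",
         paste(missing, collapse = ", "))
  g <- function(k) rhdf5::h5read(path, k)
  fingers <- if ("fingers" %in% vars) as.matrix(g("fingers"))
             else matrix(numeric(0), 5, 0)
  pb <- if ("provider_bandpass" %in% vars) as.numeric(g("provider_bandpass"))
        else NULL
  raw_recording(as.matrix(g("ecog")), fingers,
                fs_ecog = as.numeric(g("fs_ecog")),
                fs_glove = as.numeric(g("fs_glove")),
                subject_id = as.character(g("subject_id")),
                channel_ids = as.character(g("channel_ids")),
                provider_bandpass = pb)
}
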