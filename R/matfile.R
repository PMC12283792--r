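# Minimal MATLAB level-5 MAT-file reader/writer.
#
# Covers exactly what the competition release and the synthetic fixtures need:
# top-level real numeric arrays (2-D), stored either as plain miMATRIX elements
# or inside zlib-compressed miCOMPRESSED elements, little-endian. Everything
# else (cells, structs, sparse, complex, big-endian files) is out of scope and
# rejected loudly.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

mat_numeric_types <- c(MI_INT8, MI_UINT8, MI_INT16, MI_UINT16,
                       MI_INT32, MI_UINT32, MI_SINGLE, MI_DOUBLE)

.read_u32 <- function(raw, off) {
  # read as signed int32: fine for the tag words and sizes we handle (< 2^31)
  readBin(raw[(off + 1):(off + 4)], "integer", 1L, size = 4L,
          endian = "little")
}

.decode_numeric <- function(raw, type, nbytes) {
  con <- raw
  switch(as.character(type),
    "1" = as.numeric(readBin(con, "integer", nbytes, size = 1L, signed = TRUE)),
    "2" = as.numeric(readBin(con, "integer", nbytes, size = 1L, signed = FALSE)),
    "3" = as.numeric(readBin(con, "integer", nbytes / 2, size = 2L,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(con, "integer", nbytes / 2, size = 2L,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(con, "integer", nbytes / 4, size = 4L,
                             endian = "little")),
    "6" = as.numeric(readBin(con, "integer", nbytes / 4, size = 4L,
                             endian = "little")),  # uint32 read as int32
    "7" = as.numeric(readBin(con, "numeric", nbytes / 4, size = 4L,
                             endian = "little")),
    "9" = readBin(con, "numeric", nbytes / 8, size = 8L, endian = "little"),
    stop("unsupported MAT numeric type: ", type)
  )
}

# Parse one data element starting at byte offset `off` (0-based) of `raw`.
# Returns list(type, bytes (raw payload), next_off).
.read_element <- function(raw, off) {
  word1 <- .read_u32(raw, off)
  small_size <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small_size > 0L) {  # small data element: 4-byte payload inside the tag
    type <- bitwAnd(word1, 0xFFFFL)
    payload <- raw[(off + 5):(off + 4 + small_size)]
    list(type = type, bytes = payload, next_off = off + 8)
  } else {
    type <- word1
    nbytes <- .read_u32(raw, off + 4)
    payload <- if (nbytes > 0) raw[(off + 9):(off + 8 + nbytes)] else raw(0)
    pad <- (8 - (nbytes %% 8)) %% 8
    list(type = type, bytes = payload, next_off = off + 8 + nbytes + pad)
  }
}

.parse_matrix_element <- function(payload) {
  off <- 0
  flags_el <- .read_element(payload, off)
  stopifnot(flags_el$type == MI_UINT32)
  flags_word <- .read_u32(flags_el$bytes, 0)
  class_id <- bitwAnd(flags_word, 0xFFL)
  complex_flag <- bitwAnd(flags_word, 0x0800L) != 0L
  off <- flags_el$next_off

  dims_el <- .read_element(payload, off)
  stopifnot(dims_el$type == MI_INT32)
  dims <- readBin(dims_el$bytes, "integer", length(dims_el$bytes) / 4,
                  size = 4L, endian = "little")
  off <- dims_el$next_off

  name_el <- .read_element(payload, off)
  name <- rawToChar(name_el$bytes[name_el$bytes != as.raw(0)])
  off <- name_el$next_off

  if (complex_flag)
    stop("MAT variable '", name, "': complex arrays are not supported")
  # numeric array classes are 6..13 (double..uint32)
  if (!(class_id %in% 6:13))
    return(list(name = name, value = NULL))  # skipped (cell/struct/char/...)

  data_el <- .read_element(payload, off)
  if (!(data_el$type %in% mat_numeric_types))
    stop("MAT variable '", name, "': unsupported storage type ", data_el$type)
  values <- .decode_numeric(data_el$bytes, data_el$type, length(data_el$bytes))
  if (length(dims) == 2L) {
    value <- matrix(values, nrow = dims[1], ncol = dims[2])
  } else {
    value <- array(values, dim = dims)
  }
  list(name = name, value = value)
}

#' Read numeric variables from a MATLAB v5 MAT-file
#'
#' A deliberately small reader for level-5 `.mat` containers: real numeric
#' arrays at the top level, plain or zlib-compressed, little-endian. This is
#' sufficient for the BCI Competition IV dataset 4 release and for the
#' synthetic fixtures written by [write_mat()]; anything fancier is rejected
#' with an error.
#'
#' @param path path to a `.mat` file.
#' @return Named list of numeric matrices/arrays (non-numeric variables are
#'   skipped with a warning).
#' @seealso [write_mat()], [load_competition_recording()]
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("MAT file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT v5 file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (endian == "MI")
    stop("big-endian MAT files are not supported: ", path)
  if (endian != "IM")
    stop("not a MAT v5 file (bad endian indicator): ", path)

  out <- list()
  off <- 128
  n <- length(raw)
  while (off + 8 <= n) {
    el <- .read_element(raw, off)
    payload <- el$bytes
    type <- el$type
    if (type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- .read_element(payload, 0)
      type <- inner$type
      payload <- inner$bytes
    }
    if (type == MI_MATRIX) {
      v <- .parse_matrix_element(payload)
      if (is.null(v$value)) {
        warning("skipping non-numeric MAT variable '", v$name, "'")
      } else {
        out[[v$name]] <- v$value
      }
    }
    off <- el$next_off
  }
  out
}

.write_element_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

.pad8 <- function(con, nbytes) {
  pad <- (8 - (nbytes %% 8)) %% 8
  if (pad > 0) writeBin(raw(pad), con)
}

#' Write numeric matrices to a MATLAB v5 MAT-file
#'
#' Writes each element of `vars` as an uncompressed double-precision miMATRIX
#' element, little-endian. Round-trips through [read_mat()].
#'
#' @param vars named list of numeric matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, written by ecogflex, %s", format(Sys.time())))
  header <- c(header, rep(as.raw(0x20), 124 - length(header)))[1:124]
  writeBin(header, con)
  writeBin(as.raw(c(0x00, 0x01)), con)          # version 0x0100
  writeBin(charToRaw("IM"), con)                # little-endian indicator
  for (name in names(vars)) {
    m <- vars[[name]]
    stopifnot(is.numeric(m))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    name_raw <- charToRaw(name)
    npad <- function(k) (8 - (k %% 8)) %% 8
    body_bytes <- 16 +                                     # array flags
      8 + 8 +                                              # dims (2 int32 + pad)
      8 + length(name_raw) + npad(length(name_raw)) +      # name
      8 + 8 * length(m)                                    # double data
    .write_element_tag(con, MI_MATRIX, body_bytes)
    .write_element_tag(con, MI_UINT32, 8L)
    writeBin(as.integer(c(MX_DOUBLE_CLASS, 0L)), con, size = 4L,
             endian = "little")
    .write_element_tag(con, MI_INT32, 8L)
    writeBin(as.integer(dim(m)), con, size = 4L, endian = "little")
    .write_element_tag(con, MI_INT8, length(name_raw))
    writeBin(name_raw, con)
    .pad8(con, length(name_raw))
    .write_element_tag(con, MI_DOUBLE, 8L * length(m))
    writeBin(as.vector(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}
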