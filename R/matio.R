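# Minimal MAT v5 (Level 5, little-endian) reader/writer for numeric arrays.
# Covers what the public 12-class SSVEP distribution needs: plain and
# zlib-compressed data elements, real numeric arrays of the common storage
# types, and n-d dimensions. Cell/struct/char arrays are out of scope.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_NUMERIC_CLASSES <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)  # double..uint32

mat_read_values <- function(raw, type, nbytes) {
  con <- function(what, size, signed = TRUE)
    readBin(raw, what, n = nbytes %/% size, size = size, signed = signed,
            endian = "little")
  switch(as.character(type),
    "1" = con(integer(), 1L),
    "2" = con(integer(), 1L, signed = FALSE),
    "3" = con(integer(), 2L),
    "4" = con(integer(), 2L, signed = FALSE),
    "5" = con(integer(), 4L),
    "6" = {  # uint32: R has no unsigned 32-bit read; fix up negatives
      v <- readBin(raw, integer(), n = nbytes %/% 4L, size = 4L,
                   endian = "little")
      ifelse(v < 0, v + 2^32, as.numeric(v))
    },
    "7" = con(numeric(), 4L),
    "9" = con(numeric(), 8L),
    stop("unsupported MAT data type: ", type)
  )
}

# Parse one tag at offset (1-based); returns list(type, nbytes, data_off,
# next_off) honoring the small-data-element format and 8-byte padding.
mat_parse_tag <- function(bytes, off) {
  t32 <- readBin(bytes[off:(off + 3)], integer(), size = 4, endian = "little")
  small_size <- bitwAnd(bitwShiftR(t32, 16), 0xFFFFL)
  if (small_size > 0L) {
    list(type = bitwAnd(t32, 0xFFFFL), nbytes = small_size,
         data_off = off + 4L, next_off = off + 8L)
  } else {
    nb <- readBin(bytes[(off + 4):(off + 7)], integer(), size = 4,
                  endian = "little")
    pad <- (8L - nb %% 8L) %% 8L
    list(type = t32, nbytes = nb, data_off = off + 8L,
         next_off = off + 8L + nb + pad)
  }
}

mat_parse_matrix <- function(bytes) {
  off <- 1L
  # array flags
  tg <- mat_parse_tag(bytes, off)
  if (tg$type != MI_UINT32) stop("malformed miMATRIX: bad array-flags tag")
  flags <- readBin(bytes[tg$data_off:(tg$data_off + 3)], integer(),
                   size = 4, endian = "little")
  klass <- bitwAnd(flags, 0xFFL)
  complex <- bitwAnd(bitwShiftR(flags, 8), 0x08L) != 0L
  if (!(klass %in% MX_NUMERIC_CLASSES))
    stop("unsupported MAT array class: ", klass,
         " (only numeric arrays are handled)")
  off <- tg$next_off
  # dimensions
  tg <- mat_parse_tag(bytes, off)
  dims <- mat_read_values(bytes[tg$data_off:(tg$data_off + tg$nbytes - 1)],
                          tg$type, tg$nbytes)
  off <- tg$next_off
  # name
  tg <- mat_parse_tag(bytes, off)
  name <- if (tg$nbytes > 0)
    rawToChar(bytes[tg$data_off:(tg$data_off + tg$nbytes - 1)]) else ""
  off <- tg$next_off
  # real part
  tg <- mat_parse_tag(bytes, off)
  vals <- mat_read_values(bytes[tg$data_off:(tg$data_off + tg$nbytes - 1)],
                          tg$type, tg$nbytes)
  if (length(vals) != prod(dims))
    stop("MAT array '", name, "': expected ", prod(dims), " values, found ",
         length(vals), " (truncated file?)")
  if (complex) warning("imaginary part of '", name, "' ignored")
  arr <- array(as.numeric(vals), dim = dims)
  list(name = name, value = arr)
}

#' Read numeric arrays from a MAT v5 file
#'
#' Supports little-endian Level 5 MAT files containing real numeric arrays
#' (double, single, or integer storage), both as plain and zlib-compressed
#' data elements — the layout used by the public 12-class SSVEP recordings.
#'
#' @param path path to a `.mat` file.
#' @return Named list of numeric arrays.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bytes <- readBin(path, raw(), n = file.size(path))
  if (length(bytes) < 128L) stop("not a MAT v5 file (shorter than header): ", path)
  endian <- rawToChar(bytes[127:128])
  if (endian == "MI") stop("big-endian MAT files are not supported")
  if (endian != "IM") stop("not a MAT v5 file (bad endian indicator): ", path)

  out <- list()
  off <- 129L
  n <- length(bytes)
  while (off + 7L <= n) {
    tg <- mat_parse_tag(bytes, off)
    if (tg$data_off + tg$nbytes - 1L > n)
      stop("truncated MAT element at offset ", off)
    payload <- bytes[tg$data_off:(tg$data_off + tg$nbytes - 1L)]
    if (tg$type == MI_COMPRESSED) {
      # compressed elements are not padded to the 8-byte grid
      tg$next_off <- tg$data_off + tg$nbytes
      inner <- memDecompress(payload, type = "gzip")
      itg <- mat_parse_tag(inner, 1L)
      if (itg$type != MI_MATRIX) stop("unsupported compressed element type: ",
                                      itg$type)
      el <- mat_parse_matrix(inner[itg$data_off:length(inner)])
    } else if (tg$type == MI_MATRIX) {
      el <- mat_parse_matrix(payload)
    } else {
      off <- tg$next_off
      next  # skip non-matrix top-level elements
    }
    out[[el$name]] <- el$value
    off <- tg$next_off
  }
  out
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4, endian = "little"))
}

mat_pad <- function(bytes) {
  pad <- (8L - length(bytes) %% 8L) %% 8L
  c(bytes, raw(pad))
}

mat_matrix_bytes <- function(name, arr) {
  dims <- dim(arr); if (is.null(dims)) dims <- length(arr)
  flags <- c(writeBin(6L, raw(), size = 4, endian = "little"),  # mxDOUBLE
             raw(4))
  dimb <- writeBin(as.integer(dims), raw(), size = 4, endian = "little")
  nameb <- charToRaw(name)
  datab <- writeBin(as.numeric(arr), raw(), size = 8, endian = "little")
  body <- c(mat_tag(MI_UINT32, 8L), flags,
            mat_pad(c(mat_tag(MI_INT32, length(dimb)), dimb)),
            mat_pad(c(mat_tag(MI_INT8, length(nameb)), nameb)),
            mat_pad(c(mat_tag(MI_DOUBLE, length(datab)), datab)))
  body
}

#' Write numeric arrays to a MAT v5 file
#'
#' Companion to [read_mat()]; used to build test fixtures that mimic the
#' public dataset's on-disk layout without downloading it. Arrays are stored
#' as double-precision miMATRIX elements, optionally zlib-compressed.
#'
#' @param vars named list of numeric arrays.
#' @param path output path.
#' @param compress write each array as a compressed element (as MATLAB does
#'   by default); plain elements otherwise.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path, compress = FALSE) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars),
            all(nzchar(names(vars))))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by attenccnn on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  header <- charToRaw(desc)
  header <- c(header, raw(116L - length(header)))
  header <- c(header, raw(8L),
              as.raw(c(0x00, 0x01)),       # version 0x0100
              charToRaw("IM"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  for (nm in names(vars)) {
    body <- mat_matrix_bytes(nm, vars[[nm]])
    if (compress) {
      z <- memCompress(c(mat_tag(MI_MATRIX, length(body)), body),
                       type = "gzip")
      writeBin(c(mat_tag(MI_COMPRESSED, length(z)), z), con)
    } else {
      writeBin(c(mat_tag(MI_MATRIX, length(body)), body), con)
    }
  }
  invisible(path)
}

# Montage of the public 12-class recordings, in storage order.
PUBLIC_12CLASS_CHANNELS <- c("PO7", "PO3", "POz", "PO4", "PO8",
                             "O1", "Oz", "O2")

#' Load the public 12-class JFPM dataset
#'
#' Reads per-subject MAT files of the public 12-class SSVEP recordings
#' (variable `eeg` of shape `[12 targets x 8 channels x samples x 15
#' blocks]`) and assembles them into an [eeg_epochs] container labelled by
#' the 12-target JFPM table (`build_layout("dataset2_12class")`, whose
#' row-major order matches the storage order). The files carry no sampling
#' rate or montage metadata, so both are supplied as documented arguments
#' with the dataset's published values as defaults.
#'
#' @param path a directory of `s*.mat` files or a character vector of file
#'   paths; files are never downloaded.
#' @param channels channel names to keep, e.g. `c("O1", "Oz", "O2")` for the
#'   three-channel montage or `"Oz"` alone; default all 8.
#' @param fs sampling rate in Hz (default 256, the dataset's delivered rate).
#' @param channel_names montage in storage order; default the dataset's.
#' @return An [eeg_epochs] with `12 * 15` trials per subject; subject ids
#'   are the file basenames.
#' @export
load_public_12class <- function(path, channels = NULL, fs = 256,
                                channel_names = PUBLIC_12CLASS_CHANNELS) {
  files <- if (length(path) == 1L && dir.exists(path))
    sort(list.files(path, pattern = "\\.mat$", full.names = TRUE))
  else path
  if (length(files) == 0) stop("no .mat files found under ", path)

  all_data <- list(); all_labels <- list(); all_subj <- list()
  for (f in files) {
    vars <- read_mat(f)
    if (is.null(vars$eeg))
      stop(f, ": no variable 'eeg' (found: ",
           paste(names(vars), collapse = ", "), ")")
    eeg <- vars$eeg
    d <- dim(eeg)
    if (length(d) != 4L)
      stop(f, ": expected a 4-d 'eeg' array [targets x channels x samples x blocks], got ",
           paste(d, collapse = "x"))
    if (d[2] != length(channel_names))
      stop(f, ": ", d[2], " channels on disk but ", length(channel_names),
           " channel names supplied")
    nt <- d[1]; nb <- d[4]
    sid <- sub("\\.mat$", "", basename(f))
    # block-major trial order: block 1 targets 1..nt, block 2, ...
    dat <- array(0, dim = c(nt * nb, d[2], d[3]))
    labels <- integer(nt * nb)
    k <- 0L
    for (b in seq_len(nb)) {
      for (tg in seq_len(nt)) {
        k <- k + 1L
        dat[k, , ] <- eeg[tg, , , b]
        labels[k] <- tg - 1L
      }
    }
    all_data[[sid]] <- dat
    all_labels[[sid]] <- labels
    all_subj[[sid]] <- rep(sid, nt * nb)
  }
  n_ch <- dim(all_data[[1]])[2]; n_samp <- dim(all_data[[1]])[3]
  data <- array(0, dim = c(sum(vapply(all_data, function(x) dim(x)[1],
                                      numeric(1))), n_ch, n_samp))
  at <- 0L
  for (sid in names(all_data)) {
    n <- dim(all_data[[sid]])[1]
    data[at + seq_len(n), , ] <- all_data[[sid]]
    at <- at + n
  }
  epochs <- eeg_epochs(data, unlist(all_labels, use.names = FALSE),
                       unlist(all_subj, use.names = FALSE), fs,
                       channel_names,
                       n_classes = max(unlist(all_labels)) + 1L)
  if (!is.null(channels)) epochs <- select_channels(epochs, channels)
  epochs
}
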