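#' Read an EEG recording from disk
#'
#' Supported formats: `"matrix"` (delimited text: one header line
#' `fs=<Hz>` followed by the channel names, then one row of samples per
#' channel), `"bin"` (this package's binary container, see
#' [write_recording()]), `"edf"` (European Data Format, 16-bit), and
#' `"brainvision"` (a `.vhdr` header with a multiplexed binary or ASCII data
#' file). Values are returned in microvolts.
#'
#' @param path file to read (`.vhdr` for BrainVision).
#' @param format one of `"auto"`, `"matrix"`, `"bin"`, `"edf"`,
#'   `"brainvision"`. `"auto"` dispatches on the file extension.
#' @return An [recording()] object.
#' @export
load_recording <- function(path, format = c("auto", "matrix", "bin", "edf",
                                            "brainvision")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read recording: no such file '%s'", path), call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     edf = "edf", vhdr = "brainvision", bin = "bin",
                     tsv = "matrix", csv = "matrix", txt = "matrix",
                     abort_validation("cannot infer format from extension '.%s'", ext))
  }
  switch(format,
         matrix = read_matrix_recording(path),
         bin = read_bin_recording(path),
         edf = read_edf_recording(path),
         brainvision = read_brainvision_recording(path))
}

#' Write an EEG recording to disk
#'
#' `"matrix"` writes delimited text (lossless to ~15 significant digits);
#' `"bin"` writes a compact binary container holding the data matrix,
#' sampling rate, channel names and meta annotations losslessly; `"edf"`
#' writes a classic EDF file (16-bit quantized against the per-channel
#' physical range).
#'
#' @param rec an [recording()] object.
#' @param path destination file.
#' @param format `"matrix"`, `"bin"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("matrix", "bin", "edf")) {
  stop_if_not_recording(rec)
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop(sprintf("cannot write recording: '%s' is not writable", dir), call. = FALSE)
  switch(format,
         matrix = write_matrix_recording(rec, path),
         bin = write_bin_recording(rec, path),
         edf = write_edf_recording(rec, path))
  invisible(path)
}

## ---- delimited matrix ------------------------------------------------------

write_matrix_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(sprintf("fs=%.10g", rec$fs), rec$channel_names),
                   collapse = "\t"), con)
  body <- apply(rec$data, 1L, function(row)
    paste(formatC(row, digits = 15, format = "g"), collapse = "\t"))
  writeLines(body, con)
}

read_matrix_recording <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    abort_validation("'%s' is not a matrix recording (needs header + channels)", path)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!grepl("^fs=", hdr[[1L]]))
    abort_validation("'%s': first header field must be fs=<Hz>", path)
  fs <- as.numeric(sub("^fs=", "", hdr[[1L]]))
  names <- hdr[-1L]
  rows <- lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]]))
  if (length(rows) != length(names))
    abort_validation("'%s': %d channel names but %d data rows", path,
                     length(names), length(rows))
  data <- do.call(rbind, rows)
  recording(data, fs = fs, channel_names = names)
}

## ---- native binary container ----------------------------------------------
## Layout: magic "EEGBIN01" | int32 C | int32 N | double fs |
##   per channel: int32 nbytes, UTF-8 name | int32 nbytes, UTF-8 meta JSON |
##   C*N doubles (column-major, i.e. one topography per time point).

write_bin_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("EEGBIN01", con, nchars = 8L, eos = NULL)
  writeBin(c(nrow(rec$data), ncol(rec$data)), con, size = 4L, endian = "little")
  writeBin(rec$fs, con, size = 8L, endian = "little")
  for (nm in rec$channel_names) {
    raw <- charToRaw(enc2utf8(nm))
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
  }
  meta_raw <- charToRaw(jsonlite::toJSON(rec$meta, auto_unbox = TRUE, digits = NA))
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  writeBin(as.numeric(rec$data), con, size = 8L, endian = "little")
}

read_bin_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8L, useBytes = TRUE)
  if (!identical(magic, "EEGBIN01"))
    abort_validation("'%s' is not a microstate binary container", path)
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  fs <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  names <- character(dims[1L])
  for (i in seq_len(dims[1L])) {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    names[i] <- rawToChar(readBin(con, "raw", n))
  }
  mlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                             simplifyVector = TRUE)
  data <- matrix(readBin(con, "numeric", dims[1L] * dims[2L], size = 8L,
                         endian = "little"),
                 nrow = dims[1L], ncol = dims[2L])
  recording(data, fs = fs, channel_names = names, meta = as.list(meta))
}

## ---- EDF (classic, 16-bit) -------------------------------------------------

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

write_edf_recording <- function(rec, path) {
  C <- nrow(rec$data); N <- ncol(rec$data)
  phys_min <- apply(rec$data, 1L, min)
  phys_max <- apply(rec$data, 1L, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768; dig_max <- 32767
  # one data record holding the whole signal keeps the writer exact and simple
  duration <- N / rec$fs
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(paste(edf_field(x, width), collapse = ""),
                                      con, nchars = width * length(x), eos = NULL)
  put("0", 8L)                                   # version
  put("", 80L); put("", 80L)                     # patient / recording id
  put("01.01.00", 8L); put("00.00.00", 8L)       # start date / time
  put(sprintf("%d", 256L * (C + 1L)), 8L)        # header bytes
  put("", 44L)                                   # reserved
  put("1", 8L)                                   # number of records
  put(sprintf("%.8g", duration), 8L)             # record duration (s)
  put(sprintf("%d", C), 4L)                      # number of signals
  put(rec$channel_names, 16L)
  put(rep("", C), 80L)                           # transducer
  put(rep("uV", C), 8L)                          # physical dimension
  put(sprintf("%.8g", phys_min), 8L)
  put(sprintf("%.8g", phys_max), 8L)
  put(rep(sprintf("%d", dig_min), C), 8L)
  put(rep(sprintf("%d", dig_max), C), 8L)
  put(rep("", C), 80L)                           # prefiltering
  put(rep(sprintf("%d", N), C), 8L)              # samples per record
  put(rep("", C), 32L)                           # reserved
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(C)) {
    dig <- round((rec$data[i, ] - phys_min[i]) / scale[i]) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2L,
             endian = "little")
  }
}

read_edf_recording <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(width, n = 1L)
    trimws(vapply(seq_len(n), function(i) readChar(con, width, useBytes = TRUE), ""))
  get(8L); get(80L); get(80L); get(8L); get(8L)
  get(8L)                                        # header bytes
  get(44L)
  n_rec <- as.integer(get(8L))
  duration <- as.numeric(get(8L))
  C <- as.integer(get(4L))
  if (is.na(C) || C < 2L)
    abort_validation("EDF '%s': fewer than 2 signals", path)
  labels <- get(16L, C); get(80L, C); get(8L, C)
  phys_min <- as.numeric(get(8L, C)); phys_max <- as.numeric(get(8L, C))
  dig_min <- as.numeric(get(8L, C)); dig_max <- as.numeric(get(8L, C))
  get(80L, C)
  spr <- as.integer(get(8L, C))                  # samples per record per signal
  get(32L, C)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  chans <- lapply(seq_len(C), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(C)) {
      dig <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      chans[[i]] <- c(chans[[i]], (dig - dig_min[i]) * scale[i] + phys_min[i])
    }
  }
  data <- do.call(rbind, chans)
  fs <- spr[1L] / duration                       # samples per record / record s
  recording(data, fs = fs, channel_names = make.unique(labels))
}

## ---- BrainVision -----------------------------------------------------------

read_brainvision_recording <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list(); chans <- character(0); res <- numeric(0)
  for (l in lines) {
    l <- trimws(l)
    if (!nzchar(l) || startsWith(l, ";")) next
    if (grepl("^\\[.*\\]$", l)) { section <- gsub("^\\[|\\]$", "", l); next }
    m <- regmatches(l, regexec("^([^=]+)=(.*)$", l))[[1L]]
    if (length(m) != 3L) next
    key <- trimws(m[2L]); val <- trimws(m[3L])
    if (section == "Channel Infos") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
      chans <- c(chans, parts[1L])
      r <- if (length(parts) >= 3L && nzchar(parts[3L])) as.numeric(parts[3L]) else 1
      res <- c(res, if (is.na(r)) 1 else r)
    } else kv[[paste(section, key)]] <- val
  }
  C <- as.integer(kv[["Common Infos NumberOfChannels"]])
  fs <- 1e6 / as.numeric(kv[["Common Infos SamplingInterval"]])
  data_file <- file.path(dirname(path), kv[["Common Infos DataFile"]])
  orient <- toupper(kv[["Common Infos DataOrientation"]] %||% "MULTIPLEXED")
  fmt <- toupper(kv[["Common Infos DataFormat"]] %||% "BINARY")
  if (is.na(C) || C < 2L)
    abort_validation("BrainVision '%s': fewer than 2 channels", path)
  if (fmt == "BINARY") {
    bin_fmt <- toupper(kv[["Binary Infos BinaryFormat"]] %||% "IEEE_FLOAT_32")
    sz <- file.info(data_file)$size
    if (bin_fmt == "IEEE_FLOAT_32") {
      raw <- readBin(data_file, "numeric", n = sz / 4L, size = 4L, endian = "little")
    } else if (bin_fmt == "INT_16") {
      raw <- readBin(data_file, "integer", n = sz / 2L, size = 2L, signed = TRUE,
                     endian = "little")
    } else abort_validation("unsupported BinaryFormat '%s'", bin_fmt)
  } else {
    raw <- scan(data_file, quiet = TRUE)
  }
  N <- length(raw) %/% C
  raw <- raw[seq_len(N * C)]
  data <- if (orient == "MULTIPLEXED") matrix(raw, nrow = C) else
    t(matrix(raw, ncol = C))
  data <- data * res                             # resolution -> microvolts
  recording(data, fs = fs, channel_names = chans)
}
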