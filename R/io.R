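#' Read an EEG recording from disk
#'
#' Dispatches on the file extension: `.vhdr` (BrainVision header) or `.edf`
#' (European Data Format).
#'
#' @param path path to a `.vhdr` or `.edf` file.
#' @param subject_id subject identifier (defaults to the file stem).
#' @return a [recording()].
#' @export
read_eeg <- function(path, subject_id = NULL) {
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         vhdr = read_brainvision(path, subject_id = subject_id),
         edf = read_edf(path, subject_id = subject_id),
         stop("unsupported EEG format: .", ext,
              " (expected .vhdr or .edf)"))
}

parse_vhdr_ini <- function(lines) {
  sec <- ""
  kv <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
      kv[[sec]] <- list()
    } else if (grepl("=", ln) && sec != "") {
      k <- trimws(sub("=.*$", "", ln))
      v <- trimws(sub("^[^=]*=", "", ln))
      kv[[sec]][[k]] <- v
    }
  }
  kv
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header (INI format) and loads the data file it names.
#' Supported: MULTIPLEXED orientation, ASCII data, and binary
#' `IEEE_FLOAT_32` / `INT_16` data (with per-channel resolution scaling).
#' A `MarkerFile` declared in the header must exist next to it.
#'
#' @param vhdr_path path to the `.vhdr` file.
#' @param subject_id subject identifier.
#' @return a [recording()].
#' @export
read_brainvision <- function(vhdr_path, subject_id = "S01") {
  if (!file.exists(vhdr_path)) stop("header not found: ", vhdr_path)
  hdr <- parse_vhdr_ini(readLines(vhdr_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("malformed BrainVision header (no [Common Infos]): ",
                        vhdr_path)
  dir <- dirname(vhdr_path)
  if (!is.null(ci$MarkerFile)) {
    mf <- file.path(dir, ci$MarkerFile)
    if (!file.exists(mf))
      stop("marker file declared in header is missing: ", mf)
  }
  data_file <- file.path(dir, ci$DataFile)
  if (!file.exists(data_file)) stop("data file not found: ", data_file)
  nch <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)  # interval is in microseconds
  orient <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  if (orient != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", orient)
  chsec <- hdr[["Channel Infos"]]
  labels <- character(nch); resol <- rep(1, nch)
  for (i in seq_len(nch)) {
    entry <- chsec[[sprintf("Ch%d", i)]]
    if (is.null(entry)) {
      labels[i] <- sprintf("CH%03d", i)
    } else {
      parts <- strsplit(entry, ",")[[1]]
      labels[i] <- trimws(parts[1])
      if (length(parts) >= 3 && nzchar(trimws(parts[3])))
        resol[i] <- as.numeric(parts[3])
    }
  }
  fmt <- toupper(ci$DataFormat %||% "BINARY")
  if (fmt == "ASCII") {
    tab <- utils::read.table(data_file, header = FALSE)
    if (ncol(tab) != nch) stop("ASCII data column count (", ncol(tab),
                               ") does not match NumberOfChannels (", nch, ")")
    raw <- t(as.matrix(tab))
  } else {
    bf <- hdr[["Binary Infos"]]
    bin_fmt <- toupper(bf$BinaryFormat %||% "IEEE_FLOAT_32")
    sz <- file.size(data_file)
    con <- file(data_file, "rb")
    on.exit(close(con))
    if (bin_fmt == "IEEE_FLOAT_32") {
      n <- sz %/% 4
      v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    } else if (bin_fmt == "INT_16") {
      n <- sz %/% 2
      v <- readBin(con, "integer", n = n, size = 2, signed = TRUE,
                   endian = "little")
    } else stop("unsupported BinaryFormat: ", bin_fmt)
    if (n %% nch != 0)
      stop("data size (", n, " values) is not a multiple of channel count at byte ",
           sz)
    raw <- matrix(v, nrow = nch)
  }
  raw <- raw * resol
  recording(raw, fs = fs, channel_labels = labels, subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edf_pad <- function(x, width) formatC(substr(as.character(x), 1, width),
                                      width = width, flag = "-")

# numeric field that always fits EDF's 8 ASCII bytes
edf_num8 <- function(x) {
  s <- sprintf("%.6g", x)
  short <- sprintf("%.1e", x)
  ifelse(nchar(s) > 8, short, s)
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one-second data records, 16-bit samples scaled to each
#' channel's physical range.  The sampling rate must be an integer; samples
#' beyond the last whole second are dropped with a warning.
#'
#' @param rec a [recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  nch <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  if (n_rec * fs < ncol(rec$data))
    warning("trimming ", ncol(rec$data) - n_rec * fs,
            " samples beyond the last whole second")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  # scale with the values as they will be parsed back from the 8-byte fields
  pmin_ <- as.numeric(edf_num8(pmin_))
  pmax_ <- as.numeric(edf_num8(pmax_))
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  # each element of x padded/truncated to `width` ASCII bytes
  wr <- function(x, width) writeChar(paste0(edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8); wr(rec$subject_id, 80); wr("alphastate", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (nch + 1), 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(nch, 4)
  wr(rec$channel_labels, 16)
  wr(rep("", nch), 80)            # transducer
  wr(rep("uV", nch), 8)           # physical dimension
  wr(edf_num8(pmin_), 8)
  wr(edf_num8(pmax_), 8)
  wr(rep(dmin, nch), 8)
  wr(rep(dmax, nch), 8)
  wr(rep("", nch), 80)            # prefiltering
  wr(rep(fs, nch), 8)             # samples per data record
  wr(rep("", nch), 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(nch)) {
      dig <- as.integer(round((data[c, idx] - pmin_[c]) * scale[c]) + dmin)
      writeBin(pmin(dmax, pmax(dmin, dig)), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports continuous EDF with equal sampling rate across signals.
#'
#' @param path path to the `.edf` file.
#' @param subject_id subject identifier.
#' @return a [recording()].
#' @export
read_edf <- function(path, subject_id = "S01") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop("malformed EDF header at byte 252: ", path)
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  rd(80 * nch)  # transducer
  rd(8 * nch)   # physical dimension
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  rd(80 * nch)  # prefiltering
  ns <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  rd(32 * nch)
  if (length(unique(ns)) != 1)
    stop("EDF with per-signal sampling rates is not supported")
  fs <- ns[1] / rec_dur
  data <- matrix(0, nch, n_rec * ns[1])
  for (r in seq_len(n_rec)) {
    for (c in seq_len(nch)) {
      dig <- readBin(con, "integer", n = ns[c], size = 2, signed = TRUE,
                     endian = "little")
      idx <- ((r - 1) * ns[c] + 1):(r * ns[c])
      data[c, idx] <- pmin_[c] + (dig - dmin[c]) *
        (pmax_[c] - pmin_[c]) / (dmax[c] - dmin[c])
    }
  }
  recording(data, fs = fs, channel_labels = labels, subject_id = subject_id)
}

#' Write a scores table as CSV
#' @param scores data.frame `subject_id,total,a_hp,av_hp`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scores table from CSV
#' @param path CSV with columns `subject_id,total,a_hp,av_hp`.
#' @return data.frame.
#' @export
read_scores_csv <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "total", "a_hp", "av_hp")
  if (!all(need %in% names(sc)))
    stop("scores CSV must have columns: ", paste(need, collapse = ", "))
  sc
}
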