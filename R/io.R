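#' Parse a WFDB header file
#'
#' Reads the record line and per-signal specification lines of a `.hea` file
#' (the metadata format of the MIT-BIH Arrhythmia Database).  Only the fields
#' needed to decode format-212 signal files are extracted: file name, format,
#' gain (adu/mV), baseline (adu) and description.
#'
#' @param path Path to the `.hea` file.
#' @return A list of class `wfdb_meta`: `record_name`, `n_signals`, `fs`,
#'   `n_samples` and a data.frame `signals` with columns `file`, `format`,
#'   `gain`, `baseline`, `description`.
#' @export
read_wfdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header", call. = FALSE)
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 2L)
    stop("malformed WFDB record line", call. = FALSE)
  record_name <- sub("/.*$", "", rec[1])
  n_signals <- suppressWarnings(as.integer(rec[2]))
  fs <- if (length(rec) >= 3L)
    suppressWarnings(as.numeric(sub("/.*$", "", rec[3]))) else 250
  n_samples <- if (length(rec) >= 4L)
    suppressWarnings(as.integer(rec[4])) else NA_integer_
  if (is.na(n_signals) || n_signals < 1L)
    stop("malformed WFDB header: bad signal count", call. = FALSE)
  if (length(lines) < 1L + n_signals)
    stop("malformed WFDB header: missing signal lines", call. = FALSE)
  sig <- lapply(lines[1L + seq_len(n_signals)], function(l) {
    tk <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tk) < 2L) stop("malformed WFDB signal line", call. = FALSE)
    fmt <- as.integer(sub("[x:+].*$", "", tk[2]))
    gain <- 200; baseline <- NA_real_
    if (length(tk) >= 3L) {
      gs <- tk[3]
      if (grepl("\\(", gs))
        baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gs))
      gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gs))
      if (is.na(gain) || gain == 0) gain <- 200
    }
    adc_zero <- if (length(tk) >= 5L)
      suppressWarnings(as.numeric(tk[5])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
    desc <- if (length(tk) >= 9L)
      paste(tk[9:length(tk)], collapse = " ") else ""
    data.frame(file = tk[1], format = fmt, gain = gain,
               baseline = baseline, description = desc,
               stringsAsFactors = FALSE)
  })
  structure(list(record_name = record_name, n_signals = n_signals, fs = fs,
                 n_samples = n_samples, signals = do.call(rbind, sig)),
            class = "wfdb_meta")
}

# Decode a raw byte vector of WFDB format 212: two 12-bit two's-complement
# samples packed into 3 bytes, channels interleaved sample-frame by frame.
decode_212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_triplets <- length(b) %/% 3L
  if (n_values > 2L * n_triplets)
    stop(sprintf("truncated format-212 file: need %d samples, have %d (byte offset %d)",
                 n_values, 2L * n_triplets, length(raw_bytes)), call. = FALSE)
  i <- seq_len(ceiling(n_values / 2))
  b1 <- b[3L * (i - 1L) + 1L]
  b2 <- b[3L * (i - 1L) + 2L]
  b3 <- b[3L * (i - 1L) + 3L]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwAnd(b2, 0xF0L), 4L)
  s1[s1 > 2047L] <- s1[s1 > 2047L] - 4096L
  s2[s2 > 2047L] <- s2[s2 > 2047L] - 4096L
  out <- as.vector(rbind(s1, s2))
  out[seq_len(n_values)]
}

# Pack an integer vector of 12-bit two's-complement samples into format 212.
encode_212 <- function(samples) {
  s <- as.integer(samples)
  if (any(s < -2048L | s > 2047L))
    stop("format 212 samples must lie in [-2048, 2047]", call. = FALSE)
  if (length(s) %% 2L) s <- c(s, 0L)
  s[s < 0L] <- s[s < 0L] + 4096L
  s1 <- s[seq(1L, length(s), by = 2L)]
  s2 <- s[seq(2L, length(s), by = 2L)]
  b1 <- bitwAnd(s1, 0xFFL)
  b2 <- bitwOr(bitwShiftR(s1, 8L), bitwAnd(bitwShiftR(s2, 4L), 0xF0L))
  b3 <- bitwAnd(s2, 0xFFL)
  as.raw(as.vector(rbind(b1, b2, b3)))
}

#' Read a signal window from a WFDB format-212 record
#'
#' Decodes the packed 12-bit samples of the requested channel, converts to
#' millivolts via `(adu - baseline) / gain`, and returns the requested window
#' as an [ecg_signal].  Only format 212 (the MIT-BIH storage format) is
#' supported.
#'
#' @param header_path Path to the record's `.hea` file; the signal file is
#'   resolved relative to it.
#' @param channel Channel number, 1-based (channel 1 is MLII for MIT-BIH
#'   record 100).
#' @param start First sample to return, 0-based offset into the record.
#' @param count Number of samples to return; `NULL` means to the end of the
#'   record.  `count = 0` yields an empty signal.
#' @return An [ecg_signal] in mV with `fs` from the header.
#' @export
read_wfdb_212 <- function(header_path, channel = 1L, start = 0L,
                          count = NULL) {
  meta <- read_wfdb_header(header_path)
  channel <- as.integer(channel)
  if (channel < 1L || channel > meta$n_signals)
    stop("channel out of range", call. = FALSE)
  if (any(meta$signals$format != 212L))
    stop("only WFDB format 212 is supported", call. = FALSE)
  dat_path <- file.path(dirname(header_path), meta$signals$file[channel])
  n_rec <- meta$n_samples
  sz <- file.size(dat_path)
  if (is.na(sz)) stop("signal file not found: ", dat_path, call. = FALSE)
  n_avail <- (2L * (sz %/% 3L)) %/% meta$n_signals
  if (is.na(n_rec)) n_rec <- n_avail
  if (is.null(count)) count <- n_rec - start
  start <- as.integer(start); count <- as.integer(count)
  stopifnot(start >= 0L, count >= 0L)
  if (start + count > n_rec)
    stop("requested window exceeds record length", call. = FALSE)
  if (count == 0L)
    return(structure(list(samples = numeric(0), fs = meta$fs,
                          name = meta$record_name), class = "ecg_signal"))
  n_values <- meta$n_signals * (start + count)
  raw_bytes <- readBin(dat_path, "raw", n = 3L * ceiling(n_values / 2))
  adu <- decode_212(raw_bytes, n_values)
  ch <- adu[seq(channel, n_values, by = meta$n_signals)]
  ch <- ch[(start + 1L):(start + count)]
  mv <- (ch - meta$signals$baseline[channel]) / meta$signals$gain[channel]
  ecg_signal(mv, fs = meta$fs,
             name = sprintf("%s_ch%d", meta$record_name, channel))
}

#' Write a WFDB format-212 record
#'
#' Writes a `.hea` header and packed `.dat` signal file from a matrix of
#' integer ADC units (one column per channel).  Intended for building test
#' fixtures and for round-trip verification of the decoder.
#'
#' @param adu Integer matrix, `n_samples x n_signals`, values in
#'   \[-2048, 2047\].
#' @param path_base Output path without extension; `.hea` and `.dat` are
#'   appended.
#' @param fs Sampling rate written to the header.
#' @param gain Gain in adu/mV (recycled over channels).
#' @param baseline Baseline in adu (recycled over channels).
#' @return `path_base`, invisibly.
#' @export
write_wfdb_212 <- function(adu, path_base, fs = 360, gain = 200,
                           baseline = 0) {
  adu <- as.matrix(adu)
  ns <- ncol(adu)
  gain <- rep_len(gain, ns); baseline <- rep_len(baseline, ns)
  rec <- basename(path_base)
  hea <- c(sprintf("%s %d %g %d", rec, ns, fs, nrow(adu)),
           sprintf("%s.dat 212 %g(%d)/mV 12 0 0 0 0 ch%d", rec, gain,
                   as.integer(baseline), seq_len(ns)))
  writeLines(hea, paste0(path_base, ".hea"))
  interleaved <- as.vector(t(adu))
  writeBin(encode_212(interleaved), paste0(path_base, ".dat"))
  invisible(path_base)
}

#' Read a signal from a CSV file
#'
#' One value per row in the chosen column; an optional single header row is
#' detected automatically.  Decimal points are always `.` regardless of
#' locale.
#'
#' @param path CSV file path.
#' @param column Column name (character) or 1-based index.
#' @param fs Optional sampling rate to attach.
#' @return An [ecg_signal].
#' @export
read_csv_signal <- function(path, column = 1L, fs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first)))
    stop("empty CSV file: ", path, call. = FALSE)
  cells <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells))))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!nrow(df)) stop("CSV contains no data rows: ", path, call. = FALSE)
  col <- if (is.character(column)) {
    if (!column %in% names(df))
      stop("column not found: ", column, call. = FALSE)
    df[[column]]
  } else df[[as.integer(column)]]
  vals <- suppressWarnings(as.numeric(col))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value at data row %d of %s", bad, path),
         call. = FALSE)
  }
  ecg_signal(vals, fs = fs, name = basename(path))
}

#' Write a signal to CSV
#'
#' Single column `value`, one sample per row, full double precision.
#'
#' @param signal An [ecg_signal] or numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_signal <- function(signal, path) {
  x <- signal_samples(signal)
  writeLines(c("value", sprintf("%.17g", x)), path)
  invisible(path)
}

#' Write decomposition modes to CSV
#'
#' One column per mode (`imf1..imfK`, ascending center frequency), one row per
#' sample.
#'
#' @param result A `vmd_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modes_csv <- function(result, path) {
  stopifnot(inherits(result, "vmd_result"))
  m <- t(result$modes)
  colnames(m) <- sprintf("imf%d", seq_len(ncol(m)))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Write a two-column parameter profile to CSV
#'
#' Exports an MI-delay profile (`lag`, `mi_bits`) or an FNN profile
#' (`m`, `fnn_fraction`) for plotting.
#'
#' @param profile An `mi_profile` or `fnn_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- if (inherits(profile, "mi_profile")) {
    data.frame(lag = profile$lags, mi_bits = profile$mi_bits)
  } else if (inherits(profile, "fnn_profile")) {
    data.frame(m = profile$dims, fnn_fraction = profile$fractions)
  } else stop("unsupported profile object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
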