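# Minimal European Data Format (EDF) writer/reader: 16-bit integer samples,
# one-second data records, ASCII header per the published format layout.
# Only the features needed for session round-trips are implemented.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a multichannel recording to an EDF file
#'
#' Samples are stored as 16-bit integers in one-second data records, each
#' channel auto-scaled to its own symmetric physical range in microvolts, so
#' the quantization step of channel j is `2*max(|x_j|)/65535`.
#'
#' @param traces Numeric matrix, samples x channels, microvolts; the number
#'   of rows must be a whole number of seconds.
#' @param fs Sampling rate, Hz (integer).
#' @param path Output file path.
#' @param labels Channel labels; default from column names.
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, fs, path, labels = colnames(traces)) {
  stopifnot(is.matrix(traces), is.numeric(traces))
  fs <- as.integer(fs)
  n <- nrow(traces)
  ns <- ncol(traces)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))
  n_rec <- n / fs
  if (n_rec %% 1 != 0) {
    stop("trace length must be a whole number of one-second records",
         call. = FALSE)
  }
  n_rec <- as.integer(n_rec)

  phys_max <- apply(abs(traces), 2, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767
  dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.01", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4)
  )
  sig_hdr <- paste0(
    paste(vapply(labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, function(v) pad_field(sprintf("%.6g", v), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(v) pad_field(sprintf("%.6g", v), 8), ""),
          collapse = ""),
    paste(rep(pad_field(dig_min, 8), ns), collapse = ""),
    paste(rep(pad_field(dig_max, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    v <- round((traces[, j] + phys_max[j]) * scale[j]) + dig_min
    dig[, j] <- as.integer(pmin(pmax(v, dig_min), dig_max))
  }
  # interleave channels record by record
  idx <- matrix(seq_len(n), nrow = fs)
  for (r in seq_len(n_rec)) {
    writeBin(as.integer(as.vector(dig[idx[, r], ])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0") stop("not an EDF file (bad version field)", call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: no signals",
                                call. = FALSE)
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  list(header_bytes = header_bytes, n_rec = n_rec, rec_dur = rec_dur,
       ns = ns, labels = labels, dims = dims, phys_min = phys_min,
       phys_max = phys_max, dig_min = dig_min, dig_max = dig_max, spr = spr)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return List with `traces` (matrix, microvolts), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (length(unique(h$spr)) != 1) {
    stop("EDF parse error: heterogeneous per-channel sampling rates are not supported",
         call. = FALSE)
  }
  fs <- h$spr[1] / h$rec_dur
  n <- h$n_rec * h$spr[1]
  total <- h$n_rec * sum(h$spr)
  raw <- readBin(con, integer(), n = total, size = 2, endian = "little",
                 signed = TRUE)
  if (length(raw) != total) {
    stop(sprintf("EDF parse error: expected %d samples, found %d (record %d)",
                 total, length(raw), length(raw) %/% sum(h$spr) + 1),
         call. = FALSE)
  }
  traces <- matrix(0, nrow = n, ncol = h$ns,
                   dimnames = list(NULL, h$labels))
  arr <- array(raw, dim = c(h$spr[1], h$ns, h$n_rec))
  for (j in seq_len(h$ns)) {
    dig <- as.vector(arr[, j, ])
    gain <- (h$phys_max[j] - h$phys_min[j]) / (h$dig_max[j] - h$dig_min[j])
    traces[, j] <- h$phys_min[j] + (dig - h$dig_min[j]) * gain
  }
  list(traces = traces, fs = fs, labels = h$labels)
}
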