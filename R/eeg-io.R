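# Readers and writers: delimited-text EEG, a minimal 16-bit EDF subset,
# seizure annotation tables, and spectral-data CSV/JSON round-tripping.
# The EDF code covers the plain (continuous, int16) subset of the format,
# which is all this package produces and consumes.

#' Write / read delimited-text EEG
#'
#' One column per channel, tab-separated, with a comment header recording
#' the sampling rate (`# fs: <Hz>`).
#'
#' @param x Numeric matrix (samples x channels) or vector.
#' @param fs Sampling rate (Hz).
#' @param path File path.
#' @param labels Channel labels.
#' @return `path` (writer) or a list with `data`, `fs`, `labels` (reader).
#' @export
write_eeg_delim <- function(x, fs, path, labels = NULL) {
  x <- as.matrix(x)
  labels <- labels %||% paste0("ch", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", fs), con)
  writeLines(paste(labels, collapse = "\t"), con)
  utils::write.table(x, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_delim
#' @export
read_eeg_delim <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#\\s*fs:", first))
    stop("missing '# fs: <Hz>' header in ", path, call. = FALSE)
  fs <- as.numeric(sub("^#\\s*fs:\\s*", "", first))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           check.names = FALSE)
  list(data = as.matrix(tab), fs = fs, labels = colnames(tab))
}

#' Write / read EDF (European Data Format, 16-bit continuous subset)
#'
#' @param x Numeric matrix (samples x channels) or vector. The number of
#'   samples is truncated to whole 1 s data records.
#' @param fs Sampling rate (Hz, integer).
#' @param path File path.
#' @param labels Channel labels.
#' @return `path` (writer); a list with `data`, `fs`, `labels` (reader).
#' @export
write_eeg_edf <- function(x, fs, path, labels = NULL) {
  x <- as.matrix(x)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nc <- ncol(x)
  labels <- labels %||% paste0("ch", seq_len(nc))
  n_rec <- floor(nrow(x) / fs)
  if (n_rec < 1) stop("need at least one second of data", call. = FALSE)
  x <- x[seq_len(n_rec * fs), , drop = FALSE]
  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  span <- ifelse(pmax - pmin < 1e-12, 1, pmax - pmin)
  dmin <- -32768; dmax <- 32767
  pad <- function(s, w) formatC(substr(s, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("seizuredcm", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(as.character(256 * (nc + 1)), 8), pad("", 44),
                pad(as.character(n_rec), 8), pad("1", 8),
                pad(as.character(nc), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w)
    writeChar(paste0(vapply(as.character(vals), pad, "", w = w),
                     collapse = ""), con, eos = NULL)
  field(labels, 16); field(rep("", nc), 80); field(rep("uV", nc), 8)
  field(formatC(pmin, format = "g", digits = 7), 8)
  field(formatC(pmax, format = "g", digits = 7), 8)
  field(rep(dmin, nc), 8); field(rep(dmax, nc), 8)
  field(rep("", nc), 80); field(rep(fs, nc), 8); field(rep("", nc), 32)
  dig <- round(sweep(sweep(x, 2, pmin), 2, span, "/") * (dmax - dmin) + dmin)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nc))
      writeBin(as.integer(dig[rows, ch]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_eeg_edf
#' @export
read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(nc), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1)
    stop("mixed sampling rates are not supported", call. = FALSE)
  out <- matrix(0, n_rec * spr[1], nc)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      d <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      out[((r - 1) * spr[1] + 1):(r * spr[1]), ch] <-
        (d - dmin[ch]) / (dmax[ch] - dmin[ch]) * (pmax[ch] - pmin[ch]) +
        pmin[ch]
    }
  }
  list(data = out, fs = spr[1] / dur, labels = labels)
}

#' Read seizure annotations
#'
#' CSV with columns `onset_s`, `offset_s` and optionally `label`
#' (channel/source).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_seizure_annotations <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("onset_s", "offset_s") %in% names(tab)))
    stop("annotations need columns onset_s and offset_s", call. = FALSE)
  if (!"label" %in% names(tab)) tab$label <- NA_character_
  tab
}

#' Write / read spectral data (CSV + JSON sidecar)
#'
#' The CSV holds the long table (window, frequency, density); the JSON
#' sidecar records the window duration, averaging counts and onset index.
#'
#' @param x A `spectral_data` object.
#' @param csv_path CSV path; the sidecar is written next to it with a
#'   `.json` extension unless given.
#' @param json_path Optional sidecar path.
#' @param path CSV path (reader); sidecar looked up alongside.
#' @return `csv_path` (writer) or a `spectral_data` (reader).
#' @export
write_spectral_data <- function(x, csv_path, json_path = NULL) {
  stopifnot(inherits(x, "spectral_data"))
  json_path <- json_path %||% sub("\\.csv$", ".json", csv_path)
  utils::write.csv(as_tibble(x)[, c("window", "frequency", "density")],
                   csv_path, row.names = FALSE)
  meta <- list(window_s = x$window_s, n_seizures = x$n_seizures,
               n_avg = x$n_avg, onset_index = x$onset_index)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_spectral_data
#' @export
read_spectral_data <- function(path, json_path = NULL) {
  json_path <- json_path %||% sub("\\.csv$", ".json", path)
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  wide <- tidyr::pivot_wider(tibble::as_tibble(tab),
                             names_from = "frequency",
                             values_from = "density")
  S <- as.matrix(wide[, -1])
  new_spectral_data(S, as.numeric(colnames(S)), meta$window_s,
                    meta$n_seizures, n_avg = meta$n_avg,
                    onset_index = meta$onset_index)
}
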