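# EDF (European Data Format) reading and writing.
# EDF stores 16-bit little-endian integers mapped linearly between each
# signal's digital and physical ranges; headers are fixed-width ASCII.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "fg", digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write an EEG record to an EDF file
#'
#' Encodes each channel as 16-bit integers spanning the channel's physical
#' range (digital range -32768..32767), so the quantization step is
#' `(max - min) / 65535` per channel. Annotations, if any, are written to a
#' sidecar CSV next to the EDF (`<basename>_annotations.csv`) with header
#' `source_id,onset_s,offset_s`.
#'
#' @param record An [eeg_record()].
#' @param path Output file path.
#' @param annotations_path Optional explicit path for the sidecar annotation
#'   CSV; default places it next to `path`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, annotations_path = NULL) {
  validate_eeg_record(record)
  ns <- nrow(record$samples)
  n <- ncol(record$samples)
  rate <- record$sampling_rate_hz
  # one-second data records when the duration allows, else a single record
  if (abs(rate - round(rate)) < 1e-9 && n %% round(rate) == 0) {
    spr <- as.integer(round(rate))           # samples per data record
    n_rec <- n %/% spr
    rec_dur <- 1
  } else {
    spr <- n
    n_rec <- 1L
    rec_dur <- n / rate
  }
  pmin <- apply(record$samples, 1, min)
  pmax <- apply(record$samples, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(rec_dur, 8), edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(record$channel_names, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad(spr, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((record$samples[ch, idx] - pmin[ch]) * scale[ch]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }

  if (nrow(record$annotations)) {
    if (is.null(annotations_path)) {
      annotations_path <- edf_sidecar_path(path)
    }
    utils::write.csv(
      data.frame(source_id = edf_source_id(path),
                 onset_s = record$annotations$onset_s,
                 offset_s = record$annotations$offset_s),
      annotations_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

edf_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_annotations.csv")
}

edf_source_id <- function(path) {
  tools::file_path_sans_ext(basename(path))
}

edf_parse_num <- function(s, what) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (is.na(v)) stop("not a valid EDF file: cannot parse ", what)
  v
}

#' Read an EEG record from an EDF file
#'
#' Parses the fixed-width EDF header, decodes the 16-bit samples back to
#' physical units, and attaches seizure annotations from a sidecar CSV
#' (`source_id,onset_s,offset_s`) when one is present or given explicitly.
#' Rows are matched on `source_id` equal to the file's base name; if no row
#' matches, all rows are used.
#'
#' @param path Path to an EDF file.
#' @param annotations_path Optional path to the annotation CSV; default looks
#'   for `<basename>_annotations.csv` next to the EDF.
#' @return An [eeg_record()].
#' @export
read_edf <- function(path, annotations_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not a valid EDF file: header truncated")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256) stop("not a valid EDF file: header truncated")
  version <- trimws(substr(hdr, 1, 8))
  if (version != "0") stop("not a valid EDF file: unsupported version field")
  n_rec <- edf_parse_num(substr(hdr, 237, 244), "record count")
  rec_dur <- edf_parse_num(substr(hdr, 245, 252), "record duration")
  ns <- edf_parse_num(substr(hdr, 253, 256), "signal count")
  if (ns < 1 || ns != round(ns)) stop("not a valid EDF file: zero or invalid signal count")
  ns <- as.integer(ns)
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig, type = "bytes") < 256L * ns) stop("not a valid EDF file: signal header truncated")
  field <- function(off, width) {
    vapply(seq_len(ns), function(i) {
      substr(sig, off + (i - 1L) * width + 1L, off + i * width)
    }, "")
  }
  labels <- trimws(field(0L, 16L))
  pmin <- vapply(field(ns * (16L + 80L + 8L), 8L), edf_parse_num, 0, what = "physical min")
  pmax <- vapply(field(ns * (16L + 80L + 8L + 8L), 8L), edf_parse_num, 0, what = "physical max")
  dmin <- vapply(field(ns * (16L + 80L + 8L + 8L + 8L), 8L), edf_parse_num, 0, what = "digital min")
  dmax <- vapply(field(ns * (16L + 80L + 8L + 8L + 8L + 8L), 8L), edf_parse_num, 0, what = "digital max")
  spr <- vapply(field(ns * (16L + 80L + 8L * 5L + 80L), 8L), edf_parse_num, 0, what = "samples per record")
  if (any(spr < 1)) stop("not a valid EDF file: invalid samples-per-record")
  if (length(unique(spr)) != 1L) stop("EDF with per-signal sampling rates is not supported")
  spr <- as.integer(spr[1])
  rate <- spr / rec_dur
  n <- spr * n_rec
  samples <- matrix(0, nrow = ns, ncol = n)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr) stop("not a valid EDF file: data truncated")
      idx <- ((r - 1L) * spr + 1L):(r * spr)
      samples[ch, idx] <- pmin[ch] +
        (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    }
  }

  ann <- NULL
  if (is.null(annotations_path)) {
    cand <- edf_sidecar_path(path)
    if (file.exists(cand)) annotations_path <- cand
  }
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    tab <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    need <- c("source_id", "onset_s", "offset_s")
    if (!all(need %in% names(tab))) {
      stop("annotation CSV must have columns source_id,onset_s,offset_s")
    }
    hit <- tab$source_id == edf_source_id(path)
    if (any(hit)) tab <- tab[hit, , drop = FALSE]
    ann <- data.frame(onset_s = tab$onset_s, offset_s = tab$offset_s)
  }
  eeg_record(samples, rate, labels, ann)
}
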