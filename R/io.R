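#' Read a recording from disk
#'
#' Supported dialects: `fixture` (the package's plain-text single-file
#' container), `edf` (European Data Format, continuous 16-bit), and
#' `brainvision` (the .vhdr/.eeg/.vmrk triplet, resolved from the header
#' file). Data are returned in microvolts regardless of the on-disk unit
#' (uV/mV/V are rescaled; any other unit is an error).
#'
#' @param path file path (the .vhdr for BrainVision).
#' @param format one of "fixture", "edf", "brainvision".
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("fixture", "edf", "brainvision")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format,
         fixture = read_fixture(path),
         edf = read_edf(path),
         brainvision = read_brainvision(path))
}

unit_to_uv <- function(unit) {
  u <- trimws(unit)
  u <- sub("µ", "u", u)  # micro sign -> u
  switch(u, "uV" = 1, "mV" = 1e3, "V" = 1e6,
         abort(sprintf("unknown physical unit '%s'", unit)))
}

# ---- fixture container: JSON header line + one tab-separated row per channel

#' Write / read the plain-text fixture container
#'
#' A single self-describing file: first line a JSON header (fs, channel
#' labels, reference, annotations), then one tab-separated row of samples per
#' channel at full double precision, so write/read round-trips bit-identically.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(rec, path) {
  hdr <- jsonlite::toJSON(list(fs = rec$fs, channels = rec$channels,
                               reference = rec$reference,
                               annotations = rec$annotations),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (i in seq_len(nrow(rec$data))) {
    writeLines(paste(sprintf("%.17g", rec$data[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

read_fixture <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  data <- do.call(rbind, rows)
  ann <- tibble::as_tibble(hdr$annotations)
  if (nrow(ann) == 0) ann <- NULL
  eeg_recording(data, fs = as.numeric(hdr$fs), channels = hdr$channels,
                reference = hdr$reference, annotations = ann)
}

# ---- EDF (continuous, 16-bit integer, equal rates across signals) ----

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a minimal continuous EDF file
#'
#' One data record spanning the whole recording, 16-bit digitization against
#' the per-channel physical range. Intended for building test inputs; lossy to
#' the 16-bit quantization like any EDF export.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param physical_unit on-disk unit, "uV" (default), "mV" or "V".
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_unit = "uV") {
  ns <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  scale <- unit_to_uv(physical_unit)
  phys <- rec$data / scale
  pmin <- apply(phys, 1, min); pmax <- apply(phys, 1, max)
  pmax <- ifelse(pmax > pmin, pmax, pmin + 1)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.01", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("EDF", 44)
  wr(1, 8); wr(format(nsamp / rec$fs, digits = 8), 8); wr(ns, 4)
  for (lab in rec$channels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(physical_unit, 8)
  for (i in seq_len(ns)) wr(format(pmin[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(pmax[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(nsamp, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    dig <- round((phys[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (anyDuplicated(labels)) abort("duplicate channel label in EDF header")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) abort("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_i <- matrix(0, ns, spr[1])
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      rec_i[i, ] <- pmin[i] + (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
    chunks[[r]] <- rec_i
  }
  data <- do.call(cbind, chunks)
  for (i in seq_len(ns)) data[i, ] <- data[i, ] * unit_to_uv(units[i])
  eeg_recording(data, fs = fs, channels = labels, reference = "raw")
}

# ---- BrainVision triplet ----

#' Write a BrainVision triplet (.vhdr/.eeg/.vmrk)
#'
#' Multiplexed IEEE_FLOAT_32 data with unit resolution; markers from the
#' recording's annotations. For building test inputs.
#'
#' @param rec an [eeg_recording()].
#' @param vhdr_path path of the header file; .eeg/.vmrk written alongside.
#' @return `vhdr_path`, invisibly.
#' @export
write_brainvision <- function(rec, vhdr_path) {
  base <- sub("\\.vhdr$", "", basename(vhdr_path))
  dir <- dirname(vhdr_path)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_along(rec$channels), rec$channels))
  writeLines(hdr, vhdr_path)
  con <- file(file.path(dir, paste0(base, ".eeg")), "wb")
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")  # column-major = multiplexed
  close(con)
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Marker Infos]")
  if (nrow(rec$annotations)) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,%d,0",
                          seq_len(nrow(rec$annotations)),
                          rec$annotations$label,
                          round(rec$annotations$onset_s * rec$fs) + 1L,
                          pmax(1L, round(rec$annotations$duration_s * rec$fs))))
  }
  writeLines(mrk, file.path(dir, paste0(base, ".vmrk")))
  invisible(vhdr_path)
}

parse_vhdr_kv <- function(lines) {
  kv <- grep("^[A-Za-z0-9]+=", lines, value = TRUE)
  keys <- sub("=.*", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  kv <- parse_vhdr_kv(lines)
  dir <- dirname(vhdr_path)
  eeg_path <- file.path(dir, kv$DataFile)
  if (!file.exists(eeg_path)) abort(sprintf("missing companion file: %s", kv$DataFile))
  nchan <- as.integer(kv$NumberOfChannels)
  fs <- 1e6 / as.numeric(kv$SamplingInterval)
  fmt <- kv$BinaryFormat %||% "IEEE_FLOAT_32"
  if (!identical(kv$DataOrientation %||% "MULTIPLEXED", "MULTIPLEXED")) {
    abort("only MULTIPLEXED orientation supported")
  }
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, "", 1)
  res <- vapply(ch_parts, function(p) {
    r <- if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1
    r
  }, 0)
  units <- vapply(ch_parts, function(p) if (length(p) >= 4 && nzchar(p[4])) p[4] else "uV", "")
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw_v <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw_v <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
  } else abort(sprintf("unsupported BinaryFormat '%s'", fmt))
  data <- matrix(raw_v, nrow = nchan)  # multiplexed: channel fastest
  for (i in seq_len(nchan)) data[i, ] <- data[i, ] * res[i] * unit_to_uv(units[i])
  mrk_path <- file.path(dir, kv$MarkerFile %||% "")
  ann <- NULL
  if (nzchar(kv$MarkerFile %||% "") && file.exists(mrk_path)) {
    ml <- grep("^Mk[0-9]+=", readLines(mrk_path, warn = FALSE), value = TRUE)
    if (length(ml)) {
      parts <- strsplit(sub("^Mk[0-9]+=", "", ml), ",")
      ann <- tibble::tibble(
        onset_s = (as.numeric(vapply(parts, `[`, "", 3)) - 1) / fs,
        duration_s = as.numeric(vapply(parts, `[`, "", 4)) / fs,
        label = vapply(parts, `[`, "", 2))
    }
  }
  eeg_recording(data, fs = fs, channels = labels, reference = "raw",
                annotations = ann)
}

# ---- hypnogram and event TSVs ----

#' Read/write hypnogram TSV (columns: epoch_index, stage)
#' @param path file path.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    abort("hypnogram TSV needs columns epoch_index, stage")
  }
  df <- df[order(df$epoch_index), ]
  hypnogram(df$stage)
}

#' @rdname read_hypnogram
#' @param hyp a [hypnogram()].
#' @export
write_hypnogram <- function(hyp, path) {
  utils::write.table(as.data.frame(hyp[c("epoch_index", "stage")]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write cue-event TSV (columns: onset_sample, category, stage, block)
#' @param path file path.
#' @return a [cue_events()] tibble.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "category", "stage", "block")
  if (!all(need %in% names(df))) {
    abort(sprintf("events TSV needs columns %s", paste(need, collapse = ", ")))
  }
  cue_events(df$onset_sample, df$category, df$stage, df$block)
}

#' @rdname read_events
#' @param events a [cue_events()] tibble.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
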