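#' Write / read a recording in the plain two-file format
#'
#' The plain format stores a recording as `<path>.hdr` (key=value lines:
#' `fs`, `duration`, `labels` as a comma-separated list) and `<path>.dat`
#' (whitespace-delimited numeric matrix, one row per channel, microvolt).
#'
#' @param recording An `eeg_recording`.
#' @param path File stem (without extension).
#' @return `write_plain_recording()` returns `path` invisibly;
#'   `read_plain_recording()` returns an `eeg_recording`.
#' @export
write_plain_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  writeLines(c(
    paste0("fs=", recording$fs),
    paste0("duration=", recording$duration),
    paste0("labels=", paste(recording$channel_labels, collapse = ","))
  ), paste0(path, ".hdr"))
  write.table(recording$samples, paste0(path, ".dat"),
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_plain_recording
#' @export
read_plain_recording <- function(path) {
  hdr_file <- paste0(path, ".hdr")
  dat_file <- paste0(path, ".dat")
  if (!file.exists(hdr_file) || !file.exists(dat_file)) {
    abort(paste0("plain recording not found at stem '", path, "'"),
          class = "qeegcsa_io_error")
  }
  hdr <- readLines(hdr_file)
  get <- function(key) {
    line <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(line) != 1) {
      abort(paste0("malformed header: missing '", key, "'"),
            class = "qeegcsa_io_error")
    }
    sub(paste0("^", key, "="), "", line)
  }
  fs <- as.numeric(get("fs"))
  duration <- as.numeric(get("duration"))
  labels <- strsplit(get("labels"), ",")[[1]]
  m <- as.matrix(read.table(dat_file))
  dimnames(m) <- NULL
  if (nrow(m) != length(labels)) {
    abort("channel count in data does not match header labels",
          class = "qeegcsa_io_error")
  }
  structure(
    list(samples = m, fs = fs, channel_labels = labels, duration = duration),
    class = "eeg_recording"
  )
}

#' Write / read a recording as EDF
#'
#' Minimal European Data Format support: 16-bit samples, one 1-second data
#' record per second, physical units microvolt. Values round-trip within the
#' 16-bit quantization of each channel's physical range.
#'
#' @param recording An `eeg_recording` whose duration is a whole number of
#'   seconds.
#' @param path Output `.edf` file path.
#' @return `write_edf()` returns `path` invisibly; `read_edf()` returns an
#'   `eeg_recording`.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  ns <- nrow(recording$samples)
  n_rec <- floor(ncol(recording$samples) / recording$fs)
  if (n_rec < 1) abort("recording shorter than one data record (1 s)",
                       class = "qeegcsa_io_error")
  spr <- as.integer(recording$fs)
  pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(pad(x, width), con, nchars = width, eos = NULL)
  put("0", 8)
  put("X X X X", 80)
  put("Startdate X X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(256 + ns * 256, 8)
  put("EDF", 44)
  put(n_rec, 8)
  put(1, 8)      # record duration, seconds
  put(ns, 4)
  phys_min <- phys_max <- numeric(ns)
  for (ci in seq_len(ns)) {
    rng <- range(recording$samples[ci, ])
    span <- max(diff(rng), 1e-6)
    phys_min[ci] <- rng[1] - 0.01 * span
    phys_max[ci] <- rng[2] + 0.01 * span
  }
  for (ci in seq_len(ns)) put(recording$channel_labels[ci], 16)
  for (ci in seq_len(ns)) put("AgAgCl electrode", 80)
  for (ci in seq_len(ns)) put("uV", 8)
  for (ci in seq_len(ns)) put(sprintf("%.3f", phys_min[ci]), 8)
  for (ci in seq_len(ns)) put(sprintf("%.3f", phys_max[ci]), 8)
  for (ci in seq_len(ns)) put(-32768, 8)
  for (ci in seq_len(ns)) put(32767, 8)
  for (ci in seq_len(ns)) put("", 80)
  for (ci in seq_len(ns)) put(spr, 8)
  for (ci in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ci in seq_len(ns)) {
      x <- recording$samples[ci, idx]
      dig <- round((x - phys_min[ci]) / (phys_max[ci] - phys_min[ci]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "qeegcsa_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  getf <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  getf(8); getf(80); getf(80); getf(8); getf(8)
  header_bytes <- as.integer(getf(8))
  getf(44)
  n_rec <- as.integer(getf(8))
  rec_dur <- as.numeric(getf(8))
  ns <- as.integer(getf(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) {
    abort("malformed EDF header", class = "qeegcsa_io_error")
  }
  labels <- vapply(seq_len(ns), function(i) getf(16), character(1))
  for (i in seq_len(ns)) getf(80)
  for (i in seq_len(ns)) getf(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(getf(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(getf(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(getf(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(getf(8)), numeric(1))
  for (i in seq_len(ns)) getf(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(getf(8)), integer(1))
  for (i in seq_len(ns)) getf(32)
  if (length(unique(spr)) != 1) {
    abort("mixed per-channel sampling rates are not supported",
          class = "qeegcsa_io_error")
  }
  fs <- spr[1] / rec_dur
  m <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ci], size = 2,
                     endian = "little", signed = TRUE)
      phys <- (dig - dig_min[ci]) / (dig_max[ci] - dig_min[ci]) *
        (phys_max[ci] - phys_min[ci]) + phys_min[ci]
      m[ci, ((r - 1) * spr[ci] + 1):(r * spr[ci])] <- phys
    }
  }
  structure(
    list(samples = m, fs = fs, channel_labels = labels,
         duration = n_rec * rec_dur),
    class = "eeg_recording"
  )
}

#' Read a recording from disk
#'
#' @param path Path to an `.edf` file or the stem of a plain two-file
#'   recording.
#' @param format `"auto"` (by extension), `"edf"` or `"plain"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "plain")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "plain"
  }
  if (format == "edf") read_edf(path) else read_plain_recording(path)
}

#' Write descriptor and classification tables
#'
#' Delimited-text writers with the documented column set; the JSON report
#' variant embeds the per-subject rule trace.
#'
#' @param x Tibble of descriptors / classification results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  cols <- c("df_mean", "df_min", "df_max", "dfv", "dfv_alpha",
            "fp_delta", "fp_theta", "fp_prealpha", "fp_alpha",
            "bi_delta", "bi_theta", "bi_prealpha", "bi_alpha", "freq_ratio")
  keep <- c(intersect(c("subject_id", "region"), names(x)), cols)
  out <- as.data.frame(x[, keep])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
write_classification_report <- function(x, path) {
  keep <- intersect(c("subject_id", "region", "pattern", "abnormal",
                      "predicted_group", "rule_id", "fallback"), names(x))
  out <- as.data.frame(x[, keep])
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
write_report_json <- function(x, path) {
  x <- as_tibble(x)
  drop <- intersect(c("df_per_epoch"), names(x))
  jsonlite::write_json(x[, setdiff(names(x), drop)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
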