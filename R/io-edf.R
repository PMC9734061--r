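# Signal file I/O. EDF (European Data Format) is the polysomnography
# interchange standard: 16-bit samples with per-channel physical scaling.
# A lossless alternative (float32 flat binary + JSON sidecar) is provided
# for exact round trips. No R EDF reader is declared as a dependency, so a
# minimal EDF codec for continuous uncalibrated recordings is implemented
# here (fixed-field ASCII header + int16 little-endian data records).

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width, flag = " ")
}

fmt_num8 <- function(x) {
  for (digits in 6:1) {
    s <- formatC(signif(x, digits), format = "g", digits = digits)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into 8 EDF header bytes")
}

#' Default channel-label-to-role mapping
#'
#' Maps free-text EDF channel labels to the montage role tags used
#' throughout the package, via case-insensitive regular expressions. The
#' mapping is configurable because electrode montages vary between labs.
#'
#' @return Named character vector: names are roles, values are regexes.
#' @export
default_role_map <- function() {
  c(EEG_front = "eeg[._-]?front|frontal",
    EEG_par = "eeg[._-]?par|parietal",
    ACC = "^acc",
    AD = "^ad($|[^a-z])|anterodorsal",
    TRN = "^trn|reticular",
    Brr = "^brr|barrel",
    VPL = "^vpl",
    EMG = "emg|muscle")
}

resolve_roles <- function(labels, role_map = default_role_map(),
                          require_roles = character(0)) {
  roles <- rep(NA_character_, length(labels))
  for (role in names(role_map)) {
    hit <- grepl(role_map[[role]], labels, ignore.case = TRUE)
    if (sum(hit) > 1) {
      stop("channel role '", role, "' matched by several labels: ",
           paste(labels[hit], collapse = ", "))
    }
    if (any(hit)) {
      if (!is.na(roles[which(hit)])) {
        stop("label '", labels[hit], "' matches more than one role")
      }
      roles[which(hit)] <- role
    }
  }
  missing <- setdiff(require_roles, roles[!is.na(roles)])
  if (length(missing)) {
    stop("required channel role(s) not found in file: ",
         paste(missing, collapse = ", "))
  }
  if (anyNA(roles)) {
    stop("could not resolve a role for label(s): ",
         paste(labels[is.na(roles)], collapse = ", "))
  }
  roles
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric per-channel physical
#' range, the EDF lossy step. The sampling rate must yield an integer
#' number of samples per data record.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param record_s Data-record duration in seconds (default 1).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  ns <- ncol(rec$signals)
  spr <- rec$fs * record_s
  if (abs(spr - round(spr)) > 1e-9) {
    stop("fs * record_s must be an integer number of samples per record")
  }
  spr <- as.integer(round(spr))
  n_rec <- nrow(rec$signals) %/% spr
  if (n_rec * spr < nrow(rec$signals)) {
    warning("recording length is not a whole number of data records; ",
            nrow(rec$signals) - n_rec * spr, " trailing samples dropped")
  }
  phys_max <- vapply(seq_len(ns), function(j) {
    m <- max(abs(rec$signals[, j]), na.rm = TRUE)
    if (m == 0) 1 else m * (1 + 1e-6)
  }, numeric(1))

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_ascii(x, width), con, eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (unused)
  wr(sprintf("Startdate X ZT=%g", rec$t0_zt), 80) # recording id; ZT start hour
  wr("01.01.00", 8)                            # date placeholder
  wr("00.00.00", 8)                            # time placeholder
  wr(256 * (1 + ns), 8)                        # header bytes
  wr("", 44)                                   # reserved
  wr(n_rec, 8)
  wr(fmt_num8(record_s), 8)
  wr(ns, 4)
  for (lab in rec$labels) wr(lab, 16)
  for (j in seq_len(ns)) wr("", 80)            # transducer
  for (j in seq_len(ns)) wr("uV", 8)
  for (j in seq_len(ns)) wr(fmt_num8(-phys_max[j]), 8)
  for (j in seq_len(ns)) wr(fmt_num8(phys_max[j]), 8)
  for (j in seq_len(ns)) wr("-32768", 8)
  for (j in seq_len(ns)) wr("32767", 8)
  for (j in seq_len(ns)) wr("", 80)            # prefilter
  for (j in seq_len(ns)) wr(spr, 8)
  for (j in seq_len(ns)) wr("", 32)            # reserved

  ## physical -> digital: exact inverse of the EDF read mapping
  ## physical = phys_min + (d - dig_min) * (phys_max - phys_min) / (dig_max - dig_min),
  ## with phys_max re-read from its own 8-char header field so the scaling
  ## is reproducible on read
  pm <- vapply(phys_max, function(x) as.numeric(fmt_num8(x)), numeric(1))
  dig <- lapply(seq_len(ns), function(j) {
    d <- round((rec$signals[, j] + pm[j]) / (2 * pm[j]) * 65535) - 32768
    as.integer(pmax(pmin(d, 32767), -32768))
  })
  for (r in seq_len(n_rec)) {
    sel <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) writeBin(dig[[j]][sel], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path, role_map = default_role_map(),
                     require_roles = character(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8) # version
  rd(80) # patient
  rec_id <- rd(80)
  rd(8); rd(8) # date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: bad signal count")
  labels <- vapply(seq_len(ns), function(j) rd(16), character(1))
  for (j in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(j) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(j) rd(8), character(1)))
  for (j in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("EDF files with per-channel sampling rates are not supported")
  }
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr, n_rec, record_s))) {
    stop("corrupt EDF header: unparseable numeric field")
  }
  expected <- header_bytes + n_rec * sum(spr) * 2
  if (file.size(path) < expected) {
    stop("corrupt EDF file: ", file.size(path), " bytes, header implies ", expected)
  }
  fs <- spr[1] / record_s
  sig <- matrix(0, nrow = n_rec * spr[1], ncol = ns)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[j], size = 2, endian = "little")
      if (length(d) < spr[j]) stop("corrupt EDF file: truncated data record")
      sig[((r - 1) * spr[1] + 1):(r * spr[1]), j] <-
        phys_min[j] + (d - dig_min[j]) * scale[j]
    }
  }
  t0_zt <- 0
  m <- regmatches(rec_id, regexec("ZT=([-0-9.]+)", rec_id))[[1]]
  if (length(m) == 2) t0_zt <- as.numeric(m[2])
  roles <- resolve_roles(labels, role_map, require_roles)
  recording(sig, fs, labels, roles, t0_zt = t0_zt)
}

#' Write a recording as flat float32 binary plus JSON sidecar
#'
#' Lossless (to float32) alternative to EDF: column-interleaved samples in a
#' `.bin` file, metadata (fs, labels, roles, ZT start) in `<path>.json`.
#'
#' @param rec A [recording()].
#' @param path Output `.bin` path.
#' @return `path`, invisibly.
#' @export
write_recording_bin <- function(rec, path) {
  meta <- list(fs = rec$fs, n_samples = nrow(rec$signals),
               labels = rec$labels, roles = rec$roles, t0_zt = rec$t0_zt,
               dtype = "float32", order = "sample_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$signals)), con, size = 4, endian = "little")
  invisible(path)
}

read_recording_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  n <- meta$n_samples * length(meta$labels)
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  if (length(x) < n) stop("corrupt binary recording: truncated data")
  sig <- matrix(x, nrow = meta$n_samples, ncol = length(meta$labels), byrow = TRUE)
  recording(sig, meta$fs, meta$labels, meta$roles, t0_zt = meta$t0_zt)
}

#' Read a recording from disk
#'
#' @param path File path (`.edf` or `.bin` with JSON sidecar).
#' @param format `"auto"` (by extension), `"edf"` or `"bin"`.
#' @param role_map Label-regex-to-role mapping, see [default_role_map()].
#' @param require_roles Roles that must be present (error otherwise).
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "bin"),
                           role_map = default_role_map(),
                           require_roles = character(0)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "bin"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") read_edf(path, role_map, require_roles)
  else read_recording_bin(path)
}

#' Write a recording to disk
#'
#' @inheritParams read_recording
#' @param rec A [recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "bin"
  }
  if (format == "edf") write_edf(rec, path) else write_recording_bin(rec, path)
}
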