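# Monitor-file (AMB) and prescription-file dialects.
#
# AMB layout (little-endian):
#   header, 32 bytes: magic "AMB1" | user_id 8B ASCII right-padded |
#     YYYYMMDD uint32 | HHMMSS uint32 | mode uint8 (1=activity, 2=resting) |
#     sample_rate uint8 | CRC32 of payload (4B) | 6B zero pad
#   per-row record, 11 bytes: t_offset deciseconds uint32 | ax, ay, az int16
#     milli-g | hr uint8 bpm (0 = no beat detected at this row)
#
# Prescription record, 16 bytes: YYYYMMDD uint32 | kind uint8 (1=mandatory,
#   2=optional, 3=rest, 4=eft) | warmup uint8 | endurance uint16 | cooldown
#   uint8 | zone_lo uint8 | zone_hi uint8 | plan_week uint8 | CRC8 of the
#   first 12 bytes | 3B zero pad

AM_MODES <- c(activity = 1L, resting = 2L)
RX_KINDS <- c(mandatory = 1L, optional = 2L, rest = 3L, eft = 4L)
AMB_HEADER_BYTES <- 32L
AMB_ROW_BYTES <- 11L
RX_BYTES <- 16L

#' Parse a monitor filename
#'
#' Monitor files are named `<user>_<YYYYMMDD>_<HHMMSS>_<A|R>.amb`; the
#' filename (not the upload time) determines which intervention date the
#' data belong to. Mode code `A` is an activity recording, `R` a resting
#' heart-rate recording.
#'
#' @param name filename (basename or path).
#' @return list with `user_id`, `date` (Date), `time` ("HH:MM:SS"), and
#'   `mode` ("activity" or "resting").
#' @export
parse_am_filename <- function(name) {
  base <- basename(name)
  fl_assert(grepl("\\.amb$", base), "fitloop_format_error",
            "'%s': missing .amb extension", base)
  stem <- sub("\\.amb$", "", base)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  fl_assert(length(parts) == 4L, "fitloop_format_error",
            "'%s': expected 4 underscore-separated segments, got %d",
            base, length(parts))
  fl_assert(grepl("^[A-Za-z0-9-]{1,8}$", parts[1]), "fitloop_format_error",
            "'%s': bad user segment '%s'", base, parts[1])
  fl_assert(grepl("^[0-9]{8}$", parts[2]), "fitloop_format_error",
            "'%s': bad date segment '%s'", base, parts[2])
  date <- as.Date(parts[2], format = "%Y%m%d")
  fl_assert(!is.na(date), "fitloop_format_error",
            "'%s': bad date segment '%s'", base, parts[2])
  fl_assert(grepl("^[0-9]{6}$", parts[3]), "fitloop_format_error",
            "'%s': bad time segment '%s'", base, parts[3])
  hh <- as.integer(substr(parts[3], 1, 2))
  mm <- as.integer(substr(parts[3], 3, 4))
  ss <- as.integer(substr(parts[3], 5, 6))
  fl_assert(hh < 24 && mm < 60 && ss < 60, "fitloop_format_error",
            "'%s': bad time segment '%s'", base, parts[3])
  fl_assert(parts[4] %in% c("A", "R"), "fitloop_format_error",
            "'%s': bad mode segment '%s' (want A or R)", base, parts[4])
  list(
    user_id = parts[1],
    date = date,
    time = sprintf("%02d:%02d:%02d", hh, mm, ss),
    mode = if (parts[4] == "A") "activity" else "resting"
  )
}

am_filename <- function(user_id, date, time, mode) {
  sprintf("%s_%s_%s_%s.amb", user_id, format(date, "%Y%m%d"),
          gsub(":", "", time), if (mode == "activity") "A" else "R")
}

#' Construct a monitor file object
#'
#' @param user_id participant identifier, at most 8 ASCII characters.
#' @param file_date recording date (Date or "YYYY-MM-DD").
#' @param file_time recording start time, "HH:MM:SS".
#' @param mode "activity" or "resting".
#' @param samples data.frame with columns `t_offset` (seconds from file
#'   start, on the 0.1 s grid, strictly increasing), `ax`, `ay`, `az`
#'   (acceleration in g, |a| <= 8), `hr` (instantaneous heart rate in bpm at
#'   beat rows, 0 where no beat was detected; nonzero values in 20--250).
#' @param sample_rate rows per second (dialect constant 10).
#' @param source_name original filename; defaults to the canonical name.
#' @return an object of class `am_file`.
#' @export
am_file <- function(user_id, file_date, file_time, mode, samples,
                    sample_rate = 10L, source_name = NULL) {
  file_date <- as.Date(file_date)
  samples <- as.data.frame(samples)
  if (nrow(samples)) {
    samples$t_offset <- round(samples$t_offset, 1)
    for (col in c("ax", "ay", "az")) samples[[col]] <- round(samples[[col]], 3)
    samples$hr <- as.integer(round(samples$hr))
  }
  f <- structure(list(
    user_id = user_id,
    file_date = file_date,
    file_time = file_time,
    mode = mode,
    sample_rate = as.integer(sample_rate),
    samples = samples,
    source_name = source_name %||%
      am_filename(user_id, file_date, file_time, mode)
  ), class = "am_file")
  validate_am_file(f)
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_am_file <- function(f) {
  fl_assert(inherits(f, "am_file"), "fitloop_validation_error", "not an am_file")
  fl_assert(nchar(f$user_id) >= 1 && nchar(f$user_id) <= 8,
            "fitloop_validation_error", "user_id must be 1-8 characters")
  fl_assert(f$mode %in% names(AM_MODES), "fitloop_validation_error",
            "mode must be 'activity' or 'resting'")
  s <- f$samples
  need <- c("t_offset", "ax", "ay", "az", "hr")
  fl_assert(all(need %in% names(s)), "fitloop_validation_error",
            "samples must have columns: %s", paste(need, collapse = ", "))
  if (nrow(s)) {
    fl_assert(all(s$t_offset >= 0), "fitloop_validation_error",
              "t_offset must be non-negative")
    fl_assert(all(diff(s$t_offset) > 0), "fitloop_validation_error",
              "t_offset must be strictly increasing")
    bad <- which(abs(s$ax) > 8 | abs(s$ay) > 8 | abs(s$az) > 8)
    fl_assert(length(bad) == 0, "fitloop_validation_error",
              "acceleration out of +/-8 g range at row %d",
              if (length(bad)) bad[1] else 0L)
    badhr <- which(!(s$hr == 0 | (s$hr >= 20 & s$hr <= 250)))
    fl_assert(length(badhr) == 0, "fitloop_validation_error",
              "hr out of range (must be 0 or 20-250 bpm) at row %d",
              if (length(badhr)) badhr[1] else 0L)
  }
  invisible(f)
}

#' Duration of a monitor file in minutes
#'
#' Defined by the dialect as `nrow(samples) / (sample_rate * 60)`, exactly.
#'
#' @param f an `am_file`.
#' @return duration in minutes.
#' @export
duration_minutes <- function(f) {
  nrow(f$samples) / (f$sample_rate * 60)
}

#' @export
print.am_file <- function(x, ...) {
  cat(sprintf("<am_file> %s %s %s %s: %d samples (%.1f min at %d rows/s)\n",
              x$user_id, format(x$file_date), x$file_time, x$mode,
              nrow(x$samples), duration_minutes(x), x$sample_rate))
  invisible(x)
}

uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                  endian = "little")

read_uint32_le <- function(bytes) {
  readBin(bytes, integer(), n = length(bytes) %/% 4L, size = 4L,
          endian = "little")
}

#' Serialize a monitor file to AMB bytes
#'
#' @param f a valid `am_file`.
#' @param path optional; when given the bytes are also written to `path`.
#' @return raw vector, invisibly when `path` is given.
#' @export
write_am_file <- function(f, path = NULL) {
  validate_am_file(f)
  s <- f$samples
  n <- nrow(s)
  payload <- if (n == 0L) raw(0) else {
    m <- rbind(
      matrix(uint32_le(round(s$t_offset * 10)), nrow = 4L),
      matrix(writeBin(as.integer(round(s$ax * 1000)), raw(), size = 2L,
                      endian = "little"), nrow = 2L),
      matrix(writeBin(as.integer(round(s$ay * 1000)), raw(), size = 2L,
                      endian = "little"), nrow = 2L),
      matrix(writeBin(as.integer(round(s$az * 1000)), raw(), size = 2L,
                      endian = "little"), nrow = 2L),
      matrix(as.raw(s$hr), nrow = 1L)
    )
    as.vector(m)
  }
  user8 <- charToRaw(formatC(f$user_id, width = 8L, flag = "-"))
  header <- c(
    charToRaw("AMB1"),
    user8,
    uint32_le(as.integer(format(f$file_date, "%Y%m%d"))),
    uint32_le(as.integer(gsub(":", "", f$file_time))),
    as.raw(AM_MODES[[f$mode]]),
    as.raw(f$sample_rate),
    crc32_raw(payload),
    raw(6L)
  )
  out <- c(header, payload)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' Parse AMB bytes into a monitor file
#'
#' Inverse of [write_am_file()]: `write_am_file(read_am_file(x))` is
#' byte-identical to `x`. Truncated payloads, checksum mismatches and
#' out-of-range samples raise a parse error naming the offending row.
#'
#' @param x raw vector or path to an AMB file.
#' @param source_name original filename recorded in the result; defaults to
#'   the basename of `x` when `x` is a path.
#' @return an `am_file`.
#' @export
read_am_file <- function(x, source_name = NULL) {
  if (is.character(x)) {
    source_name <- source_name %||% basename(x)
    x <- readBin(x, raw(), n = file.size(x))
  }
  fl_assert(is.raw(x), "fitloop_parse_error", "input must be raw bytes or a path")
  fl_assert(length(x) >= AMB_HEADER_BYTES, "fitloop_parse_error",
            "truncated header: %d bytes", length(x))
  fl_assert(rawToChar(x[1:4]) == "AMB1", "fitloop_parse_error",
            "bad magic (not an AMB file)")
  user_id <- sub(" +$", "", rawToChar(x[5:12]))
  date_i <- read_uint32_le(x[13:16])
  time_i <- read_uint32_le(x[17:20])
  mode_code <- as.integer(x[21])
  fl_assert(mode_code %in% AM_MODES, "fitloop_parse_error",
            "unknown mode code %d", mode_code)
  mode <- names(AM_MODES)[match(mode_code, AM_MODES)]
  sample_rate <- as.integer(x[22])
  crc_stored <- x[23:26]
  payload <- if (length(x) > AMB_HEADER_BYTES) {
    x[(AMB_HEADER_BYTES + 1L):length(x)]
  } else raw(0)
  fl_assert(length(payload) %% AMB_ROW_BYTES == 0L, "fitloop_parse_error",
            "truncated payload: %d bytes is not a whole number of %d-byte rows",
            length(payload), AMB_ROW_BYTES)
  fl_assert(identical(crc32_raw(payload), crc_stored), "fitloop_parse_error",
            "payload checksum mismatch")
  n <- length(payload) %/% AMB_ROW_BYTES
  if (n > 0L) {
    m <- matrix(payload, nrow = AMB_ROW_BYTES)
    t_offset <- read_uint32_le(as.vector(m[1:4, ])) / 10
    rd16 <- function(rows) {
      readBin(as.vector(m[rows, ]), integer(), n = n, size = 2L,
              signed = TRUE, endian = "little")
    }
    samples <- data.frame(
      t_offset = t_offset,
      ax = rd16(5:6) / 1000,
      ay = rd16(7:8) / 1000,
      az = rd16(9:10) / 1000,
      hr = as.integer(m[11L, ])
    )
  } else {
    samples <- data.frame(t_offset = numeric(0), ax = numeric(0),
                          ay = numeric(0), az = numeric(0), hr = integer(0))
  }
  date <- as.Date(sprintf("%08d", date_i), format = "%Y%m%d")
  time <- sprintf("%02d:%02d:%02d", time_i %/% 10000L,
                  (time_i %/% 100L) %% 100L, time_i %% 100L)
  f <- tryCatch(
    am_file(user_id, date, time, mode, samples, sample_rate,
            source_name = source_name),
    fitloop_validation_error = function(e) {
      fl_stop("fitloop_parse_error", "invalid sample data: %s",
              conditionMessage(e))
    }
  )
  f
}

#' Construct a daily prescription record
#'
#' One day's dose: the session kind, the phase durations and the target
#' heart-rate zone limits the monitor enforces. Rest days carry zero
#' durations and no zone; the exercise field test (`eft`) is a fixed-duration
#' (default 12-minute) walk/run.
#'
#' @param date calendar date of the prescription.
#' @param kind one of "mandatory", "optional", "rest", "eft".
#' @param endurance_min endurance-phase minutes (0 for rest; 12 for eft).
#' @param zone_lo_bpm,zone_hi_bpm target-zone limits in bpm (0 for rest).
#' @param plan_week position in the progression table, 1--12.
#' @param warmup_min,cooldown_min phase durations (5 for activity kinds,
#'   0 for rest).
#' @return an object of class `prescription_record`.
#' @export
prescription_record <- function(date, kind, endurance_min, zone_lo_bpm,
                                zone_hi_bpm, plan_week,
                                warmup_min = if (kind == "rest") 0L else 5L,
                                cooldown_min = if (kind == "rest") 0L else 5L) {
  p <- structure(list(
    date = as.Date(date),
    kind = kind,
    warmup_min = as.integer(warmup_min),
    endurance_min = as.integer(endurance_min),
    cooldown_min = as.integer(cooldown_min),
    zone_lo_bpm = as.integer(zone_lo_bpm),
    zone_hi_bpm = as.integer(zone_hi_bpm),
    plan_week = as.integer(plan_week)
  ), class = "prescription_record")
  validate_prescription(p)
  p
}

validate_prescription <- function(p) {
  fl_assert(p$kind %in% names(RX_KINDS), "fitloop_validation_error",
            "unknown prescription kind '%s'", p$kind)
  fl_assert(p$plan_week >= 1 && p$plan_week <= 12, "fitloop_validation_error",
            "plan_week must be in 1..12")
  if (p$kind == "rest") {
    fl_assert(p$endurance_min == 0L, "fitloop_validation_error",
              "rest day must have endurance_min = 0")
  } else {
    fl_assert(p$endurance_min > 0L, "fitloop_validation_error",
              "activity day must have endurance_min > 0")
    fl_assert(p$zone_lo_bpm < p$zone_hi_bpm, "fitloop_validation_error",
              "zone_lo_bpm must be < zone_hi_bpm")
  }
  invisible(p)
}

#' @export
print.prescription_record <- function(x, ...) {
  cat(format_prescription(x), "\n")
  invisible(x)
}

format_prescription <- function(p) {
  if (p$kind == "rest") {
    sprintf("%s week %d: rest", format(p$date), p$plan_week)
  } else if (p$kind == "eft") {
    sprintf("%s week %d: EFT: %d-min run/walk, zone %d-%d bpm",
            format(p$date), p$plan_week, p$endurance_min,
            p$zone_lo_bpm, p$zone_hi_bpm)
  } else {
    sprintf("%s week %d: %s, %d min endurance, zone %d-%d bpm",
            format(p$date), p$plan_week, p$kind, p$endurance_min,
            p$zone_lo_bpm, p$zone_hi_bpm)
  }
}

#' Serialize / parse a prescription record
#'
#' Fixed-width 16-byte little-endian record with a CRC-8 over the data bytes;
#' the round trip is exact.
#'
#' @param p a `prescription_record`.
#' @param path optional output path.
#' @return raw vector of 16 bytes.
#' @export
write_prescription_file <- function(p, path = NULL) {
  validate_prescription(p)
  body <- c(
    uint32_le(as.integer(format(p$date, "%Y%m%d"))),
    as.raw(RX_KINDS[[p$kind]]),
    as.raw(p$warmup_min),
    writeBin(p$endurance_min, raw(), size = 2L, endian = "little"),
    as.raw(p$cooldown_min),
    as.raw(p$zone_lo_bpm),
    as.raw(p$zone_hi_bpm),
    as.raw(p$plan_week)
  )
  out <- c(body, crc8_raw(body), raw(3L))
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname write_prescription_file
#' @param x raw vector of 16 bytes or a path.
#' @export
read_prescription_file <- function(x) {
  if (is.character(x)) x <- readBin(x, raw(), n = file.size(x))
  fl_assert(length(x) == RX_BYTES, "fitloop_parse_error",
            "prescription record must be %d bytes, got %d", RX_BYTES, length(x))
  body <- x[1:12]
  fl_assert(identical(crc8_raw(body), x[13]), "fitloop_parse_error",
            "prescription record checksum mismatch")
  kind_code <- as.integer(x[5])
  fl_assert(kind_code %in% RX_KINDS, "fitloop_parse_error",
            "unknown prescription kind code %d", kind_code)
  prescription_record(
    date = as.Date(sprintf("%08d", read_uint32_le(x[1:4])), format = "%Y%m%d"),
    kind = names(RX_KINDS)[match(kind_code, RX_KINDS)],
    warmup_min = as.integer(x[6]),
    endurance_min = readBin(x[7:8], integer(), n = 1L, size = 2L,
                            signed = FALSE, endian = "little"),
    cooldown_min = as.integer(x[9]),
    zone_lo_bpm = as.integer(x[10]),
    zone_hi_bpm = as.integer(x[11]),
    plan_week = as.integer(x[12])
  )
}

#' Content fingerprint of a monitor file
#'
#' Digest used to eliminate repeated uploads; empty recordings (zero samples)
#' are flagged so they can be dropped. Identical content yields identical
#' fingerprints; changing any sample changes the digest.
#'
#' @param f an `am_file`.
#' @return object of class `am_fingerprint`: list with `digest` (hex string),
#'   `empty` (logical) and `n_samples`.
#' @export
file_fingerprint <- function(f) {
  payload <- serialize(list(
    f$user_id, format(f$file_date, "%Y%m%d"), f$file_time, f$mode,
    f$sample_rate, f$samples
  ), NULL, version = 2)
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  writeBin(payload, tf)
  structure(list(
    digest = unname(tools::md5sum(tf)),
    empty = nrow(f$samples) == 0L,
    n_samples = nrow(f$samples)
  ), class = "am_fingerprint")
}

#' @export
print.am_fingerprint <- function(x, ...) {
  cat(sprintf("<am_fingerprint> %s (%d samples%s)\n", x$digest, x$n_samples,
              if (x$empty) ", EMPTY" else ""))
  invisible(x)
}
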