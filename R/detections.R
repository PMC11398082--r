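# Canonical in-memory form: a tibble with one row per 3-s prediction segment.
# All timestamps are local standard time UTC-4 with no daylight-saving logic
# ("Etc/GMT+4" in the POSIX sign convention).

PAM_TZ <- "Etc/GMT+4"
SEGMENT_SECONDS <- 3

det_cols <- c("detection_id", "station_id", "recording_start",
              "segment_start", "segment_end",
              "scientific_name", "common_name", "confidence")

#' Assemble and validate a detection table
#'
#' A detection is one 3-second recognizer prediction: which station and
#' recording it came from, the segment offsets within that recording, the
#' species, and the confidence score in the open interval (0, 1). This
#' constructor normalizes a data frame into the canonical column set and
#' enforces the invariants every downstream stage assumes:
#' segment length exactly 3 s, confidence strictly inside (0, 1), and
#' (optionally) recording start times aligned with the duty-cycle schedule.
#'
#' Missing `detection_id`s are generated deterministically from
#' (station, recording start, segment start, species), so the same physical
#' prediction always gets the same id.
#'
#' @param x data frame with columns `station_id`, `recording_start`
#'   (POSIXct or "YYYY-MM-DD HH:MM:SS" text, local UTC-4), `segment_start`,
#'   `segment_end`, `scientific_name`, `common_name`, `confidence`
#'   (`detection_id` optional).
#' @param check_schedule if `TRUE`, require recording starts on the top of
#'   an hour (minute and second zero), the duty cycle used throughout.
#' @return a tibble of class `detections`.
#' @export
as_detections <- function(x, check_schedule = FALSE) {
  x <- tibble::as_tibble(x)
  need <- setdiff(det_cols, c("detection_id", names(x)))
  if (length(need)) abort(paste("missing detection columns:", paste(need, collapse = ", ")))
  if (is.character(x$recording_start)) {
    x$recording_start <- parse_local_time(x$recording_start)
  }
  if (!inherits(x$recording_start, "POSIXct")) abort("`recording_start` must be POSIXct or text.")
  attr(x$recording_start, "tzone") <- PAM_TZ
  bad_seg <- x$segment_end - x$segment_start != SEGMENT_SECONDS | x$segment_start < 0 |
    x$segment_start %% SEGMENT_SECONDS != 0
  if (any(bad_seg)) abort(sprintf("%d rows violate the 3-s segment invariant.", sum(bad_seg)))
  if (any(x$confidence <= 0 | x$confidence >= 1)) {
    abort("confidence must lie strictly inside (0, 1); reject or fix offending rows first.")
  }
  if (check_schedule) {
    lt <- as.POSIXlt(x$recording_start)
    if (any(lt$min != 0 | lt$sec != 0)) {
      abort("recording_start not aligned to the hourly schedule (minute/second not 00:00).")
    }
  }
  if (is.null(x[["detection_id"]])) x$detection_id <- make.unique(detection_id(x), sep = "#")
  structure(x[, det_cols], class = c("detections", class(tibble::tibble())))
}

#' Deterministic detection identifier
#'
#' Built from (station, recording start, segment offset, species, confidence
#' to 6 decimals), so the same physical prediction gets the same id whether
#' ids are generated in memory or regenerated after a file round trip.
#' Residual collisions are disambiguated positionally by [as_detections()].
#'
#' @param x detection table (id column ignored).
#' @return character vector `station|start-time|offset|species|confidence`.
#' @export
detection_id <- function(x) {
  sprintf("%s|%s|%04d|%s|%.6f", x$station_id, format_local_time(x$recording_start),
          as.integer(x$segment_start), gsub("\\s+", "_", x$scientific_name),
          x$confidence)
}

#' @export
print.detections <- function(x, ...) {
  cat("<detections> ", nrow(x), " predictions, ",
      length(unique(x$station_id)), " station(s), ",
      length(unique(x$scientific_name)), " species\n", sep = "")
  NextMethod()
}

format_local_time <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = PAM_TZ)

parse_local_time <- function(s) {
  t <- as.POSIXct(s, tz = PAM_TZ, format = "%Y-%m-%d %H:%M:%S")
  t
}

#' Recording-filename timestamp patterns
#'
#' Field recorders name files like `ST01_20150608_050000.wav`. A pattern is
#' a template over the tokens `STATION`, `YYYYMMDD` and `HHMMSS`; the
#' compiled pattern extracts the station id and the local recording start
#' from a file name, and formats them back when writing tables.
#'
#' @param template template string, default `"STATION_YYYYMMDD_HHMMSS"`.
#' @return object of class `filename_pattern` with `parse(filenames)` and
#'   `format(station_id, recording_start)` functions.
#' @examples
#' fp <- filename_pattern()
#' fp$parse("ST01_20150608_050000.wav")
#' @export
filename_pattern <- function(template = "STATION_YYYYMMDD_HHMMSS") {
  for (tok in c("STATION", "YYYYMMDD", "HHMMSS")) {
    if (!grepl(tok, template, fixed = TRUE)) abort(paste("template lacks token", tok))
  }
  rx <- gsub("([^A-Za-z0-9])", "\\\\\\1", template)
  rx <- sub("STATION", "([A-Za-z0-9-]+)", rx, fixed = TRUE)
  rx <- sub("YYYYMMDD", "([0-9]{8})", rx, fixed = TRUE)
  rx <- sub("HHMMSS", "([0-9]{6})", rx, fixed = TRUE)
  order_tok <- rank(c(STATION = regexpr("STATION", template, fixed = TRUE),
                      YYYYMMDD = regexpr("YYYYMMDD", template, fixed = TRUE),
                      HHMMSS = regexpr("HHMMSS", template, fixed = TRUE)))
  rx <- paste0("^", rx, "(\\.[A-Za-z0-9]+)?$")
  parse <- function(filenames) {
    base <- basename(filenames)
    m <- regmatches(base, regexec(rx, base))
    ok <- lengths(m) >= 4L
    station <- ts <- rep(NA_character_, length(base))
    get <- function(mi, tok) mi[1L + order_tok[[tok]]]
    station[ok] <- vapply(m[ok], get, "", tok = "STATION")
    ymd <- vapply(m[ok], get, "", tok = "YYYYMMDD")
    hms <- vapply(m[ok], get, "", tok = "HHMMSS")
    ts[ok] <- paste0(substr(ymd, 1, 4), "-", substr(ymd, 5, 6), "-", substr(ymd, 7, 8), " ",
                     substr(hms, 1, 2), ":", substr(hms, 3, 4), ":", substr(hms, 5, 6))
    tibble::tibble(filename = filenames, station_id = station,
                   recording_start = parse_local_time(ts), ok = ok & !is.na(parse_local_time(ts)))
  }
  fmt <- function(station_id, recording_start) {
    out <- template
    out <- sub("STATION", "%s", out, fixed = TRUE)
    out <- sub("YYYYMMDD", "%s", out, fixed = TRUE)
    out <- sub("HHMMSS", "%s", out, fixed = TRUE)
    args <- list(STATION = station_id,
                 YYYYMMDD = format(recording_start, "%Y%m%d", tz = PAM_TZ),
                 HHMMSS = format(recording_start, "%H%M%S", tz = PAM_TZ))
    args <- args[names(sort(order_tok))]
    paste0(do.call(sprintf, c(list(out), unname(args))), ".wav")
  }
  structure(list(template = template, regex = rx, parse = parse, format = fmt),
            class = "filename_pattern")
}
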