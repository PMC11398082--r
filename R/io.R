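# Readers and writers for the tabular formats the pipeline exchanges:
# recognizer detection tables (two dialects), verification manifests/labels,
# and plain-text key = value configs. All files are UTF-8.

birdnet_header <- c("File", "Start (s)", "End (s)",
                    "Scientific name", "Common name", "Confidence")
raven_header <- c("Selection", "View", "Channel", "Begin Time (s)", "End Time (s)",
                  "Low Freq (Hz)", "High Freq (Hz)", "Begin File",
                  "Scientific Name", "Common Name", "Confidence")

format_error <- function(msg) abort(msg, class = "pamthresh_format_error")

#' Read a recognizer detection table
#'
#' Supports two dialects of tab-separated selection tables:
#' `"birdnet_combined"` (one combined table: file, segment start/end seconds,
#' scientific and common name, confidence) and `"raven_selection"`
#' (Raven-style selection table with `Begin Time (s)` / `End Time (s)` and a
#' `Begin File` column). Station id and recording start time are recovered
#' from the recording file name via `pattern`.
#'
#' Rows whose confidence lies outside the open interval (0, 1) are rejected
#' (the recognizer never emits the boundaries; such rows indicate corrupt
#' input), and rows whose file name does not parse are collected and
#' surfaced with a warning — never silently dropped. Parse/reject counts are
#' attached as attributes `n_parsed` / `n_rejected`, the offending rows as
#' attribute `problems`.
#'
#' @param path file to read.
#' @param dialect `"birdnet_combined"` or `"raven_selection"`; `"auto"`
#'   (default) sniffs the header.
#' @param pattern a [filename_pattern()] extracting station and start time.
#' @return a [as_detections()] tibble.
#' @export
read_detection_table <- function(path, dialect = c("auto", "birdnet_combined", "raven_selection"),
                                 pattern = filename_pattern()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste("no such file:", path))
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (dialect == "auto") {
    dialect <- if (identical(hdr, birdnet_header)) "birdnet_combined"
      else if (identical(hdr, raven_header)) "raven_selection"
      else format_error(paste("unrecognized detection-table header in", path))
  }
  want <- switch(dialect, birdnet_combined = birdnet_header, raven_selection = raven_header)
  if (!identical(hdr, want)) {
    format_error(sprintf("header does not match dialect '%s' in %s", dialect, path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  x <- if (dialect == "birdnet_combined") {
    tibble::tibble(
      filename = raw[["File"]],
      segment_start = as.numeric(raw[["Start (s)"]]),
      segment_end = as.numeric(raw[["End (s)"]]),
      scientific_name = raw[["Scientific name"]],
      common_name = raw[["Common name"]],
      confidence = as.numeric(raw[["Confidence"]])
    )
  } else {
    tibble::tibble(
      filename = raw[["Begin File"]],
      segment_start = as.numeric(raw[["Begin Time (s)"]]),
      segment_end = as.numeric(raw[["End Time (s)"]]),
      scientific_name = raw[["Scientific Name"]],
      common_name = raw[["Common Name"]],
      confidence = as.numeric(raw[["Confidence"]])
    )
  }
  parsed <- pattern$parse(x$filename)
  x$station_id <- parsed$station_id
  x$recording_start <- parsed$recording_start
  bad_time <- !parsed$ok
  bad_conf <- is.na(x$confidence) | x$confidence <= 0 | x$confidence >= 1
  keep <- !(bad_time | bad_conf)
  problems <- tibble::tibble(
    row = which(!keep),
    reason = ifelse(bad_time[!keep], "unparseable filename/timestamp", "confidence outside (0,1)"),
    filename = x$filename[!keep]
  )
  if (nrow(problems)) {
    warn(sprintf("%d of %d rows rejected while reading %s (%s)",
                 nrow(problems), nrow(x), basename(path),
                 paste(unique(problems$reason), collapse = "; ")))
  }
  out <- as_detections(x[keep, setdiff(names(x), "filename")])
  attr(out, "n_parsed") <- sum(keep)
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "problems") <- problems
  out
}

#' Write a detection table
#'
#' Inverse of [read_detection_table()]: output is bit-stable for a fixed
#' input and dialect, and reading it back reproduces the detection
#' collection (numbers are written in shortest round-trip representation).
#' An empty collection writes a header-only file with a warning.
#'
#' @param detections a detection table.
#' @param path output file.
#' @param dialect which dialect to emit.
#' @param pattern a [filename_pattern()] used to rebuild recording file names.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(detections, path,
                                  dialect = c("birdnet_combined", "raven_selection"),
                                  pattern = filename_pattern()) {
  dialect <- match.arg(dialect)
  if (nrow(detections) == 0) warn("writing a header-only detection table (no rows)")
  fn <- if (nrow(detections)) pattern$format(detections$station_id, detections$recording_start)
        else character()
  out <- if (dialect == "birdnet_combined") {
    tibble::tibble(`File` = fn,
                   `Start (s)` = detections$segment_start,
                   `End (s)` = detections$segment_end,
                   `Scientific name` = detections$scientific_name,
                   `Common name` = detections$common_name,
                   `Confidence` = detections$confidence)
  } else {
    n <- nrow(detections)
    tibble::tibble(`Selection` = seq_len(n),
                   `View` = rep("Spectrogram 1", n), `Channel` = rep(1L, n),
                   `Begin Time (s)` = detections$segment_start,
                   `End Time (s)` = detections$segment_end,
                   `Low Freq (Hz)` = rep(0, n), `High Freq (Hz)` = rep(15000, n),
                   `Begin File` = fn,
                   `Scientific Name` = detections$scientific_name,
                   `Common Name` = detections$common_name,
                   `Confidence` = detections$confidence)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Verification manifests and label files
#'
#' The human-review step is offline: `write_manifest()` writes the sampled
#' predictions as a comma-separated manifest with an empty `correct` column
#' for the reviewer to fill in; `read_labels()` reads it back once labeled.
#'
#' `read_labels()` rejects duplicate detection ids (naming them), labels
#' whose id is unknown when a reference detection table is supplied, and
#' `correct` values that are not recognized boolean tokens under
#' `token_map` (defaults accept true/false, t/f, yes/no, y/n, 1/0,
#' correct/incorrect, case-insensitively).
#'
#' @param sampled detection table of sampled predictions (from
#'   [stratified_sample()]), with `bin_index` column.
#' @param path manifest file.
#' @param labels,detections label file and (optional) reference detections.
#' @param token_map named logical vector mapping accepted tokens to values.
#' @return `write_manifest()`: the path, invisibly. `read_labels()`: a
#'   tibble of class `verification_records` with `detection_id`, `correct`,
#'   `bin_index`, `confidence`, `reviewer`.
#' @export
write_manifest <- function(sampled, path) {
  if (is.null(sampled[["bin_index"]])) abort("`sampled` must carry a `bin_index` column.")
  out <- tibble::tibble(
    detection_id = sampled$detection_id,
    station_id = sampled$station_id,
    recording_start = format_local_time(sampled$recording_start),
    segment_start = sampled$segment_start,
    species = sampled$common_name,
    confidence = sampled$confidence,
    bin_index = sampled$bin_index,
    correct = "",
    reviewer = ""
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

default_token_map <- c("true" = TRUE, "t" = TRUE, "yes" = TRUE, "y" = TRUE,
                       "1" = TRUE, "correct" = TRUE,
                       "false" = FALSE, "f" = FALSE, "no" = FALSE, "n" = FALSE,
                       "0" = FALSE, "incorrect" = FALSE)

#' @rdname write_manifest
#' @export
read_labels <- function(labels, detections = NULL, token_map = default_token_map) {
  x <- readr::read_csv(labels, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  need <- setdiff(c("detection_id", "bin_index", "correct"), names(x))
  if (length(need)) format_error(paste("manifest lacks columns:", paste(need, collapse = ", ")))
  dup <- unique(x$detection_id[duplicated(x$detection_id)])
  if (length(dup)) {
    abort(paste("duplicate detection ids in label file:",
                paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(detections)) {
    unknown <- setdiff(x$detection_id, detections$detection_id)
    if (length(unknown)) {
      abort(paste("labels refer to unknown detection ids:",
                  paste(head(unknown, 5), collapse = ", ")))
    }
  }
  tok <- tolower(trimws(x$correct))
  bad <- !(tok %in% names(token_map))
  if (any(bad)) {
    abort(sprintf("unrecognized or missing `correct` tokens (%d rows), e.g. '%s'",
                  sum(bad), paste(head(unique(x$correct[bad]), 3), collapse = "', '")))
  }
  out <- tibble::tibble(
    detection_id = x$detection_id,
    correct = unname(token_map[tok]),
    bin_index = as.integer(x$bin_index),
    confidence = if (!is.null(x[["confidence"]])) as.numeric(x$confidence) else NA_real_,
    reviewer = if (!is.null(x[["reviewer"]])) x$reviewer else NA_character_
  )
  if (!is.null(detections) && anyNA(out$confidence)) {
    out$confidence <- detections$confidence[match(out$detection_id, detections$detection_id)]
  }
  structure(out, class = c("verification_records", class(tibble::tibble())))
}

#' Plain-text key = value configs
#'
#' One `key = value` pair per line; `#` starts a comment. Values are coerced
#' to numeric or logical where they parse as such; comma-separated values
#' become vectors.
#'
#' @param path file to read or write.
#' @param config named list to write.
#' @return `read_config()`: a named list. `write_config()`: the path.
#' @export
read_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(kv) != 3)) format_error(paste("malformed config line in", path))
  out <- lapply(kv, function(m) {
    vals <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) num
    else if (all(toupper(vals) %in% c("TRUE", "FALSE"))) as.logical(toupper(vals))
    else vals
  })
  names(out) <- trimws(vapply(kv, `[`, "", 2))
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", paste(format(v, scientific = FALSE, trim = TRUE), collapse = ", "))
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
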