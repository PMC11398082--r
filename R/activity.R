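# Diel (hour-of-day) and annual (month) vocal-activity profiles from
# threshold-filtered detections. A detection's hour is the hour of its
# recording window's start: windows cover only the first minutes of each
# hour, so segment offsets never cross an hour boundary. Months are labeled
# by calendar month, pooling the two partial years of a mid-year-to-mid-year
# deployment into one 12-bar axis running June through May.

month_axis_levels <- function(start_month = 6) {
  month.abb[((start_month - 1 + 0:11) %% 12) + 1]
}

#' Filter detections by a calibrated confidence threshold
#'
#' Keeps detections whose confidence is at or above the calibrated
#' threshold (ties at the threshold are retained; configurable). Refuses to
#' filter on a threshold whose status is not `valid` — downstream activity
#' description is meaningless when no trustworthy threshold exists — and
#' reports retained/discarded counts as attributes and a message.
#'
#' @param detections detection table.
#' @param threshold a [threshold_for_probability()] result, or a bare
#'   numeric confidence cutoff.
#' @param inclusive keep ties at the threshold (default `TRUE`).
#' @param quiet suppress the retention message.
#' @return filtered detection table with attributes `n_retained`,
#'   `n_discarded`, `threshold_used`.
#' @export
filter_by_threshold <- function(detections, threshold, inclusive = TRUE, quiet = FALSE) {
  if (inherits(threshold, "threshold_result")) {
    if (threshold$status != "valid") {
      abort(sprintf(
        "cannot filter: threshold status is '%s' (see ?threshold_for_probability)",
        threshold$status), class = "pamthresh_invalid_threshold")
    }
    cut <- threshold$confidence_threshold
  } else {
    cut <- as.numeric(threshold)
  }
  keep <- if (inclusive) detections$confidence >= cut else detections$confidence > cut
  out <- detections[keep, ]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "threshold_used") <- cut
  if (!quiet) {
    inform(sprintf("threshold %.3f: retained %d of %d detections",
                   cut, sum(keep), length(keep)))
  }
  out
}

new_activity_profile <- function(df, axis, species, threshold_used, note = NULL) {
  structure(df, axis = axis, species = species, threshold_used = threshold_used,
            note = note, class = c("activity_profile", class(tibble::tibble())))
}

build_profile <- function(filtered, cell, levels, axis,
                          pooling = c("both", "pooled", "per_station")) {
  pooling <- match.arg(pooling)
  if (nrow(filtered) == 0) abort("empty detection set: no activity profile to build.")
  cell <- factor(cell, levels = levels)
  series <- list()
  if (pooling %in% c("pooled", "both")) {
    cnt <- as.integer(table(cell))
    series$pooled <- tibble::tibble(series = "pooled", cell = levels, count = cnt)
  }
  if (pooling %in% c("per_station", "both")) {
    for (st in sort(unique(filtered$station_id))) {
      cnt <- as.integer(table(cell[filtered$station_id == st]))
      series[[st]] <- tibble::tibble(series = st, cell = levels, count = cnt)
    }
  }
  df <- dplyr::bind_rows(series)
  df <- dplyr::group_by(df, .data$series)
  df <- dplyr::mutate(df, percentage = 100 * .data$count / sum(.data$count))
  df <- dplyr::ungroup(df)
  sp <- sort(unique(filtered$common_name))
  new_activity_profile(df, axis = axis,
                       species = if (length(sp) == 1) sp else paste(sp, collapse = "+"),
                       threshold_used = attr(filtered, "threshold_used"))
}

#' Diel (hour-of-day) activity profile
#'
#' Counts and percentage shares of filtered detections by local hour 0–23,
#' pooled across stations and/or per station.
#'
#' @param filtered threshold-filtered detection table.
#' @param pooling `"both"` (default), `"pooled"` or `"per_station"`.
#' @return tibble of class `activity_profile` (`series`, `cell`, `count`,
#'   `percentage`); per-series percentages sum to 100.
#' @export
diel_profile <- function(filtered, pooling = c("both", "pooled", "per_station")) {
  hour <- as.POSIXlt(filtered$recording_start)$hour
  build_profile(filtered, sprintf("%02d", hour), sprintf("%02d", 0:23),
                axis = "hour_of_day", pooling = pooling)
}

#' Annual (monthly) activity profile
#'
#' As [diel_profile()], but by calendar month on the study-ordered axis
#' (June through May). The first and last months of a mid-year deployment
#' are only partly covered; their counts are reported as-is and the profile
#' carries a truncation note naming them.
#'
#' @inheritParams diel_profile
#' @param start_month first month of the axis (default 6 = June).
#' @export
annual_profile <- function(filtered, pooling = c("both", "pooled", "per_station"),
                           start_month = 6) {
  lt <- as.POSIXlt(filtered$recording_start)
  mon <- month.abb[lt$mon + 1L]
  prof <- build_profile(filtered, mon, month_axis_levels(start_month),
                        axis = "month", pooling = pooling)
  d <- as.Date(filtered$recording_start, tz = PAM_TZ)
  rng <- range(d)
  note <- NULL
  if (format(rng[1], "%d") != "01") {
    note <- c(note, sprintf("first month truncated: coverage starts %s", rng[1]))
  }
  month_end <- seq(as.Date(format(rng[2], "%Y-%m-01")), by = "month", length.out = 2)[2] - 1
  if (rng[2] < month_end) {
    note <- c(note, sprintf("last month truncated: coverage ends %s", rng[2]))
  }
  attr(prof, "note") <- note
  prof
}

#' @export
print.activity_profile <- function(x, ...) {
  cat("<activity_profile>", attr(x, "axis"), "|", attr(x, "species"))
  if (!is.null(attr(x, "threshold_used"))) {
    cat(sprintf(" | threshold %.3f", attr(x, "threshold_used")))
  }
  cat("\n")
  for (nt in attr(x, "note")) cat("  note:", nt, "\n")
  NextMethod()
}

#' Share of activity in a subset of axis cells
#'
#' Percentage of the pooled (or only) series' detections that fall in the
#' named cells: `100 * sum(count in cells) / total`. Used, e.g., for the
#' share of vocalizations in the March–June singing peak or in the three
#' hours after sunrise.
#'
#' @param profile an `activity_profile`.
#' @param cells axis-cell labels (e.g. `c("Mar","Apr","May","Jun")` or
#'   `c("06","07","08")`).
#' @param series which series to use (default `"pooled"`, falling back to
#'   the single available series).
#' @return percentage (numeric scalar).
#' @export
window_share <- function(profile, cells, series = "pooled") {
  if (!length(cells)) abort("`cells` must be non-empty.")
  av <- unique(profile$series)
  if (!series %in% av) {
    if (length(av) == 1) series <- av else abort(paste("no such series:", series))
  }
  p <- profile[profile$series == series, ]
  unknown <- setdiff(cells, p$cell)
  if (length(unknown)) abort(paste("unknown cell labels:", paste(unknown, collapse = ", ")))
  100 * sum(p$count[p$cell %in% cells]) / sum(p$count)
}

#' Activity profile from transcribed count tables
#'
#' Builds an `activity_profile` from per-cell counts (e.g. a published or
#' exported per-station table) instead of row-level detections, so
#' [window_share()] can be applied to transcribed summaries. Station columns
#' are summed into the pooled series.
#'
#' @param counts data frame: `cell` column plus one count column per series
#'   (stations); a `pooled` column is computed if absent.
#' @param axis `"hour_of_day"` or `"month"`.
#' @param species label.
#' @param threshold_used confidence threshold the counts were filtered at,
#'   if known.
#' @return an `activity_profile`.
#' @export
activity_profile_from_counts <- function(counts, axis = c("month", "hour_of_day"),
                                         species = NA_character_, threshold_used = NULL) {
  axis <- match.arg(axis)
  counts <- tibble::as_tibble(counts)
  if (!"cell" %in% names(counts)) abort("`counts` needs a `cell` column.")
  sc <- setdiff(names(counts), "cell")
  if (!length(sc)) abort("`counts` needs at least one count column.")
  if (!"pooled" %in% sc) {
    counts$pooled <- rowSums(counts[, sc, drop = FALSE])
  }
  long <- tidyr::pivot_longer(counts, -"cell", names_to = "series", values_to = "count")
  long <- dplyr::group_by(long, .data$series)
  long <- dplyr::mutate(long, percentage = 100 * .data$count / sum(.data$count))
  long <- dplyr::ungroup(long)
  long <- long[, c("series", "cell", "count", "percentage")]
  new_activity_profile(long, axis = axis, species = species, threshold_used = threshold_used)
}

#' Export per-station activity counts as tab-separated text
#'
#' One row per axis cell, one column per station plus the pooled total,
#' with a header line recording the species and the confidence threshold
#' applied (so tables are never ambiguous about whether counts are
#' filtered).
#'
#' @param profile an `activity_profile` built with per-station series.
#' @param path output file.
#' @export
write_activity_table <- function(profile, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(profile)[, c("series", "cell", "count")],
                             names_from = "series", values_from = "count")
  thr <- attr(profile, "threshold_used")
  hdr <- sprintf("# species: %s | axis: %s | confidence threshold: %s",
                 attr(profile, "species"), attr(profile, "axis"),
                 if (is.null(thr)) "none (unfiltered)" else format(thr))
  readr::write_lines(hdr, path)
  readr::write_tsv(wide, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Plot an activity profile
#'
#' Percentage share per axis cell, one line per series; dawn and dusk marked
#' at 06:00 and 18:00 on the diel axis. Requires ggplot2.
#'
#' @param profile an `activity_profile`.
#' @return a ggplot object.
#' @export
plot_activity <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) abort("ggplot2 is not installed.")
  df <- tibble::as_tibble(profile)
  df$cell <- factor(df$cell, levels = unique(profile$cell))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$percentage,
                                        group = .data$series, colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(profile, "axis"), y = "% of detections",
                  title = attr(profile, "species")) +
    ggplot2::theme_minimal()
  if (attr(profile, "axis") == "hour_of_day") {
    g <- g + ggplot2::geom_vline(xintercept = c("06", "18"), linetype = "dashed",
                                 colour = "grey50")
  }
  g
}
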