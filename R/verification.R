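# Stratified verification sampling and precision-by-class estimation.
# Precision is the fraction of reviewed predictions that are true detections
# of the target species; it is estimated per confidence class from a
# stratified sample (a fixed number of predictions per fine 0.1-wide bin)
# because raw recognizer output is dominated by low-score predictions.

#' Stratified sample of predictions for human review
#'
#' Draws `per_bin` predictions uniformly without replacement from each fine
#' confidence bin of `scheme` (the classical design: 50 per 0.1-wide class,
#' 450 in total over nine bins). If a bin holds fewer than `per_bin`
#' candidates, all of it is taken and a shortfall warning is attached.
#' Reproducible from `seed`.
#'
#' @param detections detection table.
#' @param scheme a [bin_scheme()].
#' @param per_bin predictions to draw per fine bin (default 50).
#' @param seed integer seed.
#' @return the sampled rows with a `bin_index` column, ordered by bin;
#'   shortfalls (if any) in attribute `shortfall`.
#' @export
stratified_sample <- function(detections, scheme = bin_scheme(), per_bin = 50, seed = 1L) {
  if (nrow(detections) == 0) abort("cannot sample from an empty detection set.")
  if (per_bin < 1) abort("`per_bin` must be at least 1.")
  bin <- bin_index(detections$confidence, scheme)
  if (anyNA(bin)) abort("some confidences fall outside the bin scheme's range.")
  run_with_seed(seed, {
    picks <- lapply(seq_len(n_fine_bins(scheme)), function(b) {
      cand <- which(bin == b)
      if (length(cand) <= per_bin) cand else cand[sample.int(length(cand), per_bin)]
    })
    n_got <- lengths(picks)
    out <- detections[unlist(picks), ]
    out$bin_index <- rep.int(seq_along(picks), n_got)
    short <- which(n_got < per_bin)
    if (length(short)) {
      warn(sprintf("bin shortfall: bin(s) %s hold fewer than %d candidates",
                   paste(short, collapse = ", "), per_bin))
      attr(out, "shortfall") <- tibble::tibble(bin_index = short, n_available = n_got[short])
    }
    out
  })
}

new_precision_table <- function(df, scheme, species = NA_character_) {
  structure(df, scheme = scheme, species = species,
            class = c("precision_table", class(tibble::tibble())))
}

#' Precision by confidence class
#'
#' Aggregates verified labels into the scheme's reported classes plus the
#' full range: number verified, number correct, and precision in percent
#' (`100 * n_correct / n_verified`, kept at full precision; round only for
#' display). A class with no labels is reported as undefined (`NA`), not
#' zero. Wilson 95% score intervals are available as optional columns.
#'
#' @param labels a `verification_records` tibble (see [read_labels()]) or
#'   any data frame with `bin_index` and logical `correct`.
#' @param scheme a [bin_scheme()].
#' @param wilson add Wilson 95% interval bounds (default off).
#' @param species optional species label carried into the table.
#' @return tibble of class `precision_table` with one row per reported
#'   class and a final `"0.1-1"`-style full-range row.
#' @export
precision_table <- function(labels, scheme = bin_scheme(), wilson = FALSE,
                            species = NA_character_) {
  if (!all(c("bin_index", "correct") %in% names(labels))) {
    abort("`labels` needs `bin_index` and `correct` columns.")
  }
  if (anyNA(labels$correct)) abort("all labels must carry a correct/incorrect value.")
  nb <- n_fine_bins(scheme)
  if (any(labels$bin_index < 1 | labels$bin_index > nb)) abort("invalid `bin_index` values.")
  cls <- names(scheme$report_classes)
  rows <- lapply(cls, function(lab) {
    in_cls <- labels$bin_index %in% scheme$report_classes[[lab]]
    tibble::tibble(class = lab, n_verified = sum(in_cls),
                   n_correct = sum(labels$correct[in_cls]))
  })
  df <- dplyr::bind_rows(rows)
  full <- tibble::tibble(
    class = sprintf("%s-%s", format(scheme$fine_edges[1]),
                    format(scheme$fine_edges[length(scheme$fine_edges)])),
    n_verified = nrow(labels), n_correct = sum(labels$correct))
  df <- dplyr::bind_rows(df, full)
  df$precision <- ifelse(df$n_verified > 0, 100 * df$n_correct / df$n_verified, NA_real_)
  if (wilson) {
    ci <- wilson_interval(df$n_correct, df$n_verified)
    df$ci_low <- 100 * ci$low
    df$ci_high <- 100 * ci$high
  }
  new_precision_table(df, scheme, species)
}

#' Precision table from published class counts
#'
#' Builds a [precision_table()] directly from per-class verified/correct
#' counts (e.g. transcribed from a printed report) instead of row-level
#' labels.
#'
#' @param class character vector of class labels matching `scheme`.
#' @param n_verified,n_correct integer counts per class.
#' @inheritParams precision_table
#' @export
precision_from_counts <- function(class, n_verified, n_correct,
                                  scheme = bin_scheme(), species = NA_character_) {
  if (!identical(as.character(class), names(scheme$report_classes))) {
    abort("`class` must match the scheme's reported classes, in order.")
  }
  if (any(n_correct < 0 | n_correct > n_verified)) abort("need 0 <= n_correct <= n_verified.")
  df <- tibble::tibble(class = as.character(class),
                       n_verified = as.integer(n_verified),
                       n_correct = as.integer(n_correct))
  full <- tibble::tibble(
    class = sprintf("%s-%s", format(scheme$fine_edges[1]),
                    format(scheme$fine_edges[length(scheme$fine_edges)])),
    n_verified = sum(df$n_verified), n_correct = sum(df$n_correct))
  df <- dplyr::bind_rows(df, full)
  df$precision <- 100 * df$n_correct / df$n_verified
  new_precision_table(df, scheme, species)
}

wilson_interval <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(low = pmax(0, ctr - half), high = pmin(1, ctr + half))
}

#' @export
print.precision_table <- function(x, digits = 1, ...) {
  sp <- attr(x, "species")
  cat("<precision_table>", if (!is.na(sp)) sp else "", "\n")
  y <- as.data.frame(x)
  y$precision <- sprintf(paste0("%.", digits, "f%%"), y$precision)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Count-pooled precision across tables and classes
#'
#' Pools raw counts — `100 * sum(n_correct) / sum(n_verified)` over the
#' selected classes of the selected tables — rather than averaging
#' percentages, so classes with more verified predictions weigh more. With
#' one table and all classes this equals that table's full-range precision.
#'
#' @param tables a `precision_table` or list of them sharing a bin scheme.
#' @param classes class labels to pool over; default all reported classes.
#' @return pooled precision in percent, with the pooled counts as
#'   attributes `n_correct` / `n_verified`.
#' @export
pooled_precision <- function(tables, classes = NULL) {
  if (inherits(tables, "precision_table")) tables <- list(tables)
  if (!length(tables)) abort("no tables supplied.")
  all_cls <- names(attr(tables[[1]], "scheme")$report_classes)
  for (t in tables) {
    if (!identical(names(attr(t, "scheme")$report_classes), all_cls)) {
      abort("tables do not share a bin scheme.")
    }
  }
  if (is.null(classes)) classes <- all_cls
  if (!length(classes) || !all(classes %in% all_cls)) {
    abort("`classes` must be a non-empty subset of the reported classes.")
  }
  nc <- nv <- 0L
  for (t in tables) {
    sel <- t$class %in% classes
    nc <- nc + sum(t$n_correct[sel])
    nv <- nv + sum(t$n_verified[sel])
  }
  if (nv == 0) abort("no verified predictions in the selected classes.")
  structure(100 * nc / nv, n_correct = nc, n_verified = nv)
}

#' Write a precision table as tab-separated text
#'
#' Two rows per table (correct counts and display-rounded precision per
#' class plus the full range), mirroring the layout such results are
#' printed in.
#'
#' @param table a `precision_table`.
#' @param path output file.
#' @export
write_precision_table <- function(table, path) {
  out <- tibble::tibble(
    Predictions = c("Correct", "Precision"),
    !!!stats::setNames(
      lapply(seq_len(nrow(table)), function(i) {
        c(as.character(table$n_correct[i]), sprintf("%.1f%%", table$precision[i]))
      }),
      table$class)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
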