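#' Confidence-score bin schemes
#'
#' Verification sampling stratifies predictions into fine 0.1-wide confidence
#' classes; precision is reported over coarser classes that group the fine
#' bins. `bin_scheme()` builds such a scheme: `fine_edges` are the cut points
#' of the fine bins (left-closed, right-open, except the last bin which is
#' closed on the right so a score equal to the top edge still bins), and
#' `report_classes` is a named list mapping each reported class label to the
#' fine-bin indices it aggregates.
#'
#' The default reproduces the survey design this package targets: nine fine
#' bins 0.1–0.2, ..., 0.9–1.0 and four reported classes 0.1–0.3, 0.3–0.5,
#' 0.5–0.7 and >0.7 (the last aggregating three fine bins, hence 150 verified
#' predictions there when 50 are drawn per fine bin).
#'
#' @param fine_edges strictly increasing numeric cut points in \[0, 1\].
#' @param report_classes named list of integer vectors; must partition
#'   `1:(length(fine_edges) - 1)` in order.
#' @return an object of class `bin_scheme`.
#' @examples
#' sc <- bin_scheme()
#' bin_index(c(0.1, 0.15, 0.95, 1), sc)
#' @export
bin_scheme <- function(fine_edges = seq(0.1, 1, by = 0.1),
                       report_classes = list(
                         "0.1-0.3" = 1:2,
                         "0.3-0.5" = 3:4,
                         "0.5-0.7" = 5:6,
                         ">0.7"    = 7:9
                       )) {
  if (length(fine_edges) < 2 || any(diff(fine_edges) <= 0)) {
    abort("`fine_edges` must be strictly increasing with at least two values.")
  }
  n_bins <- length(fine_edges) - 1L
  idx <- unlist(report_classes, use.names = FALSE)
  if (!identical(sort(as.integer(idx)), seq_len(n_bins)) ||
      is.null(names(report_classes)) || any(names(report_classes) == "")) {
    abort("`report_classes` must be a named list partitioning the fine bins.")
  }
  structure(
    list(fine_edges = as.numeric(fine_edges),
         report_classes = lapply(report_classes, as.integer)),
    class = "bin_scheme"
  )
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat("<bin_scheme>", length(x$fine_edges) - 1L, "fine bins on [",
      x$fine_edges[1], ",", x$fine_edges[length(x$fine_edges)], "]\n")
  cat("  classes:", paste(names(x$report_classes), collapse = ", "), "\n")
  invisible(x)
}

#' Fine-bin index of a confidence score
#'
#' @param confidence numeric vector of scores.
#' @param scheme a [bin_scheme()].
#' @return integer vector of fine-bin indices (1-based); scores outside the
#'   scheme's range give `NA`.
#' @export
bin_index <- function(confidence, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  edges <- scheme$fine_edges
  idx <- findInterval(confidence, edges, rightmost.closed = TRUE)
  idx[confidence < edges[1] | confidence > edges[length(edges)]] <- NA_integer_
  as.integer(idx)
}

#' Reported class label of a fine bin
#'
#' @param bin integer vector of fine-bin indices.
#' @param scheme a [bin_scheme()].
#' @return character vector of class labels (`NA` for unknown bins).
#' @export
report_class <- function(bin, scheme = bin_scheme()) {
  map <- rep(NA_character_, length(scheme$fine_edges) - 1L)
  for (lab in names(scheme$report_classes)) map[scheme$report_classes[[lab]]] <- lab
  map[bin]
}

n_fine_bins <- function(scheme) length(scheme$fine_edges) - 1L
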