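test_that("threshold filtering is inclusive at the boundary and refuses invalid status", {
  det <- make_detections(3, confidence = c(0.85, 0.90, 0.95))
  out <- filter_by_threshold(det, 0.9, quiet = TRUE)
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_discarded"), 1L)
  # exclusive comparison is available
  expect_identical(nrow(filter_by_threshold(det, 0.9, inclusive = FALSE, quiet = TRUE)), 1L)
  # threshold at the data minimum is the identity
  expect_identical(nrow(filter_by_threshold(det, min(det$confidence), quiet = TRUE)), 3L)

  bad <- structure(list(status = "invalid_unattainable", confidence_threshold = NA_real_),
                   class = "threshold_result")
  expect_error(filter_by_threshold(det, bad), class = "pamthresh_invalid_threshold")
})

test_that("retained count is non-increasing in the threshold (property)", {
  set.seed(12)
  det <- make_detections(500, confidence = runif(500, 0.1, 0.999))
  kept <- vapply(seq(0.1, 0.95, by = 0.05),
                 function(th) nrow(filter_by_threshold(det, th, quiet = TRUE)), 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("diel profiles report counts and percentages per series", {
  hours <- c(rep(6, 4), rep(18, 4), rep(12, 2))
  det <- as_detections(tibble::tibble(
    station_id = rep(c("ST01", "ST02"), 5),
    recording_start = sprintf("2015-07-01 %02d:00:00", hours),
    segment_start = 0, segment_end = 3,
    scientific_name = "s", common_name = "s",
    confidence = 0.8))
  prof <- diel_profile(det)
  pooled <- prof[prof$series == "pooled", ]
  expect_equal(pooled$percentage[match(c("06", "18", "12"), pooled$cell)], c(40, 40, 20))
  expect_equal(sum(pooled$count), 10)
  # per-station counts sum to pooled counts cell-wise
  st <- prof[prof$series != "pooled", ]
  by_cell <- tapply(st$count, st$cell, sum)
  expect_equal(as.integer(by_cell[pooled$cell]), pooled$count)
  # percentages sum to 100 per series
  sums <- tapply(prof$percentage, prof$series, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_error(diel_profile(det[0, ]), "empty")
})

test_that("annual profiles use the study-ordered month axis and note truncation", {
  det <- make_detections(50)
  det$recording_start <- as.POSIXct("2015-06-08 06:00:00", tz = "Etc/GMT+4") +
    (0:49) * 7 * 86400   # weekly through May 2016
  prof <- annual_profile(det)
  pooled <- prof[prof$series == "pooled", ]
  expect_identical(pooled$cell, c("Jun", "Jul", "Aug", "Sep", "Oct", "Nov",
                                  "Dec", "Jan", "Feb", "Mar", "Apr", "May"))
  expect_match(paste(attr(prof, "note"), collapse = "; "), "first month truncated")

  only_march <- det[format(det$recording_start, "%m") == "03", ]
  p2 <- annual_profile(only_march)
  pm <- p2[p2$series == "pooled", ]
  expect_equal(pm$percentage[pm$cell == "Mar"], 100)
})

test_that("profiles are invariant under row permutation (property)", {
  set.seed(13)
  sim <- generate_detections(study_preset(0.02), seed = 3)
  det <- sim$detections
  shuf <- det[sample(nrow(det)), ]
  expect_equal(tibble::as_tibble(diel_profile(det)), tibble::as_tibble(diel_profile(shuf)))
  expect_equal(tibble::as_tibble(annual_profile(det)), tibble::as_tibble(annual_profile(shuf)))
})

test_that("window_share computes subset percentages and validates cells", {
  tabs <- synthetic_activity_tables("month")
  prof <- tabs[[1]]
  expect_equal(window_share(prof, prof$cell[prof$series == "pooled"]), 100)
  expect_error(window_share(prof, "Movember"), "unknown cell")
  expect_error(window_share(prof, character()), "non-empty")
  # conservation: hour totals equal month totals for the same detections
  sim <- generate_detections(study_preset(0.02), seed = 3)
  d <- diel_profile(sim$detections, "pooled")
  m <- annual_profile(sim$detections, "pooled")
  expect_identical(sum(d$count), sum(m$count))
  expect_identical(sum(d$count), nrow(sim$detections))
})

test_that("dawn-heavy preset concentrates the diel profile as constructed", {
  sim <- emulate_study(seed = 2, scale = 0.1)
  keep <- sim$truth$correct   # activity description targets true vocalizations
  det <- sim$detections[keep & sim$detections$scientific_name == "Simulavis praerupta", ]
  prof <- diel_profile(det, "pooled")
  expect_gt(window_share(prof, c("06", "07", "08")), 50)
  mode_hour <- prof$cell[which.max(prof$count)]
  expect_identical(mode_hour, "07")
  ann <- annual_profile(det, "pooled")
  mar_jun <- window_share(ann, c("Mar", "Apr", "May", "Jun"))
  expect_gt(mar_jun, window_share(ann, c("Jul", "Aug", "Sep", "Oct")))
  expect_identical(ann$cell[which.max(ann$count)] %in% c("Mar", "Apr", "May", "Jun"), TRUE)
})

test_that("activity tables export with threshold labeling and re-import", {
  sim <- generate_detections(study_preset(0.02), seed = 3)
  filt <- filter_by_threshold(sim$detections, 0.4, quiet = TRUE)
  prof <- diel_profile(filt)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_activity_table(prof, path)
  lines <- readLines(path)
  expect_match(lines[1], "confidence threshold: 0.4")
  wide <- readr::read_tsv(path, skip = 1, show_col_types = FALSE)
  expect_identical(nrow(wide), 24L)
  back <- activity_profile_from_counts(wide[, c("cell", paste0("ST0", 1:5))],
                                       axis = "hour_of_day")
  pooled_back <- back[back$series == "pooled", ]
  pooled_orig <- prof[prof$series == "pooled", ]
  expect_equal(pooled_back$count, as.double(pooled_orig$count))
})
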