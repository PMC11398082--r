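# Synthetic detection generator. Emulates the recording design the analysis
# assumes — several stations recording the first 15 min of every hour over a
# year — and a recognizer whose per-segment correctness follows a (optionally
# plateaued) logistic law in the logit-scale confidence score. This is the
# exact generative structure the calibration module fits, which is what makes
# sharp parameter-recovery tests possible.

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of one simulated species
#'
#' @param scientific_name,common_name species labels.
#' @param alpha_true,beta_true intercept and slope of the correctness law on
#'   the logit scale: `P(correct | c) = pi_max * plogis(alpha + beta * logit(c))`.
#' @param pi_max asymptotic maximum correctness probability in (0, 1\];
#'   values below the target probability make a valid threshold unattainable,
#'   the failure mode seen for species the recognizer confuses even at high
#'   scores.
#' @param confidence_shape two positive Beta shape parameters; scores are
#'   drawn Beta(shape1, shape2) and rescaled into \[0.1, 1), the range a
#'   recognizer run at minimum confidence 0.1 emits.
#' @param mean_detections_per_window expected detections per 15-min
#'   recording window before diel/seasonal modulation.
#' @return named list of class `species_params`.
#' @export
species_params <- function(scientific_name, common_name,
                           alpha_true, beta_true, pi_max = 1,
                           confidence_shape = c(0.9, 2.2),
                           mean_detections_per_window = 0.3) {
  if (pi_max <= 0 || pi_max > 1) abort("`pi_max` must lie in (0, 1].")
  if (length(confidence_shape) != 2 || !all(is.finite(confidence_shape)) ||
      any(confidence_shape <= 0)) {
    abort("degenerate confidence-score distribution: need two finite positive shapes.")
  }
  structure(list(scientific_name = scientific_name, common_name = common_name,
                 alpha_true = alpha_true, beta_true = beta_true, pi_max = pi_max,
                 confidence_shape = as.numeric(confidence_shape),
                 mean_detections_per_window = mean_detections_per_window),
            class = "species_params")
}

#' Two-peak diel weight profile
#'
#' Hourly activity weights with Gaussian peaks at dawn and dusk over a
#' nocturnal floor, normalized to mean 1. Presets fix sunrise at 06:00 and
#' sunset at 18:00 local time.
#'
#' @param dawn_hour,dusk_hour peak hours (0–23).
#' @param dawn_width,dusk_width peak widths in hours.
#' @param dusk_ratio dusk:dawn peak height ratio.
#' @param floor nocturnal baseline weight.
#' @return numeric vector of 24 non-negative weights (hours 0–23), mean 1.
#' @export
diel_weights <- function(dawn_hour = 6, dusk_hour = 18,
                         dawn_width = 1.5, dusk_width = 2,
                         dusk_ratio = 0.4, floor = 0.05) {
  h <- 0:23
  w <- floor +
    exp(-0.5 * ((h - dawn_hour) / dawn_width)^2) +
    dusk_ratio * exp(-0.5 * ((h - dusk_hour) / dusk_width)^2)
  if (all(w <= 0)) abort("diel profile must have at least one positive weight.")
  w / mean(w)
}

#' Simulation configuration
#'
#' The defaults state the monitoring design the package emulates: 5 stations
#' recording the first 15 minutes of each hour, 24 h/day, 8 June 2015
#' through 31 May 2016 (359 days), in local standard time UTC-4.
#'
#' @param n_stations number of recording stations.
#' @param start_date,end_date first and last recording days (`Date` or text).
#' @param minutes_per_hour_recorded duty cycle within each hour.
#' @param species list of [species_params()].
#' @param diel 24 hourly weights, e.g. from [diel_weights()].
#' @param month_multipliers 12 non-negative seasonal weights (Jan–Dec);
#'   normalized to mean 1 internally.
#' @param fp_time_profile temporal distribution of incorrect detections:
#'   `"uniform"` spreads them evenly over the schedule, `"same_as_tp"` gives
#'   them the same diel/seasonal profile as correct ones.
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_stations = 5,
                       start_date = "2015-06-08", end_date = "2016-05-31",
                       minutes_per_hour_recorded = 15,
                       species = list(species_params("Simulavis alpha", "Simulated Wren A",
                                                     alpha_true = 1.57, beta_true = 1.5)),
                       diel = diel_weights(),
                       month_multipliers = c(0.8, 0.8, 1.5, 1.7, 1.7, 1.4,
                                             0.8, 0.7, 0.7, 0.8, 0.9, 1.4),
                       fp_time_profile = c("uniform", "same_as_tp")) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (end_date < start_date) abort("`end_date` precedes `start_date`.")
  if (length(diel) != 24 || any(diel < 0) || all(diel == 0)) {
    abort("`diel` must be 24 non-negative weights with at least one positive.")
  }
  if (length(month_multipliers) != 12 || any(month_multipliers < 0)) {
    abort("`month_multipliers` must be 12 non-negative weights.")
  }
  if (inherits(species, "species_params")) species <- list(species)
  structure(list(n_stations = n_stations, start_date = start_date, end_date = end_date,
                 minutes_per_hour_recorded = minutes_per_hour_recorded,
                 species = species, diel = diel / mean(diel),
                 month_multipliers = month_multipliers / mean(month_multipliers),
                 fp_time_profile = match.arg(fp_time_profile)),
            class = "sim_config")
}

#' Recording schedule for a duty-cycled deployment
#'
#' One recording window per station per hour per day in the configured
#' range; deterministic (no randomness involved). The default configuration
#' yields 5 stations x 359 days x 24 hours = 43,080 windows.
#'
#' @param config a [sim_config()].
#' @return tibble with `station_id`, `recording_start` (POSIXct, UTC-4).
#' @export
generate_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- seq(config$start_date, config$end_date, by = "day")
  stations <- sprintf("ST%02d", seq_len(config$n_stations))
  grid <- expand.grid(hour = 0:23, day = days, station_id = stations,
                      stringsAsFactors = FALSE)
  start <- as.POSIXct(paste0(format(grid$day), " ", sprintf("%02d", grid$hour), ":00:00"),
                      tz = PAM_TZ)
  tibble::tibble(station_id = grid$station_id, recording_start = start)
}

#' Generate synthetic detections with ground truth
#'
#' For each recording window the detection count is Poisson with rate
#' `mean_detections_per_window * diel_weight(hour) * month_multiplier(month)`
#' (both weight vectors normalized to mean 1). Each detection draws a
#' confidence score from the species' rescaled Beta law and a correctness
#' flag with probability `pi_max * plogis(alpha_true + beta_true * logit(c))`.
#' Correct detections keep the window that produced them, so their
#' timestamps follow the diel/seasonal profile; incorrect ones are
#' re-assigned per `fp_time_profile`. Fully reproducible from `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `detections` (an [as_detections()] tibble) and `truth`
#'   (tibble `detection_id`, `correct`, `scientific_name`), the generating
#'   config attached as attribute `config`.
#' @export
generate_detections <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- generate_schedule(config)
  hour <- as.POSIXlt(schedule$recording_start)$hour
  month <- as.POSIXlt(schedule$recording_start)$mon + 1L
  w <- config$diel[hour + 1L] * config$month_multipliers[month]
  n_seg <- config$minutes_per_hour_recorded * 60 %/% SEGMENT_SECONDS
  run_with_seed(seed, {
    per_species <- lapply(config$species, function(sp) {
      counts <- rpois(nrow(schedule), sp$mean_detections_per_window * w)
      widx <- rep.int(seq_len(nrow(schedule)), counts)
      n <- length(widx)
      conf <- 0.1 + 0.9 * rbeta(n, sp$confidence_shape[1], sp$confidence_shape[2])
      correct <- rbinom(n, 1L, sp$pi_max * plogis(sp$alpha_true + sp$beta_true * to_logit(conf))) == 1L
      if (config$fp_time_profile == "uniform" && any(!correct)) {
        widx[!correct] <- sample.int(nrow(schedule), sum(!correct), replace = TRUE)
      }
      seg <- (sample.int(n_seg, n, replace = TRUE) - 1L) * SEGMENT_SECONDS
      tibble::tibble(
        station_id = schedule$station_id[widx],
        recording_start = schedule$recording_start[widx],
        segment_start = seg, segment_end = seg + SEGMENT_SECONDS,
        scientific_name = sp$scientific_name, common_name = sp$common_name,
        confidence = conf, correct = correct
      )
    })
    all <- dplyr::bind_rows(per_species)
    all <- dplyr::arrange(all, .data$scientific_name, .data$station_id,
                          .data$recording_start, .data$segment_start, .data$confidence)
    det <- as_detections(all[, setdiff(det_cols, "detection_id")])
    truth <- tibble::tibble(detection_id = det$detection_id, correct = all$correct,
                            scientific_name = all$scientific_name)
    structure(list(detections = det, truth = truth), config = config)
  })
}

#' Labeled confidence scores from the generative correctness law
#'
#' Convenience generator for calibration tests: draws `n` scores from the
#' rescaled Beta law and correctness flags from the plateaued logistic law,
#' without any recording-schedule bookkeeping.
#'
#' @inheritParams generate_detections
#' @param n number of labeled predictions.
#' @param sp a [species_params()].
#' @return tibble `confidence`, `correct`.
#' @export
simulate_labels <- function(n, sp, seed = 1L) {
  run_with_seed(seed, {
    conf <- 0.1 + 0.9 * rbeta(n, sp$confidence_shape[1], sp$confidence_shape[2])
    correct <- rbinom(n, 1L,
                      sp$pi_max * plogis(sp$alpha_true + sp$beta_true * to_logit(conf))) == 1L
    tibble::tibble(confidence = conf, correct = correct)
  })
}

#' Study-shaped three-species preset
#'
#' A preset whose three species reproduce, qualitatively, the spread of
#' calibration behaviors seen in practice: one well-calibrated species whose
#' 90%-probability threshold lands near 0.6, one steeply calibrated species
#' with a threshold near 0.43, and one plateaued species (`pi_max = 0.8`)
#' for which no confidence score ever attains 90% correctness, so the
#' threshold search must report failure. Per-window rates were fixed once so
#' that threshold-filtered totals land at the order of magnitude a year of
#' field recordings produces (tens of thousands and hundreds respectively).
#'
#' @param seed integer seed.
#' @param scale rate multiplier in (0, 1\] to shrink the dataset for quick
#'   tests; 1 is the stated full-scale world.
#' @return as [generate_detections()].
#' @export
emulate_study <- function(seed = 1L, scale = 1) {
  cfg <- study_preset(scale)
  generate_detections(cfg, seed = seed)
}

#' @rdname emulate_study
#' @export
study_preset <- function(scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  # dawn peak centered on the first full hour after a 06:00 sunrise, so that
  # the 06-08 h window carries the majority of daily activity; weak dusk
  # peak at 18:00 and a low nocturnal floor
  sim_config(
    diel = diel_weights(dawn_hour = 7, dawn_width = 1.2,
                        dusk_hour = 18, dusk_width = 1.5,
                        dusk_ratio = 0.25, floor = 0.02),
    species = list(
    species_params("Simulavis plana", "Simulated Wren A",
                   alpha_true = 1.57, beta_true = 1.5, pi_max = 1,
                   confidence_shape = c(0.9, 2.0),
                   mean_detections_per_window = 0.10 * scale),
    species_params("Simulavis praerupta", "Simulated Wren B",
                   alpha_true = 2.78, beta_true = 2.0, pi_max = 1,
                   confidence_shape = c(0.8, 1.6),
                   mean_detections_per_window = 0.80 * scale),
    # confusable species: correctness plateaus at pi_max = 0.8 already at the
    # bottom of the score range (alpha large), and high scores are rare, so
    # no attainable confidence yields 90% correctness
    species_params("Simulavis saturata", "Simulated Wren C",
                   alpha_true = 8.0, beta_true = 1.0, pi_max = 0.8,
                   confidence_shape = c(2, 10),
                   mean_detections_per_window = 0.30 * scale)
  ))
}
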