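test_that("schedule enumerates one window per station-hour-day", {
  one_day <- sim_config(n_stations = 1, start_date = "2015-06-08", end_date = "2015-06-08")
  s <- generate_schedule(one_day)
  expect_identical(nrow(s), 24L)
  lt <- as.POSIXlt(s$recording_start)
  expect_true(all(lt$min == 0 & lt$sec == 0))

  # full study design: 5 stations x 359 days x 24 h (calendar arithmetic:
  # 8 Jun 2015 .. 31 May 2016 inclusive spans a leap year)
  full <- sim_config()
  n_days <- as.integer(as.Date("2016-05-31") - as.Date("2015-06-08")) + 1L
  expect_identical(n_days, 359L)
  expect_identical(nrow(generate_schedule(full)), 5L * 359L * 24L)

  expect_error(sim_config(start_date = "2016-01-01", end_date = "2015-01-01"), "precedes")
})

test_that("generation is deterministic and conserves counts", {
  cfg <- study_preset(scale = 0.01)
  a <- generate_detections(cfg, seed = 5)
  b <- generate_detections(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_detections(cfg, seed = 6)
  expect_false(identical(a$detections$confidence, c$detections$confidence))
  # every truth row pairs one detection
  expect_identical(a$truth$detection_id, a$detections$detection_id)
  expect_true(all(a$detections$confidence >= 0.1 & a$detections$confidence < 1))
})

test_that("flat calibration law yields ~50% correctness in every bin", {
  sp <- species_params("s", "s", alpha_true = 0, beta_true = 0, pi_max = 1)
  lab <- simulate_labels(20000, sp, seed = 21)
  bins <- bin_index(lab$confidence)
  for (b in sort(unique(bins))) {
    p <- mean(lab$correct[bins == b])
    n <- sum(bins == b)
    expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / n))
  }
})

test_that("identity calibration makes bin precision equal bin-mean confidence", {
  # alpha = 0, beta = 1, pi_max = 1  =>  P(correct | c) = c
  sp <- species_params("s", "s", alpha_true = 0, beta_true = 1, pi_max = 1)
  lab <- simulate_labels(50000, sp, seed = 22)
  bins <- bin_index(lab$confidence)
  for (b in sort(unique(bins))) {
    sel <- bins == b
    p_true <- mean(lab$confidence[sel])
    p_emp <- mean(lab$correct[sel])
    se <- sqrt(p_true * (1 - p_true) / sum(sel))
    expect_lt(abs(p_emp - p_true), 3 * se + 1e-12)
  }
})

test_that("a plateau below the target caps empirical precision in the top class", {
  sp <- species_params("s", "s", alpha_true = 1, beta_true = 1, pi_max = 0.8)
  lab <- simulate_labels(20000, sp, seed = 23)
  top <- lab$confidence >= 0.7
  expect_lt(mean(lab$correct[top]), 0.9)
})

test_that("degenerate score distributions are refused", {
  expect_error(species_params("s", "s", 0, 1, confidence_shape = c(Inf, 1)), "degenerate")
  expect_error(species_params("s", "s", 0, 1, confidence_shape = c(-1, 2)), "degenerate")
  expect_error(species_params("s", "s", 0, 1, pi_max = 0), "pi_max")
})

test_that("correct detections' hour histogram peaks at the configured dawn hour", {
  cfg <- sim_config(diel = diel_weights(dawn_hour = 6, floor = 0.02),
                    species = list(species_params("s", "s", 2, 1,
                      mean_detections_per_window = 1.5)),
                    start_date = "2015-06-08", end_date = "2015-09-08")
  sim <- generate_detections(cfg, seed = 31)
  ok <- sim$truth$correct
  expect_gt(sum(ok), 10000)
  hrs <- as.POSIXlt(sim$detections$recording_start[ok])$hour
  expect_identical(as.integer(names(which.max(table(hrs)))), 6L)
})

test_that("incorrect detections follow the configured false-positive time profile", {
  base <- list(diel = diel_weights(dawn_hour = 6, floor = 0.01, dusk_ratio = 0),
               species = list(species_params("s", "s", alpha_true = -2, beta_true = 0,
                                             mean_detections_per_window = 0.5)),
               start_date = "2015-06-08", end_date = "2015-08-08")
  sim_u <- generate_detections(do.call(sim_config, c(base, fp_time_profile = "uniform")), seed = 8)
  sim_s <- generate_detections(do.call(sim_config, c(base, fp_time_profile = "same_as_tp")), seed = 8)
  hr_u <- as.POSIXlt(sim_u$detections$recording_start[!sim_u$truth$correct])$hour
  hr_s <- as.POSIXlt(sim_s$detections$recording_start[!sim_s$truth$correct])$hour
  # uniform: night hours well represented; same_as_tp: concentrated at dawn
  expect_gt(mean(hr_u %in% c(0:3, 20:23)), 0.2)
  expect_lt(mean(hr_s %in% c(0:3, 20:23)), 0.1)
  expect_gt(mean(hr_s == 6), mean(hr_u == 6))
})

test_that("the study preset reproduces the qualitative precision ordering", {
  sim <- emulate_study(seed = 1)
  joined <- dplyr::inner_join(sim$detections, sim$truth, by = "detection_id")
  sc <- bin_scheme()
  expect_gt(nrow(joined), 10000)
  for (sp in c("Simulavis plana", "Simulavis praerupta")) {
    d <- joined[joined$scientific_name.x == sp, ]
    expect_gt(nrow(d), 2000)
    prec <- tapply(d$correct, report_class(bin_index(d$confidence), sc), mean)
    prec <- prec[names(sc$report_classes)]
    expect_true(all(diff(prec) > 0))   # rising per-class precision
  }
  d3 <- joined[joined$scientific_name.x == "Simulavis saturata", ]
  high <- bin_index(d3$confidence, sc) >= 4   # upper half of its score range
  expect_gt(sum(high), 300)
  expect_lt(mean(d3$correct[high]), 0.9)  # plateaued species stays below target
})
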