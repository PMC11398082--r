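test_that("to_logit matches the closed form and round-trips", {
  expect_identical(to_logit(0.5), 0)
  expect_equal(to_logit(0.9), log(9))
  set.seed(3)
  c <- runif(500, 0.001, 0.999)
  expect_equal(inv_logit(to_logit(c)), c, tolerance = 1e-12)
  expect_error(to_logit(1.2), "outside")
  expect_error(to_logit(-0.1), "outside")
  # boundary clamp rather than Inf
  expect_true(is.finite(to_logit(1)))
  # sensitivity divisor for recognizers run at sensitivity != 1
  expect_equal(to_logit(0.9, sensitivity = 1.5), log(9) / 1.5)
  expect_equal(inv_logit(to_logit(0.7, sensitivity = 1.5), sensitivity = 1.5), 0.7)
})

test_that("the IRLS fit recovers generative parameters within 3 SE", {
  sp <- species_params("s", "s", alpha_true = -2, beta_true = 1.5, pi_max = 1)
  lab <- simulate_labels(5000, sp, seed = 101)
  fit <- fit_logistic(lab)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  expect_lt(abs(fit$alpha - (-2)) / fit$se_alpha, 3)
  expect_lt(abs(fit$beta - 1.5) / fit$se_beta, 3)
})

test_that("the fit agrees with glm and with a brute-force grid search", {
  # 6 hand-made labeled points: grid-search oracle to 1e-3
  hand <- tibble::tibble(confidence = c(0.15, 0.25, 0.4, 0.6, 0.75, 0.9),
                         correct = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
  fit <- fit_logistic(hand)
  ref <- grid_mle(to_logit(hand$confidence), as.numeric(hand$correct))
  expect_equal(fit$alpha, ref[1], tolerance = 1e-3)
  expect_equal(fit$beta, ref[2], tolerance = 1e-3)

  # and against R's own glm on a larger sample, coefficients and SEs
  sp <- species_params("s", "s", alpha_true = 0.5, beta_true = 2, pi_max = 1)
  lab <- simulate_labels(2000, sp, seed = 55)
  fit2 <- fit_logistic(lab)
  g <- stats::glm(correct ~ logit, family = stats::binomial(),
                  data = data.frame(correct = lab$correct, logit = to_logit(lab$confidence)))
  expect_equal(unname(fit2$alpha), unname(coef(g)[1]), tolerance = 1e-6)
  expect_equal(unname(fit2$beta), unname(coef(g)[2]), tolerance = 1e-6)
  se <- sqrt(diag(summary(g)$cov.unscaled))
  expect_equal(c(fit2$se_alpha, fit2$se_beta), unname(se), tolerance = 1e-4)
  expect_equal(fit2$log_likelihood, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("perfect separation is flagged and fails the threshold", {
  sep <- tibble::tibble(confidence = c(0.2, 0.3, 0.4, 0.6, 0.7, 0.8),
                        correct = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  fit <- fit_logistic(sep)
  expect_true(fit$separation_flag)
  expect_false(fit$converged)
  thr <- threshold_for_probability(fit)
  expect_identical(thr$status, "invalid_fit_failed")
  expect_true(is.na(thr$confidence_threshold))
})

test_that("single-outcome data are refused by name", {
  expect_error(fit_logistic(tibble::tibble(confidence = c(0.3, 0.6), correct = c(TRUE, TRUE))),
               "single-outcome")
  expect_error(fit_logistic(tibble::tibble(confidence = 0.5, correct = TRUE)), "at least 2")
})

test_that("threshold inversion satisfies its defining identity", {
  # identity calibration: alpha 0, beta 1 => threshold equals the target
  id_fit <- structure(list(alpha = 0, beta = 1, converged = TRUE, separation_flag = FALSE,
                           sensitivity = 1, labeled_confidence = c(0.1, 0.99)),
                      class = "logistic_fit")
  thr <- threshold_for_probability(id_fit, p_target = 0.9)
  expect_identical(thr$status, "valid")
  expect_equal(thr$logit_threshold, log(9))
  expect_equal(thr$confidence_threshold, 0.9, tolerance = 1e-12)

  # algebraic case: alpha -3, beta 2
  f2 <- structure(list(alpha = -3, beta = 2, converged = TRUE, separation_flag = FALSE,
                       sensitivity = 1, labeled_confidence = c(0.1, 0.999)),
                  class = "logistic_fit")
  t2 <- threshold_for_probability(f2, p_target = 0.9)
  expect_equal(t2$logit_threshold, (log(9) + 3) / 2)
  expect_equal(plogis(-3 + 2 * t2$logit_threshold), 0.9, tolerance = 1e-12)

  # randomized inversion identity + properties
  set.seed(4)
  for (i in 1:50) {
    a <- runif(1, -4, 4); b <- runif(1, 0.2, 4); p <- runif(1, 0.05, 0.95)
    f <- structure(list(alpha = a, beta = b, converged = TRUE, separation_flag = FALSE,
                        sensitivity = 1, labeled_confidence = c(0.1, 1 - 1e-12)),
                   class = "logistic_fit")
    t <- threshold_for_probability(f, p_target = p)
    expect_lt(abs(plogis(a + b * t$logit_threshold) - p), 1e-9)
    # equivariance: shifting alpha by delta shifts the logit threshold by -delta/beta
    d <- runif(1, -1, 1)
    fs <- f; fs$alpha <- a + d
    ts <- threshold_for_probability(fs, p_target = p)
    expect_equal(ts$logit_threshold, t$logit_threshold - d / b, tolerance = 1e-9)
    # monotonicity in the target
    t_hi <- threshold_for_probability(f, p_target = min(p + 0.04, 0.99))
    expect_gt(t_hi$confidence_threshold, t$confidence_threshold)
  }
})

test_that("failure statuses are reported, not thrown", {
  neg <- structure(list(alpha = 2, beta = -1, converged = TRUE, separation_flag = FALSE,
                        sensitivity = 1, labeled_confidence = c(0.1, 0.9)),
                   class = "logistic_fit")
  expect_identical(threshold_for_probability(neg)$status, "invalid_nonpositive_slope")

  # plateaued generative law: no score attains 90%, so the threshold search
  # must report failure (shallow/nonpositive slope or unattainable cut)
  sp <- species_params("s", "s", alpha_true = 8, beta_true = 1, pi_max = 0.8,
                       confidence_shape = c(2, 8))
  lab <- simulate_labels(5000, sp, seed = 66)
  fit <- fit_logistic(lab)
  thr <- threshold_for_probability(fit, p_target = 0.9)
  expect_match(thr$status, "^invalid_")

  # a configurable explicit bound can override the observed-max rule
  sp_ok <- species_params("s", "s", alpha_true = 1.57, beta_true = 1.5)
  fit_ok <- fit_logistic(simulate_labels(5000, sp_ok, seed = 67))
  expect_identical(threshold_for_probability(fit_ok)$status, "valid")
  capped <- threshold_for_probability(fit_ok, attainability_bound = 0.3)
  expect_identical(capped$status, "invalid_unattainable")
})

test_that("calibration reports round-trip through the key-value format", {
  sp <- species_params("s", "s", alpha_true = -1, beta_true = 1.2)
  lab <- simulate_labels(500, sp, seed = 9)
  fit <- fit_logistic(lab)
  thr <- threshold_for_probability(fit)
  path <- withr::local_tempfile()
  write_calibration_report(fit, thr, path)
  rep <- read_config(path)
  expect_equal(rep$alpha, fit$alpha, tolerance = 1e-6)
  expect_identical(rep$status, thr$status)
})
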