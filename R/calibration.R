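# Logistic calibration of recognizer confidence scores. The verified labels
# give a binary correct/incorrect response; the predictor is the confidence
# score back-transformed to the recognizer's internal logit scale. The fitted
# model P(correct) = plogis(alpha + beta * logit(c)) is inverted to the
# confidence threshold attaining a target probability of correct
# identification:
#
#   logit_threshold = (ln(p / (1 - p)) - alpha) / beta
#
# Failure to produce a usable threshold is a status, not an exception: the
# fit may not converge (separation), the slope may be non-positive, or the
# implied threshold may exceed any confidence the recognizer actually emits.

#' Fit the logistic calibration model
#'
#' Maximum-likelihood logistic regression of label correctness on the
#' logit-scale confidence score, via iteratively reweighted least squares
#' written out explicitly (convergence when the score-vector norm drops
#' below `tol`, at most `max_iter` iterations, starting from intercept =
#' log-odds of the overall precision and slope 0). Complete or
#' quasi-complete separation — labels perfectly split by the score, under
#' which the MLE diverges — is detected and flagged; a flagged fit yields
#' threshold status `invalid_fit_failed` downstream.
#'
#' @param labels data frame with logical `correct` and either `confidence`
#'   (transformed internally) or `logit_score`.
#' @param sensitivity recognizer sensitivity passed to [to_logit()].
#' @param tol,max_iter IRLS convergence tolerance on the score norm and
#'   iteration cap.
#' @return object of class `logistic_fit`: coefficients `alpha`, `beta`,
#'   their standard errors, `log_likelihood`, `n_labels`, `converged`,
#'   `separation_flag`, and the observed labeled-confidence range used by
#'   the attainability rule.
#' @export
fit_logistic <- function(labels, sensitivity = 1, tol = 1e-8, max_iter = 100) {
  if (!"correct" %in% names(labels)) abort("`labels` needs a `correct` column.")
  y <- as.numeric(labels$correct)
  if (length(y) < 2) abort("need at least 2 labels.")
  if (all(y == 1) || all(y == 0)) {
    abort("single-outcome data: both correct and incorrect labels are required to calibrate.")
  }
  z <- if (!is.null(labels[["logit_score"]])) labels$logit_score
       else to_logit(labels$confidence, sensitivity = sensitivity)
  if (anyNA(z)) abort("missing scores in `labels`.")
  X <- cbind(1, z)
  b <- c(qlogis(mean(y)), 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    wt <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * wt, X)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # dampen overshooting steps far from the optimum
    if (sqrt(sum(step^2)) > 20) step <- step * 20 / sqrt(sum(step^2))
    b <- b + step
  }
  eta <- drop(X %*% b)
  mu <- plogis(eta)
  eps <- 1e-8
  separated <- (min(mu[y == 1]) > 1 - eps && max(mu[y == 0]) < eps) ||
    (!converged && max(abs(b)) > 1e3)
  if (separated) converged <- FALSE
  wt <- pmax(mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(crossprod(X * wt, X)), error = function(e) matrix(NA_real_, 2, 2))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  structure(list(alpha = unname(b[1]), beta = unname(b[2]),
                 se_alpha = sqrt(vcov[1, 1]), se_beta = sqrt(vcov[2, 2]),
                 log_likelihood = ll, n_labels = length(y),
                 iterations = it, converged = converged, separation_flag = separated,
                 sensitivity = sensitivity,
                 max_labeled_confidence = if (!is.null(labels[["confidence"]]))
                   max(labels$confidence) else inv_logit(max(z), sensitivity),
                 labeled_confidence = if (!is.null(labels[["confidence"]]))
                   labels$confidence else inv_logit(z, sensitivity)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n_labels, "\n")
  cat(sprintf("  alpha = %.4f (SE %.4f)   beta = %.4f (SE %.4f)\n",
              x$alpha, x$se_alpha, x$beta, x$se_beta))
  cat(sprintf("  logLik = %.2f   converged = %s%s\n", x$log_likelihood, x$converged,
              if (x$separation_flag) "   [separation detected]" else ""))
  invisible(x)
}

#' Confidence threshold for a target probability of correct identification
#'
#' Inverts the fitted calibration model at `p_target` (default 0.90): the
#' logit-scale threshold is `(ln(p/(1-p)) - alpha) / beta`, mapped back to
#' the confidence scale by the inverse logit. The result always reports a
#' status rather than throwing:
#' \describe{
#'   \item{`valid`}{usable threshold; the fitted probability at it equals
#'     `p_target` to within 1e-9.}
#'   \item{`invalid_fit_failed`}{the fit did not converge or showed
#'     separation.}
#'   \item{`invalid_nonpositive_slope`}{`beta <= 0`: higher scores do not
#'     mean higher precision, so no meaningful cut exists.}
#'   \item{`invalid_unattainable`}{the implied threshold exceeds the
#'     attainability bound — by default the maximum confidence observed
#'     among the labeled predictions — so no real prediction could pass it.
#'     This is the failure mode of species the recognizer still confuses at
#'     its highest scores.}
#' }
#'
#' @param fit a [fit_logistic()] result.
#' @param p_target target probability in (0, 1).
#' @param attainability_quantile quantile of the labeled confidences used as
#'   the attainability bound (default 1 = the observed maximum); ignored if
#'   `attainability_bound` is given.
#' @param attainability_bound explicit confidence bound overriding the
#'   quantile rule.
#' @return object of class `threshold_result` with `p_target`,
#'   `logit_threshold`, `confidence_threshold`, `status`.
#' @export
threshold_for_probability <- function(fit, p_target = 0.9,
                                      attainability_quantile = 1,
                                      attainability_bound = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (p_target <= 0 || p_target >= 1) abort("`p_target` must lie in (0, 1).")
  lt <- (log(p_target / (1 - p_target)) - fit$alpha) / fit$beta
  ct <- inv_logit(lt, fit$sensitivity)
  bound <- if (!is.null(attainability_bound)) attainability_bound
           else unname(quantile(fit$labeled_confidence, attainability_quantile, names = FALSE))
  status <- if (!fit$converged || fit$separation_flag) "invalid_fit_failed"
    else if (fit$beta <= 0) "invalid_nonpositive_slope"
    else if (ct > bound) "invalid_unattainable"
    else "valid"
  structure(list(p_target = p_target,
                 logit_threshold = if (status == "invalid_fit_failed") NA_real_ else lt,
                 confidence_threshold = if (status == "invalid_fit_failed") NA_real_ else ct,
                 attainability_bound = bound, status = status,
                 alpha = fit$alpha, beta = fit$beta),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result> p_target =", x$p_target, "\n")
  if (x$status == "valid") {
    cat(sprintf("  confidence threshold = %.3f (logit %.3f)\n",
                x$confidence_threshold, x$logit_threshold))
  }
  cat("  status:", x$status, "\n")
  invisible(x)
}

#' Write fit and threshold as a key-value report
#'
#' @param fit a `logistic_fit`.
#' @param threshold a `threshold_result`.
#' @param path output file.
#' @export
write_calibration_report <- function(fit, threshold, path) {
  write_config(list(
    alpha = fit$alpha, beta = fit$beta,
    se_alpha = fit$se_alpha, se_beta = fit$se_beta,
    log_likelihood = fit$log_likelihood, n_labels = fit$n_labels,
    converged = fit$converged, separation = fit$separation_flag,
    p_target = threshold$p_target,
    logit_threshold = threshold$logit_threshold,
    confidence_threshold = threshold$confidence_threshold,
    attainability_bound = threshold$attainability_bound,
    status = threshold$status
  ), path)
}
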