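#' Logit and inverse-logit transforms
#'
#' Recognizer confidence scores are a sigmoid transform of the network's
#' internal logit, so the calibration regression is fit on the log-odds scale.
#' `to_logit()` maps a confidence score `c` in (0, 1) to `ln(c / (1 - c))`;
#' `inv_logit()` is its inverse `1 / (1 + exp(-z))`.
#'
#' Scores within `eps` of 0 or 1 are clamped to `eps` / `1 - eps` before the
#' transform (the recognizer never emits exact 0 or 1, but file round-trips
#' can); anything outside `[0, 1]` is a domain error. If the recognizer was
#' run with a sensitivity parameter other than 1, pass it as `sensitivity`:
#' the reported score is then `plogis(sensitivity * logit)`, so the raw logit
#' is recovered by dividing by it.
#'
#' @param c numeric vector of confidence scores in (0, 1).
#' @param z numeric vector of logit-scale scores.
#' @param sensitivity recognizer sigmoid sensitivity; default 1 (the study
#'   setting), in which case `to_logit()` is the plain log-odds.
#' @param eps boundary clamp width, default 1e-9.
#' @return numeric vector.
#' @examples
#' to_logit(0.9)        # log(9)
#' inv_logit(to_logit(0.37))
#' @export
to_logit <- function(c, sensitivity = 1, eps = 1e-9) {
  if (!is.numeric(c)) abort("`c` must be numeric.")
  bad <- !is.na(c) & (c < 0 | c > 1)
  if (any(bad)) {
    abort(sprintf("confidence outside [0, 1]: %s",
                  paste(format(head(c[bad], 5)), collapse = ", ")))
  }
  c <- pmin(pmax(c, eps), 1 - eps)
  qlogis(c) / sensitivity
}

#' @rdname to_logit
#' @export
inv_logit <- function(z, sensitivity = 1) {
  plogis(z * sensitivity)
}
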