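# Shared builders and independent oracles for the test suite.

# small hand-built detection table; n rows across 2 stations, hourly windows
make_detections <- function(n = 10, confidence = NULL, seed = 42) {
  set.seed(seed)
  if (is.null(confidence)) confidence <- runif(n, 0.1, 0.999)
  hours <- sprintf("2015-06-%02d %02d:00:00", 8 + (seq_len(n) %% 3), (seq_len(n) * 5) %% 24)
  as_detections(tibble::tibble(
    station_id = rep(c("ST01", "ST02"), length.out = n),
    recording_start = hours,
    segment_start = 3 * (seq_len(n) %% 100),
    segment_end = 3 * (seq_len(n) %% 100) + 3,
    scientific_name = "Simulavis alpha",
    common_name = "Simulated Wren A",
    confidence = confidence
  ))
}

# independent logistic log-likelihood (stable log-scale evaluation)
loglik_logistic <- function(a, b, z, y) {
  eta <- a + b * z
  sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
}

# brute-force coarse-to-fine grid search for the logistic MLE; independent of
# the package's IRLS path
grid_mle <- function(z, y, lo = c(-8, -8), hi = c(8, 8), stages = 5, pts = 41) {
  best <- c(0, 0)
  rng_a <- c(lo[1], hi[1]); rng_b <- c(lo[2], hi[2])
  for (s in seq_len(stages)) {
    as <- seq(rng_a[1], rng_a[2], length.out = pts)
    bs <- seq(rng_b[1], rng_b[2], length.out = pts)
    ll <- outer(as, bs, Vectorize(function(a, b) loglik_logistic(a, b, z, y)))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as[ij[1]], bs[ij[2]])
    half_a <- diff(rng_a) / (pts - 1)
    half_b <- diff(rng_b) / (pts - 1)
    rng_a <- best[1] + c(-1, 1) * half_a
    rng_b <- best[2] + c(-1, 1) * half_b
  }
  best
}

# expand published per-class counts into row-level verification records
labels_from_class_counts <- function(classes, n_verified, n_correct,
                                     scheme = bin_scheme()) {
  rows <- Map(function(cl, nv, nc) {
    bin <- scheme$report_classes[[cl]][1]
    tibble::tibble(bin_index = bin, correct = rep(c(TRUE, FALSE), c(nc, nv - nc)))
  }, classes, n_verified, n_correct)
  dplyr::bind_rows(rows)
}
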