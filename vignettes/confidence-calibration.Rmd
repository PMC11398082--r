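---
title: "Calibrating recognizer confidence scores for passive acoustic monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating recognizer confidence scores for passive acoustic monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamthresh)
```

## The problem

Passive acoustic monitoring surveys record far more audio than anyone can
listen to, so species detection is delegated to an automated recognizer that
scans recordings in 3-second segments and attaches a confidence score in
(0, 1) to every prediction. That score is a sigmoid transform of the
network's internal logit and is **not** a calibrated probability: a score of
0.5 does not mean a 50% chance the species is really there, and how score
maps to correctness differs sharply between species, sites and noise
conditions. Before recognizer output can support any ecological statement —
here, diel and seasonal patterns of vocal activity of wetland songbirds —
two questions must be answered from a human-verified sample:

1. How often is the recognizer right, as a function of its own score
   (*precision by confidence class*)?
2. Which score cutoff retains only predictions with a chosen probability of
   being correct (*the calibrated threshold*)?

`pamthresh` implements that post-classifier workflow: stratified
verification sampling, precision estimation, logistic calibration on the
logit scale, threshold inversion with explicit failure semantics, and
activity profiling of the threshold-filtered detections. A synthetic-data
module stands in for the recording/recognizer stage so the entire pipeline
runs and is testable at desk scale.

## The calibration model

Let $c \in (0,1)$ be a prediction's confidence and $z = \mathrm{logit}(c) =
\ln\{c/(1-c)\}$ its score on the recognizer's internal scale (the
recognizer's sensitivity parameter is assumed 1, its default; a divisor is
available for other settings). With verified labels $y_i \in \{0,1\}$
(correct/incorrect), the calibration model is plain logistic regression

$$\Pr(y = 1 \mid c) = \mathrm{logit}^{-1}(\alpha + \beta z),$$

fit by maximum likelihood. Inverting the fitted curve at a target
probability $p$ (0.90 by default) gives the threshold on the logit scale,

$$T = \frac{\ln\{p/(1-p)\} - \alpha}{\beta},$$

and $\mathrm{logit}^{-1}(T)$ is the confidence-scale cutoff used to filter
the full detection table. Regression is performed on $z$, not on $c$: on
the logit scale the recognizer's score is the raw evidence the sigmoid was
applied to, and the linear model is the natural (and field-standard) choice.

### Failure is a status, not an exception

A usable threshold does not always exist, and the package treats that as a
first-class outcome (`threshold_for_probability()` always returns, with a
status):

* `invalid_fit_failed` — the likelihood did not converge, including
  complete/quasi-complete separation, where the MLE diverges;
* `invalid_nonpositive_slope` — $\hat\beta \le 0$: higher scores do not mean
  higher precision, so no cutoff is meaningful;
* `invalid_unattainable` — the implied cutoff exceeds any confidence
  actually observed among labeled predictions.

The attainability rule deserves a note, because the real-world failure it
represents (a species the recognizer confuses with relatives even at its
highest scores) is reported in the literature without a stated criterion,
and both non-convergence and unattainability are plausible readings. We
adopt *"the threshold exceeds the maximum observed labeled confidence"*
(quantile configurable, an explicit bound can be supplied): a cutoff that no
real prediction can reach is operationally meaningless regardless of why the
fit put it there. Downstream stages (`filter_by_threshold()`, the
`patterns` pipeline stage) refuse to run on any non-valid status rather
than silently producing activity profiles from uncalibrated detections.

## Verification design and precision

Raw recognizer output is dominated by low-score predictions, so a uniform
random sample would say almost nothing about the high-score region where
the threshold lives. `stratified_sample()` therefore draws a fixed number
of predictions (default 50) uniformly without replacement from each fine
0.1-wide confidence bin — 450 predictions over the nine bins of the default
scheme. Bins are left-closed/right-open with a closed top bin; a bin with
fewer candidates than requested is taken whole, with a shortfall warning.

`precision_table()` reports, per coarse class (default 0.1–0.3, 0.3–0.5,
0.5–0.7, >0.7 — the last aggregating three fine bins) and for the full
range, the number verified, number correct, and precision
$100 \cdot n_\mathrm{correct}/n_\mathrm{verified}$, kept at full precision
internally and rounded to one decimal only for display. Wilson 95%
intervals are optional and off by default, matching how such tables are
usually printed. `pooled_precision()` pools **counts**, not percentages,
across species and classes, so a 150-prediction class weighs more than a
100-prediction one — the convention the published pooled figures follow.
Classes with no labels are reported as undefined (`NA`), never as zero.

## The synthetic world

`sim_config()` defaults state the monitoring design the package emulates:
5 stations, each recording the first 15 minutes of every hour, 24 h/day,
8 June 2015 – 31 May 2016 (359 days, 43,080 recording windows), clock time
fixed at UTC−4 with no daylight saving. Within each window the detection
count is Poisson with rate

$$\lambda_w = \mu \cdot d_{h(w)} \cdot m_{M(w)},$$

where $\mu$ is the species' mean detections per window and $d$, $m$ are
hour-of-day and month weight vectors, each normalized to mean 1. Every
detection draws its confidence from a Beta law rescaled into $[0.1, 1)$
(the range a recognizer run at minimum confidence 0.1 emits) and its
correctness from

$$\Pr(\text{correct} \mid c) = \pi_{\max} \cdot
  \mathrm{logit}^{-1}(\alpha_0 + \beta_0 \, \mathrm{logit}(c)).$$

Correctness is drawn *directly* from this (optionally plateaued) logistic
law rather than emerging from separate true/false-positive score mixtures.
That is a deliberate design choice: it guarantees the generator has exactly
the structure the calibration module fits, which is what makes sharp
parameter-recovery tests possible (truth within 3 SE, threshold within
±0.03, across seeded replicates). The plateau $\pi_{\max} < 1$ is the
mechanism for the no-valid-threshold failure mode. Correct detections keep
the window that generated them, so their timestamps carry the diel/seasonal
signal; incorrect detections are re-assigned per `fp_time_profile` —
`"uniform"` by default (false positives have no reason to follow the
species' song schedule; no published temporal distribution exists for
them), or `"same_as_tp"`.

The diel profile is two Gaussian peaks over a nocturnal floor. Presets fix
sunrise at 06:00 and sunset at 18:00 local time — field reports give clock
hours, not solar ephemerides — and center the dawn peak on the first full
hour after sunrise with a weaker dusk peak, so that the 06–08 h window
carries the majority of daily activity, as observed for the wrens this
design emulates. Month multipliers peak in March–June (onset of the
Pantanal dry season) with a secondary December bump.

### The three-species preset

`study_preset()` fixes, once, a world shaped like the published study:

| species | $\alpha_0$ | $\beta_0$ | $\pi_{\max}$ | scores | $\mu$/window |
|---|---|---|---|---|---|
| *Simulavis plana* (well-calibrated) | 1.57 | 1.5 | 1 | Beta(0.9, 2.0) | 0.10 |
| *Simulavis praerupta* (steep) | 2.78 | 2.0 | 1 | Beta(0.8, 1.6) | 0.80 |
| *Simulavis saturata* (plateaued) | 8.0 | 1.0 | 0.8 | Beta(2, 10) | 0.30 |

The first two give rising per-class precision and 90%-probability
thresholds near 0.6 and 0.43 respectively (the order of magnitude the
study reports; its exact values are not recomputable because the underlying
labels are unpublished). Rates $\mu$ were chosen once so that
threshold-filtered totals land at the order of magnitude a year of field
recordings produced (roughly $10^4$ and $10^3$) and were not revisited.

The plateaued species encodes the species for which no threshold could be
identified: its correctness sits at $\pi_{\max} = 0.8$ across the entire
observed score range (the plateau is reached below the 0.1 score floor) and
its scores rarely exceed 0.7 — the portrait of a species the recognizer
confuses at every score level. Because a finite 450-label sample can, with
small probability, produce a chance fit whose curve crosses 0.9 inside the
observed range, the failure mode is a statistical property, not a pointwise
certainty; the acceptance test asserts it as a dominant fraction over
seeded replicates (it held in 194 of 200 seeds at full scale during
development), mirroring how the parameter-recovery criteria are phrased.

### What a green test does not establish

The generator emulates the *statistical* structure the analysis assumes; it
deliberately omits features of real deployments: spatial correlation
between stations, weather/rain masking, recognizer score drift with
ambient noise, non-logistic miscalibration shapes, and observer error in
the verification labels. Green tests establish that the pipeline's
arithmetic and inference are correct under the stated model — not that any
particular field dataset satisfies that model.

## Numerical choices

* **Logistic fit**: hand-written iteratively reweighted least squares;
  convergence when the score-vector norm drops below $10^{-8}$, at most 100
  iterations, starting from $(\mathrm{logit}(\bar y), 0)$; Newton steps are
  damped to length 20 to survive wild starts. Separation is flagged when
  fitted probabilities at the data are numerically 0/1 on the correct sides,
  or when iteration diverges. `stats::glm()` is used in the test suite as an
  independent oracle (together with a coarse-to-fine grid search of the
  likelihood), never as the implementation.
* **No regularization** — matching standard practice for this analysis;
  separation is reported, not penalized away.
* **Logit boundary**: scores within $10^{-9}$ of 0/1 are clamped before the
  transform; scores outside $[0,1]$ are a domain error. At the I/O layer,
  confidences outside the open interval are *rejected* (with a surfaced
  count), never clamped: raw data are kept honest, and clamping happens only
  inside the calibration transform.
* **Bin edges**: left-closed/right-open, top bin closed, so 0.1 is included
  and an exact 1.0 (never emitted by the recognizer) would still bin.
* **Threshold ties**: filtering keeps detections *at* the threshold
  (configurable); published wording ("above the score") does not resolve
  ties, and the inclusive rule makes the identity threshold a no-op.
* **Detection hour**: the hour of the recording window's start — windows
  cover only the first 15 minutes of an hour, so a segment can never cross
  an hour boundary.
* **Months**: one bar per calendar month on a June→May axis, pooling the
  two partial years; the partial first/last months are reported as-is with
  a truncation note attached to the profile.

## Open design points, resolved

* **Input dialects**: recognizer exports differ (one combined table vs
  per-recording selection tables); both a combined tab-separated table and a
  Raven-style selection table are supported, with station and timestamp
  recovered from the recording filename by a configurable pattern
  (default `STATION_YYYYMMDD_HHMMSS`, the conventional field-recorder
  naming).
* **Class grouping**: the top reported class aggregates three fine bins
  (hence 150 verified there versus 100 elsewhere); the grouping is
  configurable in `bin_scheme()` since nothing forces that asymmetry.
* **Failure reason for the uncalibratable species**: both candidate
  readings are representable as distinct statuses; under this generator and
  the observed-max rule the plateaued preset most often lands in
  `invalid_unattainable`, with `invalid_nonpositive_slope` when the chance
  slope estimate is negative — either way the pipeline halts filtering.
* **Stage coupling**: pipeline stages communicate through files because
  human verification is an offline gap in the real workflow; the manifest
  written by `sample` is exactly what a reviewer fills in.

## Limitations

Recall is out of scope: verification of sampled *predictions* estimates
precision only, and a threshold calibrated for 90% precision says nothing
about how many true vocalizations fall below it. Activity profiles are
descriptive percentages; no statistical comparison between species or
periods is attempted. The calibration assumes a single pooled relationship
across stations (as the emulated study did); per-station calibration would
need its own verified sample per station.
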