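---
title: "Methods: from eye-aspect-ratio signals to mediation path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from eye-aspect-ratio signals to mediation path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkpath)
```

`blinkpath` implements a complete analysis chain for studies that relate
spontaneous eye-blink rate (SBR) to psychometric measures: blink
quantification from facial-landmark-derived eye-aspect-ratio signals,
personalized threshold calibration, questionnaire scoring, and a saturated
standardized mediation path model with suppression detection. This vignette
documents the models, the tunable parameters, the numerical conventions, and
the design decisions taken where the method description left genuine
latitude.

## 1. The EAR signal

For six eye landmarks per eye (temporal corner $p_1$, nasal corner $p_4$,
upper lid $p_2, p_3$, lower lid $p_6, p_5$) the eye aspect ratio is

$$\mathrm{EAR} = \frac{A + B}{2C}, \qquad
A = \lVert p_2 - p_6 \rVert,\;
B = \lVert p_3 - p_5 \rVert,\;
C = \lVert p_1 - p_4 \rVert .$$

EAR is dimensionless and invariant to translation, rotation and uniform
scaling of the landmark set, so camera distance and head pose (in-plane)
do not bias it. The detection signal is the per-frame mean of both eyes
(mEAR), at the 30 frames-per-second convention of laptop video.

*Degenerate frames.* Landmark regression occasionally fails or collapses
($C$ below an epsilon of $10^{-6}$ pixels, configurable). Such frames are
**masked, not dropped**, so frame indices stay aligned with the video
timeline; if only one eye fails, the other carries the frame and it is
flagged. Masking is our convention — upstream blink software rarely
documents its handling of failed detections.

## 2. Blink segmentation and rate statistics

A blink event is a **maximal run of consecutive unmasked frames with
mEAR strictly below the threshold**. Two filters follow:

* `min_frames = 2` (about 67 ms at 30 fps) discards single-frame noise
  crossings. Spontaneous blinks last roughly 220–380 ms, far above two
  frames, so the filter costs no real events.
* `max_duration_ms = 500` flags longer closures as voluntary or
  intentional; they are retained with `valid = FALSE` for audit but
  excluded from all counts and rates.

Masked frames break runs: a blink cannot span a detection failure.

Rates are computed by tiling the recording into complete, non-overlapping
60-second windows; the mean and sample standard deviation of per-window
counts give blinks/minute. Three conventions here are ours: a blink
straddling a window boundary belongs to its **onset** window; partial
trailing minutes are **dropped** rather than prorated; and
"mean blinks per minute" is the per-window mean (rather than total
events / total duration) so that the standard deviation is defined on the
same units.

## 3. Threshold calibration by bisection

The threshold separating "closed" from "open" differs between people
(eye shape, camera geometry), so it is calibrated per participant against a
manual blink count on a calibration window — conventionally the first two
minutes of the recording. Starting from the interval $[0.05, 0.45]$
(spanning physiologic mEAR; an `auto` mode uses the observed signal range
instead), bisection evaluates the automatic count at the midpoint and
narrows: automatic count below the manual count raises the lower limit,
above it lowers the upper limit. The orientation follows from monotonicity
of the *frame set*: the set of below-threshold frames grows with the
threshold, so too few detected blinks means the threshold is too low. The
loop stops at an exact count match, after `max_iter = 50` iterations, or
when the interval is narrower than `min_interval = 1e-4`.

The blink *count*, unlike the frame set, is not monotone in the threshold
(adjacent runs merge as the threshold rises), and no threshold need
reproduce the manual count exactly. In that case the result is the visited
midpoint minimizing the absolute count difference, ties broken towards the
lower (more conservative) threshold, reported with `converged = FALSE` and
the full iteration trace for audit.

A consequence worth knowing: bisection stops at the *first* matching
midpoint, which can sit at the edge of the plateau of matching thresholds.
At a high edge (e.g. 0.25 with a 0.30 baseline and noise SD 0.02) rare
two-frame noise runs can add a false event or two over a five-minute
recording; at a low edge the shortest blinks hold only two sub-threshold
frames and a single noise excursion can split them. In simulation this
leaves a few percent of runs one or two events off the ground truth. A
plateau-centred stopping rule would remove this, but we kept the
first-match rule because it is the method as described.

## 4. Questionnaire scoring

* **BFI-2** (60 items, 1–5): five domains of 12 items each, scored as item
  means after reflecting reverse-keyed items
  ($x \mapsto \min + \max - x$). Domain means live on the 1–5 scale.
* **PSS-14** (14 items, 0–4): summed after reflecting the seven positively
  worded items; totals span 0–56, higher = more perceived stress.
* **Subjective blinking**: a single 1–7 self-rating.

The shipped keys are the published instrument keys (they also live in
`inst/extdata/default_keys.json`; site-specific keying can be loaded with
`read_keying_json()`). Aggregation conventions follow the scales'
manuals — means for trait domains, a sum for the stress total. Missing
responses error by default; an opt-in policy imputes up to two items by the
person mean.

Internal consistency uses Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with sample
variances. Descriptives are the SPSS-compatible adjusted estimators —
skewness $G_1$ and excess kurtosis $G_2$ with the small-sample
correction — because studies in this area overwhelmingly report those.
Pearson correlations carry two-tailed p-values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df.

## 5. The saturated standardized mediation model

With standardized predictor $X$, mediator $M$ and outcome $Y$, the model

$$M = aX + e_M, \qquad Y = c'X + bM + e_Y$$

is *saturated*: it reproduces the observed $3\times3$ correlation matrix
exactly, has zero degrees of freedom, and its maximum-likelihood point
estimates coincide with the OLS normal-equation solutions

$$a = r_{XM}, \qquad
b = \frac{r_{MY} - r_{XM} r_{XY}}{1 - r_{XM}^2}, \qquad
c' = \frac{r_{XY} - r_{XM} r_{MY}}{1 - r_{XM}^2},$$

with the exact decomposition $c = r_{XY} = c' + ab$ (asserted to $10^{-12}$
in the tests) and explained variances $R^2_M = a^2$,
$R^2_Y = c' r_{XY} + b\, r_{MY}$. Global fit indices are undefined for a
saturated model and are deliberately not reported.

*Inference.* t statistics use finite-sample OLS forms:
$t_a = a\sqrt{n-2}/\sqrt{1-a^2}$ on $n-2$ df, and for the outcome equation
$t = \beta \big/ \sqrt{(1 - R^2_Y)/\{(n-3)(1 - r_{XM}^2)\}}$ on $n-3$ df.
SEM software reports asymptotic (critical-ratio) standard errors instead;
point estimates agree exactly, t values only approximately. We chose the
finite-sample forms because they are exact for the OLS-equivalent model and
reproducible from the correlation matrix alone.

*Classification.* With significance at two-tailed $\alpha = 0.05$:

* **suppression** — indirect effect $ab$ and direct effect $c'$ carry
  opposite signs and $c'$ is significant: adding the mediator strengthens
  (and possibly reverses) the predictor–outcome association;
* **indirect-only** — both $a$ and $b$ significant, $c'$ not
  (inconsistent mediation with a null direct path);
* **consistent-mediation** — same signs, indirect paths significant;
* **no-effect** — anything else.

*Bootstrap.* `bootstrap_indirect()` provides a seeded case-resampling
percentile CI for $ab$. One caveat is intrinsic to percentile intervals
for a product: under a **complete null** ($a = 0$ *and* $b = 0$) the
product's sampling distribution is a sharply peaked product-normal and the
interval covers zero essentially always — far above nominal. Our null
simulation (n = 200, 2000 resamples, 500 outer replicates) measures
coverage ≈ 1.00, the textbook conservativeness of this estimator; coverage
approaches the nominal 95% only when at least one path is truly nonzero.
The interval is therefore a conservative screen, not an exact test, at the
complete null.

*Covariates.* The model is fixed at one X, one M, one Y; age/gender
covariates are out of scope (adding them did not alter the published
pattern they were dropped from).

## 6. What the synthetic generators emulate

`generate_ear_signal()` emulates the *measured* signal, not the face:
Gaussian noise (SD 0.02) around an open-eye baseline of 0.30, blink dips to
0.08, sampled at 30 fps. Onsets follow a **renewal process** — eyes-open
gaps are a hard 200 ms refractory period plus a gamma interval (shape 2)
whose mean is set so the long-run rate matches `rate_bpm` (default 15, the
middle of the typical 10–25 resting range). A renewal rather than Poisson
process was chosen so events can never overlap, honouring the refractory
period of real blinks. Durations are truncated-normal, mean 300 ms, SD
50 ms, truncated to [200, 500] ms — the conventional spontaneous-blink
range. Each dip is a symmetric V (linear closure to full depth and back,
sampled at frame midpoints so every ground-truth frame carries nonzero
closure); the V shape makes onset/offset detection non-trivial at threshold
crossings, unlike a square pulse. Ground truth is returned frame-exactly.

What it does **not** emulate: landmark jitter correlated over time, head
motion, illumination drift, partial closures, camera compression — so
passing recovery tests here demonstrates the algorithmic chain, not
robustness to real video artifacts.

`generate_trait_sample()` draws standardized multivariate-normal samples
with a target correlation matrix (default: a reference structure with the
trait–stress, trait–blink and stress–blink correlations typical of this
literature, e.g. Neuroticism–stress 0.35, stress–blink 0.27; trait
intercorrelations default to zero). Real questionnaire data are discrete,
skewed and heteroscedastic; the generator tests estimator consistency, not
distributional robustness. `generate_likert_responses()` adds the discrete
layer: items are the latent score shrunk towards the scale midpoint by
`1 - loading`, plus noise, clipped and rounded, with reverse-keyed items
emitted pre-reversed so scoring recovers the latent mean. `loading` spans
$[0, 1]$; 0 yields pure-noise items (an $\alpha \approx 0$ limit case), 1
yields items centred on the latent score.

## 7. Numerical conventions and problem sizes

* Strict inequality (`mEAR < threshold`) defines closure; thresholds are
  never attained exactly by design-relevant values.
* PSD checks tolerate eigenvalues down to $-10^{-10}$.
* All generators take an explicit integer seed; nothing depends on global
  RNG state beyond the seeded call.
* R² values are conventionally reported to two decimals or as whole
  percentages.

The test suite exercises: oracle equivalence of run-length segmentation on
1000 random signals; calibration convergence on 200 seeded two-minute
signals; end-to-end count recovery on 100 seeded five-minute recordings;
mediation parameter recovery within ±0.03 on 100 cohorts of n = 10,000;
and the bootstrap null simulation above. These sizes keep the full suite in
a few minutes while leaving Monte-Carlo error well below the asserted
tolerances.

## 8. Known limitations

* Per-participant calibration requires a manual count; inter-rater
  disagreement between manual counters is not modelled.
* The duration filter is the only voluntary-blink guard; no
  voluntary/involuntary classifier is included.
* SEM asymptotic standard errors are not replicated (see §5); published
  critical ratios are matched only approximately.
* The bisection first-match rule inherits the plateau-edge sensitivity
  described in §3.
* BFI-2 facet-level (15-facet) scoring and measurement-invariance testing
  are out of scope.
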