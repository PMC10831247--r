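---
title: "Two-tone image pipelines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tone image pipelines: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Two-tone ("Mooney") images are grayscale photographs degraded by Gaussian
smoothing followed by luminance binarization. The resulting black-and-white
images are often unrecognizable on first viewing, yet after a single look at
the source photograph they snap into a stable percept — *perceptual
reorganization*, a signature of prior knowledge reshaping perception.
Developmental touchscreen studies of this effect collect, per participant
and image: a naive naming response to the two-tone, a naming response to the
grayscale cue, touches on two prompted object features on the cued two-tone,
and control touches on the grayscale. This package implements every stage of
that design as reusable, seeded, testable code: stimulus synthesis, image
statistics, response scoring, a synthetic-cohort generator, and the
multilevel inference layer.

## Stimulus model

`make_twotone()` smooths with an isotropic Gaussian (SD `sigma` in pixels)
and binarizes at a luminance `threshold` on the 0–255 scale. Two conventions
are fixed so results are bit-reproducible:

* **Boundary handling.** Smoothing pads by symmetric reflection (edge pixel
  repeated). Circular or zero padding would wrap content or pull dark halos
  into the border, which then flip binarization near edges.
* **Tie rule.** A smoothed value strictly greater than the threshold maps to
  white; a value exactly equal maps to black. Any fixed rule would do; this
  one makes thresholding idempotent on already-binary images.

Catch stimuli (`make_catch()`) are thresholded without smoothing — easily
recognizable two-tones used to index task compliance. `make_morph_sequence()`
builds the grayscale-to-two-tone fade used when cueing: luminance is
re-quantized over a decreasing number of levels, by default
`255, 64, 16, 4, 2` over five frames. Only the endpoints of the schedule
(full depth down to binary over five steps) are constrained by the design;
the geometric spacing between them is our choice, and smoothing is applied
only on the final frame, which is bitwise-equal to the `make_twotone()`
output.

Per-image smoothing and threshold levels in real stimulus sets are curated
by hand. `choose_twotone_params()` standardizes that: `sigma` is a fraction
of image height (default 1.2%, about 8 px at the display's 680 px) and the
threshold is the smoothed-luminance quantile that hits a target black-pixel
fraction (default 0.5). Both values are recorded in the stimulus provenance.

## Display geometry

All millimetre quantities derive from one scale: stimuli are presented at a
fixed height of 680 px spanning 273.9 mm, so `mm_per_px = 273.9/680 ≈
0.4028`. Touch coordinates use the image pixel frame: origin top-left,
x rightward, y downward, 0-based.

## Synthetic grayscale fixtures

`generate_synthetic_grayscale()` renders a mid-grey background (128), an
optional linear luminance ramp in a random direction, embedded
high-contrast ellipses and convex polygons (the "objects" whose features
become pointing targets), and additive noise with a 1/f amplitude spectrum.
The pink-noise SD defaults to 35 luminance units: this was calibrated once
so that the synthetic grayscales land in the Sobel edge-density range
typical of grayscale photographs (≈ 0.1), i.e. so the fixtures carry
photograph-like fine-scale texture. With much smoother fixtures the
two-tone transform *adds* edges instead of removing them, which inverts a
directional property that holds for photographs.

What the generator does *not* emulate: semantic content (no nameable
objects), occlusion and shadow structure, and the curated difficulty range
of a hand-picked stimulus set. Tests passing on these fixtures certify the
pipeline's mechanics and statistical calibration, not claims about any
particular photograph set.

## Image statistics

* `edge_density()`: mean 3×3 Sobel gradient magnitude over interior pixels,
  normalized by the response to an ideal 0→255 step (1020) and capped at 1.
* `contrast_map()`: difference-of-Gaussians (centre minus surround) local
  contrast magnitude at two scales — a fine "parvo" scale (centre SD 1 px by
  default) and a coarse "magno" scale (4× coarser), surround:centre SD ratio
  1.6 at both scales. The exact filter constants behind published
  contrast-energy/spatial-coherence statistics are not fully specified in
  public sources; these defaults follow the standard centre-surround model
  family, are configurable arguments, and are recorded with every result.
* `weibull_fit()`: maximum-likelihood Weibull fit of the pooled contrast
  magnitudes. The scale parameter is reported as contrast energy (CE), the
  shape parameter as spatial coherence (SC). Zero-contrast pixels are
  excluded before fitting (the likelihood is undefined at zero); values
  below `1e-8` of the sample maximum count as zero, because flat regions of
  a difference-of-Gaussians map carry floating-point cancellation dust many
  orders of magnitude below real contrast that would otherwise dominate the
  shape estimate. An all-zero sample returns the sentinel `CE = 0, SC = NA`
  with a warning rather than an error.

On the synthetic fixture set the two-tone transform raises CE, lowers SC,
and lowers edge density relative to the grayscale, and smoothed two-tones
have lower edge density than unsmoothed catch versions — the direction
expected for photographs.

## Scoring model

ROIs are simple polygons in display pixels. Membership
(`point_in_roi()`) is boundary-inclusive: child touch data favours crediting
boundary hits, and a fixed rule keeps the raster-oracle tests exact.
Pointing distance is the Euclidean distance between the cued two-tone touch
and the grayscale-control touch for the same target, in mm.

The pointing-error taxonomy (`classify_error()`) has precedence
`correct > local > global > other`: a touch in the correct ROI is correct;
otherwise a touch in a local-distractor ROI (an incorrect feature matching
the target's local shape, with area equal to the correct ROI) is a *local*
error; otherwise a touch within the similar polygon of three times the
correct ROI's area, scaled about the centroid, is a *global* error. The 3×
region's *shape* is our choice — only its area ratio is constrained — and
the precedence rule resolves overlaps, which the source design leaves
unstated.

Exclusions are two-tiered (`apply_exclusions()`): trials with incorrect
grayscale naming leave all analyses; trials additionally leave
cued-pointing analyses when not both targets were attempted in both
conditions or grayscale localization failed. Every exclusion carries a
machine-readable reason code, and accuracy denominators are attempted
targets, consistent with those rules.

Naming is scored against a per-image dictionary (accepted basic/subordinate
labels with synonym clusters, rejected superordinate labels). Labels are
normalized (lowercase, punctuation stripped). Naive naming is correct only
if it is accepted *and* in the same synonym cluster as a correct grayscale
name, so "cat" for a tiger counts when the grayscale was also named within
the cat cluster, while "animal" never counts.

## The synthetic cohort

`simulate_cohort()` mirrors the analysis model so that inference can be
validated by parameter recovery:

* grayscale naming ~ Bernoulli(`plogis(mu_gray)`);
* naive recognition ~ Bernoulli(`plogis(mu_naive + u_participant +
  v_image)`), with crossed Gaussian intercepts (`sd_participant = 0.8`,
  `sd_image = 0.6` by default);
* cued recognition is certain for naively recognized images, and otherwise
  adds `reorg_gain` (the perceptual-reorganization parameter, additive on
  the log-odds scale for compatibility with the logistic analysis) to the
  same linear predictor;
* touches: recognized targets scatter isotropically around the correct ROI
  centroid with SD `touch_sd_mm`; unrecognized touches land on a
  local-distractor centroid with probability `p_local` (when the target has
  one) and are otherwise uniform over the display; grayscale-control
  touches scatter with a 3 mm SD at every age. Each target is attempted
  with probability `p_attempt`.

The cohort defaults are the reference design: groups of 31/23/18/13
participants (4–5, 7–9, 10–12 years, adults), 20 two-tone trials with an
easy catch trial in every 5th slot (4 catches), two targets per image.
`make_presets()` supplies illustrative group parameters: naive-recognition
means rising from `qlogis(0.26)` to `qlogis(0.63)` (the marginal accuracy
range a developmental sample spans), reorganization gain rising from 0
(youngest — cueing does not create new recognition) to 6 log-odds (adults —
cueing saturates, so recognized and unrecognized images point equally
well), local-capture probability falling from 0.55 to 0, touch scatter
falling from 11 to 5 mm, attempt rates rising from 0.88 to 0.99. The touch
and attempt numbers are not constrained by any published estimate; they are
fixed once at values plausible for child touchscreen work and flagged as
illustrative.

Generated decoy geometry: 30% of targets receive a local-distractor ROI,
placed far enough from the correct target that it cannot fall inside the 3×
global region (real stimulus sets have shape-matching decoys for only a
subset of targets — eight, in the reference design).

## Inference layer

All mixed models are fitted with lme4 (Laplace approximation, `bobyqa`),
the same estimation machinery the field uses:

* **Naming:** logistic, `correct ~ age_group + (1|participant) + (1|image)`,
  treatment coding with the adult reference so each age coefficient is a
  child-vs-adult contrast tested by a Wald z.
* **Pointing accuracy:** logistic, adding a `recognized` (naively
  recognized vs not) main effect and its age interaction, plus a random
  intercept for ROI area. A continuous grouping factor is ill-defined, so
  ROI area enters as decile bins; treating it as a fixed covariate instead
  is possible by putting `roi_area` in the fixed terms.
* **Pointing distance:** Gaussian mixed model on log-transformed distances
  (distances are strictly positive; exact zeros are offset by half the
  smallest positive value, with a message), fitted by ML so nested models
  are comparable. Exponentiated coefficients are distance ratios. A
  log-link Gamma model is a defensible alternative; the log-transform
  reading was chosen and is stated here.

Age trends are tested by likelihood-ratio tests against the model without
the effect of interest (`lrt()`, Χ² clamped at zero against boundary
noise); pairwise group comparisons by Wald z (`wald_contrast()`), with no
multiple-testing correction across contrasts (none is standard in this
design). Group means carry percentile-bootstrap 95% CIs
(`bootstrap_ci()`, 10,000 resamples by default, seeded). Complete
separation is detected (constant outcome, or fixed effects beyond ±10
log-odds) and reported with a warning and an honest `converged = FALSE`
flag; no penalized refit is attempted.

## Calibration checks and problem sizes

The test suite validates the inference layer by simulation, at sizes chosen
to give stable Monte-Carlo estimates:

* LRT type-I error of the age effect: 500 null replicates at a reduced
  cohort of 4 × 20 participants and 8 images. Age varies between
  participants, so chi-squared calibration requires a near-design
  participant count; the reduced dimension is trials per participant. The
  rejection rate must fall in [0.03, 0.07].
* Wald 95% CI coverage of the three child-vs-adult contrasts: 200
  replicates at the full design (31/23/18/13 × 20 images); pooled coverage
  must fall in [0.90, 0.98].
* End-to-end reorganization signature: 200 replicate single-group
  pipelines (simulate → score → exclude → fit). With the youngest preset
  (zero gain) the recognized-vs-unrecognized pointing LRT must reject with
  power ≥ 0.8; with the adult preset (saturating gain) rejections must stay
  at the nominal false-positive rate.
* Scoring geometry: `point_in_roi()` and `classify_error()` must agree with
  an independent scanline-rasterization oracle on over 10,000 random
  display points with zero disagreements.

## Known limitations

* The synthetic fixtures carry no semantic content, so nothing here speaks
  to which *objects* are hard to recognize — only to the pipeline's
  mechanics, calibration and the direction of image-statistic shifts.
* CE/SC filter constants are declared defaults, not reconstructions of any
  specific published filter bank; comparisons of absolute CE/SC values
  across implementations are not meaningful.
* The generator treats naive recognition as implying cued recognition
  (no forgetting between stages) and simulates no learning, reaction times
  or memory decay.
* `fit_mixed_logistic()` reports separation honestly but does not fit a
  penalized model.
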