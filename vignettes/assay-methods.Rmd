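---
title: "Quantifying larval aggregative tendency: model, null, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval aggregative tendency: model, null, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvagg)
```

## The assay

Groups of 2–8 sawfly larvae are placed equidistantly on the wall of a
14.5-cm petri dish and filmed for 90 minutes. The question the assay
answers is behavioural, not demographic: do the animals *choose* to stay
near one another once placement effects have worn off?

The pipeline reduces each video to a single number in four steps:

1. **Extraction.** One frame every 15 s → 360 raw frames.
2. **Subsampling.** One analysed frame every 180 s → 30 frames.
   Retained frames start at *t* = 0, so frame *k* sits at 180 *k*
   seconds; the phase is fixed and deterministic.
3. **Acclimation discard.** The first 12 analysed frames (2,160 s) are
   dropped: early positions reflect where the experimenter put the
   animals, and handling agitates them. 18 frames remain.
4. **Pooling.** All pairwise Euclidean distances from the retained
   frames are averaged into the video's **mean pairwise distance**
   (cm), and its natural log is taken for all downstream statistics.

Because every complete frame of an *n*-larva video contributes the same
*n(n−1)/2* pairs, the pooled mean is identical to the mean of per-frame
mean distances; `summarize_video()` computes it that way and also
returns the per-frame series for stabilisation plots. Frames with a
missing individual are a hard error by default — the reader's
`allow_partial` mode drops such frames with a warning, and nothing is
ever imputed. The natural log is fixed (no base option): it tames the
right skew of distance data, and since it is monotone it never changes
which of two videos looks more aggregative.

Degenerate inputs are surfaced, not smoothed over: a video whose
retained frames are all coincident points has no defined log statistic
and raises a log-undefined error rather than returning −∞; irregular
raw-frame spacing (beyond 0.5 s of slack, the jitter a frame extractor
can introduce) names the offending frame; positions are allowed to sit
on the dish wall to within 10⁻⁹ cm, since annotated head capsules of
wall-following larvae land exactly there.

## The random-dispersal null

A small mean pairwise distance is only evidence of aggregation relative
to what aimless animals would produce, so the reference is complete
spatial randomness (CSR): every individual independent and uniform over
the dish *area* (radius drawn as \(R\sqrt{U}\) — uniform in radius
would pile density at the centre). A null "video" is 30 independent
uniform placements of the group; 100 such videos give the reference
distribution of video-level means, and the 95% band of those 100 means
is the gray reference band against which observed videos are classified
(below = aggregative, inside = random, above = overdispersed).

Two design choices deserve a note:

* **Procedural identity.** Null videos are genuine `video_track`
  objects pushed through the same `summarize_video()` code path as
  observed data (with zero acclimation frames, as a null video has no
  placement artefact), not a parallel shortcut implementation.
* **Percentile type.** The band is the empirical percentile interval of
  the simulated means computed with quantile type 6, for which the
  interval between order statistics *i* and *j* of *m* draws covers a
  fresh draw with expected probability (*j* − *i*)/(*m* + 1) — equal to
  the nominal level. The default quantile definition would give a band
  with ≈ 93% expected coverage at *m* = 100, i.e. a classifier that
  cries "non-random" too often. Classification happens on the log scale
  to match the inference layer; monotonicity of ln makes the verdict
  identical to linear-scale banding.

The null has a sharp external check: the expected distance between two
uniform points in a disk of radius *r* is \(128r/(45\pi)\), which is
6.5643 cm at *r* = 7.25. By linearity of expectation the grand mean is
the same for every group size — only the spread shrinks as more pairs
are averaged per frame — and the Monte Carlo grand means for *n* = 2,
5, 6, 8 agree with the closed form to well under 1% at the sizes the
test suite uses.

## Inference

The unit of replication is the video (individuals within a dish are not
independent). Three tools cover the designs:

* `one_way_anova()` — classical fixed-effects one-way ANOVA on log mean
  pairwise distance, reported with its full sums-of-squares
  decomposition so F can be audited against hand arithmetic. Welch's
  correction is deliberately not applied; a variance-ratio diagnostic
  is attached but not enforced. Zero residual variance with unequal
  means is reported as an infinite F with a flag rather than an error;
  fully constant data are an error.
* `tukey_hsd()` — all-pairs comparisons via the studentized range
  distribution, with the Tukey–Kramer harmonic adjustment for unequal
  group sizes (the assay's designs are unbalanced). With two groups the
  adjusted p collapses to the pooled-variance t test (q = t√2), which
  the tests verify numerically.
* `compare_with_null_group()` — the "vs. random" contrast is an
  ordinary Tukey comparison in which the 100 simulated null video means
  enter as one pseudo-group of 100 log values. All 100 are entered
  (rather than subsampling to match treatment n); the choice is exposed
  through the `null` argument, since a caller can always rebuild a
  smaller null. The band classification of each treatment's mean is
  reported alongside, because a figure-style verdict and a p value
  answer subtly different questions.
* `continuous_predictor_anova()` — the latitude-style test: simple
  linear regression of the log statistic on a covariate, F with
  df (1, N − 2).

p values are reported at full floating precision with no correction
beyond Tukey's family-wise control. Group sizes are analysed
separately throughout, because the attainable distance range shrinks
as larvae are added to a fixed dish.

## The synthetic-movement generator

The assay's original videos are not available, so the package ships a
generator whose sole purpose is controllable ground truth. It is a
biased random walk, not a mechanistic larva model:

* Individuals start equidistant on the perimeter (random rotation),
  exactly like the live assay.
* Each 15-s step is \(L\,[(1-|a|)\,\varepsilon + a\,u]\): ε an
  isotropic unit vector, *u* the unit vector toward the centroid of
  neighbours within `interaction_range_cm` (nearest individual if none
  in range — the fallback that keeps the rule meaningful at *n* = 2),
  `a` ∈ [−1, 1] the attraction, and *L* ∼ |N(`step_cm`,
  `step_sd_cm`)|.
* The wall reflects: overshoot beyond radius *R* is folded back to
  2*R* − *r*. Absorbing or sliding walls were rejected because they
  destroy the uniform-disk equilibrium of the unbiased walk, which is
  the property that makes `attraction = 0` a usable negative control.

Defaults: `step_cm = 0.5` per 15 s (the order of a larva body length —
a convention, as no quantitative movement data exist for this system),
`step_sd_cm = 0.25`, and `interaction_range_cm = 15`. The range default
exceeds the dish diameter on purpose: within a 14.5-cm arena larvae
plausibly perceive conspecifics anywhere in the dish, and a short range
has a pathological regime — under strong attraction, two tight clusters
farther apart than the range become mutually invisible (each animal's
nearest neighbour is a cluster-mate) and never merge, breaking the
monotone attraction–aggregation relationship the generator exists to
provide. Users exploring local-interaction dynamics can still narrow
the range explicitly.

What the generator does and does not emulate: it produces the right
*geometry* (arena, start configuration, cadence) and a tunable, monotone
aggregation signal; it does not model feeding sites, pheromone trails,
wall-following, circadian structure, or individual variation. Passing
tests therefore demonstrate that the pipeline measures what it claims
on tracks with known structure — not that real larvae move like the
model.

One mixing caveat, documented rather than hidden: at the default step
length the walk traverses only ~1.7 cm (RMS) between consecutive
analysed frames, so the 18 retained frames of an `attraction = 0` video
are autocorrelated. Its long-run mean matches the CSR expectation, but
video-level means spread wider than the null band built from 30
*independent* frames, so somewhat fewer than 95% of zero-attraction
videos classify as "random". The tests assert the replicate-averaged
mean and a majority-random classification for this case; exact 95%
calibration is asserted where it actually holds, for CSR-generated
videos.

## Problem sizes and numerical conventions

The test suite and the acceptance script rescale the Monte Carlo work
to what the checks need: 10,000 null videos pin the *n* = 2 grand mean
to ≪ 1% (the spec of the closed form), 3,000 suffice for the
group-size-invariance check, band calibration uses 1,000 fresh CSR
videos against 100 independently rebuilt 100-video bands (the
between-band variance is part of the reported standard error), the
ANOVA type-I rate uses 1,000 replicates of 3 × 5 CSR groups, and the
feeding/nonfeeding recovery uses 30 full-length replicate experiments.
All randomness flows from explicit seeds; identical seeds give
bit-identical distributions, tracks and output files, and every
pipeline run writes a manifest with its seed and a config hash.

## Known limitations

* The movement model's attraction parameter is not an estimate of any
  biological quantity; only its sign and ordering are meaningful.
* The CSR null ignores wall-following, which real larvae may exhibit in
  a dish; a wall-biased null would shift the band upward.
* Classification uses the group *mean* against the band, as the figures
  do; single videos near the band edge carry the usual multiple-look
  caveats.
* Mixed models, repeated measures and phylogenetic corrections are out
  of scope; the video is the unit of replication throughout.
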