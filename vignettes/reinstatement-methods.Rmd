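---
title: "Temporal-context reinstatement analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-context reinstatement analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinstatr)
```

## The scientific problem

When an image is encountered repeatedly over days to months, each encounter
happens in a different temporal context. Temporal-context models of episodic
memory hold that a slowly drifting ensemble representation — carried in
humans by hippocampal CA1 and entorhinal cortex — is bound to each event, and
that *reinstating* the first encounter's context during later encounters
strengthens the association that lets people later judge *when* the image was
first seen. The analysis battery in this package operationalizes that idea
for continuous-recognition fMRI experiments: if trial-level activity
patterns at re-exposures resemble the pattern at the first exposure
(high exposure-pair similarity), memory for the first exposure's temporal
position should be more precise; and this should be (a) specific to the
E1–E2 pair, which is the first opportunity to reinstate, (b) dissociable
from recognition confidence (overall memory strength), and (c) driven by
image-specific rather than session-level or generic signals.

## Behavioral scoring

Timeline estimates suffer a center-of-timeline response bias, so both
estimated and actual first-exposure positions are converted to
within-participant midranks before any analysis; temporal memory error is
the absolute rank difference, and a per-participant median split labels
items high- vs low-precision. Design choices where conventions were open:

* **Ties in ranks** get the average rank (midranks), which conserves the
  rank sum `n(n+1)/2`.
* **Ties at the median** go to the low-precision class (`error >= median`
  is "low"); the split is deterministic and the imbalance it can introduce
  is bounded by twice the number of values tied with the median.
* **Chance test statistic**: mean temporal error, recomputed after
  shuffling the estimated ranks across images within participant
  (1000 permutations by default). The p-value is the plain proportion of
  null statistics at or below the observed mean; an add-one conservative
  variant is available (`conservative = TRUE`). For `n` items the null mean
  has the closed form `(n^2 - 1) / (3n)`, which the tests verify.
* **Temporal lags** (start→E1, E1→E2, E2→E3, E3→final test) are expressed
  in seconds and natural-log transformed, with intervals floored at 1 s so
  the first trial's lag is defined (log 1 = 0).
* **Recognition**: hits and false alarms use the old/new boundary of the
  1–6 confidence scale (>= 4 = "old"); d' applies the standard 1/(2N)
  correction to extreme rates. The low/medium/high confidence bins default
  to {3,4}, {2,5}, {1,6} — pairing ratings equidistant from the boundary —
  and are configurable, since any such mapping is a convention.
* **Accuracy model**: estimated rank on actual rank with per-participant
  random intercepts *and* slopes, falling back to intercepts only when the
  random-slope fit is singular.

## Representational similarity

For each tested image and ROI, Pearson correlations are computed between
the voxel patterns of the three exposure pairs, Fisher-z transformed
(`atanh`), and averaged over *valid* pairs. A pair is valid only if its two
exposures occurred in different scanning runs (session and run jointly
identify a run): same-run pairs share slow scanner noise that inflates
similarity. Images with no valid pair are excluded from mean-similarity
analyses. The high/low permutation statistic is the across-participant mean
of the within-participant difference in mean similarity between
high- and low-precision images; the null shuffles precision labels within
participant, respecting the within-participant design. Correlations are
computed on amplitude patterns as stored, with no extra voxel-wise
normalization.

## Mixed-effects inference

Trial-level links between similarity and memory use mixed models with a
random intercept per participant — the minimal structure for repeated
measures per participant: logistic (log-odds scale, Wald z tests) for the
binary precision label, Gaussian for confidence treated as numeric.
Predictors enter unstandardized (`standardize = TRUE` is available). All
fits are maximum likelihood (never REML) so that nested models are
comparable by likelihood ratio: `chi2 = -2 (logL_reduced - logL_full)` with
df equal to the difference in fixed-effect counts. Confidence intervals are
Wald (`beta ± 1.96 se`). Bonferroni correction (`min(1, m p)`) is applied
across ROIs for the headline tests, with `m` defaulting to the number of
ROIs tested.

Numerical choices: logistic fits use the Laplace approximation with the
bobyqa optimizer (the nlopt default occasionally trips lme4's gradient
check with spurious warnings at max|grad| just above tolerance); singular
boundary fits are flagged separately from genuine non-convergence, and
non-converged fits propagate a flag that downstream consumers must check.
A response that is constant within every participant is refused rather
than fitted, since the random-intercept likelihood degenerates.

## Image-specificity analyses

Two resampling analyses ask whether the similarity→precision link is
carried by image-specific information:

1. **Shuffled-mapping null.** Each image's E1 is re-paired with a different
   image's E2 within participant (uniform permutation with self-pairings
   redrawn — a derangement is not required, only excluded), the E1–E2
   similarity and the corresponding E1→E2 lag are recomputed, and the
   logistic model is refitted, yielding a null distribution of similarity
   coefficients. Re-paired exposures falling in the same run are excluded
   exactly as in the intact analysis. Only lag 1 is recomputed under the
   shuffle (lags 0, 2, 3 belong to the target image, whose precision label
   is being predicted). Because the null requires ~1000 refits, both the
   observed and every null coefficient are estimated with the fast nAGQ = 0
   (penalized-least-squares) variant of the same GLMM, built once and
   updated per permutation; using the identical estimator on both sides
   preserves the exchangeability that the proportion p-value relies on.
2. **Target-vs-foil difference.** Foils for a target share its E1 session
   and E2 session but differ in run at both exposures (read distributively
   from the matching rule), and must have received the same
   continuous-recognition judgments as analysis targets: correct rejection
   at E1, hits at E2 and E3. Foil similarity is the median Fisher z of
   r(target E1, foil E2) when two or more foils exist; the difference
   (target − foil) enters the logistic model as predictor. Targets with no
   qualifying foil are excluded and counted.

## The synthetic experiment generator

The generator emulates the structure the analyses assume, with exported
ground truth so every pipeline stage can be tested for parameter recovery:

* **Design.** Each of `n_images` images appears exactly three times;
  repeats land in the same session as the previous exposure with
  probability `p_within_session_repeat` (default 0.3) and otherwise in a
  later session chosen with probability proportional to its free trial
  slots (which keeps late sessions from jamming and the realized
  same-session rate at the nominal value). Spare slots become
  single-exposure fillers, as in a real continuous-recognition stream where
  most trials are never probed again. Sessions are separated by one
  simulated day (86,400 s), giving day-scale log lags; trials last 4 s.
  The default study size — 8 participants, 10 sessions × 5 runs × 15
  trials, 150 probed images — is a desk-scale version of a many-session
  continuous-recognition experiment, chosen so the full battery runs in
  minutes while keeping ~100+ analysis images per participant.
* **Patterns.** Per trial, `x_t = s_img + c_t + noise`, where `s_img` is a
  fixed per-image vector and the context `c_t` is a shared per-session
  component plus a stationary first-order autoregressive
  (Ornstein–Uhlenbeck) drift with timescale `tau` (default 30 trials,
  with an extra session's worth of drift inserted at session boundaries).
  The OU form is the simplest stationary drift with the closed-form
  autocorrelation `exp(-lag/tau)` that the tests verify. At re-exposures
  the context component becomes `w c_ref + sqrt(1 - w^2) c_t`: for a
  "precision" region `w = rho_i` (the image's reinstatement strength,
  Beta(2,2) by default) with `c_ref` the trial-specific E1 context; for a
  "confidence" region `w = m_i` (an independent memory-strength latent) at
  E3 only; for a "session" region `c_ref` is the E1 *session* component
  with constant weight — coarse temporal context carrying no
  image-specific information, which is exactly what the specificity
  analyses must reject.
* **Behavior.** The timeline estimate is the true normalized E1 position
  plus Gaussian noise with sd `sigma0 exp(-kappa_precision rho_i)`,
  truncated to [0, 1] (ranks downstream are insensitive to truncation
  except at the extremes); confidence is a fixed monotone discretization
  of `kappa_confidence (m_i - 1/2) + bias + noise` onto 1–6. Correctness
  flags are Bernoulli with rates 0.9/0.92/0.94, retaining ~79% of images
  for analysis, comparable to selection rates in real continuous-
  recognition studies. Defaults `sigma0 = 0.25`, `kappa_precision = 2`,
  `kappa_confidence = 2` give hit − FA differences near 0.3, d' near 2,
  and a similarity→precision effect detectable but not trivial at the
  default study size.

What the generator does *not* emulate: hemodynamic dynamics and HRF
variation, voxel-level noise correlations, motion and physiological
artifacts, semantic structure among images, and response-time effects.
Passing tests therefore demonstrate that the pipeline's statistics recover
the couplings they target under a faithful generative model of the
*design*, not that real fMRI data meet the model's assumptions. One
caution learned from the generator itself: pushing `rho` toward 1 while
increasing `kappa_precision` *saturates* rank-scale precision (everyone is
near-perfect) and destroys the very coupling being planted; moderate
spread in `rho` is what carries the effect.

## A calibration caveat for the unadjusted permutation test

The test battery surfaced one structural property worth knowing: under a
complete null (no precision coupling, no reinstatement variance), the
lag-adjusted GLMM rejects at the nominal 5% rate, but the *unadjusted*
high/low label-shuffle test over-rejects substantially. The cause is design
geometry, not a defect of the shuffle: (i) rank-based temporal error is
bounded, so items near the ends of the timeline mechanically receive
smaller errors and hence "high-precision" labels more often; (ii) any
drifting context signal makes exposure-pair similarity decrease with the
lag between exposures, and late-first-exposure images have compressed
lags; so labels and similarity share lag-driven variance even when no
item-level coupling exists. The label shuffle preserves neither margin, so
its one-sided p is anticonservative. This is precisely the recency/lag
confound that motivates including the four log-lag covariates in the
mixed-model analyses, and it is why conclusions here should rest on the
lag-adjusted models; the unadjusted permutation difference is a useful
descriptive statistic, not a calibrated test, whenever similarity carries
temporal-distance structure.

## Problem sizes used by the test battery

Calibration checks (null rejection rates of the high/low permutation test
and the similarity GLMM) use 200 replicates at the default study size.
Planted-effect recovery and the precision/confidence dissociation use 20
replicates at the default size; the image-specificity replicates use 6
participants × 120 images with 1000-permutation nulls, a size at which the
pilot effect was reliably detectable. These sizes are the package's chosen
trade-off between Monte-Carlo error and a test battery that completes in
minutes on one CPU.

## Known limitations

* Random-effects structure is intercept-only for the trial-level models;
  random slopes for similarity are plausible but left out as the minimal
  stated structure.
* Confidence is modeled as numeric Gaussian; an ordinal model would
  respect the 1–6 scale better but is out of scope.
* The shuffled-mapping null recomputes only lag 1; if re-paired E2s also
  changed other lag covariates in a real design, that choice would need
  revisiting.
* Wald (not profile) confidence intervals throughout.
* The two-component repeat-spacing model reproduces the short/long lag
  mixture of real continuous-recognition designs but not any specific
  placement distribution.
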