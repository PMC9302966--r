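---
title: "Models and methods behind oneshotadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oneshotadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oneshotadapt)
```

`oneshotadapt` analyzes experiments in which a speaker's first-formant (F1)
auditory feedback is unpredictably shifted on a subset of trials. This
vignette documents the measurement model, the statistical procedures, the
synthetic-data generator used to validate them, and the numerical and design
choices a user should know about.

## Measurement model

All frequencies are carried in mels, m = 2595·log10(1 + f/700). The
constants are exposed in `hz_to_mel()`/`mel_to_hz()` because more than one
mel convention circulates in speech acoustics; this pair is the one used by
the common real-time perturbation systems, so magnitudes expressed this way
line up with the applied shifts.

A trial's trajectory is uniformly sampled F1 from vowel onset (t = 0),
default step 5 ms. Source recordings rarely share a native frame rate, and
the analysis windows are stated in milliseconds, so the package assumes the
input table is already on a uniform grid and simply checks it; 5 ms puts
20 samples in the narrowest (100 ms) analysis window, comfortably more than
needed for window means while keeping permutation matrices small.

Roles are assigned by session order: perturbed trials (up/down), post-up and
post-down trials (unperturbed trials whose *immediately preceding* trial,
by consecutive index, was perturbed), and baseline trials. Adjacency never
looks back more than one trial: the one-shot response is defined as the
aftereffect of a single exposure, and a gap in the index sequence breaks
adjacency rather than guessing.

Each trial is normalized by subtracting its participant- and word-specific
baseline mean trajectory, computed pointwise across the baseline trials at
each time point and truncated at the last point where at least
`baseline_min_n = 3` trials contribute — beyond that the "mean" would rest
on one or two unusually long vowels. Two baseline pools exist:

- **Compensation baseline**: all unperturbed trials. Post-perturbation
  trials are unperturbed, so by default they stay in this pool; since they
  carry the (small) one-shot aftereffect, `include_post_in_comp_baseline =
  FALSE` removes them as a sensitivity check, and `comp_baseline_role =
  "adapt"` restricts the pool to unperturbed-after-unperturbed trials
  entirely. With balanced up/down schedules the aftereffects largely cancel
  in the pooled mean, which is why the inclusive pool is a reasonable
  default.
- **Adaptation baseline**: unperturbed trials that directly follow another
  unperturbed trial, so the reference for the one-shot measure is
  guaranteed free of the effect being measured.

Scalar responses are means of the normalized trajectory over half-open
windows `[t0, t1)`: compensation over [150, 250) ms (past the ~100–150 ms
feedback latency), adaptation over [0, 100) ms (before feedback can act on
the current trial). The half-open convention makes windows tile without
double-counting shared edges; with windows much wider than the sampling
step, the choice is numerically immaterial. An alternative adaptation
window [50, 150) ms that skips the consonant transition is available via
`adapt_window = c(50, 150)`. A window value is reported missing when the
vowel covers less than `min_coverage = 0.5` of the window's grid points:
many vowels end inside the compensation window, and a mean over a sliver of
it measures mostly onset noise. Participant-level responses average the
normalized trajectories pointwise *first* and then take the window mean
(average-then-window); with unequal vowel lengths this weights each time
point by the trials that reach it, which is not the same as averaging
trial-level window means.

Sign correction multiplies responses from upward-shift conditions by −1,
putting both directions on a scale where positive values oppose the shift.
Direction models intentionally run on raw values (the direction contrast
*is* the effect); relationship analyses require sign-corrected input and
refuse anything else, and `sign_correct()` refuses to run twice.

Exclusions: vowels shorter than 100 ms are dropped (too short to carry the
windows), and participant sessions whose direction-collapsed average
compensation or adaptation lies more than 4 SD from the across-session mean
are screened out in a single, non-iterative pass. A single pass with means
and SDs computed over everyone is deliberately conservative; note that with
fewer than ~18 sessions no point *can* exceed 4 SD of a sample that
includes it, so the screen only bites at realistic cohort sizes.

## Inference

**Direction models.** `response ~ direction + (1 | participant) + (1 |
study)`, REML, with Satterthwaite degrees of freedom via lmerTest.
Treatment coding with "down" as reference makes the coefficient the
up-minus-down difference, so opposing responses give negative β. Per-term
effect size is d = β / residual SD, and partial η² is t²/(t² + df) — the
standard coefficient-level approximation; it is labeled as partial in the
output because η² definitions vary. A random term whose grouping factor has
fewer than two levels is unestimable and is dropped with a record in the
result (`dropped_random`); a singular fit is flagged but kept, since
zeroed variance components do not bias the fixed effects.

**Cluster-based permutation tests.** Per-participant condition-average
normalized trajectories on the 0–250 ms grid are tested against zero (or
between conditions, paired) with a one-sample t at each time point. Time
points with |t| above the two-tailed critical value at `alpha_point = 0.05`
are marked; maximal runs of marked points with the same sign form clusters
scored by the sum of their t values. The null distribution of the maximum
absolute cluster mass is built from random sign flips of whole participant
trajectories — for the paired contrast a sign flip of the difference is
exactly a condition-label swap, which is why the between test is paired
(the design is within-participant). Cluster p uses the add-one convention
p = (1 + #exceedances)/(1 + n_perm), which never reports exactly zero;
`n_perm = "exhaustive"` enumerates all 2^n assignments and then reports
exact proportions instead. Participants contribute only at time points
their average covers; trailing points with fewer than 3 contributors are
dropped from the tested range with a warning. The default `n_perm = 10000`
makes the Monte-Carlo error on p ≈ 0.05 about ±0.004; tests in this package
use 100–2000 permutations to keep runtimes short.

**Relationship analyses.** Each post-perturbation trial's adaptation is
paired with the compensation of the perturbed trial directly before it
(participant level: the two directional averages per session). The model is
`adaptation ~ compensation + magnitude_norm + direction +
compensation:magnitude_norm + (1 | participant)`, where `magnitude_norm` is
the shift magnitude divided by its grand mean so that predictors share a
common scale (the mean normalized magnitude is exactly 1). Study is not a
random intercept here — it is collinear with participant and magnitude —
and no random compensation slope is included. When every pair shares one
magnitude the magnitude main effect and interaction are unidentifiable;
the model drops them and says so in `$note` rather than returning aliased
coefficients. Word identity across the perturbed/post pair is not required
by default (most multi-word sessions mix words across the pair);
`same_word_pairs = TRUE` restricts to same-word pairs as a sensitivity
analysis.

**Per-participant correlations.** Pearson's r between compensation and the
following adaptation, per participant session with at least `min_pairs =
10` pairs, Fisher-transformed (z = atanh r), t-tested against zero, and the
mean z back-transformed for interpretation. |r| = 1 (degenerate input) is
clamped to 1 − 1e−12 with a warning so z stays finite. A secondary check
correlates each participant's r with their overall adaptation magnitude, to
ask whether the coupling is confined to strong adapters.

## The synthetic-data generator

`simulate_experiment()` draws complete experiments from an explicit
generative model so that every pipeline stage can be validated against
known ground truth:

- word baseline b_w(t) = target + onset_offset·e^(−t/τ), an exponential
  rise out of the consonant (onset_offset = −80 mels, τ = 30 ms, targets
  ~740 mels ± 45 between participants ± 15 between words — typical /ɛ/
  values for adult speakers);
- compensation c(t) = −sign(shift)·g_c·|shift|·ramp(t), a piecewise-linear
  ramp from 0 at 120 ms to full value at 200 ms — the simplest monotone
  shape consistent with an onset latency of 100–125 ms;
- one-shot adaptation a = −sign(previous shift)·g_a·|previous shift|,
  constant across the vowel (the aftereffect is feedforward, present from
  onset), injected only on the single trial after a perturbation;
- noise: a per-trial offset (SD 30 mels) plus within-trial Gaussian noise
  (marginal SD 20 mels) smoothed by a 25 ms moving average.

Schedules place round(p·n) perturbed trials (up/down balanced within one)
uniformly at random, re-drawing until the configured minimum counts of
post-up, post-down and baseline pairs exist; words cycle over shuffled
blocks of the word list. Shift magnitudes are constant within participant
(mean 125 mels, the modal study value; a between-participant SD is
available for designs with participant-specific shifts). Durations are
log-normal (median 220 ms, clipped to 100–400 ms) with a configurable 1%
of sub-100 ms vowels to exercise the duration filter. Per-participant
gain pairs (g_c, g_a) are bivariate normal; defaults g_c = 0.05 ± 0.08,
g_a = 0.015 ± 0.04, correlation 0.4.

The effect and noise scales were fixed once from the published statistics
of the multi-study dataset this design emulates: a trial-level response
noise near 33 mels (implied by a direction effect of ~7 mels with
per-coefficient d ≈ 0.2), mean responses of a few mels for compensation
and 1–2 mels for adaptation, and between-participant spreads large enough
that individual sessions can oppose or follow the shift. A single gain per
participant per measure cannot reproduce *every* published statistic at
once — real up/down responses are not exact mirror images, so one number
cannot match both the per-direction spread and the up-minus-down spread —
and the defaults sit between those two implied values. Consequences for
interpretation: passing parameter-recovery tests shows the estimators are
unbiased and correctly signed under this model; it does not certify
behavior under direction-asymmetric responses, non-Gaussian noise,
drifting baselines, or generalization across words, none of which the
generator models.

All randomness flows from the single `seed` through named substreams
(participants, schedule, durations, noise; the analysis pipeline adds a
permutation substream), so experiments are bit-reproducible and changing
one stage's draw count does not silently reseed another.

## Validation strategy and problem sizes

The test suite validates each stage against independent recomputation
(brute-force loops for window means, baselines, normalization and the
outlier screen; a separately written rle-based cluster implementation with
full 2^n enumeration at n = 4), then checks the assembled pipeline on
simulated experiments: null simulations (all gains zero; 200 experiments of
20 participants × 120 trials) for family-wise and per-model false-positive
rates, recovery runs (40 × 240, g_c = 0.05, g_a = 0.015, shift 125 mels)
for unbiasedness and effect ordering, and coupling runs at the pooled-study
scale (131 sessions × 240 trials) for the relationship machinery, with 500
uncoupled participants to confirm the per-participant correlations center
on zero. These sizes mirror the emulated studies (sessions of 120–800
trials, 14–40 participants per study, 131 sessions pooled).

## Known limitations

- The pipeline takes vowel onset and F1 tracks as given; no audio, formant
  tracking, or onset re-estimation.
- F2 is out of scope; two-dimensional shifts must be projected onto F1
  ("up"/"down") upstream.
- One-shot adaptation is modeled and measured strictly one trial back;
  multi-trial carryover would bias the baseline pools if present in real
  data.
- Stepwise model simplification is not applied; the stated models are
  fitted in full.
- The cluster test assumes exchangeability of sign flips across
  participants (symmetric null), the standard assumption of the method.
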