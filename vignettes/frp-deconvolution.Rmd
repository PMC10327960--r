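---
title: "Deconvolution of fixation-related potentials with refixation categorization: models and methods"
author: "frpdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FRP deconvolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In free viewing, the gaze frequently returns to locations visited seconds
earlier. Three functional categories of fixations arise from this revisit
structure: *precursor fixations* (the first visit to a location the eyes
later return to), *refixations* (the returns themselves), and *ordinary
fixations* (locations visited exactly once). If return plans are prepared
already at the first visit, the EEG time-locked to precursor fixations —
the fixation-related potential (FRP) — should differ from the other
categories.

Two obstacles stand between raw co-registered EEG and that comparison:

1. **Overlap.** Fixation-locked EEG responses outlast fixations (mean
   duration here about 247 ms, responses 500 ms and longer), so each
   epoch is a superposition of the responses to several consecutive
   saccades, plus the stimulus-onset response.
2. **Oculomotor covariates.** Low-level properties of the eye movements —
   incoming saccade size (lambda wave amplitude), fixation rank within the
   trial (late FRP amplitude), fixation duration, vertical position —
   modulate the EEG and differ systematically between categories.

The package implements the standard answer: regression-based
deconvolution. A single sparse linear model spans the continuous
recording; each event contributes a set of time-lagged predictors, so
overlapping responses are unmixed by least squares, and nonlinear
covariate influences are absorbed by spline regressors.

## Fixation categorization

`label_fixations()` applies the revisit rules per trial, with a strict
Euclidean criterion `distance < radius` (default 2 degrees of visual
angle; ties at exactly the radius are a measure-zero event and count as
outside):

* a **refixation** must (i) lie within the radius of an earlier fixation,
  (ii) after the gaze left that fixation's region (at least one
  intervening fixation outside the radius), and (iii) enter the region
  from outside — its immediate predecessor is not within the radius.
  Consequently a run of consecutive fixations inside one region yields at
  most one refixation, the first return; later run members go to the
  leftover category.
* the **precursor** of a refixation is the earliest qualifying earlier
  fixation; a refixation within the radius of several mutually close
  fixations is scored once. Several refixations may share one precursor,
  so refixations are at least as numerous as precursors.
* a fixation qualifying as both precursor and refixation keeps neither
  label (category `other`), removing any ambiguity in assigning
  fixation-locked EEG.
* fixations immediately preceding a refixation carry preparatory activity
  specific to the upcoming return; by default (`drop_pre_refixation`)
  they are reassigned to `other`. They are reassigned, never deleted:
  the deconvolution model must contain *every* fixation, or the
  uncorrected overlap would leak into the categories of interest.
* **ordinary** fixations are fixations "without history": no other
  fixation of the trial lies within the radius. Everything else —
  same-spot chains (which qualify equally as refixation of the previous
  and precursor of the next fixation), revisited locations whose
  precursor role was not attributed — is `other`.

Where the source rules admit two readings (what happens to later members
of a refixation chain; whether a chain's first-visit fixation can keep a
precursor label), we resolved them as above: the first return and its
attributed precursor keep their labels, all other chain members do not.
A brute-force reference labeler that enumerates all fixation pairs
independently encodes the same rules; the test suite checks exact
agreement on thousands of random scanpaths.

`merge_ordinary_other = TRUE` reproduces the merged-reference variant
(ordinary and leftover fixations as a single level) by relabeling before
the design is built.

## The deconvolution model

Per event type the default model (`default_model_formula()`) is, in
Wilkinson notation,

```
fixation:  y ~ 1 + category + spline(rank, 5) + spline(duration, 5)
               + spline(incoming_size, 5) + spline(outgoing_size, 5)
               + spline(y_position, 5)
stimulus:  y ~ 1
```

* The four-level fixation category is treatment-coded against the
  leftover `other` category, so the three dummies are differential FRPs
  relative to it. In a linear model the choice of reference is
  immaterial once marginal waveforms are compared; a test refits with a
  permuted reference and checks the category differences are unchanged.
* Each continuous covariate enters through a five-function cubic
  B-spline basis. Knots sit on the participant-specific equally spaced
  quantiles of the covariate, `n_basis - 2` of them, i.e. probabilities
  `seq(0, 1, length.out = 3)` for five functions: the 0th, 50th and
  100th percentiles, with the boundary knots repeated to full cubic
  multiplicity. This is the only placement for which a cubic basis with
  quantile knots has exactly five functions *and* forms a partition of
  unity over the whole data range — both properties the design relies
  on (the identifiability drop below assumes the basis sums to one).
  With an intercept present one spline column per covariate (the first)
  is removed for identifiability, so each covariate contributes 4
  columns. Values outside the fitting range are clamped to the boundary
  knots. A basis needs at least 4 functions; requests for 3 are
  rejected.
* Total mass-univariate predictors: 1 intercept + 3 category dummies +
  5 covariates x 4 columns + 1 stimulus intercept = **25**.

`time_expand()` replicates every predictor over a lag grid covering
-200 to +500 ms. Lags follow the half-open sample convention
`round(t_min * fs) ... round(t_max * fs) - 1`, giving exactly **175**
lags at 250 Hz and **4,375** expanded columns. Event times map to the
nearest sample. Each event pastes its mass-design row at
`event_sample + lag`; overlapping events sum, which is precisely what
lets least squares separate them. Excluded intervals (inter-trial gaps,
artifacts, unwanted trials) are handled by `zero_out_intervals()`:
entire rows of the expanded design are set to zero, which removes those
samples' influence on the fit while preserving the timing of the
continuous recording.

## Estimation

`fit_deconvolution()` solves one sparse least-squares problem per channel
with LSMR, the iterative Golub–Kahan/MINRES-type algorithm for sparse
rectangular systems, implemented in the package over `Matrix` sparse
matrices. Numerical choices:

* deterministic start at zero; relative tolerances `1e-10`
  (`solver_options()`); iteration cap `10 * ncol(design)`, with a
  non-convergence flag in the diagnostics rather than an error;
* rank-deficient designs (an empty category level, say) converge to the
  minimum-norm solution — flagged, not hidden;
* channels are independent; fitting jointly or singly is identical, so
  large montages can be fit channel-subset by channel-subset.

Tests pin the solver to a dense SVD pseudoinverse on instances up to
2,000 samples x 200 columns (relative error below 1e-6), including
rank-deficient cases, and verify the classical limit: with isolated
events and no covariates the deconvolved coefficients equal the
event-locked average to 1e-8.

## Marginal FRPs, baseline, ROIs, windows

Raw dummy coefficients are difference waves; to compare categories on the
scale of classical FRPs, `reconstruct_marginal_frps()` evaluates every
spline at a fixed level (by default the participant's mean of each
covariate, clamped into the spline range) and adds the identical
covariate contribution to each category's waveform: reference =
intercept + spline terms at the mean; non-reference = reference + its
dummy. Category differences therefore remain exactly the dummy
coefficients and are invariant to the reference level and to which
spline column was dropped.

Windows are half-open `[t0, t1)` on the sample grid throughout, so the
adopted baseline 0–20 ms after fixation onset covers exactly 5 samples
at 250 Hz. The baseline is deliberately *post*-onset: in free viewing a
pre-saccadic window is contaminated by the previous fixation's response;
the first 20 ms after onset precede the earliest perceptual response.
`baseline_correct()` subtracts the window mean per channel and category
(idempotent, commutes with ROI averaging). A vetting recipe for the two
candidate baselines (-200..-100 ms vs 0..20 ms) is demonstrated in
`analysis/03_roi_stats.R`: compute window measures on uncorrected FRPs
in both candidates and require no category effect.

`roi_average()` averages seven channels (a landmark electrode and its
six neighbors) per ROI; the eight default ROIs around F3/F4/C3/C4/P3/P4/
O1/O2 consume 56 distinct channels and carry region x hemisphere factor
labels. `window_mean()` takes time means in the named analysis windows:
lambda 30–130 ms (the 100 ms window centered on the 80 ms lambda peak)
and late 200–400 ms.

## Group statistics

`rm_anova()` implements the classical fully within-subject decomposition
for one to three factors via orthonormal effect contrasts. Sphericity:
the Greenhouse–Geisser epsilon of the effect's contrast covariance feeds
the Huynh–Feldt step-up
`(n d eGG - 2) / (d (n - 1 - d eGG))`, capped at 1 and never below the
GG value; the correction multiplies both degrees of freedom and is
applied only to effects with at least two numerator degrees of freedom.
Tests verify the two-level identity F = t², agreement with
`stats::anova.mlm(test = "Spherical")`, and agreement with naive
cell-means sums-of-squares oracles.

`newman_keuls()` runs the stepwise studentized-range procedure on the
effect's (marginal or interaction-cell) means. The error term is the
effect's participant-by-effect mean square on the scale of means averaged
over the complementary cells — with two levels this reduces exactly to
the paired comparison (`q = sqrt(2) |t|`). Ranges are tested outside-in;
a nonsignificant range gates all nested comparisons, whose p values are
monotonized against the enclosing range. The error-term convention for
interaction cells follows the same rule and is fixed by these tests; the
original desktop statistics packages do not document theirs.

## The synthetic study and what it does (not) show

`simulate_scanpaths()` generates 8-second trials on a 30 x 30 degree
display. Defaults are the study conditions, set once:

| parameter | default | why |
|---|---|---|
| fixation duration | gamma, mean 247 ms, shape 6 | reported task mean; shape gives a realistic right-skewed spread |
| fixations per trial | ~32 (renewal filling of 8 s) | 8 / 0.247; onsets abut, saccade flight time folded into duration |
| saccade amplitude | gamma, mean 4.5 deg | a few degrees, typical of search in dense displays |
| revisit probability | 0.14 per fixation | yields ~7% precursor / ~8.5% refixation shares, matching the reported per-participant category counts |
| intervening fixations | 4 + Poisson(5), mean 9 | reported mean revisit lag of 9 intervening fixations |
| revisit jitter | <= 0.7 deg | returns land well inside the 2-degree radius |
| minimum separation | 2.5 deg | new locations stay outside each other's radius, keeping the category structure controlled |
| EEG noise | white, 5 uV per sample | moderate single-trial SNR for band-limited cleaned EEG |

`make_default_truth()` supplies the forward model: a lambda-like
occipital positivity peaking at 100 ms whose amplitude follows a
saturating function of incoming saccade size; a late negativity around
300 ms scaled linearly by fixation rank; a precursor-specific
raised-cosine negativity supported exactly on 200–400 ms (window mean
-1.5 uV, i.e. peak -3 uV); and a stimulus-onset kernel. Effect
functions are normalized to 1 at the sample mean, so the marginal
category waveforms at mean covariate levels equal the raw kernels — the
ground truth the recovery tests compare against. The `"null"` preset
zeroes the precursor offset. Category-dependent saccade asymmetries
(larger incoming, smaller outgoing saccades at precursors) are available
behind `saccade_asymmetry = TRUE` so the pipeline can be exercised with
and without category-covariate confounding; the default keeps them off
so kernel recovery isolates the overlap problem.

What the generator deliberately does **not** emulate: ocular artifacts
and their cleaning (the simulated EEG is artifact-free by construction),
1/f background spectra (white noise by default), biophysical head
models (topographies are fixed weight vectors), the actual search
stimulus, or the heterogeneous "other" fixations of real data (the
reported ~16% leftover share includes ambiguities a clean generator
cannot create; ours is ~8.5%). Passing recovery tests therefore show the
*estimator* is correct under the linear-superposition model — not that
real recordings satisfy that model.

### Problem sizes and the two-tier power design

The test suite and the acceptance script fit one full participant
end-to-end: 70 trials, ~2,300 fixations, a 175,000-sample x 4,375-column
sparse design, four channels. That scale was chosen as the smallest one
at which the overlap structure is representative (over 2,000 fixation
events at the 247 ms overlap scale) while a desk-scale run stays
pleasant; recovery margins are wide (category NRMSE under 0.07 against a
0.15 bound).

Group-level power is assessed hierarchically. A replicate-level Monte
Carlo of the *full* EEG pipeline for 21 participants x 200 replicates
would add nothing statistically — the single-participant fit shows the
measurement stage recovers the late-window offset within a few percent
with estimation noise an order of magnitude below the between-participant
spread — so `category_power_sim()` draws the late-window window-measures
directly from the generator's group model: precursor offset scaled by
region topography, participant (SD 1.5 uV) and participant-by-category
(SD 0.35 uV) random effects, and cell noise (1.0 uV residual plus 0.2 uV
measurement error in quadrature). The default offset (-1.5 uV window
mean) was fixed a priori from the noncentral-F power of the category
main effect in the 3 x 4 x 2 design at n = 21 (analytic power > 0.95 at
alpha = 0.05). The companion `anova_type1_sim()` verifies the corrected
test's size under a compound-symmetric null.

## Degenerate inputs and tie-breaks

* Unsorted fixation tables, overlapping fixation intervals, non-finite
  positions: rejected.
* First/last fixations lack an incoming/outgoing saccade: covariates are
  imputed at the participant median so every fixation enters the model.
* The following-fixation duration is recorded only when the next
  fixation is `ordinary`/`other` (category-specific preparation would
  otherwise leak into the covariate); it is descriptive and not part of
  the default model.
* Distance ties at exactly the radius count as outside (strict `<`).
* Empty event lists time-expand to an all-zero design with a warning;
  all-zero designs fit to all-zero coefficients (minimum-norm).
* Covariate means outside the spline boundary are clamped before
  evaluation.

## Known limitations

* No regularized or temporal-basis deconvolution, no spline
  interactions, no cross-validated model selection.
* Circular statistics for saccade angles are not implemented; angle
  summaries are descriptive.
* The ROI machinery assumes the montage provides all listed channels;
  real high-density layouts must supply their own `roi_spec()`.
* `rm_anova()` requires complete balanced designs — by design, since the
  upstream pipeline always produces one measure per participant and
  cell; missing cells are an error, not an imputation.
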