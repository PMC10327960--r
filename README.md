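# frpdeconv

Overlap-corrected fixation-related potentials (FRPs) for free-viewing
EEG / eye-movement co-registration, with scanpath refixation
categorization — for researchers who need to compare EEG between
*precursor fixations* (first visits to locations the gaze later returns
to), *refixations* and *ordinary fixations* without the estimate being
distorted by overlapping responses of consecutive saccades or by
oculomotor covariates.

## What it computes

1. **Categorization** — rule-based labeling of fixations by revisit
   structure (2° radius, region must be left and re-entered, chains and
   double-role fixations to a leftover `other` category, pre-refixation
   fixations reassigned so every fixation stays in the model).
2. **Deconvolution** — a single sparse linear model over the continuous
   EEG. Per event type (Wilkinson notation):

   ```
   fixation:  y ~ 1 + category + spline(rank,5) + spline(duration,5)
                  + spline(incoming_size,5) + spline(outgoing_size,5)
                  + spline(y_position,5)
   stimulus:  y ~ 1
   ```

   Treatment coding against `other`; cubic B-splines with
   participant-specific quantile knots (one column dropped per covariate
   for identifiability): 25 mass-univariate predictors, time-expanded
   over −200…+500 ms at 250 Hz into 175 lags / 4,375 sparse columns.
   Excluded intervals are zeroed row-wise; coefficients are estimated
   per channel by LSMR (iterative sparse least squares, minimum-norm
   under rank deficiency).
3. **Marginal FRPs** — per-category waveforms reconstructed at mean
   covariate levels, baseline-corrected 0–20 ms post-onset, averaged
   into eight 7-electrode ROIs (F3/F4/C3/C4/P3/P4/O1/O2), summarized in
   the lambda (30–130 ms) and late (200–400 ms) windows.
4. **Group statistics** — repeated-measures ANOVA with Huynh–Feldt
   sphericity correction and Newman–Keuls stepwise post hocs.
5. **Synthetic ground truth** — a scanpath generator with revisit
   structure and a forward EEG model (lambda wave scaled by saccade
   size, rank-scaled late negativity, precursor-specific 200–400 ms
   offset, stimulus kernel, seeded noise) for end-to-end recovery
   testing.

## Worked example

```r
library(frpdeconv)

# one synthetic participant: 70 trials x 8 s, ~2,300 fixations
sim <- simulate_participant(scanpath_config(n_trials = 70), seed = 202)

ev  <- sim$events
md  <- build_mass_design(ev, default_model_formula())
xd  <- time_expand(md, round(ev$onset * 250) + 1L, c(-0.2, 0.5), 250,
                   sim$eeg$n_samples)
bet <- fit_deconvolution(sim$eeg, xd, channels = c("O1", "O2", "P3", "F3"))
frp <- baseline_correct(reconstruct_marginal_frps(bet))

lw  <- which(frp$times >= 0.2 & frp$times < 0.4)
mean(frp$waves$precursor[c("O1","O2"), lw] -
     frp$waves$ordinary [c("O1","O2"), lw])
```

Running `analysis/02_deconvolve.R` (which is this example plus the
comparison against naive averaging) prints:

```
Mass design: 25 predictors; expanded: 175124 x 4375

Kernel recovery at O1 (normalized by true peak-to-peak):
   category nrmse_deconv rmse_deconv rmse_naive naive_to_deconv
  precursor       0.0426       0.575       1.47            2.56
 refixation       0.0603       0.633       1.57            2.48
   ordinary       0.0347       0.365       1.35            3.71

Recovered precursor late-window offset: -1.535 uV (configured: -1.5 uV)
Saccade-size effect on the lambda window: cor(fitted, generating) = 0.963
```

Read: with realistic overlap (mean fixation duration 247 ms), the
deconvolved waveforms recover the generating kernels to within ~4–6% of
their peak-to-peak range, 2.5–3.7× more accurately than classical
fixation-locked averaging, and the configured −1.5 µV precursor-specific
late negativity is recovered within a few percent. The fitted spline
effect of incoming saccade size reproduces the generating saturating
modulation of the lambda window.

The numbered scripts under `analysis/` tell the full story:
`01_simulate_scanpaths.R` (eye-movement structure: ~33 fixations/trial,
category shares, mean revisit lag ≈ 8.8 intervening fixations),
`02_deconvolve.R` (above), `03_roi_stats.R` (ROI window measures, the
late-window category ANOVA with post hocs, baseline-candidate vetting),
`04_calibration.R` (type-I error and power of the corrected test). Each
writes its tables under `results/`.

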