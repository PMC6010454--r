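---
title: "Methods: decoding, connectivity and outcome statistics in bcifes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding, connectivity and outcome statistics in bcifes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bcifes` implements the computational machinery of a sham-controlled
rehabilitation paradigm in which a brain-computer interface (BCI) decodes
hand-extension attempts from sensorimotor-rhythm EEG and, in the active arm,
triggers functional electrical stimulation (FES) of the extensor digitorum
communis; the sham arm receives FES on a random schedule. The package covers
four analysis layers — online decoding, effective connectivity, decoder-FES
contingency, and clinical outcome statistics — plus a synthetic-data layer
that generates every input with known ground truth. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic studies can and cannot show.

## The decoding chain

**Spatial filtering.** Each of the 16 sensorimotor channels (512 Hz) is
Laplacian-derived: the weighted average of its orthogonal grid neighbours is
subtracted (`apply_laplacian()`). We use equal weights summing to one per
channel; boundary channels use whatever orthogonal neighbours exist. A
distance-scaled weighting would be a drop-in replacement via the
`neighbor_map` argument; with the near-uniform spacing of a 16-channel strip
the difference is minor, so equal weights are the default.

**Features.** Welch power spectral densities over the trailing second,
recomputed every 62.5 ms during the active period: five Hann segments of
500 ms with 75% overlap, one-sided density scaling (`welch_psd_features()`).
At 512 Hz a 500-ms segment gives exactly 2-Hz bins, so the 4-40 Hz grid
(19 bins x 16 channels = 304 candidate features) needs no zero padding.
Trial-relative time is measured from the "Start" cue at 0 s; windows are
half-open `[t - 1, t)`.

**Feature selection and classification.** Candidate features are ranked by
the two-class canonical discriminant ratio (between- over within-class
variance, computed per feature over all trial time-steps;
`rank_features()`). The multi-feature canonical analysis collapses to this
ratio in the per-feature two-class case; an optional logical mask lets the
user impose prior neurophysiological constraints (task-relevant bands and
electrodes), mirroring how selection is done in practice. At most 10
features feed a two-class Gaussian classifier with one prototype per class,
diagonal covariance and equal priors (`fit_classifier()`); the posterior of
a sample is `N_attempt / (N_attempt + N_rest)`. Class variances are floored
at `1e-8` of the pooled feature variance to guard degenerate calibrations.

**Evidence accumulation.** Posteriors are integrated by an exponential leaky
integrator, `p_acc(t) = alpha * p_acc(t-1) + (1 - alpha) * p(t)`, starting
at 0.5, with a decision when `p_acc` reaches the confidence threshold
`th in (0.5, 1]` (`accumulate_evidence()`). The original system describes
the integration only qualitatively; the leaky integrator is our
reconstruction, chosen because it is the simplest accumulator with a
tunable memory and it admits a closed-form crossing time under constant
input, `n* = ceil(log((1 - th)/0.5) / log(alpha))`, which the tests pin
down. Defaults: `alpha = 0.96` per 62.5-ms step, `th = 0.8`, 7-s timeout.
Online, only attempt-crossings act (they trigger FES and end the trial);
offline evaluation is two-sided, and a trial that never crosses is a
"no-decision". Offline rates are reported with both the decided-trials
denominator and the all-trials denominator, because printed conventions
differ (a decided-only TPR and an ND fraction can legitimately sum beyond
100%).

**Threshold shaping.** Between runs the confidence threshold moves by
`delta = 0.02` to keep FES deliveries in the 10-12 band per 15-trial run —
"hard but feasible" (`shape_threshold()`). The banded rule is our choice;
only the target band is prescribed by the paradigm.

## Effective connectivity

Pre/post resting recordings are band-passed 1-50 Hz with a 4th-order
non-causal Butterworth (zero-phase forward-backward), decimated to 512 Hz
(exact integer factor; the 50-Hz low-pass is the anti-alias filter),
common-average referenced (`preprocess_hd()`), and hemisphere-aligned by
swapping homologous channels for right-lesion patients (`flip_montage()`),
so the lesioned hemisphere is always "left".

Connectivity is the short-time direct directed transfer function (SdDTF):
multi-trial MVAR models are fit in 1-s windows sliding by 200 ms
(`sddtf_sliding()`), pooling the lagged regressors of all trials per window
(no cross-trial continuity). From the transfer matrix
`H(f) = (I - sum_k A_k e^{-2 pi i f k / fs})^{-1}`:

* full-frequency DTF: `eta_ij(f) = |H_ij(f)| / sqrt(sum_{m,f} |H_im(f)|^2)`
  (per-target normalisation over all sources *and* frequencies, so
  `sum eta^2 = 1` per target, verified to 1e-10 on every fit);
* partial coherence `chi_ij(f)`, from the inverse cross-spectrum
  `S = H Sigma H*` with a diagonal loading of `1e-10 * trace(S)/k` for
  conditioning — this is what suppresses indirect cascade routes;
* `delta_ij(f) = eta_ij(f) * chi_ij(f)`, flow from source `j` to target `i`.

The model order is selected once per subject/session by the Schwarz
criterion over orders 3-12 and held fixed across windows; window-wise
re-selection would let the estimator chase noise. Values are referenced by
subtracting the mean over baseline windows (centres in [-3.5, -1] s before
the cue) from the mean over analysis windows ([0, 2.5] s), then averaged
over regions of interest (ordered channel pairs, self-pairs excluded) and
over the mu (10-12 Hz) and beta (18-24 Hz) bins of the 2-48-Hz grid.
Referencing by subtraction keeps the null at zero regardless of the
per-subject connectivity scale; ROI averages use `delta` itself rather than
`delta^2` (the choice is documented rather than derivable — `delta^2` would
only compress the scale).

One property of the direct-flow correction deserves emphasis because it
shaped the synthetic study design: on a chain `A -> B -> C`, strengthening
`B -> C` *lowers* the partial coherence of `A -> B` (the downstream channel
conditions away shared variance), so the band-averaged `delta` is not
monotone in coupling strength for multi-edge graphs. The cohort generator
therefore injects a single directed edge, for which `delta` is monotone in
the coupling strength over the range used (verified over strengths
0.15-0.7).

## Contingency between decoding and FES

Per therapy trial, the last feature sample at or before FES onset (or the
final active-period sample when no FES occurred) is classified attempt/rest
by the subject's own decoder at the 0.5 posterior boundary (ties count as
attempt), giving TP/FP/FN/TN as percentages of trials
(`build_contingency()`). In the closed-loop arm FP = 0 *structurally*: FES
follows only an attempt-evidence crossing, and a crossing step necessarily
carries a posterior above the threshold. The five standard metrics (TPR,
TNR, PPV, NPV, accuracy) are computed with explicit missing values for
empty denominators, never imputed.

Recovery is regressed on the four cells,
`dFMA = w1 TP + w2 TN + w3 FP + w4 FN`, with leave-one-out cross-validated
explained variance (`loocv_regression()`). Because the cells sum to 100%,
FN is dropped from the design matrix and the full weights are recovered by
back-substitution; the held-out `r^2 = 1 - SS_pred / SS_tot` may be
negative. The single-predictor accuracy model (`loocv_accuracy_r2()`) is
the benchmark it is compared against.

## Clinical statistics

The battery (`clinical_battery()` and its parts) comprises: a mixed
two-way ANOVA with within-subject TIME and between-subject GROUP factors,
computed as classical univariate F tests via an `Error(id)` stratum with
listwise deletion of incomplete patients and sphericity assumed (the
standard Mauchly-justified convention at two or three levels); Wilcoxon
rank-sum/signed-rank tests, exact for n <= 25 without ties and
tie-corrected normal approximation otherwise, with Bonferroni correction
applied within a post-hoc family; odds ratios with Woolf (log-normal)
intervals and Haldane 0.5 correction for zero cells, accompanied by Fisher
exact p-values; Pearson correlations with t-distribution p-values on n - 2
degrees of freedom; pooled-SD Cohen's d; and Lilliefors-corrected
Kolmogorov-Smirnov normality checks. On the bundled 27-patient score
tables this battery reproduces the printed trial results — group means to
one decimal, the responders odds ratio 7.33 with CI (1.16, 46.23), the
TIME x GROUP interaction p = 0.04 — which the acceptance script recomputes
end to end.

## The synthetic-data layer

The generators are first-class, tested code; they define the conditions
under which every ground-truth claim is evaluated.

* **Background EEG**: 1/f (pink) noise plus white sensor noise per channel;
  narrow-band mu (~11 Hz) and beta (~21 Hz) oscillators with random-walk
  phase. ERD is a multiplicative envelope reduction on the ERD channels
  during the active period: depth `d` scales band power by `1 - d`
  (default 0.5, a moderate desynchronisation).
* **Protocol**: 3-s preparation, 1-s cue, 4-s active period (calibration)
  or up-to-7-s active period (therapy), 2-s stop, 3-4.5-s inter-trial
  interval; 15 trials per run, 3 calibration runs.
* **Sham FES**: 9-11 deliveries per 15-trial run (discrete uniform — only
  the range is documented for the original schedule), delivery times
  uniform in 3.5-5.5 s. The whole schedule is drawn *before* any EEG is
  synthesised, so its independence from the neural realisation holds by
  construction, and regenerating with the same seed but different ERD
  depth provably leaves the schedule unchanged.
* **Resting sessions for connectivity** are generated directly as
  time-varying MVAR processes over ROI channels (identity mixing): each
  channel is an oscillatory AR(2) (poles at radius 0.85 near 11 Hz), and
  graph edges add lag-1 cross-coefficients whose strength rises by a
  factor `1 + mod` after the cue. The group x time effect multiplies the
  post-session modulation of the active arm by `coupling_change`
  (default 2.5, placed with the base strength 0.2 on the monotone part of
  the `delta`-vs-strength curve). Stability (companion spectral radius
  < 1) is verified before synthesis; unstable graphs are rejected with a
  diagnostic, never clipped.
* **Clinical cohorts**: `dFMA = effect * 1[bci] + link_slope * accuracy +
  cell effects + noise`, with per-patient contingency cells emulating the
  closed-loop (FP = 0) vs random-FES structure, pre-scores uniform on the
  moderate-to-severe 5-40 range and post-scores clipped (flagged) to 0-66.

**Problem sizes.** The cohort-level studies run at region-of-interest scale:
6 channels, 128 Hz, 20 resting trials, 12 subjects per arm for the
power study (50 cohorts); the null-calibration study uses a compact
variant (6 trials, 64 Hz, mu bins, [-1.5, 1.5]-s epochs, 500 replicates)
whose rejection rate sits at the nominal 5% within Monte-Carlo error.
These sizes are the package's chosen desk-scale study conditions; they are
stated here so the simulations can be scaled up verbatim.

**What passing tests do not show.** The generators contain no volume
conduction or head-model mixing, no ocular/muscular artifacts, no
non-stationary drifts across a session, and subject heterogeneity only as
a 10% coupling-strength jitter; real 64-channel EEG is far less friendly.
Ground-truth recovery here validates the estimators' correctness — their
identifiability, normalisation, calibration and structural properties —
not clinical-grade performance on recorded data. The printed EEG-dependent
performance numbers of the original trial (offline TPR/FPR, contingency
accuracy by arm, connectivity-recovery correlations) are therefore
mirrored as *structural and ordering properties* (FP = 0 only under brain
control, a >20-point accuracy gap, the four-cell regression beating
accuracy-only) rather than asserted as equalities.

## Numerical and degenerate-input choices

* Welch: Hann taper, one-sided density scaling, halved DC/Nyquist bins;
  trials shorter than the window are skipped with a warning.
* Posterior ties (`p = 0.5`) classify as attempt; documented and tested.
* Zero within-class variance caps a discriminant score at `+Inf` with a
  warning; singular class variances are floored and flagged.
* Ill-conditioned MVAR normal equations fall back to a ridge of
  `1e-8 * mean(diag(X'X))`, with the penalty logged.
* Negative partial-coherence values from roundoff are clamped to zero with
  a warning counter.
* Baseline referencing refuses to run twice; empty referencing intervals,
  empty contingency denominators, empty margins in 2x2 tables, constant
  samples in the normality check, and missing decoders in the closed-loop
  arm are all explicit errors or explicit `NA`s — never silent defaults.
* Score-table fixtures are checksum-verified at load time; missing
  follow-ups are `NA`, never zero.

## Known limitations

The mixed ANOVA reports classical univariate dfs; corrections for
sphericity violations (Greenhouse-Geisser) are out of scope at two or
three within-subject levels. The EDF writer targets the plain 16-bit
continuous case (one data record), which is sufficient for interchange
with standard readers but not a general EDF+ implementation. Connectivity
is sensor-space by design; source projection, surrogate-based single-edge
significance and adaptive (Kalman) MVAR variants are intentionally not
implemented.
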