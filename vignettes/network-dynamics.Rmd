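---
title: "Quantifying EEG network-state dynamics with correlation and power dynamics matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EEG network-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdyn)
```

## The model

Multichannel scalp EEG can be summarized at every moment by two
network-level descriptions: the pattern of channel-to-channel
correlations (which functional network is active) and the distribution
of band power across channels (where oscillatory energy sits). Both
descriptions fluctuate over time, and the way they fluctuate — how often
the brain revisits the same configuration, and how abruptly it switches —
carries diagnostic information that conventional visual EEG review does
not quantify. Severe early-infantile epileptic encephalopathies are a
natural test case: burst suppression (Ohtahara syndrome) and
hypsarrhythmia (West syndrome) disrupt background dynamics pervasively.

`eegdyn` implements the sliding-window analysis of 10-s,
average-referenced EEG segments:

1. A 2-s window slides across the segment (canonically one sample at a
   time, giving $k = 8 f_s + 1$ windows). For each window we compute
   the $n \times n$ Pearson correlation matrix between channels,
   vectorized to its $m = n(n-1)/2$ upper-triangle entries, and the
   $n$-vector of mean band power per channel.
2. Correlating every pair of window vectors yields two $k \times k$
   matrices: the **correlation dynamics matrix** (CDM) and the **power
   dynamics matrix** (PDM). Blocks of high off-diagonal values are
   recurrent network states; their borders are state transitions.
3. Each matrix is reduced to three scalars: the **mean**
   $\sum_{x,y} f_{x,y} / k^2$, the **contrast**
   $\sum_{x,y} (f_{x,y} - f_{x+1,y+1})^2$, and the **Brenner
   sharpness** $\sum_{x,y} (f_{x+2,y} - f_{x,y})^2 + (f_{x,y+2} -
   f_{x,y})^2$. Over six frequency bands (broadband 0.1–60 Hz, delta
   1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–60 Hz) and both
   matrix types this gives 36 named measures per segment.

Nonstationarity is assessed per segment against 100 (configurably
fewer) amplitude- and cross-correlation-adjusted surrogate series. The
scheme is a multivariate IAAFT variant: all channels start from the
same random phase increments (preserving the cross-spectrum), free
per-channel IAAFT iterations then converge spectra and amplitude
distributions — genuinely destroying bursts and state runs — and a
final targeted step restores the original *relative* phases at the
dominant low-frequency bins (which carry the zero-lag correlations
under 1/f spectra) up to a common rotation taken from the randomized
iterate. Each channel's amplitude distribution is preserved exactly (a
permutation), its spectrum to a fraction of a percent, and zero-lag
cross-correlations to within ±0.05 on stationary test signals. Each measure is z-scored against its surrogate null;
values outside roughly ±2 indicate dynamics that stationary correlated
noise cannot produce.

For classification, every measure is scored by the purity
$P(\Omega, \mathbb{C}) = \frac1N \sum_k \max_j |\omega_k \cap c_j|$
of the three-way clustering induced by two optimized thresholds
(simulated annealing with a deterministic midpoint polish), measures
are ranked by achievable purity, and k-means on the top-$r$ ranked
measures is evaluated by purity, sensitivity and specificity against
the known groups.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_len` | 2 s | sliding-window length; sets the slowest resolvable transition |
| `step` | 1 sample | window-start spacing; $k = \lfloor (d - w) f_s / \text{step} \rfloor + 1$ |
| bands | 6 canonical | broadband plus five clinical bands, order-4 zero-phase Butterworth |
| surrogate `count` | 100 | ensemble size per segment; 15–20 already give stable z-scores |
| surrogate `tol` | 1e-4 | relative spectral L2 error at IAAFT convergence |
| anneal schedule | T0 = 1, cooling 0.95, 2000 iters, 4 restarts | two-threshold purity search |
| k-means `restarts` | 100 | random initializations kept by within-cluster SS |

Window length trades temporal resolution against correlation-estimate
noise: 2 s at 128–512 Hz gives stable 19-channel correlation estimates
but averages out high-frequency state switching, which is why the most
discriminative measures concentrate in the lower bands. Step size only
thins the window grid; results at step 16 track the canonical
one-sample step closely at a small fraction of the cost, and the test
suite and acceptance script use fs = 128 Hz with step 16 ($k = 65$)
throughout.

## The synthetic cohort generator

No clinical recordings ship with the package; every downstream stage is
exercised on synthetic archetypes that emulate the *qualitative*
phenomenology of the study conditions, not neonatal biophysics:

* a latent state sequence with exponential dwell times (mean
  `state_dwell_mean`) selects among four cross-covariance patterns
  $(1-\rho) I + \rho\, u u^{\top}$ built from random sign vectors $u$
  (balanced signs: the average montage removes uniform synchrony, so
  only polarity structure survives referencing); transitions are
  crossfaded over $(1 - \text{transition\_sharpness}) \cdot
  \text{state\_dwell\_mean}$ seconds;
* each state instance carries an independent 1/f (pink) noise stream;
* **stationary controls** hold a single weak-correlation state
  ($\rho = 0.05$) with a fixed channel-gain profile — their CDM is
  quasi-diagonal (far-off-diagonal mean < 0.3), which calibrates the
  surrogate z-scores;
* **normal background** drifts slowly among weak patterns
  ($\rho = 0.1$, smooth crossfades) with a fixed gain profile, so power
  topography recurs strongly while correlation patterns do not — the
  mean CDM − PDM difference is reliably negative;
* the **pathological archetypes** use strong patterns ($\rho = 0.9$)
  with a dominant motif revisited with probability 0.7 (abnormally
  recurrent network states), while per-channel log-gains wander as
  independent Ornstein–Uhlenbeck processes (correlation time
  `state_dwell_mean`/4): network motifs recur but the power topography
  does not, giving the positive CDM − PDM difference;
* **burst suppression** additionally co-modulates all channels with an
  alternating envelope — bursts of ~0.5–1.5 s at `burst_amplitude_gain`
  separated by suppression gaps of at least 1.5 s at
  `suppression_level`. The guaranteed gaps keep burst-free windows in
  every realization, and each channel is centred by its
  envelope-weighted mean before enveloping so the suppressed background
  carries no DC offset (a 0.1-Hz high-pass cannot remove DC within a
  10-s segment);
* **hypsarrhythmia** uses faster switching (dwell 1.5 s), high
  amplitude, and strong chaotic synchrony.

Choices the generator does *not* attempt: sleep architecture, artifacts
(blink, EMG), seizure onsets, realistic scalp topography, or any
spectral claim about hypsarrhythmia beyond "high-amplitude,
mixed-frequency, highly correlated". Passing tests on these archetypes
demonstrates that the *pipeline* measures what it claims to measure;
they say nothing about clinical sensitivity, which requires the
deposited clinical segments.

## Numerical choices and degenerate inputs

* Butterworth order 4, applied forward–backward (`signal::filtfilt`)
  for zero phase; phase distortion would corrupt window-to-window
  correlations. The order is a clinical convention; the original
  analysis does not state one.
* Upper-triangle vectorization is row-major; any fixed order gives the
  same Pearson values, one is canonized for determinism.
* A channel that is constant within a window (or a constant window
  vector) has undefined correlations; entries are set to 0, counted,
  and reported via a warning rather than propagating NaN.
* Dynamics matrices are symmetrized against rounding and their diagonal
  forced to exactly 1.
* Contrast and sharpness sums run over in-bounds index pairs only (no
  padding, no wraparound); a zero-padding variant exists behind a flag.
  Measures are computed on raw matrix values; no per-matrix
  normalization, and no division by $k^2$ — all segments of one
  analysis share a single $k$.
* Surrogate z-scores use the ensemble SD with denominator $n-1$; a zero
  SD yields a flagged `NA`, never ±Inf.
* The annealer's purity landscape is piecewise constant with jumps at
  midpoints between adjacent sorted values, so each annealing restart
  is polished by coordinate-wise sweeps over all candidate midpoints;
  on instances of ≤ 50 segments the result matches exhaustive grid
  search in every randomized check.
* k-means standardizes each measure column after a signed-log map
  $\operatorname{sign}(x)\log(1+|x|)$. The quadratic texture measures
  are heavy-tailed across segments, and Euclidean k-means on raw
  standardized columns splits the widest group instead of separating
  groups; the signed-log map is monotone, near-identity on
  correlation-scale values, and variance-stabilizing for the quadratic
  measures. Set `stabilize = FALSE` for plain standardization.

## Design decisions where the method was open

* **"Cross-correlation between window vectors"** is implemented as
  zero-lag Pearson correlation — the dynamics matrices are bounded in
  $[-1, 1]$ with unit diagonal, which matches how they are displayed
  and summarized; no lagged variant is computed.
* **Window counting** includes both endpoints (start 0 and start
  $d - w$), so $k = 8 f_s + 1$ on the canonical segment.
* **Mean band power** is the time-domain mean square of the
  band-filtered signal, not a PSD integral: the band is already imposed
  by the filter, and the two agree by Parseval up to leakage.
* **Surrogate variant**: the original analysis names amplitude- and
  cross-correlation-adjusted surrogates but not the multivariate
  scheme; common phase increments at initialization plus the
  common-rotation spectral step preserve the stated invariants, and a
  short per-channel polish trims the residual spectral error of the
  multivariate fixed point.
* **Directional claims**: for persistent-state signals the CDM *mean*
  can sit on either side of its surrogate null — the surrogate inherits
  the time-averaged (burst-dominated) correlation pattern, whose static
  recurrence can exceed the empirical one. Nonstationarity of the mean
  is therefore tested two-sidedly (as in the underlying group-level
  t test of z ≠ 0), while contrast and sharpness deviate strongly
  per segment.
* **Smoothing sensitivity**: with the direct difference formulas used
  here, the lag-1 diagonal contrast is *more* smoothing-sensitive than
  the lag-2 Brenner operator (which has a Nyquist null), on every
  pattern family we examined. The property suite asserts what these
  operators do guarantee: smoothing reduces both, amplitude doubling
  quadruples both, and the two manipulations factorize. A
  GLCM-quantized contrast, which some toolboxes use, behaves
  differently; it would need an arbitrary bin count and is not
  implemented.
* **Transition-sharpness resolution**: crossfades shorter than the
  analysis window are invisible by construction; the monotonicity of
  CDM sharpness in `transition_sharpness` is therefore verified with
  1-s windows against 4-s dwells, where the crossfade grid (0–3 s) is
  resolvable.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
params <- phenotype_params("burst_suppression", fs = 256, seed = 7)
rec <- average_reference(generate_recording(params))
seg <- eeg_segment(rec$data, rec$fs, parent_id = "demo")

dyn <- segment_dynamics(seg, "broadband", window_len = 2, step = 16)
plot(dyn$cdm)
matrix_mean(dyn$cdm)          # time-averaged recurrence of network states
cdm_pdm_difference(dyn$cdm, dyn$pdm)

fv <- feature_vector(seg, step = 16)          # all 36 measures
ens <- null_distribution(make_surrogates(seg, count = 20, seed = 1),
                         step = 16)
z <- zscore_features(fv, ens)
z[c("cdm_mean_broadband", "cdm_contrast_broadband",
    "cdm_sharpness_broadband")]
```

A full cohort run — simulation to EDF, features, surrogates, ranking
and the k-means sweep — is orchestrated by `run_pipeline()`; see
`default_config()` for the demo and full-resolution profiles.

## Known limitations

* The archetypes are phenomenological; effect sizes on synthetic
  cohorts do not transfer to clinical recordings.
* Segments from one synthetic "subject" are independent draws, unlike
  clinical repeats; subject identifiers are carried so
  leave-one-subject-out analyses remain possible.
* Mixed 256/512 Hz cohorts change $k$ and hence the scale of contrast
  and sharpness; comparisons across sampling rates should use the
  normalize-by-count option or a common step grid.
* IAAFT convergence degrades on strongly bimodal amplitude
  distributions (burst suppression): spectral error a few percent
  instead of < 1%. The z-scores there are dominated by genuine
  nonstationarity, orders of magnitude larger.
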