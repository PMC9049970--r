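---
title: "Modeling task-related hemodynamic responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling task-related hemodynamic responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trrtools)
```

## The problem

During slow event-related visual tasks, early visual cortex produces large
hemodynamic responses that are time-locked to the trial structure but are
neither stimulus-evoked nor attributable to spatial attention: they appear
in the hemisphere *ipsilateral* to the stimulus, far from its retinotopic
representation. These task-related responses (TRRs) scale with task
difficulty and behavioral performance, track arousal measures (pupil size,
heart rate, respiration), and survive the standard fMRI "denoising" steps
(global signal regression, physiological artifact projection).

`trrtools` implements the full analysis chain for this phenomenon as a
tested pipeline operating on synthetic data whose generative structure
matches the assumptions of the analysis: an adaptive-staircase behavioral
protocol, BOLD series with a three-input TRR, pulse/respiration/motion/pupil
streams with arousal-coupled modulation, a 24-column GLMM design, circular
phase-variability statistics, and permutation machinery with finite-sample
exact-p correction.

## The protocol and behavioral model

Trials are 15 s (0.2-s stimulus + 14.8-s interstimulus interval), 16 per
240-s run, with BOLD sampled at TR = 1.5 s, so the task frequency is
1/15 Hz and each trial spans exactly 10 volumes. Easy runs fix the grating
tilt at ±20°; hard runs drive tilt with a one-up/two-down staircase whose
fixed point is a percent correct of $\sqrt{1/2} \approx 70.7\%$.

The simulated observer has a folded cumulative-Gaussian psychometric
function with a guess rate of 0.5 and an attentional error rate
$\lambda = 0.1$,

$$p(\mathrm{correct} \mid t) = 0.5 + (0.5 - \lambda)\,
  \left(2\Phi(|t|/\sigma) - 1\right),$$

so accuracy saturates near 90% on easy trials (the protocol's design
target) while the staircase can still reach its ~70.7% fixed point on hard
runs. Response times are log-normal with median ≈ 0.55 s and
$\sigma_{\log} = 0.545$ (calibrated so ~86% of RTs fall under 1 s and
>99% under 4 s), truncated to the ISI, with additive log-scale shifts for
hard and incorrect trials. Lapse (no-response) trials occur with
probability 6.68% on easy and 4.48% on hard runs.

## The generative TRR model

The TRR is the sum of three HRF-convolved inputs per trial: an impulse at
trial onset (TO), an impulse at the button press (BP), and a unit boxcar
spanning onset to button press (time on task, ToT). The HRF is a
six-parameter double gamma,

$$h(t) = A\left[g(t;\alpha_1,\beta_1) - c\, g(t;\alpha_2,\beta_2)\right],$$

with $g$ a gamma *density* (shapes > 1, so $h(0)=0$), evaluated on a 32-s
support. The conventional parameterization of the double-gamma family is not
fully standardized across the literature; any six-parameter double-gamma
family spans the same curves, so this normalized-density form is fixed and
documented here.

Condition effects enter as multiplicative amplitude gains applied at trial
resolution to the sampled response:
`gain = difficulty_gain^[hard] * error_gain^[incorrect] *
easy_error_boost^[easy & incorrect]`, with defaults 1.3 / 1.4 / 1.5 and a
separate `lapse_gain` (2.2). This makes hard > easy and incorrect >
correct, with easy-incorrect and lapse trials largest — the orderings the
analysis is designed to detect. Per-trial temporal jitter is a zero-mean
Gaussian common shift of all three inputs, with spreads ordered
easy-correct (1.0 s) > hard-correct (0.8) > hard-incorrect (0.6) >
easy-incorrect (0.2 s), mirroring the observed ordering of temporal
variability across conditions.

Applying gains to the *sampled* response (rather than to the event
amplitudes before convolution) makes the deterministic limit of the
generator lie exactly in the span of the design's task × condition
interaction columns — a tested invariant that pins the generator and the
analysis to the same model.

### Noise model and the global signal

Each voxel receives white Gaussian noise (sd 1.0 psc), a slow per-voxel
AR(1) drift (sd 0.3, AR 0.98 at TR), a shared global component, and
optionally a physiological artifact built by convolving the simulated
pulse/respiration traces with their canonical response kernels. The global
component has its own faster dynamics (sd 0.5, AR 0.8): the whole-brain
mean fluctuates at respiratory timescales, not at drift timescales.

The ROI is a small fraction of the brain, so the simulation includes
background voxels (default 10× the ROI count) carrying everything *except*
the TRR. Without them, the global signal would essentially equal the TRR
and global-signal regression would delete the phenomenon of interest —
contrary to what is observed in real data, where GSR does not remove the
TRR.

With a 20-voxel ROI the cleaned ROI residual is ≈ 0.25–0.3 psc against a
TRR of ≈ 0.06 psc (sd), so per-trial response amplitude (std over a trial)
lands near 0.3 psc and the session-level GLMM $R^2$ lands near 0.1 — the
same order as real data. ROI-level noise here comes entirely from finite
voxel count with iid voxel noise; real V1 noise is partly shared across
voxels, which this generator does not model (a green test therefore
establishes correct behavior under iid voxel noise, not under spatially
correlated noise).

### What a green test does and does not establish

The generator emulates trial-locked structure, condition-dependent gains
and jitter, arousal-coupled physiology, and blink-interrupted pupil
traces. It does not emulate scanner spikes, spatially structured noise,
motion-correlated signal dropout, or retinotopic spatial structure. Green
pipeline tests establish that the implemented operations recover known
parameters under the stated generative model, not that they would do so
under every real-world artifact.

## Preprocessing

Pipeline order is fixed and tested: percent-signal-change scaling →
per-run global-signal projection from each voxel → optional
physiological/motion projection → ROI averaging → epoching with the
exclusion rules (first trial of each run removed; lapse trials split into
a separate partition). Projection residualizes on an intercept plus the
nuisance columns and adds the run mean back so amplitude statistics stay
in percent-change units; runs are treated as independent acquisitions
(the session-level alternative was rejected because runs are separate
scans).

A note on what projection can achieve: the cleaned series is orthogonal to
the *measured* global signal within each run by construction. Against the
*latent* injected global component, per-run regression on a noisy estimate
retains an O(1/√run-length) random admixture (~8% per voxel at 160
volumes/run); the tests therefore assert exact decorrelation from the
measured global plus strong (>3×) attenuation of the injected component,
not an unattainable exact removal.

## Design matrix

24 fixed-effect columns: intercept; fMRI_TO, fMRI_BP, fMRI_ToT (built at a
10-Hz working rate from unit-area impulses and unit boxcars, convolved
with the HRF, then decimated to TR); difficulty (run-level indicator,
hard = 1); accuracy (trial-window indicator, incorrect = 1; lapse windows
zero); cardiac and respiration predicted-BOLD regressors (raw 50-Hz traces
convolved with the canonical cardiac/respiration response functions at the
native rate, then decimated); six motion traces; and the ten factorial
interactions {3 task} × {difficulty, accuracy}, difficulty × accuracy, and
{3 task} × difficulty × accuracy, formed as elementwise products. The
24-coefficient contract includes the intercept; dropping motion leaves 18.
Difficulty enters at run level because difficulty is blocked by run;
0/1 indicator coding matches the "time course" phrasing of the design and
is configurable.

Decimation low-pass filters at 0.8× the target Nyquist. All low-pass and
band-pass filters in the package are exact zero-phase frequency-domain
filters applying the *squared* Butterworth magnitude — the transfer
function of a forward-backward (filtfilt) IIR pass — with reflection
padding; this meets the zero-phase contract exactly and makes the analytic
attenuation bounds testable in closed form.

## Mixed model and inference

The GLMM is fit with `lme4`: the 24 fixed effects plus a per-observer
random intercept and random slopes for the three task predictors. With
`random = NULL` the model reduces exactly to OLS (the zero-variance limit,
used as an oracle). Contrast F-tests are Wald tests
$F = (L\hat\beta)^\top (LVL^\top)^{-1} (L\hat\beta)/q$ with a
residual-based denominator df approximation ($n - p$); the realized
random-effect coefficient count is recorded rather than asserted, since a
9-observer session yields 9 × (1 + 3) = 36 coefficients, and any reference
count depends on the observer cohort.

Model rows are cleaned before fitting: volumes belonging to the first
trial of each run and to lapse trials are dropped from design and
response, following the data-cleaning rules ("removed ... for all data
types"); the reference dataset's GLMM row count (≈ 16.4k for 9 observers) is consistent with
this row exclusion at ~12 runs/observer, which is also the scale at which
the power properties are evaluated.

Permutation tests shuffle two-group labels (difference of means), count
ties as exceedances (conservative), and report the finite-sample exact
p-value $(b+1)/(m+1)$, which can never be zero. For small groups the test
can enumerate all label assignments exhaustively. The two-stage adaptive
FDR procedure runs a linear step-up at $q' = \alpha/(1+\alpha)$, estimates
the number of true nulls $m_0 = m - r_1$, and reruns the step-up at
$q' m/m_0$.

The visual-field border test compares the mean amplitude in a band of
given thickness hugging the screen edge against the same-dimension band
translated to uniformly random centers, with out-of-field pixels excluded.
A thickness- and area-matched band can never fit strictly inside the field
(with fixed thickness, matching band area forces the outer
width + height to equal the field's), so an area-matched
null necessarily involves clipping; translation-with-clipping is the
implementation here, and p-values are invariant to adding a constant to
the map.

## Spectral and circular statistics

Per-trial amplitude is the sample std of the 10-volume trial window.
Per-trial phase is the phase of the single-cycle Fourier component of the
mean-removed window. Temporal variability is the *angular deviation*
$s = \sqrt{2(1-R)}$ of those phases ($R$ = mean resultant length): the
stated bounds (0 for identical phases, $\sqrt 2$ for uniform) force this
form over the alternative circular standard deviation
$\sqrt{-2\ln R}$, which is unbounded. Epochs are mean-removed per trial
before the harmonic fit; $s$ is invariant to common phase rotations and
rises monotonically with injected jitter spread (tested).

## Physiological and pupil metrics

Pulse peaks are local maxima above an adaptive threshold (median + 0.5 IQR)
refined to sub-sample precision by intersecting lines fit to 3 rising- and
3 falling-flank samples. The flank windows are placed symmetrically about
the likely apex (chosen by comparing the apex-adjacent samples), which
makes the refinement exact for symmetric peaks with the apex midway
between samples. Per 15-s trial bin: HR = 60/mean(IBI); HRV = RMSSD of
IBIs (invariant to constant IBI shifts — the high-pass property);
HR acceleration = mean of Δ(instantaneous rate in beats/s) divided by the
elapsed time, positive for a speeding heart. The literal "derivative of
interpeak durations" has units of s/s, not the conventional beats/s²; the
rate-based reading used here is a documented interpretation, sign-checked
against the stated convention. Respiration metrics per bin: volume = std
of the percent-change trace, frequency = non-DC spectral peak,
variability = RMSSD of unrefined peak-to-peak intervals.

Pupil traces are deblinked by cubic-spline interpolation across each blink
span padded by 100 ms per side (the padding absorbs the partial-occlusion
shoulders around a blink; the source protocol does not state a margin),
then band-passed 0.03–10 Hz with the fourth-order zero-phase Butterworth
described above. Evoked responses are trial-locked epochs averaged by
condition; amplitude defaults to the std of the condition-mean time course
(per-trial variant available). Fixation stability is the within-trial std
of the gaze-to-fixation distance, which is zero for any constant-radius
gaze path by construction.

## Numerical choices

* HRF fitting: Nelder-Mead over the four gamma shape/rate parameters with
  the two linear coefficients (scale, undershoot) profiled out by least
  squares at each step; restart from a perturbed start; objective
  tolerance ~1e-14; fit window ⌊16/TR⌋ samples; 32-s evaluation support.
  The profiled form makes noiseless round-trips exact to ~1e-14.
* Working rate for impulse placement: 10 Hz (RT resolution ≪ TR, cheap
  convolutions).
* Tie handling in permutation counts: ties count toward the exceedance
  count (validity over power).
* Degenerate inputs: constant traces yield empty peak lists; constant
  epochs are excluded from phase statistics with a warning; rank-deficient
  designs warn and name the offending columns; singular random-effect
  fits are kept and flagged.

## Known limitations

* No spatially correlated voxel noise; ROI SNR is governed by voxel count.
* No scanner spikes, motion-correlated dropout, or multi-echo structure
  (data are generated "post-ME-ICA" by construction).
* The respiration/cardiac kernels use the canonical published constants;
  no subject-specific physiological response fitting.
* The border test operates on an already-gridded visual-field map; the
  projection from cortical surface to visual field is out of scope.
* Difficulty-blocked designs leave the difficulty × task interaction
  power limited by between-run noise; at the reference data scale the
  difficulty contrast is comfortably powered but individual seeds can
  fail at α = 0.05.
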