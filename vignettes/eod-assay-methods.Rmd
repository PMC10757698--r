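---
title: "Methods: the synthetic EOD anesthesia assay and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the synthetic EOD anesthesia assay and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

The electric organ discharge (EOD) of the weakly electric fish *Apteronotus
leptorhynchus* is a continuous quasi-sinusoidal field at ~650–1000 Hz whose
frequency follows, one to one, the oscillation of the medullary pacemaker
nucleus. Because the EOD can be recorded non-invasively, its frequency is a
real-time proxy for the activity of a defined brainstem circuit, which makes
it a sensitive neuro-behavioral readout for testing how water-borne
anesthetics act on central neurons. The assay this package implements
follows one fish through a 30-min baseline recording, a 5-min immersion in
an anesthetic bath (control water, or eugenol at 30, 45 or 60 µL/L), and
180 min of post-treatment recording, and quantifies four things:

1. the stability of the baseline frequency (coefficient of variation of
   59 median values, `coefficient_of_variation()`);
2. the dose-dependent frequency drop and its recovery, summarized by the
   four-parameter model `F(t) = a + ((c − a)t + d·t²)/(b + t)`
   (`fit_recovery_model()`);
3. the rate of type-2 chirps — transient (~10–50 ms) frequency rises below
   150 Hz with a small amplitude dip — before and after anesthesia
   (`detect_chirps()`);
4. amplitude-collapse episodes at the highest dose
   (`detect_amplitude_collapse()`).

Statistical inference uses exact two-tailed sign tests across the 8 fish,
a split-plot linear mixed model
`Y_ijk = δ0 + δ1·c_i + β_j(i) + δ2·t_k + δ12·c_i·t_k + ε_ijk`
(`fit_mixed_model()`), and a Bonferroni-corrected sliding-window estimate of
the recovery time (`recovery_time()`).

Because no public recordings exist for this assay, the package pairs the
analysis chain with a synthetic-data generator whose defaults encode the
study conditions; every analysis stage is validated against the generator's
ground truth.

## The generator

`generate_experiment()` draws one baseline frequency per fish (uniform on
650–1000 Hz) and reuses it across all four conditions; treatment order per
fish is a random permutation (randomized complete block design), giving
8 × 4 = 32 recordings.

**Frequency profile.** Baseline wander is a mean-reverting Gaussian random
walk on a 1-s grid with stationary sd 0.0035·f0 and e-folding time 45 s.
These two numbers were calibrated once, by simulating the jitter model
alone, so that the coefficient of variation of the 59 baseline medians falls
mid-way inside the 0.12–0.59% range reported for the real assay; across
seeds and baseline frequencies the simulated cv spans ≈0.18–0.42%. A purely
absolute step size cannot satisfy that target uniformly across the 650–1000
Hz range, which is why the wander is parametrized relative to f0. During
immersion the frequency holds for a 60-s latency (treated conditions) and
then declines smoothly to `a·f0`; after the return to the home tank it
follows `f0·F(t)` with the per-concentration recovery parameters as
defaults. The drop floor `a` receives a per-fish Gaussian perturbation
(sd 0.02) so that fish scatter around the pooled recovery curve, as real
fish do; this perturbation is also what gives the split-plot model's
fish-within-treatment variance component something real to estimate.

**Chirps.** Event times are Poisson: 0.05/min outside the boosted window
(the observed median spontaneous rate) and 4/min during the 30 min after
treatment (the observed increases of ~100–160 chirps per 30 min). Each
chirp adds `ΔF · Φ(t − t_event; α)` to the frequency profile with
`Φ(ξ; α) = 2e^{αξ}/(1 + e^{2αξ}) = sech(αξ)`, with ΔF uniform on 30–150 Hz
and α uniform on 200–1500 s⁻¹ (~10–50 ms events; the event duration is not
printed in the source literature, so the α range is a modeling choice), and
multiplies the amplitude by `1 − dip·Φ` with dip uniform on 0.1–0.6. Chirp
support is truncated where Φ < 0.01 (|ξ| = 5.3/α); overlapping events are
redrawn.

**Amplitude.** Movement of the fish relative to the tube electrodes is
modeled as multiplicative log-normal jitter (OU on a 1-s grid, sd 0.1),
suppressed while the fish is anesthetized. At 60 µL/L, half of the fish (per
draw) undergo an amplitude collapse: a 30-s sigmoidal fall to 10% of
baseline starting 210 s after immersion, held until the return, then a
linear recovery over 6 min.

**Carrier.** `synthesize_waveform()` renders
`A(t)·Σ_h w_h sin(2π h θ(t))` with θ the cumulative integral of the
frequency profile at the sampling rate, default 3 harmonics with weights
(1, 0.3, 0.1) — real discharges are non-sinusoidal — and additive Gaussian
noise with sd 0.05 relative to unit amplitude (a clean electrode recording).
Synthesis refuses sampling rates below 4× the highest modeled harmonic.

What the generator does *not* emulate: electrode drift, multi-fish
interference, tank-transfer artifacts (available as an option but off by
default), temperature-driven frequency trends (the default tank sits at the
26 °C reference, so the Q10 adjustment is exercised as an identity in the
pipeline and as arithmetic in its own tests), and any relationship between
chirp rate and dose beyond a common post-treatment boost. Passing tests on
synthetic data therefore demonstrate that the analysis chain is correct and
well calibrated for signals with this structure, not that it would be robust
to every artifact of a real tank.

## Frequency tracking

`track_frequency()` implements adaptive dominant-frequency tracking: window
`k` is Hann-tapered, zero-padded 4×, and the power-spectral argmax is taken
inside `[0.9, 1.1]·f_{d,k−1}`, refined by quadratic interpolation of the
log-power around the peak bin; `f_{d,0}` comes from a Welch average over the
baseline (`baseline_dominant_frequency()`). Windows without an acceptable
in-band local maximum (transfer gaps, silence) carry the previous value
forward and are flagged rather than aborting the track. Each window can
optionally be bandpass-filtered to `[0.4, 1.4]·f_{d,k}` (zero-phase
forward–backward Butterworth) and retained.

Window sizes are not prescribed by the source method, so two presets are
provided. The default 50-ms window / 25-ms step gives ~20 Hz raw resolution
(sub-Hz after interpolation) and is right for the slow quantities (median
series, drops, cv). Chirp analysis instead uses `chirp_track_config()`:
5-ms windows stepped every 1.25 ms. The reason is physical: a ≤50-ms chirp
inside a 50-ms window barely moves the window's spectral argmax, so a
coarse track cannot see chirps at all. Even the 5-ms window smears the
fastest events — a ΔF = 30 Hz, α = 1500 s⁻¹ chirp appears as a ~21 Hz bump —
which is why the detector's onset threshold sits at 12 Hz (≈6× the tracker's
~2 Hz jitter at the default signal-to-noise ratio) rather than above the
smallest generated rise.

Per-window RMS amplitude is carried on the track. The chirp detector vetoes
candidates where it falls below 25% of the track median: when the discharge
amplitude collapses, frequency estimates degrade as 1/SNR and would
otherwise flood the detector with spurious excursions.

## Chirp fitting and classification

Candidates are contiguous runs ≥2 steps above the local baseline (running
median over 2 s, which chirps are far too short to bias). `fit_chirp()`
takes ΔF as the peak baseline-subtracted excursion and fits α by 1-D
minimization on log α (grid-initialized, bounds 50–5000 s⁻¹), iterating the
fit window once to half-width 5/α. Classification is strict: type-2 iff
ΔF < 150 Hz *and* the sech fit explains ≥70% of the variance. The 0.7
goodness cut (rather than a higher one) reflects the measured sech purity
of fast chirps seen through the 5-ms analysis window (R² ≈ 0.78–0.85),
while steps and noise runs stay below 0.6; both thresholds were calibrated
against generator ground truth, since the source method's values are not
reprinted anywhere.

## Recovery model and statistics

Normalized series divide by the median of the 30-min baseline medians, with
t = 0 at the return to the home tank; only t ≥ 0 points enter the recovery
fit. Fitting uses Levenberg–Marquardt with starts a = min(y), b = 1 min,
c = 1, d = 0 and fall-back restarts over b ∈ {0.5, 2, 5} (the bare
`nls.lm` interface, because the `nls`-style front ends reject
nearly-collinear Jacobians at the start point that LM damping handles
fine). An exactly flat series short-circuits to a = c = mean(y). Note one
systematic effect visible in the pipeline: because each series point is a
median over a 1-min window, the steep early recovery is averaged upward,
and the pooled fitted `a` sits below the generator's value — the same kind
of extrapolated-intercept behaviour the real assay's fits show relative to
their data minima.

The split-plot model is fitted by REML (`lme4`), with
fish-within-treatment random intercepts, concentration entering as its
numeric µL/L value. The joint 2-df test of {δ1 = 0, δ12 = 0} is a
likelihood-ratio test on ML refits against χ²₂; on exactly noise-free data
the mixed fit degenerates and the package falls back to ordinary least
squares with σβ² = 0 (flagged singular), which is also the analytic answer.
Its type-I error at nominal 0.01, measured over 1000 null simulations in
the acceptance suite, stays within [0.004, 0.02].

`recovery_time()` scans windows q = 0, 1, …: each tests k ∈ {q+1, …, q+15}
(7.5 min of the 30-s grid), Bonferroni-multiplied by the number of windows
examined so far, stopping at the first non-rejection; t_r = r/2 min is the
start time of that window. The sequential per-window reading was chosen over
a cumulative pooled test (available via `cumulative = TRUE`) because the
pooled reading can never recover once early windows dominate the likelihood.
One property worth knowing: t_r falls as measurement noise grows, because
the window test loses power and stops rejecting earlier — recovery-time
estimates from noisy recordings are anti-conservative, not conservative.
Under the assay-like simulation (recovery following the 60 µL/L parameters,
iid noise sd 0.01, flat control), a 20-seed Monte-Carlo run of this
implementation gives t_r ∈ [27, 43.5] min (median 34), the envelope the
acceptance tests assert against and the same scale as the assay's ~30-min
recovery.

## Problem sizes and numerical choices

The full 215-min × 32-recording design is exercised in "profile mode":
median series and chirp logs come from generator ground truth, which makes
the complete statistical pipeline run in seconds and is exact by
construction. The waveform path (synthesis → tracking → detection) is
validated on shorter recordings and reduced sampling rates chosen so that
accuracy is unaffected: tracker accuracy depends on cycles per window and
zero-padding, not absolute rate, so baseline-stability runs use a 4.8-kHz
single-harmonic carrier (30 min × 8 fish), and chirp-detection runs use
8 kHz over ~5 min with 100 ground-truth events. Determinism is contractual:
`generate_experiment()` and `run_full_analysis()` reproduce byte-identical
outputs for identical (config, seed), and seeding never leaks into the
caller's RNG stream.

Known limitations: the tracker needs ~0.5 s to descend through a
faster-than-10%-per-window frequency cliff (the adaptive band is a
rate limiter by design); chirps occurring during an amplitude collapse are
vetoed along with the collapse; fitted recovery parameters inherit the
1-min-median smoothing bias described above; and the mixed model treats
residuals as independent, while profile-mode residuals are serially
correlated baseline wander — one reason the control-condition sign tests,
not the mixed model, carry the null checks.
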