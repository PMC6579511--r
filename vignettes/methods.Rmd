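---
title: "Methods: quantifying taste-neuron imaging and PER behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying taste-neuron imaging and PER behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytaste)
```

## What this package computes

flytaste implements the analysis chain used to quantify taste-evoked
calcium signals in fly gustatory sensory neurons and to analyze the
proboscis extension response (PER) assay:

1. **Registration.** Single-plane two-photon movies (256×256 px at 3–4 Hz
   in the emulated protocol) are corrected for x-y motion within and across
   trials by sub-pixel rigid registration.
2. **Quantification.** The mean pixel intensity inside a manually drawn ROI
   gives a per-frame trace; the mean of the 20 frames immediately preceding
   stimulus onset is the baseline F₀; ΔF/F₀ = (F − F₀)/F₀. The *peak
   response* is the mean of the two highest consecutive ΔF/F₀ frames during
   the 2 s tastant presentation; the *integrated response* is the time
   integral of ΔF/F₀ over a response window. A fly *responds* to a tastant
   when its trial-averaged peak (≥3 trials) exceeds its water peak by at
   least θ = 0.15 ΔF/F₀ (15 percentage points; 0.10 and 0.20 are the
   conventional sensitivity alternatives).
3. **Behavior.** A PER test is two brief stimulus applications; a full
   extension on either trial scores positive. Groups of 15–20 flies are the
   statistical unit, summarized as percent responding. Directional-PER
   trials are tallied as toward / away / neither the stimulated side.
4. **Statistics.** Group percentages (or per-fly imaging statistics) are
   analyzed by repeated-measures ANOVA — one-way within-subject, or two-way
   mixed with a between factor such as hunger state — followed by
   Bonferroni or Dunnett post-tests.

Every stage is exercised against a synthetic-data module with known ground
truth, so the pipeline's accuracy claims are measured, not assumed.

## The transient model and why the peak statistic is unbiased

The simulator drives the indicator with the 2 s stimulus step: inside the
ROI the fluorescence is `baseline × (1 + a·k(t))`, where `k(t)` rises as
`1 − exp(−t/τ_rise)` while the stimulus is on, decays as
`exp(−(t−offset)/τ_decay)` afterwards, and is normalized to peak at exactly
1 (at stimulus offset). Defaults are τ_rise = 0.1 s and τ_decay = 0.4 s,
fast-indicator (GCaMP6f-like) values; the underlying protocol states none,
so these are generator choices, not rig estimates.

We deliberately model the *step response* of the two-time-constant system
rather than its impulse response. An impulse-shaped transient that decays
with τ = 0.4 s is sampled only 1–2 times near its maximum at a 3–4 Hz scan
rate, so the two-highest-consecutive-frame statistic would systematically
read ~40–60% below the true amplitude. A sustained 2 s tastant holds
calcium elevated for most of the stimulus window, the kernel plateaus near
1, and the peak statistic reads out `a` essentially exactly (the package
verifies slope 1 ± 10⁻⁶ against ground truth). The realized per-trial
amplitude is `a = schedule[stimulus] × adaptation^n_prior × LN(1, cv)` with
a mean-1 lognormal trial factor (default cv = 0.2, reflecting the reported
trial-to-trial variability of acid responses) and multiplicative adaptation
per preceding presentation of the same stimulus (default 0.9; responses
measured late in an ascending concentration series are smaller, which is
why presentation order is part of the session generator).

Noise is Poisson photon noise (gain, counts per photon) plus Gaussian read
noise, the standard two-photon detector model. Motion is a rigid random
walk (mean drift + jitter) applied by periodic Fourier resampling, so
shift/unshift round-trips are exact and registration accuracy can be scored
against truth without interpolation confounds. The resting projection is
visible above the surround (`roi_baseline_contrast`, default 0.5) — as in
real recordings, where the baseline fluorescence is what makes manual ROI
drawing and registration possible — plus a static smooth background
texture. Not modeled, deliberately: optics/PSF, neuropil contamination,
z-drift, multi-plane volumes, spike inference.

## Registration

`estimate_shift()` locates the cross-correlation peak on the pixel grid by
FFT, then refines it on a `1/upsample`-spaced grid (default 20, i.e.
0.05 px) in a ±0.75 px window around the coarse peak using a small
matrix-multiply DFT of the cross-power spectrum — the single-step upsampled
cross-correlation approach standard for this kind of data. Images are
mean-subtracted; a constant image is an explicit error. The refinement
window is odd-sized so the grid contains the coarse peak itself and
self-alignment returns exactly (0, 0).

The reference policy is configurable because the underlying protocol does
not state one: the default, matching "within and across trials", is the
mean of the first trial's baseline frames; per-trial first-frame and
global-mean references, or an external matrix, are alternatives. Boundary
handling is periodic (Fourier), chosen for exact testability. On synthetic
64×64 sessions with realistic drift and noise, mean absolute shift error is
~0.02–0.03 px (the acceptance bar is <0.1 px).

## Quantification choices

* **Stimulus window**: frames from onset to offset inclusive (~7 frames at
  3.5 Hz for a 2 s stimulus). An optional post-stimulus extension for the
  peak window exists (default 0 s) because slow transients can peak after
  valve closure.
* **Integrated response window**: stimulus plus 2 s post-stimulus by
  default; the source analysis does not state its window, so it is exposed
  as a parameter. The integral is the per-frame sum divided by the frame
  rate; since frames sample bin midpoints this is the midpoint rule,
  second-order accurate, and it makes a constant 0.5 ΔF/F₀ over a 2 s
  window integrate to exactly 1.0 ΔF/F₀·s.
* **θ units**: "15%" is read as 15 percentage points of ΔF/F₀ (0.15
  absolute), since responses are reported in %ΔF/F₀ throughout; a relative
  mode exists but is off by default.
* **Tie-breaking**: the earliest consecutive pair wins on exact ties.
* **Degenerate inputs**: non-finite frames inside the baseline or response
  windows reject the trial (no imputation); F₀ ≤ 0, empty ROIs, all-trials-
  excluded averages and <3-trial responder calls are errors, not silent
  values.

## The behavioral generator

Per-trial PER probability is a two-pathway logistic:

```
P = plogis(baseline_logit + fly_offset + g_app(state)·A(dose) − g_av(state)·B(dose))
```

with saturating drives `A(d) = B(d) = d/(d+2)`, appetitive gains increasing
and aversive gains decreasing with starvation, a water floor of
`plogis(baseline_logit) = 0.05`, and a per-fly latent offset
`~ N(0, 0.5)` shared by the two trials of a test (the "≥1 of 2 positive"
rule only matters under within-fly dependence, so the dependence is
explicit and controllable). The default gains — appetitive 0.5 / 3 / 4.5
and aversive 3 / 1.2 / 0.4 for fed / 1-day / 2-day starved — were set once
from the qualitative two-pathway picture (hunger both boosts the sugar
pathway and suppresses the bitter pathway): fed flies stay below a 2% test-
level response at the top acid dose while 2-day-starved flies reach ~85%,
consistent with the published ~86% benchmark, with 1-day starvation
intermediate. Because `A = B`, monotonicity of P in starvation at every
dose is structural, not tuned. The generator stores every record's
generative probability, and `per_test_prob()` gives the analytic test-level
probability `1 − E[(1−p)²]` for recovery tests.

Group sizes are drawn uniformly from 15–20. The 500 mM sucrose check is
simulated from the same fly offset (default pass rate 0.95), supporting the
`wildtype_starved` QC policy: a fly negative on *every* stimulus **and**
failing the sucrose check is excluded (the check is only administered to
all-negative flies, which is why it is conditional); the `compare_groups`
policy excludes only flies flagged very sick. Exclusion is fly-level across
the whole assay.

## Statistics: implementation notes

The ANOVA is a from-scratch balanced sums-of-squares decomposition.
Sphericity is assumed (no Greenhouse–Geisser correction), matching the
conventional analysis of this assay; percentages are analyzed
untransformed by default with an arcsine-square-root option. Incomplete or
unbalanced designs are rejected outright rather than silently refit as
mixed models — the designs this package targets are complete. An effect
with zero SS reports F = 0, p = 1 rather than 0/0.

Bonferroni post-tests follow the Prism-style convention for the mixed
design: between-group comparisons at each within level, t statistics on the
pooled subject + within-error MS, family size = pairs × levels.

Dunnett's many-to-one test uses the RM error MS and a seeded Monte-Carlo
approximation of the max-|t| null (k correlated t variates, pairwise
correlation 0.5 under sphericity; default 10⁵ draws, adjusted-p tolerance
about ±0.005). The null table depends only on (k, df, draws, seed) and is
cached, which is what makes 1000-simulation family-wise-error audits cheap.
Monte-Carlo adjusted p-values are clamped from below by the raw p so the
adjusted ≥ raw invariant survives tail noise.

## What a green test does and does not establish

The synthetic movies have rigid, periodic motion, a single bright ROI, and
stationary noise; the synthetic behavior has exchangeable flies and a
correctly specified logistic dose-response. Green acceptance tests
therefore establish that the *pipeline's arithmetic and inference are
correct under the stated model* — registration recovers known shifts to
<0.1 px, amplitudes are recovered within 10%, type-I error is calibrated
within ±0.02 of α, and the hunger-switch interaction is detected in >80%
of simulated experiments. They do not establish robustness to non-rigid
motion, ROI mis-specification, neuropil contamination, or model
misspecification of the dose-response — real-data concerns outside this
package's scope. Published biological effect sizes (e.g. specific %ΔF/F₀
values) come from live-fly data that are not reusable at desk scale; they
serve here as calibration anchors for the generator, not as reproduction
targets.

## Runtime and determinism

All randomness flows from a single integer seed through named substreams
(`substream_seed()`), so every generator is bit-reproducible and adding
draws to one module does not perturb another. Acceptance simulations run at
64×64 px (the registration criterion's stated size) to keep the full suite
within minutes on one CPU; the statistics criteria use their stated 1000
(calibration) and 200 (power) simulation counts unreduced.
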