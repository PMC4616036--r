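---
title: "Quantifying body-size information in juvenile crocodilian calls"
author: "callometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying body-size information in juvenile crocodilian calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callometry)
```

## The scientific problem

Juvenile crocodilians produce short, harmonically rich "distress" calls when
seized. As an animal grows, its vibratory membrane (the palatal valve) and
the resonating nasal and buccal cavities grow with it, so two things happen
to the call: the fundamental frequency (pitch) drops, and the energy in the
frequency spectrum shifts downward. Whether mothers exploit this acoustic
size information — responding more readily to smaller, more
predation-vulnerable juveniles — is a question answered with a combination
of descriptive acoustics (how exactly do calls change with body size?),
synthetic-stimulus design (can pitch alone drive the response?), and
playback experiments scored on behavioural scales.

`callometry` implements that entire chain as reusable, tested code: the 13
call descriptors, the pitch tracker, the PCA acoustic space and its
mixed-model size-coding tests, the stimulus synthesizer, the
playback-response scores and their analysis, and — because the original
recordings are not publicly deposited — a seeded synthetic call population
that reproduces the statistical structure the analysis assumes, so that the
whole pipeline can be exercised end to end and its statistical calibration
verified by simulation.

## The 13 call descriptors

Each call is summarized by 13 variables in two families.

**Eight spectrum descriptors**, computed from the call's averaged
magnitude spectrum within a 0–5 kHz band (Hann-windowed frames of 1024
samples with 99% overlap, magnitudes averaged across frames and normalized
to unit mass): the mode (frequency of maximal energy), the energy quartiles
Q25 and Q75 (first frequency at which cumulative mass reaches 0.25 / 0.75 —
a first-crossing convention without interpolation, deterministic at the
~43 Hz bin resolution of the defaults), their difference IQR, the spectral
centroid \(\sum_k f_k m_k\), the skewness and kurtosis of the spectral mass
distribution (third and fourth standardized central moments), and the
spectral flatness sfm (geometric over arithmetic mean of the bin
magnitudes, near 1 for noise and near 0 for a pure tone). Whether the
original analysis averaged magnitude or power spectra, and with which
window, is not recorded; magnitude + Hann is used here and both choices are
isolated behind `spectrumConfig()`. All eight descriptors are invariant to
recording gain. A spectrum with all its mass in one bin has undefined
moments; skewness and kurtosis are then 0 by convention and the result is
flagged.

**Five pitch descriptors** summarize the fundamental-frequency contour:
start, maximum, minimum, mean and end pitch.

## The pitch tracker

F0 is estimated by normalized cross-correlation: for each frame, a short
segment (default 10 ms) is correlated against itself at every candidate lag
in `[1/fmax, 1/fmin]` (defaults 1200 Hz and 150 Hz, covering the juvenile
range with margin), each correlation normalized by the energies of the two
segments so that a periodic frame scores 1 regardless of amplitude or
tapering. Among near-best local maxima the smallest lag wins (suppressing
half-frequency errors), and the winning lag is refined by parabolic
interpolation; a frame is voiced when its best correlation reaches the
voicing threshold (default 0.45). Because the estimate of a frame reflects
the whole correlated stretch, frame times are reported at
`t0 + (window + lag)/2`.

Interactive pitch-editor workflows repair octave jumps by hand; here that
step is a deterministic rule (`correctOctaveJumps()`): a voiced frame whose
ratio to the running median of its five nearest voiced neighbours falls
within a tolerance of exactly 2 (or 1/2) is halved (doubled), iterated to a
fixed point, so the repair is idempotent and smooth contours pass through
untouched. Removing the human from that loop is what makes the pipeline
reproducible.

**Contour summaries and the edge problem.** A frame-based tracker cannot
place an estimate at the very first or last sample of a call: the first
usable frame centre sits roughly half a window inside the call. For
contours that move quickly near their edges — the synthetic stimuli fall by
thousands of Hz per second — the literal "F0 of the first/last voiced
frame" is biased by several percent, and an arithmetic frame mean is biased
because the frame grid does not cover the call edges. `summarizeContour()`
therefore extends tracked contours to the call edges: start and end pitch
are local-linear extrapolations of the nearest voiced frames to t = 0 and
t = duration (with a gap cap and a clamp against wild extrapolations), and
mean pitch is the time-weighted trapezoidal mean of the extended contour —
the convention PRAAT-style "mean pitch" measures follow. Min and max are
taken over the extended contour so the ordering invariants always hold.
Hand-built contours that carry no call duration use the literal frame
conventions instead. With these conventions the synthesized stimuli
round-trip their printed design anchors within 3%, which is the package's
own acceptance check; contours whose rising limb is shorter than about two
frames remain unresolvable in principle, which is why the synthetic
population's start-pitch feature is a (consistently biased) proxy rather
than an exact recovery.

## Stimulus synthesis

The three experimental signals are frequency-modulated pure tones defined
only by printed anchors: SYNTsmall (start 630 Hz, mean 638 Hz, end 350 Hz,
160 ms), SYNTlarge (300/384/200 Hz, 160 ms) and the unmodulated 500 Hz
control NOFM. The contour family chosen to realize them is two-segment
piecewise-linear: a rise from `fStart` to a peak at a fraction p of the
duration (default 0.25), then a fall to `fEnd`, with the peak solved in
closed form so the time-average equals the target mean:

\[ f_{peak} = 2 f_{mean} - p\, f_{start} - (1-p)\, f_{end}. \]

For the printed constraints this gives 856 Hz (SYNTsmall) and 543 Hz
(SYNTlarge) — inside the printed natural maximum-pitch ranges (969 and
529 Hz) — but the true FM shape of the original stimuli between their three
anchors is unknown; only the anchors are treated as ground truth, and the
rise–fall shape is a modelling choice mirroring natural calls. When the
solved peak falls below both endpoints the requested mean is unattainable
in this family; the design degrades to a single linear segment and reports
the achievable mean. Tones are synthesized by integrating the instantaneous
frequency into phase (click-free by construction), with 5 ms raised-cosine
ramps, and `round(duration × rate)` samples so durations are exactly
recoverable. Harmonic-stack call mimics add partials at integer multiples
of the contour with amplitudes decaying by a spectral tilt (dB per
harmonic); with one harmonic the stack reduces exactly to the pure tone.

## The synthetic call population

No recordings are deposited, so the generator is the pipeline's test bed.
Its defaults are calibrated to the published per-size-class acoustic means
(`allometryAnchors()`): for both mean pitch and spectral centroid, class
means are regressed on class midpoints, weighted by the number of recorded
individuals per class and excluding single-individual classes (a class mean
from n = 1 is not a usable anchor — notably the 100–120 cm Nile class,
whose single 222 Hz individual would otherwise dominate the slope), with
one shared slope across species and per-species intercepts. The shared
slope mirrors the finding that the species follow a common allometric rule
(no size-by-species interaction); the calibrated model predicts the Nile
30/90 cm anchors within one printed class SD. Linear (not log-log)
pitch–length relations are used, matching the original regressions, and age
is deliberately not modelled.

Each individual draws a body length uniformly over its species' recorded
range (alligator 24–113 cm, Nile 26–118, caiman 25–60, Morelet's 51–61,
Orinoco 30–100), an individual-level acoustic offset (SD 45 Hz pitch,
150 Hz centroid), and 1–20 calls (rounded normal, mean 15, SD 5,
truncated). Each call draws call-level noise (SD 30 Hz pitch, 100 Hz
centroid; the individual/call split is an assumption — only their
combination is constrained by the printed class SDs), builds a contour with
start ≈ 1.25× and end ≈ 0.68× the mean (ratios from the published class
means, jittered per call, with the start ratio clamped to keep the
rise–fall design solvable) and an early peak (p = 0.1), and solves the
spectral tilt of its harmonic stack (by `uniroot` on the closed-form stack
centroid) so the call's centroid follows the centroid allometry.

Two rendering paths share this generative core. The audio path synthesizes
every call and re-analyses it with the full signal chain; it is exercised
end to end at small n in the tests (tracked mean pitch agrees with the
generator's target within 3%, measured centroid within ~5%). The analytic
path computes the 13 descriptors directly from the idealized contour and
harmonic line spectrum plus 3% multiplicative measurement noise; it is
orders of magnitude faster and drives the replicate-heavy simulation
studies. What the generator does **not** emulate: background noise,
reverberation and microphone coloration; any formant-like resonance, so the
spectral mode tracks the fundamental rather than a mid-band energy
concentration as in real calls; non-stationary amplitude envelopes; and
individual vocal idiosyncrasies beyond a level offset. Passing tests
therefore demonstrate that the *analysis machinery* is correct and
calibrated, not that real crocodilians behave like the generator.

## Acoustic space and size-coding tests

The 13 descriptors are standardized (they carry mixed units) and reduced by
correlation-matrix PCA without rotation; the first two components are the
acoustic dimensions AD1 and AD2, with signs fixed so the centroid loads
positively on AD1 and mean pitch positively on AD2. The PCA is fitted on
call-level rows — matching the mixed models, which are call-level with an
individual random intercept — and per-individual mean scores serve the
acoustic-space map and the allometric regressions. On study-scale synthetic
data the loading structure reproduces the published pattern qualitatively:
spectral-energy descriptors dominate AD1, mean pitch dominates AD2, with
AD1 explaining the larger share of variance.

Size coding is tested by likelihood-ratio tests between nested linear mixed
models (`lme4`, maximum likelihood — REML likelihoods are not comparable
across fixed-effect structures): size + species against species alone (df
1), against size alone (df = species − 1), and size × species against the
additive model (df = species − 1). Singular fits warn but return. The LRT
statistic is invariant to rescaling the size covariate. Per-species
regressions of individual mean pitch and centroid on body length are
ordinary least squares; the slope difference between two species is the
interaction term of the pooled two-line model and the intercept difference
is the species term of the common-slope model.

Simulation calibration (the problem sizes are the package's own choices,
stated here so the numbers in the test suite are interpretable):

* **Power / recovery** — 50 replicates at the full study scale (164
  individuals, ~15 calls each, analytic path): the size LRT is required at
  p < 0.001 on both ADs in ≥ 95% of replicates, and the per-species OLS
  slopes must cover the generator's shared slopes within their 95% CIs in
  ≥ 90% of the 200 CIs.
* **Interaction null** — the same replicates: per-test rejection at
  α = 0.05 stays below 0.16 with median p above 0.2. The pitch channel
  satisfies the shared-slope null exactly; the spectral descriptors are
  mildly nonlinear transforms of the latent centroid allometry (quartiles
  quantize to the harmonic grid, the tilt solution is curved), so a slight
  AD1 lack-of-fit is expected and observed — rejection stays near, not at,
  the nominal rate.
* **Type-I error** — 200 replicates with both slopes at (numerically) zero,
  on a reduced population (2 species × 12 individuals, ~6 calls) since
  type-I calibration does not require study-scale n: the size-term
  rejection rate at α = 0.05 must lie in 0.05 ± 0.03 and the mean p near
  0.5.

## Playback scoring and analysis

Field responses are coded on the ordinal −2..+2 intensity scale with the
boundary conventions "exactly half the distance → +1" and "exactly 5 m
retreat → −1" (the stronger codes require *more than*). Captive responses
are triplets — orientation (0–2), number of females approaching, maximal
approach (0–2) — collapsed into the first principal component of the
standardized criteria, sign-fixed so more approaching females means a
higher score; the composite is invariant to affine rescaling of any
criterion, and constant criteria are dropped with a warning.

The stimulus effect is a mixed-model LRT (ML) with random intercepts for
the experimental unit and the playback order; order has very few levels and
its variance is often estimated at zero (warned), so a fixed-effect order
fallback is available behind `orderAsFixed = TRUE`. Where the original
write-up labels some of these tests "GLM" while describing linear mixed
models, the mixed-model LRT is implemented as the single canonical test,
with a Gaussian response assumed. Post-hoc pairwise contrasts are
Tukey-style simultaneous comparisons (`multcomp::glht`, single-step
adjustment) computed from a REML refit and referenced against a t
distribution with containment degrees of freedom
(n − (categories−1) − (units−1) − 1): with eight units the asymptotic
normal reference is anti-conservative (simulated family-wise error ~0.16
instead of 0.05), while the t reference restores FWE ≈ α, which the test
suite verifies over 200 null replicates.

The simulated captive experiment (`simulatePlaybackExperiment()`) gives
each cluster a latent response strength — stimulus effect + cluster
intercept (SD 0.5) + order effect (SD 0.2) + trial noise (SD 0.5) —
discretized into the two ordinal criteria and driving a Poisson count of
approaching females. For the elevated-category demonstration the SYNTsmall
latent effect is set to 2.0, chosen by a power sweep (effects ≥ 1.5 give
≥ 95% probability of the full qualitative pattern: the elevated category
significant against both others, the remaining pair not); the harness is
required to reproduce that pattern in ≥ 90% of 100 replicates.

## Numerical choices and degenerate inputs

* Quartiles: first-crossing, no interpolation; ties in the spectral mode go
  to the lowest bin.
* Spectral flatness uses the geometric mean, so any exactly-zero bin sends
  it to 0; measured spectra never contain exact zeros (window leakage).
* The tracker clamps refined F0 into `[fmin, fmax]` and declares a frame
  unvoiced below an energy floor; a fully unvoiced call is an error, and
  such calls are excluded (and logged) during feature assembly.
* `uniroot` tilt solving clamps unattainable centroid targets to the
  attainable range of the harmonic stack.
* Generation errors out (rather than silently clamping) if a drawn mean
  pitch falls at or below 50 Hz — with the default per-species size ranges
  this is a > 4.5 SD event.
* All randomness flows through per-call `seed` arguments or a single
  dataset seed; the caller's RNG state is saved and restored.

## Known limitations

* Segmentation (`segmentCalls()`) is a stand-in: how calls were delimited
  before the original analysis is not recorded, so the envelope segmenter
  is a reasonable default, not a reconstruction.
* The tracker's frame/fmin defaults trade edge resolution against the
  lowest trackable pitch; contours below ~150 Hz need a custom `fmin` and
  correspondingly longer frames.
* The 99% spectral overlap of the reference configuration is honoured but
  expensive; ~75% overlap is spectrally near-equivalent for these
  descriptors and configurable.
* Headline chi-square statistics of the original field and captive
  experiments depend on undeposited recordings and live animals; they are
  covered here by qualitative pattern checks and calibration properties,
  not numeric reproduction.
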