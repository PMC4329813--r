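---
title: "Methods: stimuli, stereology and simulated cohorts in cochleostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimuli, stereology and simulated cohorts in cochleostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleostat)
```

`cochleostat` models one complete noise-induced hearing loss (NIHL)
experiment in the mouse: synthesize a band-limited "violet" exposure
stimulus, lesion a cochlea, count surviving hair bundles stereologically,
plot the cytocochleogram on a place–frequency axis, and compare it with
simulated ABR/DPOAE audiometry. This vignette documents the models, the
parameters that matter, and the design decisions taken where the problem
was genuinely open.

## Violet stimuli

Both stimulus kinds apply a gain that rises linearly with frequency
("violet" coloring, +6 dB/octave in power) inside a band
$[f_\mathrm{low}, f_\mathrm{high}]$:

* **Violet noise** (`synth_violet_noise()`) reshapes Gaussian white noise
  in the frequency domain: the amplitude spectrum is multiplied by
  $f/f_\mathrm{high}$ inside the band and zeroed outside. The exact
  high-pass filter used to produce the original exposure noise is not
  published; we use raised-cosine tapers over 5% of the band at each edge,
  which avoid ringing while keeping out-of-band leakage far below the 1%
  band-containment requirement. The frequency-domain route was chosen
  because it realizes "gain linear in frequency" exactly rather than
  approximating it with an IIR slope.
* **Violet sweep** (`synth_violet_sweep()`): instantaneous frequency rises
  linearly from $f_\mathrm{low}$ to $f_\mathrm{high}$ over the sweep
  duration (default 10 s), with amplitude envelope proportional to the
  instantaneous frequency; sweeps tile back-to-back over the total
  duration (30 min in the modeled paradigm, 180 complete repeats). Because
  the sweep spends equal time per Hz and its envelope is linear in $f$, its
  long-term spectrum has the same +6 dB/octave slope as the violet noise.

Verification (`verify_stimulus()`) estimates the power slope by a
log–log linear fit to a Welch-averaged periodogram (Hann windows, 4096
points, 50% overlap) over the band interior — the tapered edges are
excluded because they do not follow the in-band slope — plus the fraction
of power outside the 10%-widened band and, for sweeps, the linearity
($R^2$) of the spectrogram ridge. Levels are set by RMS scaling against a
configurable reference pressure (default 20 µPa); no transducer or chamber
transfer function is modeled, so "dB SPL" refers to the digital waveform.
The default 96 kHz sampling rate leaves comfortable margin above the
20 kHz band edge. The 9–13 kHz variant is the same synthesis with
different band edges, which is all the exposure paradigm changes.

## The synthetic cochlea

`build_control_map()` emulates a flattened, phalloidin-stained
organ-of-Corti whole mount covering the apical 80% (configurable 70–85%)
of a 5.13 mm basilar membrane, the basal "hook" being lost to dissection.
Bundles are generated per row (1 IHC row at 1/8 per µm, 3 OHC rows at 1/9
per µm each) as independent homogeneous Poisson processes along the
length. Two choices deserve comment:

* **Poisson, not lattice.** A real epithelium is nearly crystalline; a
  jittered lattice would be strongly underdispersed and would produce
  coefficients of error far below the empirical ~0.17. Poisson placement
  reproduces the count-variance regime in which the reported precision
  arises, which is what the estimator's calibration needs.
* **Lateral positions are uniform across the fringe.** The stereociliary
  fringe (default width 28 µm) is the reference space. With the default
  25 µm frames jittered about the fringe midline, *any* lateral layout
  concentrated enough to sit inside every frame (e.g. fixed row offsets)
  would be oversampled by the factor fringe/frame = 28/25, biasing
  densities up by 12%. A uniform lateral marginal makes the capture window
  exactly `frame_height / fringe_width` of the bundles regardless of the
  jitter draw, so the corner-count ratio estimator is exactly unbiased.
  Row identity is kept as a label; only the lateral coordinate is
  randomized. The closed-form expectations are then simply
  `rows × intensity / fringe_width × 1000` per 1000 µm²: 11.90 for OHC and
  4.46 for IHC — above the >10 and >4 floors reported for control ears.

What the generator does **not** emulate: stereocilia morphology (a bundle
is a point, present or absent), supporting-cell pathology, the spiral
geometry (positions are percent of arc length), dissection artifacts other
than global coverage, and inter-animal variation in intensity. Passing
tests therefore demonstrate correctness of the estimators on a known
ground truth, not fidelity to any individual micrograph.

## The lesion model

`survival_probability()` gives each bundle a loss probability

$$p_\mathrm{loss} = \mathrm{clip}\Big(\mathrm{peak}(L)\,\big[\,w_f F(cf) + S(cf)
  + g\,\max(0, d-55)\,\big],\,0,\,1\Big)$$

with $cf$ the bundle's characteristic frequency from the place map and $d$
its percent distance from the apex:

* $S$ — a Gaussian in octave distance to the band's upper edge shifted
  **1 octave basally** (σ = 1.2 octaves): the classic displacement of
  noise injury half to two octaves above the exposure band.
* $F$ — an **in-band direct component**, Gaussian in octave distance to the
  band's geometric mean, σ = max(0.4 × bandwidth, 0.2) octaves, weighted by
  $w_f = \min(1, 0.5/\mathrm{bandwidth~in~octaves})$. The weight encodes an
  energy-density argument: a fixed overall level spread over fewer octaves
  delivers more energy per octave, so a narrow band lesions its own place
  acutely while a wide band's direct damage is diluted. Without this
  component a single shifted Gaussian cannot reproduce the observed focal
  lesion of the 9–13 kHz exposure at sectors 25–30 (the 10.8 kHz place):
  damage anchored only at 26 kHz (= 13 kHz + 1 octave, the 60% place)
  would decrease monotonically toward the apex across the whole 5–55%
  range.
* $g$ — a basal susceptibility gradient (0.006 per % beyond 55%),
  capturing the progressive basal decline seen in all exposed groups.
* $\mathrm{peak}(L)$ — piecewise-linear in level through (85 dB, 0),
  (105 dB, 0.55), (120 dB, 0.98): no loss at ambient levels, partial loss
  at 105 dB SPL, near-total loss at 120 dB SPL. IHC loss is multiplied by
  `ihc_factor` = 0.6 (OHCs are the more vulnerable class).

The peak-loss values, component weights and gradient are **calibration
constants**, not biology: they were set so that the default 105 dB
2–20 kHz exposure reproduces the reported mean OHC coefficient of error
(~0.21 versus ~0.17 in controls), the 120 dB exposure empties the basal
region, and the 9–13 kHz exposure focuses on sectors 25–30 — all under the
stated geometry and intensities. Under these defaults the 105 dB 2–20 kHz
exposure leaves mean OHC survival ≈ 0.65 across the dissected length.
Lesioning is one-shot by design: re-exposing an already lesioned map is
rejected rather than compounding losses whose interaction the model does
not describe.

## Stereology

`estimate_sector()` composes four operations, all exposed individually:

1. **Frame placement** — systematic-uniform-random along the sector (one
   frame per equal subinterval at a common random offset, so frames never
   overlap), lateral jitter uniform within the fringe. A sector too short
   for the requested frames is an error, not a silent reduction.
2. **Counting** — Gundersen edge rule: strictly inside, or on the top/right
   inclusion edges; bottom/left exclusion edges do not count. The rule
   itself is a convention; any consistent inclusion/exclusion pair is
   unbiased.
3. **Reference area** — corner-point counting: each of the four frame
   corners hitting the fringe contributes a quarter of the frame area.
   With the default geometry frames sit inside the fringe and all corners
   hit; the machinery matters for non-default frames and substrates.
4. **Density and error** — $N_A = \Sigma q \cdot 1000 / \Sigma a$, and
   Cochran's ratio-estimator CE computed per cell class over the per-frame
   $(q_i, a_i)$, classes sharing the same frames and areas. A sector with
   zero counts has $N_A = 0$ and an undefined (flagged `NA`) CE; a zero
   sampled area is an explicit error, never a silent zero or infinity.

**The $n/(n-1)$ factor.** The bare quadratic form
$\Sigma q^2/(\Sigma q)^2 + \Sigma a^2/(\Sigma a)^2 - 2\Sigma qa/(\Sigma q \Sigma a)$
and the textbook ratio-estimator variance (sample variances over $n$)
differ exactly by $n/(n-1)$. With 5 frames per sector this matters:
Monte-Carlo shows the corrected form's mean tracks the Poisson limit
$1/\sqrt{nm}$ to ~2% and lands on the reported 0.17/0.21 values, while
the uncorrected form undershoots by ~15%. The corrected form is therefore
the default (`ce_correction = TRUE` in `sampling_design()`); the
uncorrected variant remains available since which variant produced the
published values cannot be determined from the text, and whether CE was
computed per class or pooled is equally unstated (per class here, sharing
areas).

Defaults — 5 frames of 25 × 25 µm per 5% sector — give expected per-sector
OHC totals of ~37 bundles and a mean control CE of ~0.15–0.16; they are
calibrated choices, as the original counting parameters are not reported.

## Cochleogram and place map

Sectors are half-open 5% bins `(k−5, k]` labeled by their basal edge,
apex = 0. The place map is log-linear, $f = 10^{(A - d_\mathrm{base})/B}$,
with the published mouse constants A = 156.5, B = 82.5 as defaults
(≈4.8 kHz at the apex, ≈79 kHz at the base; the undissected basal fifth
corresponds to ≈45–79 kHz, matching the reported 50–80 kHz information
loss). The cited anatomical alternative map does not print its constants
in the modeled study, so rather than hard-coding guessed values the
backend accepts arbitrary (A, B); the frequency axis attached to a
cochleogram uses each sector's midpoint. Region summaries group sectors
5–25 (apical), 30–55 (middle) and 60–80 (basal); the pooled region CE is
the count-weighted root-mean-square of sector CEs, a pragmatic rule since
no pooling rule is published. Percent loss against a control cochleogram
is clipped to [0, 100] — sampling noise can push a lesioned estimate above
control — and sectors with zero control density are flagged rather than
divided by.

## Simulated audiometry

Each subject × stimulus × timepoint draws a true threshold from a
calibrated normal distribution (`default_calibration()`), simulates a
response-versus-level series, and detects the threshold by rule: lowest
presented level whose amplitude exceeds `criterion_k` (default 2) times
the noise floor with all higher levels also responding. Level grids
descend 90 → 10 dB SPL in 5 dB steps for ABR and 80 → 30 for DPOAE. The
presentation protocol stops at 20 dB SPL, yet reported baselines are
17 ± 5 dB; the grid floor was therefore extended to 10 dB so such
baselines are representable — detections at the floor or absent at the
ceiling are flagged and excluded from summaries with their count
reported. The response model is a clipped linear growth from zero at
threshold to saturation 40 dB above (offset 5 dB so the threshold level
itself responds); noise-free, the detected threshold is exactly the grid
ceiling of the true threshold.

The calibration table encodes the study's group trajectories: flat
controls; a ~50 dB click shift at day 2 in all exposed groups; progressive
worsening without recovery after 120 dB; partial recovery after 105 dB;
and for the 9–13 kHz group a persistent 8–10 kHz audiogram notch whose
day-28 tone shifts are rank-aligned with the structural lesion, so the
structure–function Spearman correlation is positive by construction — the
simulation demonstrates the analysis chain, not an independent biological
discovery. DPOAE primaries follow $f_1 = 0.909F$, $f_2 = 1.09F$ (ratio
$f_2/f_1 = 1.199$; the paradigm's stated "f1/f2 = 1.2" is interpreted as
this $f_2/f_1$ ratio, the only reading consistent with the multipliers),
distortion product at $2f_1 - f_2$. Treatment arms (saline/P17/P144)
share the exposed distributions — an explicit null effect. Threshold
shifts are paired post-minus-baseline differences; negative shifts
(recovery) are legal, and flags propagate.

## Numerical and reproducibility choices

* Half-open intervals everywhere (sectors, counting edges) so boundary
  cells belong to exactly one bin and edge bundles to exactly one frame.
* All stochastic functions take integer seeds and use scoped RNG
  (`withr::with_seed`), so library state is never disturbed; pipeline
  stages derive child seeds from one master seed and record them in a
  manifest, making any stage regenerable in isolation. Reruns produce
  byte-identical CSVs.
* CE is floored at zero before the square root to absorb rounding on
  exact-ratio inputs.
* WAV I/O is a minimal self-contained RIFF reader/writer (PCM16 and
  float32, mono).
* Test problem sizes are chosen for tight Monte-Carlo bounds at modest
  cost: 200 maps for generator convergence (<2%), 100 long-sector seeds
  for estimator unbiasedness (<5% at 50 frames), 10⁴ replicates for the
  Poisson CE limit, 10–20 seeds for lesion-pattern checks.

## Known limitations

Percent positions ignore true cochlear curvature and length variation;
the lesion model is phenomenological (no synaptopathy, no temporary
component — structure is evaluated once, at end point); ABR simulation is
threshold-level only (no wave morphology, latencies or amplitudes);
audiometric and structural noise are independent, so the simulated
structure–function correlation lacks the shared biological variance of
real animals; and the calibration constants inherit the uncertainty of
the graphical sources they were tuned against.
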