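---
title: "The resonance-deflection model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The resonance-deflection model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vtsynth)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what the test suite does and does not establish.

## The model in brief

Speech is usually modeled by orchestrating articulators. This package
implements the complementary view: an utterance is a timeline of
*relative acoustic events*, each specifying only the intended directions
of change of the first three vocal tract resonances (an RDP, three
coefficients in [−1, 1]) with a Gaussian time course. The vocal tract
shape that realizes those deflections is *derived*, not scripted, via
acoustic sensitivity functions. Constriction locations — lips for a
bilabial pattern, post-incisor region for an alveolar one, palate
junction for a velar one — emerge from the acoustics alone, and because
event functions overlap in time, coarticulation is automatic.

The pipeline: neutral tract Ω(i) → transmission-line acoustics
(resonances, modal pressures/flows) → energy-based sensitivities S_j(i) →
balanced/normalized Z_j(i) → combined pattern y(i) = Σ δ_j Z_j(i) →
deformation D(i) = 1 − μE(n) y(i)/min y(i), clipped at 0 → A(i, n) =
Ω(i) D(i, n) → waveguide synthesis.

## Assumptions

- One-dimensional (plane-wave) acoustics in a tubelet chain; valid below
  roughly 4–5 kHz for an adult tract. No nasal coupling.
- The sensitivity relation is first-order perturbation theory: exact for
  infinitesimal, lossless perturbations, approximate at the finite
  deformations the model actually applies. The model uses only the
  *shape* of the sensitivities (via the balanced Z_j), so this is a
  design principle, not a quantitative requirement.
- The glottal source is non-interactive: flow is prescribed, not coupled
  to tract pressure.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_sections` | 44 | – | tubelet count; ties into L = c/(2F_s) |
| `sound_speed` | 35 000 | cm/s | warm moist air |
| `sampling_rate` | 44 100 | Hz | audio rate; fixes L = 0.396825 cm |
| `frame_rate` (f_svt) | 146 | Hz | tract-modulation rate (articulatory-database convention) |
| `mu` | event-specific | – | constriction degree; 1 = point closure |
| `t_p`, `t_w`, `t_h` | event-specific | s | Gaussian peak, FWHM, hold |
| adjustment cutoff | 0.1 | × spatial Nyquist | low-pass in the S→Z balance |
| `activity_threshold` | 1e−3 | – | event amplitude below which a frame skips the event |
| `occlusion_floor` | 0.01 | cm² | area floor for in-loop acoustics |
| `gap_threshold` | 0.05 | cm² | "occluded or nearly so" for track breaks |
| `re_c`, noise gain | 1200, 1e−6 | – | turbulence gate and scale |
| noise band | 500–2500 | Hz | band-pass of the noise source |

Loss defaults (`loss_config()`) are standard tube-acoustics values in cgs:
wall resistance 1600 dyn·s/cm³, wall mass 1.5 g/cm², wall stiffness
3×10⁵ dyn/cm³ (per unit wall area), air density 0.00114 g/cm³, viscosity
1.86×10⁻⁴ dyn·s/cm², and a piston-in-baffle radiation load. The wall
shunt raises the first resonance a few percent while the radiation
inertance lowers all peaks a similar amount, so lossy peaks sit within 5%
of the lossless ones — a property the tests check.

## Design decisions in genuinely open territory

**Deformation offset.** The deformation is implemented as
D = 1 − μE·y/min(y) (clipped at 0). This is the unique affine form that
satisfies all the stated behaviors at once: neutrality at E = 0, complete
closure exactly at argmin y when μE = 1, a spreading contiguous closure
for μE > 1, and synergistic expansion (D > 1) where y > 0. It is isolated
in `deformation_frame()` so an alternative reconstruction is a one-line
change.

**Zero-phase adjustment filter.** The |S_j| low-pass in the adjustment is
applied forward–backward (zero-phase) along the section axis with
odd-reflection padding. A causal pass would shift the smoothed trend
lipward and with it the constriction locations; reflection padding
matters because 44-sample vectors are short. The cutoff "0.1" is read as
a fraction of the spatial Nyquist (the usual signal-processing
convention).

**Hold placement.** A positive hold t_h inserts a unit plateau *centered*
on t_p, with the two Gaussian halves attached at its edges — the least
committal reading; it lives in `event_function()` alone.

**Sequencing cadence.** Multi-event frames recompute resonances and
sensitivities of the working tract for *every* event, in ascending-μ
order (ties: earlier t_p, then script order). A cached fast mode
(`cache_sensitivities = TRUE`) reuses the neutral tract's sensitivities
for the first event of each frame; it is off by default because the full
recomputation is the point of the sequencing loop.

**Occlusion floor.** The frequency-domain solver requires strictly
positive areas, so when an earlier event has (nearly) closed the working
tract, areas are floored at 0.01 cm² *for the acoustics only*; geometry
keeps true values. The same floor serves the resonance tracker, which
marks frames below 0.05 cm² as gaps ("occluded or nearly so" is not
given a number anywhere authoritative; 0.05 cm² is our configurable
choice).

**Voice source.** The kinematic vocal-fold model behind the original
synthesis demonstrations is not specified in the text we implement from;
the package uses a parameterized glottal flow pulse (raised-cosine open
phase, open quotient 0.6, peak 350 cm³/s) with F0 breakpoints and
abduction gestures (amplitude ramps out, a 150 cm³/s leak with a
0.15 cm² glottal opening ramps in). Any per-sample flow generator can be
substituted through the `voice_source` interface.

**Eq.-style consistency test without the branch.** The first-order shift
identity is verified without the piriform branch: the sensitivity
normalization sums energy over main-tract sections only, so
branch-stored energy would bias the comparison for reasons unrelated to
the identity being checked.

**Editorial event values.** The demonstration-sentence timing (t_p, t_w,
t_h; 1.64 s; f_svt = 146 Hz) is as published. Deflection magnitudes and
constriction degrees are only partially specified there, so the fixtures
make documented choices: stops use the canonical place patterns at
μ = 1.0 ({d}: 1.1), {f} = (−1, −1, 0) at μ = 0.98, {r}/{l} =
(−0.3, 0, ∓/±1) at μ = 0.8/0.9, vowels at μ = 0.5 with target-formant
sign patterns ({ao} = (+1, −1, 0); {eh}, {ih} negative-δ₁ /
positive-δ₂,δ₃; {ah}, {aa} positive-δ₁ / negative-δ₂). Events carry
explicit consonant/vowel tags because {r} (μ = 0.8) falls below the
μ ≥ 0.9 tagging heuristic of the vowels-only variant.

## Numerical choices

- Frequency responses are evaluated on a 50–5000 Hz grid at 10 Hz;
  peaks are refined parabolically on the dB grid and then polished by
  golden-section maximization of the continuous response, which resolves
  shifts far below the grid spacing (needed for the first-order
  brute-force comparisons).
- The waveguide uses half-sample tubelets (two scattering passes per
  audio sample), so a 44-section lossless closed-open tube rings at
  exactly F_s/88 = 501.1 Hz and odd multiples — the analytic
  cross-validation anchor. Interior losses are a frequency-flat
  per-section attenuation (0.9965 per half-pass), boundary reflectances
  0.98 (glottis) and −0.9 (lips), output is differentiated lip flow.
- Areas below 0.001 cm² are clamped for scattering, making occlusions
  (nearly) fully reflecting closed junctions; release transients emerge
  from the stored wave states.
- Movie frames are linearly interpolated to per-sample areas.
- Noise streams are uniform in [−0.5, 0.5], band-pass filtered, and
  fully determined by `rng_seed`; synthesis is bit-reproducible.

## What the tests show — and what they do not

The test suite establishes the model's internal claims at desk scale: the
analytic tube geometry; quarter-wave agreement of both engines; bounded,
polarity-correct, amplitude-invariant sensitivities; first-order shift
predictions within 10% (or 0.001 absolute near sensitivity
zero-crossings, where relative error is meaningless); the deformation
identities; and — the central claim — that in both demonstration
sentences every specified nonzero deflection is realized with the right
sign relative to its running context (vowels vs. the neutral reference,
consonants vs. the vowels-only rendering), including the coarticulated
{t} whose second and third resonances exceed the already-raised diphthong
tracks.

Two honest caveats. First, the built-in neutral tract is a stand-in: its
resonances (about 501, 1294, 2256 Hz with the branch) are speech-like but
are not the published adult-male values (596, 1401, 2331 Hz), which
require the externally published area table; load one with
`read_area_table()` to reproduce them. Second, the time-domain engine
omits the piriform branch and the reactive part of the wall load, so its
spectral peaks sit at the lossless frequency-domain positions; audio
checks therefore reference the lossless, unbranched model. Passing tests
show the machinery is self-consistent, not that the synthesis matches any
human talker — the model's authors position perceptual evaluation and
articulatory comparison as separate work, and so do we.

A related subtlety: "more drive never widens the tract" is true at the
constriction site (the minimum of y) but not for the whole-tract minimum
area at small drives — with the stand-in tract the global minimum starts
at the laryngeal inlet, where y can be positive, so a small deformation
first *raises* the global minimum while the constriction narrows. The
tests assert the site-wise form.

## Problem sizes

Test-suite renderings use the two 1.64 s sentences (239 frames, 44
sections) with full per-event sensitivity recomputation, plus short
(0.05–1 s) scripts for unit checks; audio runs at 44.1 kHz. These sizes
were chosen as the smallest that exercise every code path of the
sentence-level demonstrations.

## Known limitations

- No nasal tract, no interactive source, no articulator-level
  parameterization (deliberately: the model is area-function-based).
- Sensitivity theory is first-order; large μE deformations rely on the
  sign structure surviving, which the deflection suite verifies
  empirically per sentence.
- The Reynolds-number formula and air constants for the turbulence gate
  are standard stand-ins (hydraulic diameter of the circular-equivalent
  section, ν = 0.15 cm²/s); only the threshold and gain are specified by
  the model.
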