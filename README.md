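# vtsynth

Sentence-level articulatory speech synthesis in which an utterance is
planned as a timeline of *relative acoustic events* rather than articulator
movements. Each event is a resonance deflection pattern (RDP) — a triple
(δ₁, δ₂, δ₃) ∈ [−1, 1]³ giving the intended direction and normalized
magnitude of change of the first three vocal tract resonances — attached to
a Gaussian event function E(n) with peak time t_p, half-maximum width t_w,
and an optional hold t_h. Acoustic sensitivity functions turn each RDP into
a deformation of the vocal tract shape; overlapping events are applied in
sequence, so coarticulation emerges automatically rather than being
scripted. The package is aimed at speech-production researchers who want a
self-contained, scriptable implementation of this resonance-deflection
approach: area-function modeling, the full event-to-deformation transform,
time-domain synthesis, and analysis tooling.

## The model

The vocal tract is a chain of N_x = 44 uniform tubelets, each of length
L = c/(2F_s) = 0.396825 cm (c = 35 000 cm/s, F_s = 44 100 Hz), total
length 17.46 cm. A time-varying area function is the product of a neutral
configuration and a deformation:

    A(i, n) = Ω(i) · D(i, n)

For one event, the pipeline is:

1. **Sensitivity functions.** A transmission-line model (chain-matrix
   cascade with yielding-wall, viscous, heat-conduction, and radiation
   losses, plus a piriform side branch) gives the frequency response of
   Ω(i), its resonances f_R1 < f_R2 < f_R3, and per-tubelet modal
   pressures p_j(i) and flows u_j(i). The sensitivity of resonance j to a
   fractional area change at tubelet i is the normalized
   kinetic/potential-energy difference
   S_j(i) = (K_e(i) − P_e(i)) / Σᵢ (K_e(i) + P_e(i)), which satisfies the
   first-order perturbation relation Δf_Rj/f_Rj = Σᵢ S_j(i) ΔΩ(i)/Ω(i).
2. **Adjustment.** Each S_j(i) is magnitude-balanced along the tract
   (polarity store, zero-phase Butterworth low-pass of |S_j|, trend
   removal) and normalized to unit peak, giving Z_j(i).
3. **Deformation.** y(i) = δ₁Z₁(i) + δ₂Z₂(i) + δ₃Z₃(i), and
   D(i) = 1 − μ·E(n)·y(i)/min y(i), clipped at 0. The constriction degree
   μ sets how far the tract closes: μ < 1 partial (vowels, liquids,
   fricatives), μ = 1 complete closure at the minimum of y, μ > 1 a
   spatially spread closure. Where y(i) > 0 the tract expands
   synergistically.
4. **Sequencing.** At every frame (f_svt = 146 Hz), active events are
   applied in ascending order of μ, each recomputing the sensitivities of
   the working tract left by the previous one — this is where
   coarticulation comes from.

The resulting tract movie is rendered to audio by a one-dimensional
wave-reflection (Kelly–Lochbaum) synthesizer with a parametric glottal
source (F0 contour, abduction gestures) and Reynolds-number-gated
turbulence noise U_nois = N_f (Re² − Re_c²)·10⁻⁶ for Re > Re_c = 1200,
injected at the glottis and immediately downstream of supraglottal
constrictions.

The published adult-male neutral tract is not tabulated here; the package
ships a documented parametric stand-in (`neutral_tract_standin()`) and a
loader (`read_area_table()`) for user-supplied area functions.

## Worked example

```r
library(vtsynth)

omega <- neutral_tract_standin()
find_resonances(frequency_response(omega, branch = side_branch()))
#> <resonance_set> f_R: 500.9, 1294.1, 2256.1 Hz

script <- sentence_script(1)       # "a dog ate a bug", 9 events
script
#> <utterance_script> 9 events, 1.64 s @ 146 Hz (239 frames), 1 abduction interval(s)
#>   {d} {ao} {g} {eh} {ih} {t} {b} {ah} {g}

movie <- render_movie(script, omega, branch = side_branch())
movie
#> <tract_movie> 239 frames x 44 sections @ 146 Hz (1.64 s), min area 0.0000 cm^2

audio <- synthesize(movie, noise = noise_params(rng_seed = 1))
audio
#> <audio_result> 1.637 s @ 44100 Hz (72191 samples), peak 0.891
write_wav(audio, "a_dog_ate_a_bug.wav")
```

The neutral resonances are the flat reference lines of the analysis plots;
the zero minimum area of the movie shows the stop closures ({d}, {g}, {b},
{g}) actually occlude the tract; and the audio is the full synthesized
sentence, devoiced around the {t} by its abduction gesture. Resonance
tracks and deflection checks:

```r
tracks <- track_resonances(movie, side_branch())
vowels <- render_movie(vowels_only_variant(script), omega, branch = side_branch())
autoplot(dplyr::bind_rows(tracks,
         track_resonances(vowels, side_branch(), variant = "vowels_only")))
deflection_verdict(tracks, track_resonances(vowels, side_branch()),
                   script$events[6, ])   # the {t}: c(-1, 1, 1)
```

A command-line front end ships at
`system.file("exec", "vtsynth", package = "vtsynth")` with subcommands
`synth`, `sensitivity`, `fixtures`, and `validate`.

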