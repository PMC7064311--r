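Package: vtsynth
Title: Sentence-Level Speech Synthesis from Relative Acoustic Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an articulatory speech synthesis model in which an
    utterance is specified as a timeline of discrete, relative acoustic
    events: directional deflections of the first three vocal tract
    resonances. Acoustic sensitivity functions computed with a lossy
    transmission-line model of the tubelet-discretized vocal tract transform
    each resonance deflection pattern into a deformation of the neutral area
    function; overlapping events are sequenced so that coarticulation emerges
    automatically. The resulting time-varying area function is rendered to
    audio with a one-dimensional wave-reflection (Kelly-Lochbaum) synthesizer
    with a parametric glottal source and Reynolds-number gated turbulence
    noise. Includes resonance tracking, spectrograms, script fixtures for two
    demonstration sentences, and plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    broom,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
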