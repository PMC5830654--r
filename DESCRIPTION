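Package: transcoin
Title: Translational Coincidence Modelling of Photoperiod-Dependent Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and tests the "translational coincidence" mechanism, by which
    diel rhythms in transcript abundance interact with light-stimulated translation
    to produce photoperiod-dependent changes in protein abundance. Provides the
    steady-state coincidence model (clock entrainment, light/dark synthesis
    integrals, normalised protein abundance and between-photoperiod change scores),
    inference of protein turnover and light/dark synthesis-rate ratios from partial
    stable-isotope labelling time courses, transcript rhythm classification with
    arrhythmicity and circadian-consistency filters, photoperiod proteome statistics
    (per-protein ANOVA with Benjamini-Hochberg correction, Tukey HSD contrasts,
    fold-change window and phase-bin enrichment by Fisher's exact test, set-overlap
    hypergeometric tests, model-versus-measurement evaluation), and a seeded
    synthetic-data generator emulating a multi-photoperiod replicated study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
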