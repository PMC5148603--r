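Package: pulseHDX
Title: Pulse-Labeling HDX-MS Analysis of Catalyzed Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hydrogen-deuterium exchange mass spectrometry (HDX-MS)
    studies of protein unfolding. Synthesizes peptide isotope envelopes
    (natural isotopic distributions, binomial deuterium incorporation,
    folded/unfolded mixtures), deconvolutes bimodal envelopes into
    fraction-unfolded values by constrained two-Gaussian fitting with
    BIC model selection, and turns fraction time courses into
    spontaneous-corrected initial rates and the catalytic unfolding
    efficacy of inhibitor proteins such as the ANGPTL family.
    Continuous-labeling analytics include relative-uptake tables,
    residue-level heat maps, butterfly difference plots with a
    replicate-SD significance rule, EX1/EX2 envelope-width diagnostics
    and sequence coverage. A seeded synthetic-data generator emulates
    replicate pulse-labeled and continuous-labeling spectra for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'envelopes.R'
    'peptides.R'
    'synthetic.R'
    'deconvolution.R'
    'kinetics.R'
    'uptake.R'
    'plots.R'
    'workbench.R'
    'cli.R'
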