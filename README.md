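# pulseHDX

Analysis of protein unfolding by pulse-labeled hydrogen–deuterium
exchange mass spectrometry (HDX-MS), built around the workflow used to
show that ANGPTL proteins *catalytically* unfold the hydrolase domain
of lipoprotein lipase (LPL): a brief (10 s) pulse of 70% D₂O snapshots
the instantaneous folded/unfolded population; the isotope envelope of
a diagnostic peptic peptide turns bimodal as molecules unfold
cooperatively; and the area ratio of a two-Gaussian fit to that
envelope measures the unfolded fraction. Time courses of that fraction
yield initial unfolding rates, and the slope of molar rate versus
inhibitor concentration is the **catalytic unfolding efficacy**
(substrate molecules unfolded per inhibitor molecule per minute).

The package is for HDX-MS practitioners and kineticists who want a
tested, scriptable implementation of that measurement chain, plus the
surrounding continuous-labeling analytics (relative-uptake tables,
residue heat maps, butterfly difference plots with a
max-replicate-SD significance band, EX1/EX2 envelope-width
diagnostics, sequence coverage).

## The model

Isotope envelopes are synthesized as natural isotopic distributions
(per-element convolution) convolved with binomial deuterium uptake:
`Binomial(n_amides, p)` placed at multiples of the H→D mass difference
(1.00628 Da). A partially exchanged folded state and a fully exchanged
unfolded state (p equal to the D₂O fraction) are mixed with weight *u*,
the unfolded fraction. Deconvolution fits

```
I(m) = A₁ exp(−(m−µ₁)²/2σ₁²) + A₂ exp(−(m−µ₂)²/2σ₂²)
```

with centroids anchored near folded/unfolded reference states, accepts
bimodality when ΔBIC ≥ 6 against a single-Gaussian null, and reports
`u = area₂ / (area₁ + area₂)`.

Unfolding kinetics follow a two-state model

```
u(t) = 1 − exp(−(k_spont·t + k_cat·g(t))),   k_cat = efficacy × [I]/[S]
```

with `g(t) = t`, or `(1 − e^(−k_decay·t))/k_decay` for inhibitors whose
activity decays (as for the E15K variant). After subtracting the
spontaneous course, initial rates are through-origin OLS slopes over
points below a substrate-depletion cutoff, and
`efficacy = d(molar rate)/d[I]` by linear regression.

Because no raw spectra are deposited with the study, a seeded
synthetic-data generator reproduces every experimental condition as a
named preset (e.g. `spont_30` = 29% unfolded after 30 min; `wt1uM_5` =
60.3% after 5 min with 1 µM inhibitor), and the pipeline is validated
by round-trip recovery of those generating values.

## Worked example

```r
library(pulseHDX)

## triplicate pulse-labeled spectra of the diagnostic peptide after
## 30 min of spontaneous unfolding, then two-Gaussian deconvolution
specs <- simulatePulseSpectra(getPreset("spont_30"), replicates = 3,
                              noise = noiseModel(seed = 101))
fits <- deconvolveSpectra(specs)
fits[, c("preset", "replicate", "model", "fraction_unfolded")]
#>     preset replicate   model fraction_unfolded
#> 1 spont_30         1 bimodal         0.2914311
#> 2 spont_30         2 bimodal         0.2933978
#> 3 spont_30         3 bimodal         0.2902126

## full efficacy chain on the wild-type kinetic preset: simulate dose
## series + spontaneous control, deconvolute, subtract, rate, regress
pipe <- efficacyPipeline(presetRegistry()$kinetic$wt,
                         concs = c(1.0, 0.5, 0.25), seed = 101)
pipe$efficacy
#> EfficacyEstimate: 1.553 +/- 0.004 substrate molecules per inhibitor per min
#>   intercept -0.0667 uM/min, R^2 1.0000, through-origin slope 1.464
#>   based on 3 concentrations
```

The three replicate fractions scatter around the generating value of
0.29, and the recovered efficacy sits near the generating 1.6 LPL
molecules per ANGPTL4 molecule per minute — the quantity the
dose-regression slope estimates.

A thin command-line wrapper is installed at
`inst/scripts/pulsehdx` with subcommands `simulate`, `deconvolve`,
`kinetics`, `uptake` and `report`; see `?hdxCLI`.

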