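---
title: "pulseHDX: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulseHDX: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseHDX)
```

# Scope

pulseHDX implements the measurement chain of a pulse-labeled HDX-MS
unfolding study: synthesis of peptide isotope envelopes, two-Gaussian
deconvolution of bimodal envelopes into fraction-unfolded values,
kinetic analysis yielding the catalytic unfolding efficacy of an
inhibitor protein, and continuous-labeling uptake analytics. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open — and what the passing test suite
does and does not demonstrate about real data.

# Envelope synthesis

**Natural distributions.** Elemental compositions come from a standard
residue table plus one water, or — when the peptide's sequence is
unknown, as for the diagnostic hydrolase-domain reporter peptide
(residues 131–165, modeled at 3800 Da) — from an averagine stand-in
whose C/N/O/S counts are rounded and whose hydrogen count is adjusted
so the average mass matches the target. Only envelope *geometry*
matters for fraction recovery, not peptide identity. Isotopologues are
aggregated by neutron count during per-element convolution, each
aggregate carrying the abundance-weighted mean mass, so envelope
centroids are exact; the suite checks agreement with brute-force
isotopologue enumeration to 1e-9 for small compositions. Peaks below
1e-5 of the tallest (default truncation) are dropped and the envelope
renormalized.

**Deuteration.** All exchange-competent backbone amides (residues
minus the N-terminal one and minus non-terminal prolines) exchange
with a single incorporation probability; the envelope is convolved
with `Binomial(n_amides, p)` at multiples of 1.00628 Da. There is no
per-site rate spectrum, no side-chain hydrogens, and no back-exchange
by default (the study quantified uptake relative to its own controls);
a uniform loss factor can be emulated by lowering the incorporation
probabilities. This is sufficient to reproduce the bimodal
phenomenology being quantified, and no more.

**Coordinates.** Envelopes live in neutral-mass space. m/z conversion
(`toMz()`/`fromMz()`, proton mass 1.00728 Da) is a boundary operation:
charge is instrument metadata, not part of the analysis.

# The synthetic-data generator

The generator emulates the study's conditions as an immutable preset
registry. *Empirical* presets carry a named condition and its
generating unfolded fraction (e.g. `spont_30` = 0.29, `wt2uM_10_gpihbp1`
= 0.08). *Kinetic* presets carry rate parameters of the two-state model

$$u(t) = 1 - \exp\!\big(-(k_{spont}\,t + k_{cat}\,g(t))\big), \qquad
k_{cat} = \text{efficacy} \times [I]/[S],$$

with $g(t) = t$, or $(1 - e^{-k_{decay} t})/k_{decay}$ when inhibitor
activity decays first-order. The two kinds exist because the study's
spontaneous measurements (7.0% at 5 min, 29% at 30 min) are not
mutually consistent under a single exponential: fraction-level
conditions are therefore generated from their printed values directly,
while the kinetic presets use $k_{spont} = 0.0114\,\text{min}^{-1}$
(calibrated once so the spontaneous curve passes 29% at 30 min),
wild-type efficacy 1.6 and E15K efficacy 0.6 with
$k_{decay} = 0.05\,\text{min}^{-1}$. Whether the E15K activity decay
is truly first-order is not known; first-order is the simplest form
that flattens progress curves at longer times, and the value 0.05 was
fixed before any estimator work and not revisited.

Defaults that are declared assumptions rather than measured values:

* folded-state pulse incorporation `pFolded = 0.25` of amides — gives a
  ~14 Da centroid separation from the 70%-D₂O unfolded state for the
  31-amide reporter peptide;
* noise: per-peak multiplicative Gaussian with CV 3% plus additive
  baseline noise at 0.5% of the tallest peak, negatives clipped —
  a minimal model adequate for recovery testing, not
  instrument-calibrated;
* replicates default to 3, matching triplicate labeling;
* time grid for kinetic simulations: 0.5, 1, 1.5, 2, 2.5, 3, 4, 5,
  7.5, 10 min — inside the study's 0.5–30 min sampling, truncated at
  10 min and densified early because the analysis uses the early
  linear phase.

Every stochastic output is reproducible from (seed, preset, time,
replicate): each combination derives its own 31-bit RNG stream, so
fixtures are byte-identical across runs and insertion of new
conditions does not shift existing ones.

*What passing round-trip tests do not show:* real spectra have
chromatographic interference, charge-state effects, correlated noise
and imperfect peak picking, none of which are modeled. Recovery of a
generating fraction here validates the estimator chain, not the
instrument-facing steps that are out of scope.

# Deconvolution

Stick spectra are fitted as weighted points on a continuous mass axis
(no profile re-binning) by bounded Levenberg–Marquardt least squares.

**Model selection.** Both a single-Gaussian null and the constrained
two-Gaussian model are fitted; bimodality is accepted when
$\mathrm{BIC}_{uni} - \mathrm{BIC}_{bi} \ge 6$, the conventional
"strong evidence" threshold. When the unimodal model is retained, the
fraction is assigned 0 or 1 if the fitted centroid lies within 20% of
the folded→unfolded span of the corresponding reference, and is
otherwise reported missing with an ambiguity flag — never silently 0.
Non-convergence is likewise report-and-flag.

**Constraints.** Component centroids may move at most ±3 Da from the
folded/unfolded reference centroids; widths are bounded globally in
[0.5, 6] Da and fitted independently per component. References come
from noiseless pure-state envelopes (a t = 0 folded envelope and a
full-deuteration envelope), which makes fits reproducible; the
original procedure's initialization is not recorded anywhere, so this
is this package's choice.

**Width anchoring.** The binomial components are skewed, and an
unconstrained minor Gaussian inflates its width (σ → 5–6 Da) to absorb
the major component's tail, biasing small fractions upward by up to
~3 percentage points. When reference states are available the
per-component width window is therefore tightened to 0.8–1.2× the
pure-state envelope width (still inside the global bounds) — the same
reference-anchoring idea used for centroids. Residual bias is largest
at small fractions (~1 pp near 5–10% unfolded, from the
Gaussian-versus-binomial shape mismatch) and falls below 0.5 pp above
~30%; the suite enforces < 2 pp across 0.05–0.95. A
natural-abundance-aware binomial-mixture fit would remove this bias
but is a strictly richer model than the two-Gaussian procedure being
implemented, and is deliberately out of scope.

**Detection floor.** ΔBIC ≥ 6 cannot detect a minor mode below roughly
2% of total area at default noise; such envelopes are classified
unimodal and read as fraction 0. This matters for the kinetics (next
section).

# Kinetics

Replicate fractions are aggregated to mean ± SD per time (single
replicates report missing SD, never 0; no smoothing). The spontaneous
course is subtracted pointwise (quadrature SDs, negatives clipped and
flagged). Initial rates are ordinary least-squares slopes *through the
origin* — catalyzed unfolding is zero at t = 0 after background
subtraction — over points whose corrected fraction does not exceed the
substrate-depletion cutoff, with an optional linear-phase time cap
(default 10 min) for decaying inhibitors. The efficacy is the
free-intercept OLS slope of molar rate (µM/min) on inhibitor
concentration (µM); the through-origin slope is kept as a secondary
diagnostic since the original regression's form is not recorded.

**The depletion cutoff (default 0.30).** Two opposing systematics meet
here. Under first-order unfolding, a through-origin fit that admits
points up to corrected fraction *u* is biased low (the latest included
point dominates the fit, and the instantaneous rate there has fallen
by the factor 1 − *u*): in isolation this argues for a much stricter
cutoff. But the spontaneous control sits below the ~2% bimodality
detection floor at early times and reads as zero there, which inflates
the corrected course by exactly the spontaneous fraction — an upward
bias concentrated on the earliest points. Calibrated on the full
synthetic chain against known generating efficacies, the two effects
largely cancel at 0.30, while stricter cutoffs over-correct and can
leave the highest dose with fewer than two usable points (rates are
then withheld, never extrapolated). The cutoff remains configurable,
and every exclusion is recorded with a machine-readable reason.

A global weighted nonlinear fit of the two-state model
(`fitKineticModel()`) complements the piecewise linear analysis;
comparing fits with and without the decay term by AIC detects
decaying-inhibitor behavior.

# Continuous labeling and uptake analytics

Closed-state uptake follows EX2 kinetics,
$p(t) = d_{2o}\,(1 - e^{-k_{int} t / PF})$ with intrinsic rate
$k_{int} = 1\,\text{s}^{-1}$ and protection factor *PF*, while a
cooperatively opened subpopulation $w(t) = 1 - e^{-k_{open} t}$
exchanges fully (EX1 component). Uptake is the envelope centroid minus
the undeuterated centroid; relative uptake divides by the
full-deuteration control (values above 1 are flagged, not clipped).
Residue heat maps take the unweighted mean of covering peptides
(shortest-peptide priority available), and uncovered residues are
missing, never zero. Butterfly differences use the study's
significance rule — the largest replicate SD across all data sets,
applied symmetrically — rather than a formal multiple-testing
procedure; a grouping column supports bimodality-binned comparisons.
The EX1 diagnostic is the envelope's second central moment, which for
a two-mode mixture equals $\sigma^2 + w(1-w)d^2$ (checked against that
closed form to 1e-6): a series is called "EX1-containing" when its
maximum variance exceeds the earliest-time variance two-fold (the
factor is configurable; transient broadening peaks at w = 0.5).

The bundled 159-residue inhibitor-domain region presets (a tiled
synthetic peptide map with two protected helical regions, residues
19–43 and 85–111, and a destabilized-variant mode that opens the
N-terminal helix ~6-fold faster) are declared modeling choices for
validation; peptides overlapping a helix take the helix's parameters
wholesale, which is coarser than real per-residue averaging.

# Numerical choices and degenerate inputs

* Isotope abundances, the H→D mass difference (1.00628 Da) and proton
  mass (1.00728 Da) are pinned as constants in one file.
* Peak coalescence during convolution/mixing merges sticks closer than
  0.5 Da by abundance-weighted mean; total abundance and centroids are
  preserved exactly.
* Envelopes with essentially all mass in one stick pin the fitted
  width at its lower bound and are flagged `degenerate`.
* Empty compositions yield a flagged single peak at mass 0; empty
  envelopes, zero controls, single concentrations, and single time
  points are explicit errors or withheld results, never imputed.
* Fraction ties in the unimodal 0/1 assignment cannot occur (the 20%
  windows around the two references are disjoint by the separation
  precondition).

# Problem sizes

The validation suite and the reproduction script use 50 replicate
spectra per pulse-labeling condition, triplicate time courses on a
10-point grid for the kinetic chains, and triplicate continuous
labeling at 10/100/1000 s — sizes chosen to match the study's
replication (2–4 replicates) while keeping Monte-Carlo error on
recovered quantities well below their acceptance tolerances.

# Known limitations

* Two-Gaussian area ratios inherit a small positive bias at low
  unfolded fractions (Gaussian-versus-binomial shape mismatch) and a
  ~2% bimodality detection floor.
* The single-probability deuteration model cannot represent per-site
  protection spectra within a peptide.
* The noise model is minimal; conclusions about instrument-level
  robustness cannot be drawn from it.
* Empirical presets are single-time conditions; they validate fraction
  recovery, not kinetics.
* The efficacy estimator's accuracy at the default cutoff relies on
  the bias cancellation described above; on data with a very different
  spontaneous rate or noise level the cutoff should be revisited.
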