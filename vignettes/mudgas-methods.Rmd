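---
title: "Models and design choices in mudgas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mudgas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mudgas)
```

## The scientific problem

Gas seeping from mud volcanoes is usually thermogenic methane with a tail of
C2+ alkanes, but by the time it reaches the surface subsurface microbes may
have reworked it: sulfate-, nitrate- or iron-reducing prokaryotes oxidize
propane and ethane anaerobically, and methanogens convert the liberated
CO2/H2 (or acetate) back into methane — "secondary methanogenesis". Bulk
δ¹³C values alone are ambiguous about these overprints. The package combines
three lines of evidence: position-specific ¹³C of propane (which isolates the
biodegradation signal on the molecule's central carbon), conventional
chemical/isotopic source diagnostics, and the taxonomic composition of the
associated mud.

## Position-specific reconstruction

Pyrolysis fragments CH₄ and C₂H₆ sample only propane's terminal carbons,
while C₂H₄ carries one terminal and one central carbon. `terminal_delta()`
takes the peak-area-weighted mean of the CH₄ and C₂H₆ fragment deltas —
weighting by raw areas, not mole-corrected areas, because the weighted mean
is insensitive to the constant fragmentation stoichiometry and the raw areas
are what the instrument reports. `central_delta()` closes the mass balance,
and `bulk_from_positions()` provides the 2:1 consistency check against the
independently measured bulk δ¹³C of propane. We treat a disagreement larger
than 0.1 ‰ (one rounding unit of a routine data table) as a flag for
re-inspection, not a hard failure, since the bulk and position measurements
come from different instruments.

Replicate handling mirrors lab practice: fragments are combined area-weighted
*within* an injection, then the 3–5 injections are averaged unweighted.
`propagate_uncertainty()` resamples every fragment delta from its stated
1σ (Monte-Carlo, default 10 000 draws, seed mandatory, caller's RNG state
restored). For the small sigmas typical of GC-C-IRMS the Monte-Carlo sigma
agrees with closed-form linear propagation to a few percent, which the test
suite checks; the Monte-Carlo route is kept because it extends unchanged to
asymmetric inputs and replicate structures.

## Rayleigh model and the extent of biodegradation

The residual substrate of a fractionating reaction follows

$$\delta(f) = (\delta_0 + 1000)\,f^{-\varepsilon/1000} - 1000,$$

with $f$ the fraction remaining and $\varepsilon > 0$ (per mil,
$\varepsilon \approx 1000(\alpha-1)$) meaning the residue enriches. Culture
work with sulfate-reducing propane oxidizers gives
$\varepsilon_{central} = 33$ ‰ and $\varepsilon_{terminal} = 3$ ‰ — the only
position-specific factors measured to date; archaeal degraders activate the
*terminal* carbon and their factors are unknown, which is a real caveat when
applying the inversion to mixed communities.

For field data, `extent_from_offset()` inverts the relation applied directly
to the offset $\Delta^{13}C_{central}$ with $\varepsilon_{central}$ and an
assumed source offset $\Delta_0 = 0$ (thermogenic propane shows no relative
central enrichment). This treats the terminal position as a
quasi-conservative reference — defensible because its factor is eleven times
smaller — and is the convention under which the packaged field suite spans
extents of about 57–70 %. The exact convention behind any published range is
rarely printed; we therefore assert bounds, not interior values, in our
checks.

The generator, by contrast, enriches *both* positions with their own
factors. Inverting its output through the offset convention would carry a
systematic bias of a few percentage points (the offset grows slightly slower
than the central position alone), so `recovery_experiment()` inverts the
recovered *central-position* delta against the known source value. That
choice makes the noise-free round trip exact and isolates measurement noise
as the only error source in recovery statistics. Both inversions are
exported; for field data, where the source delta is unknown but $\Delta_0$
can be argued to be zero, the offset route is the usable one.

For small offsets the exact inversion reduces to
$B \approx 1 - e^{-\Delta/\varepsilon}$; the package keeps the exact form
throughout (the approximation drifts past 0.5 percentage points above
roughly 20 ‰).

## Co-degradation, secondary methane, classification

`codegradation_slope()` regresses propane mole % (response) on ethane mole %
(predictor) by OLS. This orientation is a deliberate choice: it is the one
that turns the packaged concentration table into the published-style slope of
0.4, and the regression is reported with its Pearson r so the user can judge
the linearity themselves. `secondary_methane_indicator()` codifies three
fingerprints — every δ¹³C_CO₂ above a threshold (+15 ‰ by default; published
discussions call +19 to +35 ‰ "high" without naming a cutoff, so the
threshold is exposed), a negative Δ¹³C_Central–δ¹³C_CH₄ trend, and a positive
Δ¹³C_Central–%CH₄ trend — and returns "consistent" only when all three hold,
"indeterminate" when any series is missing or degenerate.

Source classification (Schoell δD–δ¹³C and Bernard C₁/(C₂+C₃) diagrams) is
point-in-polygon against genetic fields shipped as YAML configuration rather
than code: published field boundaries are drawn, not tabulated, so baking a
particular guess into the package would lend it false authority. Boundary
ties go to the first-listed field; the "altered" flag fires when methane
δ¹³C sits in the thermogenic band but the Bernard ratio exceeds a threshold
(default 100), the signature of C2+ stripping or methane addition.
Two-end-member mixing uses standard concentration-weighted blending and
conserves each species' isotope-weighted concentration by construction.

## Synthetic scenarios

`scenario_config()` defaults encode the study conditions the analysis is
meant for: per-sample fractions remaining drawn uniformly from
[0.29, 0.45] (extents 55–71 %), position factors 33/3 ‰, a propane-on-ethane
concentration slope ρ = 0.4 with a small ethane fractionation (1 ‰ — ethane's
isotope shift is known to be slight), and measurement noise at routine
repeatability: 0.5 ‰ on bulk deltas and 0.5 ‰ per fragment delta, which maps
to about 1.3 ‰ on the reconstructed offset, inside the 1.5 ‰ replicate
repeatability of the PSIA method. Secondary methane is produced from a CO₂
pool fed by the oxidized carbon: methanogens draw ~0.75 mol CH₄ per mol C
oxidized with an effective 60 ‰ normal isotope effect, which leaves residual
CO₂ at roughly +19 to +25 ‰ and depresses δ¹³C_CH₄ and raises %CH₄ with
extent — the three indicator fingerprints by construction. The 1 : 1 : 0.3
CH₄ : C₂H₄ : C₂H₆ fragment-area stoichiometry is arbitrary but fixed (the
terminal reconstruction is weighting-robust). Ethane depletion is linear in
propane consumed, matching a linear concentration cross-plot; a first-order
option exists behind `first_order_ethane`.

What the generator does **not** emulate: mixing of end members with distinct
sources (Gamou vs Murono offsets), migration/diffusion fractionation,
archaeal fractionation factors, open-system behaviour, or any correlation
structure in the noise. Passing recovery tests therefore demonstrates the
pipeline's internal consistency under closed-system Rayleigh assumptions,
not the validity of those assumptions for any particular field site.

Problem sizes used in the shipped tests were chosen to keep the suite quick
at desk scale: recovery runs use 10–200 synthetic samples with 3 fragment
replicates each, and Monte-Carlo stages use 100–10 000 draws.

## Degenerate inputs and conventions

* Below-detection-limit is a first-class state (tri-state cells:
  value / bdl / missing). bdl contributes zero only to the composition-sum
  sanity check; everywhere else it is excluded and propagates (a bdl offset
  yields an undefined extent, never 0 %).
* A Bernard denominator that is bdl or exactly zero yields an undefined
  ratio (`NA`), never infinity.
* Correlations over constant series are reported as `NA` and push the
  indicator to "indeterminate" rather than erroring.
* All randomness flows from explicit integer seeds; generation and the
  report bundle are byte-identical under a fixed seed.
* Composition tables may sum slightly over 100 (rounding slack 0.5); values
  outside [0, 100] are rejected outright.

## Known limitations

The extent inversion inherits every assumption of the closed-system Rayleigh
model with bacterial factors: unknown archaeal factors, possible temperature
or nutrient dependence of ε, and source Δ₀ ≠ 0 would all bias it. The guild
lookup is a curated substring table, not a phylogenetic placement; it is
meant for coarse presence/absence statements at genus/family/order rank, and
nested taxonomies are resolved by most-specific-rank precedence
(e.g. *Geobacter*, an iron reducer, inside the sulfate-reducer order
Desulfuromonadales).
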