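# mudgas

Interpretation toolkit for the chemical and stable-isotope composition of
natural gas from mud volcanoes and seeps, where thermogenic hydrocarbons are
reworked by subsurface microbial communities. It is aimed at isotope
biogeochemists who have routine gas data (mole % composition, bulk δ¹³C/δD)
plus position-specific ¹³C measurements of propane, and who want to turn those
numbers into quantitative statements about anaerobic hydrocarbon
biodegradation and secondary microbial methanogenesis.

## What it computes

**Position-specific isotope analysis (PSIA) of propane.** On-line pyrolysis
splits propane into CH₄, C₂H₄ and C₂H₆ fragments; CH₄ and C₂H₆ derive from the
terminal carbons only, C₂H₄ from one terminal and one central carbon. The
package reconstructs

    δ¹³C_Terminal = (δ¹³C_CH₄·A_CH₄ + δ¹³C_C₂H₆·A_C₂H₆) / (A_CH₄ + A_C₂H₆)
    δ¹³C_Central  = 2·δ¹³C_C₂H₄ − δ¹³C_Terminal
    Δ¹³C_Central  = δ¹³C_Central − δ¹³C_Terminal

with Monte-Carlo uncertainty propagation over replicate injections.

**Extent of anaerobic propane oxidation.** Sulfate-reducing propane oxidizers
activate the central carbon, so the residual propane pool enriches in ¹³C
preferentially at the central position with Rayleigh fractionation,

    δ(f) = (δ₀ + 1000)·f^(−ε/1000) − 1000,

ε = 33‰ (central) and 3‰ (terminal) from pure cultures. Inverting the observed
Δ¹³C_Central with ε = 33‰ and Δ₀ = 0 gives the fraction remaining f and the
extent of biodegradation B = 100·(1 − f) %.

**Diagnostics.** Bernard ratio C₁/(C₂+C₃) and Schoell (δD–δ¹³C) source
classification with configurable genetic fields, ethane–propane
co-degradation regression, an inverse-trend indicator for secondary microbial
methane (¹³C-enriched CO₂, falling δ¹³C_CH₄ and rising %CH₄ with
biodegradation), two-end-member mixing curves, and guild annotation of
genus-level 16S abundance tables (methanogens, ANME, sulfate/nitrate/iron
reducers) cross-checked against the isotope verdicts.

**Synthetic data.** `scenario_config()` / `generate_scenario()` produce sample
tables, pyrolysis-fragment replicates and a ground-truth ledger under a
configurable degradation + secondary-methanogenesis scenario, so the whole
pipeline can be validated with `recovery_experiment()`.

The seven-sample field dataset from the Tokamachi mud-volcano area (Murono
and Gamou sites, Niigata, Japan) ships as packaged fixtures.

## Worked example

```r
library(mudgas)

s <- tokamachi_samples()
extent_from_offset(ifelse(is_present(s, "delta_central"),
                          s$delta_central, NA), id = s$id)
#> # A tibble: 7 × 4
#>   id    offset fraction_remaining extent_percent
#> 1 G-1     31.5              0.391           60.9
#> 2 G-2     30.5              0.402           59.8
#> 3 M-1     29.2              0.418           58.2
#> 4 M-2     28.3              0.429           57.1
#> 5 M-3     NA               NA               NA
#> 6 M-4     40.5              0.300           70.0
#> 7 M-5     37.2              0.331           66.9

codegradation_slope(s[s$site == "Murono", ])$slope
#> [1] 0.3973619
secondary_methane_indicator(s[s$site == "Murono", ])$verdict
#> [1] "consistent"
```

Reading: six of the seven gases have lost 57–70 % of their original propane
to anaerobic oxidation (M-3's offset is below detection, so its extent is
undefined rather than zero); ethane disappears in lockstep with propane with
a concentration slope of 0.4; and the ¹³C-enriched CO₂ together with the
methane trends is consistent with secondary microbial methane production.
`run_pipeline(s, "out/")` writes the full per-sample results CSV, JSON
summaries and a markdown report.

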