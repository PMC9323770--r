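# Genetic fields for methane source diagnostics.
#
# Schoell fields are rectangles in (d13c_ch4, dd_ch4) space, per mil vs
# VPDB / VSMOW; Bernard fields are rectangles in (d13c_ch4, log10 C1/(C2+C3))
# space. Boundaries follow the conventional genetic fields of the
# Schoell / Whiticar / Bernard diagrams as commonly drawn; they are
# configuration, not constants of nature -- edit to taste. Where fields abut,
# the first field listed here wins.
schoell:
  - name: thermogenic
    d13c: [-50, -20]
    dd: [-275, -100]
  - name: biogenic-CO2-reduction
    d13c: [-110, -60]
    dd: [-250, -150]
  - name: biogenic-methyl-fermentation
    d13c: [-65, -50]
    dd: [-400, -250]
bernard:
  # log10 of the C1/(C2+C3) ratio on the y axis
  - name: thermogenic
    d13c: [-50, -20]
    log10_ratio: [0, 3]
  - name: biogenic
    d13c: [-90, -55]
    log10_ratio: [2, 5]
# Above this C1/(C2+C3) ratio a thermogenic gas is flagged "altered"
# (C2+ removal or methane addition).
altered_ratio_threshold: 100
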