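# Default taxon -> metabolic guild lookup for mud-volcano 16S genus tables.
#
# Patterns are matched case-insensitively as substrings of the taxon name or
# of a SILVA-style lineage string, at the declared rank. When patterns at
# different ranks both match one taxon the most specific rank wins
# (genus > family > order); two matches at the SAME rank are an error and the
# lookup must be disambiguated. Membership reflects the organisms commonly
# implicated in subsurface hydrocarbon cycling: hydrogenotrophic and
# acetoclastic methanogens, anaerobic methanotrophs (ANME), sulfate-reducing
# orders, nitrate-reducing alkane oxidizers (Rhodocyclaceae) and iron-reducing
# Geobacter. Edit or extend for other settings.
guilds:
  hydrogenotrophic_methanogen:
    - {pattern: Methanoregula, rank: genus}
    - {pattern: Methanobacterium, rank: genus}
    - {pattern: Methanolinea, rank: genus}
    - {pattern: Methanospirillum, rank: genus}
    - {pattern: Methanomicrobiales, rank: order}
  acetoclastic_methanogen:
    - {pattern: Methanosaeta, rank: genus}
    - {pattern: Methanothrix, rank: genus}
    - {pattern: Methanosarcina, rank: genus}
  ANME:
    - {pattern: ANME, rank: genus}
    - {pattern: Methanoperedens, rank: genus}
  sulfate_reducer:
    - {pattern: Desulfuromonadales, rank: order}
    - {pattern: Desulfobacterales, rank: order}
    - {pattern: Desulfobacteriales, rank: order}
    - {pattern: Desulfovibrionales, rank: order}
    - {pattern: Desulfarculales, rank: order}
    - {pattern: Desulfarculates, rank: order}
    - {pattern: Syntrophobacterales, rank: order}
    - {pattern: Syntrophobacteriales, rank: order}
    - {pattern: Desulfosarcina, rank: genus}
  nitrate_reducing_alkane_oxidizer:
    - {pattern: Rhodocyclaceae, rank: family}
  iron_reducer:
    - {pattern: Geobacter, rank: genus}
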