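# Shared test fixtures, built in code.

murono <- function(x = tokamachi_samples()) x[x$site == "Murono", ]

# delta_central with bdl rows as NA, for regression/inversion inputs
offset_series <- function(x) {
  ifelse(is_present(x, "delta_central"), x$delta_central, NA_real_)
}

# write a small sample CSV and return its path
write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# a small synthetic genus table in the shape of a mud-volcano community
synthetic_guild_table <- function() {
  tibble::tibble(
    taxon = c(
      "Methanoregula",
      "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanolinea",
      "Methanobacterium",
      "Methanosaeta",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Betaproteobacteriales;Rhodocyclaceae;Azoarcus",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;Geobacter",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfobacterales;Desulfobacteraceae;Desulfosarcina",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfovibrionales;Desulfovibrio",
      "ANME-2a-2b",
      "Bacteria;Bacteroidetes;Flavobacterium",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Unknown"),
    `M-1` = c(2.0, 1.0, 0.5, 0.3, 12, 2.5, 3.0, 1.0, 0.5, 9, 30),
    `M-2` = c(1.5, 0.8, 0.6, 0.2, 10, 2.0, 2.5, 1.2, 0.4, 8, 28),
    `M-4` = c(2.5, 1.2, 0.4, 0.5, 11, 1.8, 3.5, 0.9, 0.0, 10, 25),
    `M-5` = c(1.8, 0.9, 0.7, 0.4, 13, 2.2, 2.8, 1.1, 0.0, 9, 27))
}
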