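test_that("annotation sums abundances into guilds and keeps the remainder", {
  tab <- synthetic_guild_table()
  ann <- annotate_guilds(tab)
  sm <- ann$summary
  expect_equal(sm$`M-1`[sm$guild == "hydrogenotrophic_methanogen"],
               2.0 + 1.0 + 0.5)
  expect_equal(sm$`M-1`[sm$guild == "acetoclastic_methanogen"], 0.3)
  expect_equal(sm$`M-1`[sm$guild == "nitrate_reducing_alkane_oxidizer"], 12)
  expect_equal(sm$`M-1`[sm$guild == "iron_reducer"], 2.5)
  expect_equal(sm$`M-1`[sm$guild == "sulfate_reducer"], 3.0 + 1.0)
  expect_equal(sm$`M-1`[sm$guild == "other"], 9 + 30)
  # guild sums never exceed the total sample abundance
  for (cn in c("M-1", "M-2", "M-4", "M-5"))
    expect_lte(sum(sm[[cn]]), sum(tab[[cn]]) + 1e-12)
  # ANME present below 0.9% in two samples, absent elsewhere
  anme <- unlist(sm[sm$guild == "ANME", -1])
  expect_true(all(anme < 0.9))
  expect_equal(unname(anme > 0), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("single-genus table and empty lookup behave as declared", {
  one <- tibble::tibble(taxon = c("Methanoregula", "Unknownus"),
                        S1 = c(5, 60))
  ann <- annotate_guilds(one)
  expect_equal(ann$summary$S1[ann$summary$guild ==
                                "hydrogenotrophic_methanogen"], 5)
  empty_lookup <- load_guild_lookup()[0, ]
  ann0 <- annotate_guilds(one, empty_lookup)
  expect_equal(ann0$summary$S1[ann0$summary$guild == "other"], 65)
})

test_that("rank specificity resolves nesting; same-rank conflicts error", {
  # Geobacter (genus) sits inside Desulfuromonadales (order): genus wins
  tab <- tibble::tibble(taxon = "Deltaproteobacteria;Desulfuromonadales;Geobacter",
                        S1 = 1)
  ann <- annotate_guilds(tab)
  expect_equal(ann$matches$guild, "iron_reducer")
  clash <- tibble::tibble(guild = c("g1", "g2"),
                          pattern = c("Methano", "Methanoregula"),
                          rank = c("genus", "genus"))
  expect_error(annotate_guilds(tibble::tibble(taxon = "Methanoregula", S1 = 1),
                               clash), "disambiguate")
})

test_that("annotation is invariant to taxon order", {
  tab <- synthetic_guild_table()
  perm <- tab[sample.int(nrow(tab)), ]
  a <- annotate_guilds(tab)$summary
  b <- annotate_guilds(perm)$summary
  expect_equal(a, b)
})

test_that("abundance reader accepts wide, transposed and long layouts", {
  wide <- write_tmp_csv(c("taxon,M-1,M-2", "Methanoregula,5,3", "Other,95,97"))
  w <- read_abundance_table(wide)
  expect_equal(names(w), c("taxon", "M-1", "M-2"))
  trans <- write_tmp_csv(c("sample,Methanoregula,Other", "M-1,5,95", "M-2,3,97"))
  t <- read_abundance_table(trans)
  expect_equal(sort(t$taxon), c("Methanoregula", "Other"))
  expect_equal(t$`M-1`[t$taxon == "Methanoregula"], 5)
  long <- write_tmp_csv(c("taxon,sample,abundance", "Methanoregula,M-1,5",
                          "Other,M-1,95", "Methanoregula,M-2,3"))
  l <- read_abundance_table(long)
  expect_equal(l$`M-2`[l$taxon == "Other"], 0)  # absent pairs fill with zero
  # tab-separated sniffing
  tsv <- write_tmp_csv(c("taxon\tM-1", "Methanoregula\t5"))
  expect_equal(read_abundance_table(tsv)$`M-1`, 5)
  # over-full samples are rejected
  bad <- tibble::tibble(taxon = c("A", "B"), S1 = c(80, 30))
  expect_error(annotate_guilds(bad), "100.5")
})

test_that("consistency report joins guild presence with isotope verdicts", {
  ann <- annotate_guilds(synthetic_guild_table())
  m <- murono()
  m$delta_central <- offset_series(m)
  ind <- secondary_methane_indicator(m)
  inv <- extent_from_offset(offset_series(m), id = m$id)
  rep <- guild_consistency_report(ann$summary, ind, extents = inv,
                                  samples = m$id)
  expect_equal(rep$verdicts$secondary_methanogenesis_support, "yes")
  expect_setequal(rep$verdicts$c2plus_oxidizer_candidates,
                  c("sulfate_reducer", "nitrate_reducing_alkane_oxidizer",
                    "iron_reducer"))
  expect_match(rep$verdicts$methane_aom_note, "ANME")
  # all-zero guild table: no support from the community side
  zero <- ann$summary
  for (cn in setdiff(names(zero), "guild")) zero[[cn]] <- 0
  rep0 <- guild_consistency_report(zero, ind, extents = inv, samples = m$id)
  expect_equal(rep0$verdicts$secondary_methanogenesis_support,
               "isotope-only support")
  expect_length(rep0$verdicts$c2plus_oxidizer_candidates, 0)
  # no overlapping samples
  expect_warning(
    none <- guild_consistency_report(ann$summary, ind, samples = "X-9"),
    "overlap")
  expect_length(none$verdicts, 0)
})
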