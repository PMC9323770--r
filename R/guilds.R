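#' @title Metabolic guild annotation of genus-level abundance tables
#'
#' @description
#' Collapses a taxon-by-sample relative-abundance table (the finished output
#' of any 16S pipeline) into the metabolic guilds relevant to subsurface
#' hydrocarbon cycling -- methanogens, anaerobic methanotrophs, sulfate
#' reducers, nitrate-reducing alkane oxidizers and iron reducers -- and
#' cross-checks guild presence against the isotope-based biodegradation
#' inferences. Matching is by case-insensitive substring against taxon names
#' or SILVA-style lineage strings at a declared rank; when patterns at
#' several ranks match one taxon the most specific rank (genus > family >
#' order) wins, and two matches at the same rank are an error that demands
#' lookup disambiguation.
#'
#' @name guilds
NULL

.rank_order <- c(genus = 1, family = 2, order = 3)

#' Load a guild lookup
#'
#' @param path YAML file mapping guild names to pattern lists
#'   (`{pattern, rank}`); default the packaged lookup transcribing the taxa
#'   implicated in mud-volcano hydrocarbon cycling.
#' @return a `guild_lookup` tibble with columns `guild`, `pattern`, `rank`.
#' @export
load_guild_lookup <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "guild_lookup.yaml", package = "mudgas",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  rows <- list()
  for (g in names(cfg$guilds)) {
    for (ent in cfg$guilds[[g]]) {
      if (is.character(ent)) ent <- list(pattern = ent, rank = "genus")
      rows[[length(rows) + 1L]] <-
        tibble::tibble(guild = g, pattern = ent$pattern,
                       rank = ent$rank %||% "genus")
    }
  }
  out <- do.call(rbind, rows)
  bad <- setdiff(unique(out$rank), names(.rank_order))
  if (length(bad)) stop("unknown ranks in lookup: ", paste(bad, collapse = ", "))
  structure(out, class = c("guild_lookup", class(out)))
}

#' Read a taxon abundance table
#'
#' Accepts wide tables with taxa in rows (first column naming the taxon,
#' remaining columns one per sample) or transposed tables whose first column
#' is named `sample`/`id` (taxa as columns), plus two-column-plus long format
#' (`taxon`, `sample`, `abundance`). Values may be fractions or percent.
#'
#' @param path CSV/TSV path (delimiter sniffed from the header line).
#' @return tibble: first column `taxon`, one numeric column per sample.
#' @export
read_abundance_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  nm1 <- tolower(names(df)[1])
  if (ncol(df) == 3 &&
      all(c("taxon", "sample", "abundance") %in% tolower(names(df)))) {
    names(df) <- tolower(names(df))
    wide <- stats::reshape(df, idvar = "taxon", timevar = "sample",
                           direction = "wide")
    names(wide) <- sub("^abundance\\.", "", names(wide))
    wide[is.na(wide)] <- 0
    return(tibble::as_tibble(wide))
  }
  if (nm1 %in% c("sample", "id", "sample_id")) {
    taxa <- names(df)[-1]
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    out <- data.frame(taxon = taxa, m, check.names = FALSE)
    names(out)[-1] <- df[[1]]
    return(tibble::as_tibble(out))
  }
  names(df)[1] <- "taxon"
  tibble::as_tibble(df)
}

.match_guild <- function(taxon, lookup) {
  hits <- lookup[vapply(lookup$pattern,
                        function(p) grepl(p, taxon, ignore.case = TRUE,
                                          fixed = FALSE), TRUE), ]
  if (nrow(hits) == 0) return("other")
  best <- min(.rank_order[hits$rank])
  hits <- hits[.rank_order[hits$rank] == best, ]
  if (length(unique(hits$guild)) > 1)
    stop("taxon '", taxon, "' matches several guilds at rank '",
         hits$rank[1], "' (", paste(unique(hits$guild), collapse = ", "),
         "): disambiguate the lookup")
  hits$guild[1]
}

#' Aggregate taxon abundances into guilds
#'
#' @param table abundance tibble from [read_abundance_table()] (column
#'   `taxon` plus one numeric column per sample).
#' @param lookup a [load_guild_lookup()] table.
#' @return list: `summary` -- tibble guild x sample of summed abundances
#'   (all lookup guilds plus `other` always present); `matches` -- tibble
#'   mapping each taxon to its guild.
#' @export
annotate_guilds <- function(table, lookup = load_guild_lookup()) {
  stopifnot(nrow(table) > 0, "taxon" %in% names(table))
  samples <- setdiff(names(table), "taxon")
  vals <- as.matrix(table[samples])
  if (any(vals < 0, na.rm = TRUE)) stop("negative abundances")
  tot <- colSums(vals, na.rm = TRUE)
  if (any(tot > 100.5)) stop("per-sample abundances exceed 100.5 (percent?)")
  if (all(tot <= 1.005)) NULL  # fractions: same check already passed
  guild_of <- vapply(table$taxon, .match_guild, "", lookup = lookup)
  guilds <- c(unique(lookup$guild), "other")
  summ <- vapply(guilds, function(g) {
    rows <- guild_of == g
    if (!any(rows)) return(stats::setNames(rep(0, length(samples)), samples))
    colSums(vals[rows, , drop = FALSE], na.rm = TRUE)
  }, stats::setNames(numeric(length(samples)), samples))
  summ <- t(matrix(summ, nrow = length(samples),
                   dimnames = list(samples, guilds)))
  list(summary = tibble::as_tibble(cbind(
         tibble::tibble(guild = guilds), as.data.frame(summ))),
       matches = tibble::tibble(taxon = table$taxon, guild = unname(guild_of)))
}

#' Cross-check guilds against isotope-based inferences
#'
#' Rule-based verdicts joining a guild summary with the biodegradation
#' report: secondary methanogenesis is *supported* when methanogens
#' (hydrogenotrophic or acetoclastic) are present in the overlapping samples
#' and the isotope indicator verdict is "consistent"; if the isotopes are
#' consistent but no methanogens are detected the support is "isotope-only".
#' Sulfate-, nitrate- and iron-reducing guilds present alongside isotopic
#' evidence of biodegradation are listed as C2+-oxidizer candidates, and a
#' note is emitted when ANME are (near-)absent, implying anaerobic oxidation
#' starts at ethane rather than methane.
#'
#' @param guild_summary `summary` tibble from [annotate_guilds()].
#' @param indicator result of [secondary_methane_indicator()].
#' @param extents optional [extent_from_offset()] tibble (isotopic evidence
#'   of biodegradation = any positive extent).
#' @param samples optional character vector restricting the guild columns to
#'   samples covered by the isotope data; `NULL` uses all columns.
#' @param presence_threshold abundance above which a guild counts as present
#'   (same units as the table).
#' @param anme_threshold abundance below which ANME count as near-absent.
#' @return list of verdicts.
#' @export
guild_consistency_report <- function(guild_summary, indicator, extents = NULL,
                                     samples = NULL,
                                     presence_threshold = 0,
                                     anme_threshold = 0.9) {
  cols <- setdiff(names(guild_summary), "guild")
  if (!is.null(samples)) {
    cols <- intersect(cols, samples)
    if (length(cols) == 0) {
      warning("no overlapping samples between guild and isotope data")
      return(list(overlap = character(), verdicts = list()))
    }
  }
  g <- function(name) {
    row <- guild_summary$guild == name
    if (!any(row)) return(numeric())
    unlist(guild_summary[row, cols, drop = FALSE])
  }
  methanogens <- c(g("hydrogenotrophic_methanogen"),
                   g("acetoclastic_methanogen"))
  methanogens_present <- any(methanogens > presence_threshold)
  iso_ok <- identical(indicator$verdict, "consistent")
  sec <- if (methanogens_present && iso_ok) "yes"
         else if (iso_ok) "isotope-only support"
         else if (methanogens_present) "guild-only support"
         else "no/indeterminate"
  biodeg_evident <- !is.null(extents) &&
    any(extents$extent_percent > 0, na.rm = TRUE)
  oxidizers <- c("sulfate_reducer", "nitrate_reducing_alkane_oxidizer",
                 "iron_reducer")
  candidates <- if (biodeg_evident)
    oxidizers[vapply(oxidizers,
                     function(n) any(g(n) > presence_threshold), TRUE)]
  else character()
  anme <- g("ANME")
  anme_note <- if (length(anme) && all(anme < anme_threshold))
    "ANME near-absent: anaerobic oxidation likely limited to C2+ alkanes"
  else NA_character_
  list(overlap = cols,
       verdicts = list(secondary_methanogenesis_support = sec,
                       c2plus_oxidizer_candidates = candidates,
                       methane_aom_note = anme_note))
}
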