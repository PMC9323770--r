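#' @title Conventional gas-source diagnostics and end-member mixing
#'
#' @description
#' Two classical diagrams separate thermogenic from microbial methane: the
#' Schoell diagram (dD vs d13C of methane) and the Bernard plot (d13C of
#' methane vs the C1/(C2+C3) "dryness" ratio). Genetic field boundaries are
#' configuration, shipped as a documented YAML, since published diagrams draw
#' rather than tabulate them. A two-end-member concentration-weighted mixing
#' model supports testing whether a sample suite lies on a mixing line
#' between an unaltered deep thermogenic gas and a biodegraded shallow gas.
#'
#' @name classify
NULL

#' Load genetic field definitions
#'
#' Reads the Schoell/Bernard field polygons and the alteration threshold from
#' a YAML file; with no argument, the packaged defaults. Rectangular fields
#' may be given as `d13c` plus `dd` (Schoell) or `log10_ratio` (Bernard)
#' ranges; arbitrary simple polygons as `polygon: {x: [...], y: [...]}`.
#' Field order matters: on a boundary the first-listed field wins.
#'
#' @param path YAML file; default the packaged field set.
#' @return list with `schoell`, `bernard` (lists of named polygons) and
#'   `altered_ratio_threshold`.
#' @export
load_source_fields <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "source_fields.yaml", package = "mudgas",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  as_poly <- function(fld, ykey) {
    if (!is.null(fld$polygon))
      return(list(name = fld$name, x = as.numeric(fld$polygon$x),
                  y = as.numeric(fld$polygon$y)))
    p <- rect_polygon(as.numeric(fld$d13c), as.numeric(fld[[ykey]]))
    list(name = fld$name, x = p$x, y = p$y)
  }
  list(schoell = lapply(cfg$schoell, as_poly, ykey = "dd"),
       bernard = lapply(cfg$bernard, as_poly, ykey = "log10_ratio"),
       altered_ratio_threshold = cfg$altered_ratio_threshold %||% 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bernard ratio C1/(C2+C3)
#'
#' Methane over ethane-plus-propane mole fractions. A bdl alkane contributes
#' nothing to the denominator; with both C2 and C3 bdl (or a measured zero
#' denominator) the ratio is undefined and `NA` is returned, never infinity.
#'
#' @param records a `mudgas_samples` table with `ch4`, `c2h6`, `c3h8`.
#' @return numeric vector of ratios, `NA` where undefined.
#' @export
bernard_ratio <- function(records) {
  stopifnot(inherits(records, "mudgas_samples"))
  c1 <- records$ch4
  c2 <- ifelse(is_present(records, "c2h6"), records$c2h6, NA_real_)
  c3 <- ifelse(is_present(records, "c3h8"), records$c3h8, NA_real_)
  denom <- ifelse(is.na(c2) & is.na(c3), NA_real_,
                  ifelse(is.na(c2), 0, c2) + ifelse(is.na(c3), 0, c3))
  out <- ifelse(is.na(denom) | denom == 0, NA_real_, c1 / denom)
  if (any(!is.na(denom) & denom == 0))
    warning("measured C2+C3 denominator is exactly zero: ratio undefined")
  out
}

.classify_point <- function(px, py, fields) {
  for (fld in fields)
    if (point_in_polygon(px, py, fld$x, fld$y)) return(fld$name)
  "mixed/unclassified"
}

#' Classify methane source on the Schoell diagram
#'
#' Point-in-polygon test of (d13C_CH4, dD_CH4) against the configured genetic
#' fields; points in no field are "mixed/unclassified".
#'
#' @param d13c_ch4,dd_ch4 methane deltas in per mil; vectorized.
#' @param fields a field set from [load_source_fields()].
#' @return character vector of field names.
#' @export
classify_schoell <- function(d13c_ch4, dd_ch4, fields = load_source_fields()) {
  mapply(function(x, y) {
    if (is.na(x) || is.na(y)) return(NA_character_)
    .classify_point(x, y, fields$schoell)
  }, d13c_ch4, dd_ch4, USE.NAMES = FALSE)
}

#' Classify methane source on the Bernard plot
#'
#' Field label from (d13C_CH4, log10 of the Bernard ratio), plus an `altered`
#' flag raised when the methane d13C sits in the thermogenic band but the
#' ratio exceeds the configured threshold -- the signature of C2+ removal
#' (biodegradation) or methane addition (methanogenesis, migration).
#'
#' @param d13c_ch4 methane d13C in per mil; vectorized.
#' @param bernard Bernard ratio (see [bernard_ratio()]); `NA` = undefined.
#' @param fields a field set from [load_source_fields()].
#' @return tibble with `field` and `altered`.
#' @export
classify_bernard <- function(d13c_ch4, bernard,
                             fields = load_source_fields()) {
  lab <- mapply(function(x, r) {
    if (is.na(x) || is.na(r)) return("unclassified")
    .classify_point(x, log10(r), fields$bernard)
  }, d13c_ch4, bernard, USE.NAMES = FALSE)
  # altered: methane d13C in the thermogenic band yet a ratio too high for an
  # unaltered thermogenic gas (C2+ stripped or methane added)
  tband <- Filter(function(f) f$name == "thermogenic", fields$bernard)
  in_band <- if (length(tband))
    d13c_ch4 >= min(tband[[1]]$x) & d13c_ch4 <= max(tband[[1]]$x)
  else lab == "thermogenic"
  altered <- !is.na(bernard) & !is.na(d13c_ch4) & in_band &
    bernard > fields$altered_ratio_threshold
  tibble::tibble(field = lab, altered = altered)
}

#' Gas end member
#'
#' @param name label.
#' @param composition named numeric vector of mole % per species.
#' @param isotopes named numeric vector of deltas (per mil) per species.
#' @return an `end_member` list.
#' @export
end_member <- function(name, composition, isotopes = numeric()) {
  if (any(composition < 0 | composition > 100))
    stop("end-member composition outside [0, 100] mole %")
  structure(list(name = name, composition = composition, isotopes = isotopes),
            class = "end_member")
}

#' Two-end-member concentration-weighted mixing
#'
#' Species concentration mixes linearly, `C = x C1 + (1 - x) C2`; species
#' delta mixes weighted by concentration,
#' `delta = (x C1 d1 + (1 - x) C2 d2) / C`, and is undefined (NA) where the
#' mixed concentration is zero. A species present in neither end member is
#' absent from the mix.
#'
#' @param e1,e2 [end_member()]s.
#' @param x fraction of `e1`, in [0, 1].
#' @return list with `composition` and `isotopes` (named numeric vectors).
#' @export
mix_end_members <- function(e1, e2, x) {
  stopifnot(inherits(e1, "end_member"), inherits(e2, "end_member"))
  if (x < 0 || x > 1) stop("mixing fraction x must lie in [0, 1]")
  species <- union(names(e1$composition), names(e2$composition))
  g <- function(v, s) if (s %in% names(v)) v[[s]] else 0
  gd <- function(v, s) if (s %in% names(v)) v[[s]] else NA_real_
  comp <- vapply(species, function(s)
    x * g(e1$composition, s) + (1 - x) * g(e2$composition, s), 0)
  iso <- vapply(species, function(s) {
    c1 <- g(e1$composition, s); c2 <- g(e2$composition, s)
    cm <- x * c1 + (1 - x) * c2
    if (cm == 0) return(NA_real_)
    d1 <- gd(e1$isotopes, s); d2 <- gd(e2$isotopes, s)
    (x * c1 * ifelse(c1 == 0, 0, d1) +
       (1 - x) * c2 * ifelse(c2 == 0, 0, d2)) / cm
  }, 0)
  list(composition = comp, isotopes = iso)
}
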