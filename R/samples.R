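#' @title Gas sample tables with below-detection-limit states
#'
#' @description
#' A `mudgas_samples` object is a tibble of per-sample measurements (one row
#' per field sample) carrying an explicit *below detection limit* (bdl) mask.
#' Every measured cell is in one of three states: a numeric value, bdl, or
#' missing. bdl is informative ("we looked, it was too low to quantify") and
#' is therefore never coerced to zero or silently dropped into regressions;
#' it is excluded from statistics and propagated through derived quantities.
#'
#' Composition columns (`ch4`, `co2`, `c2h6`, `c3h8`, `i_c4h10`, `n_c4h10`)
#' are mole percent (0-100); all other measured columns are delta values in
#' per mil (d13C vs VPDB, dD vs VSMOW).
#'
#' @name mudgas_samples
NULL

# mole-percent columns; everything else measured is a delta in per mil
.comp_cols <- c("ch4", "co2", "c2h6", "c3h8", "i_c4h10", "n_c4h10")
.meta_cols <- c("id", "site", "temperature")

.measured_cols <- function(df) setdiff(names(df), .meta_cols)

#' Construct a gas sample table from plain data
#'
#' @param df data frame with an `id` column, optional `site` and
#'   `temperature`, and numeric measurement columns.
#' @param bdl optional logical data frame/matrix, same rows as `df`, columns a
#'   subset of the measured columns; `TRUE` marks below-detection-limit cells
#'   (whose values must be `NA`). Defaults to all-`FALSE`.
#' @param site_prefixes named character vector mapping id prefixes to site
#'   names, used to fill a missing `site` column.
#' @return a `mudgas_samples` tibble.
#' @export
as_gas_samples <- function(df, bdl = NULL,
                           site_prefixes = c(G = "Gamou", M = "Murono")) {
  df <- tibble::as_tibble(df)
  if (!"id" %in% names(df)) stop("sample table needs an 'id' column")
  if (anyDuplicated(df$id)) {
    stop("duplicate sample ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (!"site" %in% names(df) && length(site_prefixes)) {
    pref <- substr(df$id, 1, 1)
    df$site <- unname(site_prefixes[pref])
  }
  meas <- .measured_cols(df)
  full <- matrix(FALSE, nrow(df), length(meas), dimnames = list(NULL, meas))
  if (!is.null(bdl)) {
    bdl <- as.data.frame(bdl)
    bad <- setdiff(names(bdl), meas)
    if (length(bad)) stop("bdl mask names unknown columns: ",
                          paste(bad, collapse = ", "))
    for (cn in names(bdl)) full[, cn] <- as.logical(bdl[[cn]])
  }
  for (cn in meas) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop("column '", cn, "' is not numeric")
    if (any(full[, cn] & !is.na(v)))
      stop("column '", cn, "': bdl cells must carry NA values")
  }
  x <- structure(df, bdl = tibble::as_tibble(as.data.frame(full)),
                 class = c("mudgas_samples", class(df)))
  .validate_samples(x)
  x
}

.validate_samples <- function(x) {
  bdl <- attr(x, "bdl")
  comp <- intersect(.comp_cols, names(x))
  for (cn in comp) {
    v <- x[[cn]]
    ok <- is.na(v) | (v >= 0 & v <= 100)
    if (!all(ok)) stop("composition column '", cn,
                       "' outside [0, 100] mole % in row(s) ",
                       paste(which(!ok), collapse = ", "))
  }
  if (length(comp) >= 2) {
    m <- as.matrix(x[comp])
    s <- rowSums(m, na.rm = TRUE)  # bdl/missing contribute 0 to the sum check
    if (any(s > 100.5)) stop("composition sums exceed 100.5 mole % in row(s) ",
                             paste(which(s > 100.5), collapse = ", "))
  }
  for (cn in setdiff(.measured_cols(x), comp)) {
    v <- x[[cn]]
    if (any(!is.na(v) & v <= -1000))
      stop("delta column '", cn, "' at or below -1000 per mil")
  }
  invisible(x)
}

#' @export
`[.mudgas_samples` <- function(x, i, j, ..., drop = FALSE) {
  bdl <- attr(x, "bdl")
  y <- NextMethod()
  if (!is.data.frame(y)) return(y)
  if (!missing(i)) bdl <- bdl[i, , drop = FALSE]
  keep <- intersect(names(bdl), names(y))
  structure(y, bdl = bdl[, keep, drop = FALSE],
            class = c("mudgas_samples", setdiff(class(y), "mudgas_samples")))
}

#' Below-detection-limit mask
#'
#' @param x a `mudgas_samples` table.
#' @param col optional column name; if given, returns a logical vector for
#'   that column, else the full logical tibble.
#' @return logical tibble or vector; `TRUE` where the cell is bdl.
#' @export
is_bdl <- function(x, col = NULL) {
  stopifnot(inherits(x, "mudgas_samples"))
  bdl <- attr(x, "bdl")
  if (is.null(col)) return(bdl)
  if (is.null(bdl) || !col %in% names(bdl)) return(rep(FALSE, nrow(x)))
  bdl[[col]]
}

#' Values with both bdl and missing cells as NA, plus presence helper
#'
#' `measured()` returns the numeric vector of a column with `NA` wherever the
#' cell is bdl or missing; `is_present()` flags cells carrying an actual
#' number.
#' @param x a `mudgas_samples` table.
#' @param col column name.
#' @export
measured <- function(x, col) {
  stopifnot(inherits(x, "mudgas_samples"))
  x[[col]]
}

#' @rdname measured
#' @export
is_present <- function(x, col) !is.na(measured(x, col)) & !is_bdl(x, col)

#' Read a delimited sample table
#'
#' Reads a CSV of per-sample gas measurements into a [mudgas_samples] table.
#' Cells equal to `bdl_token` (case-insensitive) become the
#' below-detection-limit state; cells in `missing_tokens` become missing.
#' Anything else must parse as a number.
#'
#' @param path CSV file path. Comma separated, UTF-8, "." decimal.
#' @param bdl_token token marking below-detection-limit cells (default "bdl").
#' @param missing_tokens tokens treated as missing.
#' @param site_prefixes named map from id first letter to site name, used when
#'   the file lacks a `site` column.
#' @return a `mudgas_samples` tibble.
#' @export
read_sample_table <- function(path, bdl_token = "bdl",
                              missing_tokens = c("", "-", "NA"),
                              site_prefixes = c(G = "Gamou", M = "Murono")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!"id" %in% names(raw)) stop("sample table needs an 'id' header column")
  meas <- .measured_cols(raw)
  out <- raw
  bdl <- matrix(FALSE, nrow(raw), length(meas), dimnames = list(NULL, meas))
  for (cn in meas) {
    cells <- gsub("−", "-", trimws(raw[[cn]]))  # tolerate unicode minus
    val <- rep(NA_real_, length(cells))
    isb <- tolower(cells) == tolower(bdl_token)
    ismiss <- cells %in% missing_tokens
    todo <- !isb & !ismiss
    v <- suppressWarnings(as.numeric(cells[todo]))
    if (anyNA(v)) {
      bad <- which(todo)[which(is.na(v))[1]]
      stop("cannot parse cell in row ", bad, ", column '", cn, "': '",
           raw[[cn]][bad], "'")
    }
    val[todo] <- v
    bdl[, cn] <- isb
    out[[cn]] <- val
  }
  as_gas_samples(out, bdl = bdl, site_prefixes = site_prefixes)
}

#' Write a sample table, preserving bdl states
#'
#' Inverse of [read_sample_table()]: numeric cells are written at full
#' precision, bdl cells as `bdl_token`, missing cells empty.
#' @param x a `mudgas_samples` table.
#' @param path output CSV path.
#' @param bdl_token token to write for below-detection-limit cells.
#' @export
write_sample_table <- function(x, path, bdl_token = "bdl") {
  stopifnot(inherits(x, "mudgas_samples"))
  bdl <- attr(x, "bdl")
  out <- as.data.frame(x)
  for (cn in .measured_cols(out)) {
    cells <- ifelse(is.na(out[[cn]]), "",
                    formatC(out[[cn]], digits = 17, format = "g"))
    cells[bdl[[cn]]] <- bdl_token
    out[[cn]] <- cells
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Column summaries excluding bdl and missing cells
#'
#' Per measured column: count of present values, counts of bdl and missing
#' cells, and min/max/mean over present values only. A column with no present
#' value gets `NA` statistics (unavailable), never zero.
#'
#' @param x a `mudgas_samples` table.
#' @return tibble with one row per measured column.
#' @export
summarize_samples <- function(x) {
  stopifnot(inherits(x, "mudgas_samples"), nrow(x) >= 1)
  meas <- .measured_cols(x)
  rows <- lapply(meas, function(cn) {
    v <- x[[cn]]
    b <- is_bdl(x, cn)
    pres <- v[!is.na(v)]
    tibble::tibble(
      column = cn,
      n = length(pres),
      n_bdl = sum(b),
      n_missing = sum(is.na(v) & !b),
      min = if (length(pres)) min(pres) else NA_real_,
      max = if (length(pres)) max(pres) else NA_real_,
      mean = if (length(pres)) mean(pres) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Packaged Tokamachi mud-volcano field tables
#'
#' Chemical composition (mole %) and bulk plus position-specific isotope
#' composition (per mil) of the seven gas samples from the Murono and Gamou
#' sites of the Tokamachi mud-volcano area, Japan: two mud-volcano samples
#' from Gamou, one from Murono, and four Murono seep samples.
#' `tokamachi_samples()` joins the two tables by sample id.
#'
#' @return a `mudgas_samples` tibble.
#' @export
tokamachi_composition <- function() {
  read_sample_table(system.file("extdata", "tokamachi_composition.csv",
                                package = "mudgas", mustWork = TRUE))
}

#' @rdname tokamachi_composition
#' @export
tokamachi_isotopes <- function() {
  read_sample_table(system.file("extdata", "tokamachi_isotopes.csv",
                                package = "mudgas", mustWork = TRUE))
}

#' @rdname tokamachi_composition
#' @export
tokamachi_samples <- function() {
  comp <- tokamachi_composition()
  iso <- tokamachi_isotopes()
  stopifnot(identical(comp$id, iso$id))
  newcols <- setdiff(names(iso), names(comp))
  df <- cbind(as.data.frame(comp), as.data.frame(iso)[newcols])
  bdl <- cbind(as.data.frame(attr(comp, "bdl")),
               as.data.frame(attr(iso, "bdl"))[intersect(newcols,
                                                names(attr(iso, "bdl")))])
  as_gas_samples(df, bdl = bdl)
}
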