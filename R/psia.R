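#' @title Position-specific 13C reconstruction of propane
#'
#' @description
#' On-line pyrolysis of propane yields three fragments: CH4 and C2H6, which
#' derive from the terminal carbon positions only, and C2H4, which carries one
#' terminal and one central carbon. The terminal-position delta is the
#' peak-area-weighted mean of the CH4 and C2H6 fragment deltas; the central
#' position follows by mass balance from the C2H4 fragment; and the relative
#' central-position enrichment is the difference central minus terminal.
#' These three relations let the per-position 13C composition of propane be
#' reconstructed from routine GC-pyrolysis-IRMS fragment measurements.
#'
#' @name psia
NULL

#' Make a pyrolysis fragment measurement
#'
#' One propane injection: peak areas (arbitrary units, > 0) and fragment
#' d13C values (per mil) for the CH4, C2H4 and C2H6 pyrolysis fragments,
#' with optional 1-sigma uncertainties per fragment delta.
#'
#' @param area_ch4,area_c2h4,area_c2h6 peak areas, all > 0.
#' @param delta_ch4,delta_c2h4,delta_c2h6 fragment d13C in per mil.
#' @param sigma_ch4,sigma_c2h4,sigma_c2h6 optional 1-sigma in per mil (>= 0).
#' @param sample_id optional sample identifier shared by replicates.
#' @return a `fragment_measurement` list.
#' @export
fragment_measurement <- function(area_ch4, area_c2h4, area_c2h6,
                                 delta_ch4, delta_c2h4, delta_c2h6,
                                 sigma_ch4 = 0, sigma_c2h4 = 0, sigma_c2h6 = 0,
                                 sample_id = NA_character_) {
  areas <- c(area_ch4, area_c2h4, area_c2h6)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("fragment peak areas must be >= 0")
  if (area_ch4 + area_c2h6 <= 0)
    stop("terminal position unconstrained: CH4 and C2H6 areas both zero")
  sig <- c(sigma_ch4, sigma_c2h4, sigma_c2h6)
  if (any(sig < 0)) stop("fragment sigmas must be >= 0")
  structure(list(sample_id = sample_id,
                 area_ch4 = area_ch4, area_c2h4 = area_c2h4,
                 area_c2h6 = area_c2h6,
                 delta_ch4 = delta_ch4, delta_c2h4 = delta_c2h4,
                 delta_c2h6 = delta_c2h6,
                 sigma_ch4 = sigma_ch4, sigma_c2h4 = sigma_c2h4,
                 sigma_c2h6 = sigma_c2h6),
            class = "fragment_measurement")
}

#' Terminal-position delta from pyrolysis fragments
#'
#' Area-weighted mean of the CH4 and C2H6 fragment deltas, both of which
#' sample the terminal carbons only. Raw peak areas are the weights.
#'
#' @param frag a [fragment_measurement()].
#' @return terminal-position d13C in per mil.
#' @export
terminal_delta <- function(frag) {
  stopifnot(inherits(frag, "fragment_measurement"))
  denom <- frag$area_ch4 + frag$area_c2h6
  if (denom <= 0) stop("terminal position unconstrained: both areas zero")
  (frag$delta_ch4 * frag$area_ch4 + frag$delta_c2h6 * frag$area_c2h6) / denom
}

#' Central-position delta from the C2H4 fragment
#'
#' The C2H4 fragment carries one terminal and one central carbon in equal
#' proportion, so the central position is `2 * delta_c2h4 - delta_terminal`.
#'
#' @param delta_c2h4 C2H4 fragment d13C in per mil.
#' @param delta_terminal terminal-position d13C in per mil.
#' @return central-position d13C in per mil.
#' @export
central_delta <- function(delta_c2h4, delta_terminal) {
  2 * delta_c2h4 - delta_terminal
}

#' Relative 13C enrichment of the central position
#'
#' Difference central minus terminal, in per mil. `NA` inputs (e.g. a bdl
#' position) propagate to `NA`.
#'
#' @param delta_central,delta_terminal position deltas in per mil.
#' @return the central-position offset in per mil.
#' @export
central_offset <- function(delta_central, delta_terminal) {
  delta_central - delta_terminal
}

#' Bulk propane delta from its position deltas
#'
#' Propane has two terminal carbons and one central carbon, so the molecular
#' average is `(2 * terminal + central) / 3`.
#'
#' @param delta_terminal,delta_central position deltas in per mil.
#' @return bulk d13C of propane in per mil.
#' @export
bulk_from_positions <- function(delta_terminal, delta_central) {
  (2 * delta_terminal + delta_central) / 3
}

.psia_point <- function(frag) {
  t <- terminal_delta(frag)
  c <- central_delta(frag$delta_c2h4, t)
  list(terminal = t, central = c, offset = central_offset(c, t))
}

#' Position-specific composition with Monte-Carlo uncertainty
#'
#' Combines replicate fragment measurements of one sample into the
#' terminal-position, central-position and offset deltas, and propagates the
#' per-fragment delta uncertainties by Monte-Carlo resampling: each draw
#' perturbs every fragment delta by a normal deviate with its stated sigma,
#' recomputes the positions per replicate (area-weighted within a replicate)
#' and averages the replicates unweighted. The run is deterministic for a
#' given seed and leaves the caller's RNG state untouched.
#'
#' @param replicates a list of [fragment_measurement()]s (>= 1), or a single
#'   measurement.
#' @param n_draws Monte-Carlo draws (>= 100; default 10000).
#' @param seed integer seed, mandatory.
#' @return a tibble with one row per quantity (`terminal`, `central`,
#'   `offset`): point estimate (`value`, from the unperturbed deltas), Monte-
#'   Carlo `mean` and 1-sigma (`sigma`).
#' @export
propagate_uncertainty <- function(replicates, n_draws = 10000, seed) {
  if (inherits(replicates, "fragment_measurement"))
    replicates <- list(replicates)
  stopifnot(length(replicates) >= 1, n_draws >= 100)
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  pts <- lapply(replicates, .psia_point)
  point <- vapply(c("terminal", "central", "offset"),
                  function(q) mean(vapply(pts, `[[`, 0, q)), 0)
  draws <- with_preserved_rng(seed, {
    out <- matrix(0, n_draws, 3, dimnames = list(NULL, names(point)))
    for (k in seq_len(n_draws)) {
      per <- vapply(replicates, function(fr) {
        fr$delta_ch4 <- fr$delta_ch4 + stats::rnorm(1, 0, fr$sigma_ch4)
        fr$delta_c2h4 <- fr$delta_c2h4 + stats::rnorm(1, 0, fr$sigma_c2h4)
        fr$delta_c2h6 <- fr$delta_c2h6 + stats::rnorm(1, 0, fr$sigma_c2h6)
        unlist(.psia_point(fr))
      }, c(terminal = 0, central = 0, offset = 0))
      out[k, ] <- rowMeans(per)
    }
    out
  })
  tibble::tibble(
    quantity = names(point),
    value = unname(point),
    mean = unname(colMeans(draws)[names(point)]),
    sigma = unname(apply(draws, 2, stats::sd)[names(point)])
  )
}

#' Read a fragment measurement CSV
#'
#' Expected columns: `sample_id`, `replicate`, `area_ch4`, `d13c_ch4`,
#' `area_c2h4`, `d13c_c2h4`, `area_c2h6`, `d13c_c2h6`, and optionally
#' `sigma_ch4`, `sigma_c2h4`, `sigma_c2h6`.
#'
#' @param path CSV path.
#' @return named list: one list of [fragment_measurement()]s per sample id.
#' @export
read_fragment_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, strip.white = TRUE)
  need <- c("sample_id", "area_ch4", "d13c_ch4", "area_c2h4", "d13c_c2h4",
            "area_c2h6", "d13c_c2h6")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fragment table lacks columns: ",
                         paste(miss, collapse = ", "))
  sig <- function(cn, i) if (cn %in% names(df)) df[[cn]][i] else 0
  split(seq_len(nrow(df)), df$sample_id) |>
    lapply(function(idx) lapply(idx, function(i) {
      fragment_measurement(df$area_ch4[i], df$area_c2h4[i], df$area_c2h6[i],
                           df$d13c_ch4[i], df$d13c_c2h4[i], df$d13c_c2h6[i],
                           sig("sigma_ch4", i), sig("sigma_c2h4", i),
                           sig("sigma_c2h6", i),
                           sample_id = df$sample_id[i])
    }))
}
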