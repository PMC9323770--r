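test_that("Rayleigh forward model behaves at its limits", {
  expect_equal(rayleigh_forward(1, 33, -25), -25)
  expect_equal(rayleigh_forward(0.3, 0, -25), -25)
  expect_equal(rayleigh_forward(0.5, 33, -25), -2.440967, tolerance = 1e-6)
  f <- seq(0.05, 1, by = 0.05)
  d <- rayleigh_forward(f, 33, -25)
  expect_true(all(diff(d) < 0))  # residue enriches as f shrinks
  expect_error(rayleigh_forward(0, 33, -25), "\\(0, 1\\]")
  expect_error(rayleigh_forward(-0.1, 33, -25), "\\(0, 1\\]")
})

test_that("forward and inverse Rayleigh round-trip to numerical precision", {
  for (eps in c(3, 33, 60)) {
    f <- seq(0.05, 0.95, by = 0.05)
    d <- rayleigh_forward(f, eps, -27)
    expect_equal(rayleigh_invert(d, -27, eps), f, tolerance = 1e-12)
  }
})

test_that("extent inversion is monotone, bounded and bdl-propagating", {
  p <- rayleigh_params()
  expect_equal(extent_from_offset(0, p)$extent_percent, 0)
  e <- extent_from_offset(c(28.3, 31.5, 37.2, 40.5), p)
  expect_true(all(diff(e$extent_percent) > 0))  # larger offset, larger extent
  expect_true(all(e$extent_percent >= 0 & e$extent_percent < 100))
  expect_true(is.na(extent_from_offset(NA_real_, p)$extent_percent))
  expect_error(extent_from_offset(-1, p), "negative extent")
  # round trip through the forward model
  d <- rayleigh_forward(0.4, 33, 0)
  expect_equal(extent_from_offset(d, p)$fraction_remaining, 0.4,
               tolerance = 1e-12)
})

test_that("field-sample extents span the expected biodegradation window", {
  s <- tokamachi_samples()
  e <- extent_from_offset(offset_series(s), id = s$id)
  ok <- !is.na(e$extent_percent)
  expect_equal(sum(ok), 6)  # M-3 drops out via bdl
  expect_true(all(e$extent_percent[ok] >= 50 & e$extent_percent[ok] <= 75))
  expect_gte(diff(range(e$extent_percent[ok])), 10)
})

test_that("exponential linear limit approximates the exact inversion", {
  p <- rayleigh_params()
  d <- seq(0.5, 15, by = 0.5)
  exact <- extent_from_offset(d, p)$extent_percent
  approx <- 100 * (1 - exp(-d / p$eps_central))
  expect_true(all(abs(exact - approx) <= 0.5))
})

test_that("co-degradation slope on the Murono suite is 0.4", {
  sl <- codegradation_slope(murono())
  expect_equal(round(sl$slope, 1), 0.4)
  expect_equal(sl$n, 5)
  expect_gt(sl$r, 0.9)
  # exact two-point line
  two <- as_gas_samples(tibble::tibble(id = c("A-1", "A-2"),
                                       c2h6 = c(0, 1), c3h8 = c(0, 0.4)),
                        site_prefixes = NULL)
  expect_equal(codegradation_slope(two)$slope, 0.4)
  # order invariance
  m <- murono()
  perm <- m[c(4, 1, 5, 2, 3), ]
  expect_equal(codegradation_slope(perm)$slope, sl$slope)
  flat <- as_gas_samples(tibble::tibble(id = c("A-1", "A-2", "A-3"),
                                        c2h6 = c(1, 1, 1),
                                        c3h8 = c(0.1, 0.2, 0.3)),
                         site_prefixes = NULL)
  expect_error(codegradation_slope(flat), "variance")
})

test_that("isotope co-trends carry the expected signs on Murono samples", {
  m <- murono()
  m$delta_central <- offset_series(m)
  expect_lt(isotope_cotrend(m, "delta_central", "d13c_ch4")$r, 0)
  expect_gt(isotope_cotrend(m, "delta_central", "ch4")$r, 0)
  # identity series
  ident <- as_gas_samples(tibble::tibble(id = paste0("A-", 1:4),
                                         x = 1:4 * 1.0, y = 1:4 * 1.0),
                          site_prefixes = NULL)
  t <- isotope_cotrend(ident, "x", "y")
  expect_equal(t$slope, 1)
  expect_equal(t$r, 1)
  expect_error(isotope_cotrend(m[1:2, ], "delta_central", "d13c_ch4"),
               "at least 3")
})

test_that("secondary-methane indicator reads the three fingerprints", {
  m <- murono()
  m$delta_central <- offset_series(m)
  ind <- secondary_methane_indicator(m, co2_threshold = 15)
  expect_true(ind$co2_enriched)
  expect_lt(ind$ch4_delta_trend, 0)
  expect_gt(ind$ch4_conc_trend, 0)
  expect_equal(ind$verdict, "consistent")
  # all-zero deltas: no CO2 enrichment, no trends -> not consistent
  flat <- as_gas_samples(tibble::tibble(
    id = paste0("A-", 1:4), ch4 = c(90, 91, 92, 93),
    d13c_ch4 = rep(0, 4), d13c_co2 = rep(0, 4),
    delta_central = c(10, 20, 30, 40)), site_prefixes = NULL)
  expect_false(secondary_methane_indicator(flat)$verdict == "consistent")
  # missing series -> indeterminate
  part <- as_gas_samples(tibble::tibble(id = "A-1", ch4 = 90),
                         site_prefixes = NULL)
  ind2 <- secondary_methane_indicator(part)
  expect_equal(ind2$verdict, "indeterminate")
  expect_true("d13c_co2" %in% ind2$missing)
})
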