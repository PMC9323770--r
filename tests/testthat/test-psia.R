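test_that("terminal delta is the area-weighted mean of CH4 and C2H6 fragments", {
  f <- function(a1, d1, a3, d3)
    fragment_measurement(a1, 1, a3, d1, 0, d3)
  expect_equal(terminal_delta(f(1, -20, 0.5, -20)), -20)
  expect_equal(terminal_delta(f(2, -22, 1, -18)), (-22 * 2 - 18 * 1) / 3)
  # single-fragment limit: zero C2H6 area returns the CH4 fragment delta
  expect_equal(terminal_delta(f(1.7, -31.4, 0, 99)), -31.4)
  expect_error(fragment_measurement(0, 1, 0, -20, 0, -20), "unconstrained")
  expect_error(fragment_measurement(-1, 1, 1, -20, 0, -20), ">= 0")
})

test_that("central position and offset follow fragment mass balance", {
  expect_equal(central_delta(-20, -20), -20)
  expect_equal(central_delta(0, -10), 10)
  # solve backward from the G-1 positions: C2H4 fragment at the position mean
  expect_equal(central_delta((11.2 + -20.3) / 2, -20.3), 11.2)
  expect_equal(central_offset(11.2, -20.3), 31.5)
  expect_equal(central_offset(18.2, -22.3), 40.5)
  expect_equal(central_offset(-5, -5), 0)
  expect_true(is.na(central_offset(NA, -20)))
})

test_that("bulk reconstruction matches the 2:1 carbon mass balance", {
  expect_equal(bulk_from_positions(-20.3, 11.2), -9.8)
  expect_equal(bulk_from_positions(-22.8, 14.4), -10.4)
  expect_equal(bulk_from_positions(-15, -15), -15)
})

test_that("offset of reconstructed central is 2(d - t) for all inputs", {
  set.seed(1)
  d <- runif(50, -60, 20)
  t <- runif(50, -60, 20)
  expect_equal(central_offset(central_delta(d, t), t), 2 * (d - t))
})

test_that("positions and bulk agree within rounding on every field sample", {
  s <- tokamachi_samples()
  ok <- is_present(s, "d13c_central") & is_present(s, "d13c_terminal")
  recon <- bulk_from_positions(s$d13c_terminal[ok], s$d13c_central[ok])
  expect_true(all(abs(recon - s$d13c_c3h8[ok]) <= 0.1))
})

test_that("Monte-Carlo propagation matches closed-form linear propagation", {
  frag <- fragment_measurement(1, 1, 0.3, -20, -5, -20,
                               sigma_ch4 = 0.3, sigma_c2h4 = 0.3,
                               sigma_c2h6 = 0.3)
  u <- propagate_uncertainty(frag, n_draws = 10000, seed = 7)
  s_off <- u$sigma[u$quantity == "offset"]
  # offset = 2 d_C2H4 - 2 d_T with d_T area-weighted (1, 0.3)
  var_t <- (1^2 + 0.3^2) * 0.3^2 / 1.3^2
  closed <- sqrt(4 * 0.3^2 + 4 * var_t)
  expect_lt(abs(s_off - closed) / closed, 0.05)
  expect_gt(s_off, 0.5)
  expect_lt(s_off, 1.5)
})

test_that("uncertainty propagation is deterministic and replicate-aware", {
  frag <- fragment_measurement(1, 1, 0.3, -21, -4, -20,
                               sigma_ch4 = 0.2, sigma_c2h4 = 0.2,
                               sigma_c2h6 = 0.2)
  a <- propagate_uncertainty(frag, n_draws = 500, seed = 42)
  b <- propagate_uncertainty(frag, n_draws = 500, seed = 42)
  expect_identical(a, b)
  # zero sigma everywhere: sigmas 0, means equal point estimates
  f0 <- fragment_measurement(1, 1, 0.3, -21, -4, -20)
  u0 <- propagate_uncertainty(f0, n_draws = 100, seed = 1)
  expect_equal(u0$sigma, rep(0, 3))
  expect_equal(u0$mean, u0$value)
  # two identical replicates give the same mean as one
  u2 <- propagate_uncertainty(list(f0, f0), n_draws = 100, seed = 1)
  expect_equal(u2$value, u0$value)
  # the caller's RNG stream is untouched
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(propagate_uncertainty(frag, n_draws = 100, seed = 5))
  x2 <- rnorm(1)
  expect_identical(x1, x2)
  expect_error(propagate_uncertainty(frag, n_draws = 100), "seed")
})

test_that("fragment CSV reader groups replicates by sample", {
  p <- write_tmp_csv(c(
    "sample_id,replicate,area_ch4,d13c_ch4,area_c2h4,d13c_c2h4,area_c2h6,d13c_c2h6",
    "S-1,1,1.0,-20.0,1.0,-5.0,0.3,-20.2",
    "S-1,2,1.1,-20.1,0.9,-4.9,0.3,-20.0",
    "S-2,1,1.0,-23.0,1.0,-8.0,0.3,-23.0"))
  fr <- read_fragment_table(p)
  expect_named(fr, c("S-1", "S-2"))
  expect_length(fr[["S-1"]], 2)
  expect_equal(terminal_delta(fr[["S-2"]][[1]]), -23)
  expect_error(read_fragment_table(write_tmp_csv("sample_id,area_ch4")),
               "lacks columns")
})
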