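test_that("truncation keeps channels by geometric midpoint and never rescales", {
  edges <- smps_channel_bounds()
  n <- length(edges) - 1
  sc <- mobility_scan(edges[-(n + 1)], edges[-1], rep(10, n), instrument = "smps")
  tr <- truncate_channels(sc, 6, 560)
  expect_true(all(tr$channels$midpoint >= 6 & tr$channels$midpoint <= 560))
  expect_true(all(tr$channels$concentration == 10))
  # identity truncation
  same <- truncate_channels(sc, min(sc$channels$midpoint), max(sc$channels$midpoint))
  expect_equal(same$channels, sc$channels)
  one <- mobility_scan(80, 100, 5)
  expect_error(truncate_channels(one, 200, 500), class = "aerodose_empty_scan")
})

test_that("background subtraction is channel-wise and clamped at zero", {
  sc <- mobility_scan(c(10, 20), c(20, 40), c(110, 5))
  bg <- mobility_scan(c(10, 20), c(20, 40), c(10, 10))
  out <- background_subtract(sc, bg)
  expect_equal(out$channels$concentration, c(100, 0))
  self <- background_subtract(sc, sc)
  expect_true(all(self$channels$concentration == 0))
  bg2 <- mobility_scan(c(11, 20), c(20, 40), c(1, 1))
  expect_error(background_subtract(sc, bg2), class = "aerodose_invalid_input")
})

test_that("number statistics match closed-form geometric moments", {
  # degenerate: one channel
  one <- mobility_scan(80, 100, 500)
  s <- number_stats(one)
  expect_equal(s$cmd * 1000, sqrt(80 * 100), tolerance = 1e-9)
  expect_equal(s$gsd, 1.0)
  # two equal channels with midpoints 50 and 200 -> CMD 100 nm, GSD 2
  two <- mobility_scan(c(sqrt(50^2 / 1.2), sqrt(200^2 / 1.2)),
                       c(sqrt(50^2 * 1.2), sqrt(200^2 * 1.2)),
                       c(300, 300))
  s2 <- number_stats(two)
  expect_equal(s2$cmd * 1000, 100, tolerance = 1e-9)
  expect_equal(s2$gsd, 2.0, tolerance = 1e-9)
  zero <- mobility_scan(c(10, 20), c(20, 40), c(0, 0))
  expect_error(number_stats(zero), class = "aerodose_empty_scan")
})

test_that("binned lognormals are recovered within discretisation error", {
  truth <- lognormal_psd(0.132, 2.6, basis = "number", diameter_kind = "physical")
  sc <- simulate_mobility_scan(truth, evaporation_model(0),
                               channel_bounds = fmps_channel_bounds(64, 2, 3000),
                               total_conc = 1e6)
  s <- number_stats(sc)
  expect_equal(s$cmd, 0.132, tolerance = 0.03)
  expect_equal(s$gsd, 2.6, tolerance = 0.05)
  # tighter case: >= 32 log-spaced channels spanning +-3 lnGSD
  for (pars in list(c(0.1, 1.3), c(0.05, 1.6), c(0.2, 2.0))) {
    g <- pars[2]
    lo <- pars[1] * 1000 * exp(-3 * log(g)); hi <- pars[1] * 1000 * exp(3 * log(g))
    sc2 <- simulate_mobility_scan(
      lognormal_psd(pars[1], g, basis = "number", diameter_kind = "physical"),
      evaporation_model(0), channel_bounds = fmps_channel_bounds(40, lo, hi))
    s2 <- number_stats(sc2)
    expect_equal(s2$cmd, pars[1], tolerance = 0.02)
    expect_equal(s2$gsd, g, tolerance = 0.05)
  }
})

test_that("the CMD-to-MMAD chain reproduces the instrument inter-comparison values", {
  liq3070 <- eliquid(0.3, 0.7)
  liq7030 <- eliquid(0.7, 0.3)
  mk <- function(cmd_um, gsd) {
    simulate_mobility_scan(
      lognormal_psd(cmd_um, gsd, basis = "number", diameter_kind = "physical"),
      evaporation_model(0),
      channel_bounds = fmps_channel_bounds(256, cmd_um * 1000 * exp(-5 * log(max(gsd, 1.01))),
                                           cmd_um * 1000 * exp(5 * log(max(gsd, 1.01)))))
  }
  expect_equal(round(mobility_mmad(mk(0.132, 2.6), liq3070), 2), 2.23,
               tolerance = 0.02)
  expect_equal(round(mobility_mmad(mk(0.064, 1.004), liq7030), 3), 0.067,
               tolerance = 0.01)
  # GSD 1 scan at unit density: both conversions are identities
  one <- mobility_scan(89, 90, 100)
  liq_unit <- eliquid(0.5, 0.5, effective_density = 1)
  expect_equal(mobility_mmad(one, liq_unit), number_stats(one)$cmd,
               tolerance = 1e-6)
})

test_that("statistics compose with truncation and are scale invariant", {
  truth <- lognormal_psd(0.08, 1.7, basis = "number", diameter_kind = "physical")
  sc <- simulate_mobility_scan(truth, evaporation_model(0),
                               channel_bounds = smps_channel_bounds())
  tr <- truncate_channels(sc, 6, 560)
  keep <- sc$channels$midpoint >= 6 & sc$channels$midpoint <= 560
  manual <- mobility_scan(sc$channels$d_lo[keep], sc$channels$d_hi[keep],
                          sc$channels$concentration[keep])
  expect_equal(number_stats(tr), number_stats(manual))
  # uniform scaling of concentrations leaves the MMAD unchanged
  liq <- eliquid(0.3, 0.7)
  scaled <- mobility_scan(sc$channels$d_lo, sc$channels$d_hi,
                          sc$channels$concentration * 37)
  expect_equal(mobility_mmad(scaled, liq), mobility_mmad(sc, liq))
  # GSD >= 1 and CMD within the midpoint range, always
  s <- number_stats(sc)
  expect_gte(s$gsd, 1)
  expect_gte(s$cmd * 1000, min(sc$channels$midpoint))
  expect_lte(s$cmd * 1000, max(sc$channels$midpoint))
})
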