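test_that("simulated trials conserve mass and respond only to rounding", {
  psd <- lognormal_psd(0.93, 1.43)
  tr <- simulate_impactor_trial(psd, total_mass = 7, balance_resolution = 0,
                                seed = 2)
  collected <- sum(tr$stages$post_mass - tr$stages$pre_mass) +
    tr$backup_filter_mass
  expect_equal(collected, 7, tolerance = 1e-9)
  # the 0.32/0.56/1.0 um stages jointly hold > 89% of collected mass
  m <- tr$stages$post_mass - tr$stages$pre_mass
  core <- sum(m[tr$stages$d50 %in% c(0.32, 0.56, 1.0)])
  expect_gt(core / collected, 0.89)
})

test_that("simulation is deterministic given the seed", {
  psd <- lognormal_psd(0.93, 1.43)
  a <- simulate_impactor_trial(psd, 7, seed = 11)
  b <- simulate_impactor_trial(psd, 7, seed = 11)
  expect_identical(a, b)
  c <- simulate_impactor_trial(psd, 7, seed = 12)
  expect_false(identical(a$stages$pre_mass, c$stages$pre_mass))
  # rounding jitter only: net stage masses agree within one resolution step
  expect_true(all(abs((a$stages$post_mass - a$stages$pre_mass) -
                        (c$stages$post_mass - c$stages$pre_mass)) <= 0.1 + 1e-9))

  s1 <- simulate_study(study_design(seed = 9))
  s2 <- simulate_study(study_design(seed = 9))
  expect_identical(s1, s2)
})

test_that("evaporative shrink follows cube-root volume loss and composes", {
  expect_equal(shrink_factor(evaporation_model(0)), 1)
  expect_equal(shrink_factor(evaporation_model(0.999)), 0.1)
  # composability: f1 then f2 equals 1 - (1-f1)(1-f2)
  f1 <- 0.6; f2 <- 0.9
  expect_equal(shrink_factor(evaporation_model(f1)) *
                 shrink_factor(evaporation_model(f2)),
               shrink_factor(evaporation_model(1 - (1 - f1) * (1 - f2))))
  truth <- lognormal_psd(0.1, 1.6, basis = "number", diameter_kind = "physical")
  sc <- simulate_mobility_scan(truth, evaporation_model(0.999),
                               channel_bounds = fmps_channel_bounds(48, 1, 200))
  expect_equal(number_stats(sc)$cmd, 0.01, tolerance = 0.05)
})

test_that("identity shrink recovers the truth within discretisation error", {
  truth <- lognormal_psd(0.09, 1.5, basis = "number", diameter_kind = "physical")
  sc <- simulate_mobility_scan(truth, evaporation_model(0, 1))
  s <- number_stats(sc)
  expect_equal(s$cmd, 0.09, tolerance = 0.03)
  expect_equal(s$gsd, 1.5, tolerance = 0.03)
})

test_that("a high volatile fraction reproduces the mobility-sizer size collapse", {
  # shrink ~900 nm droplets to ~70 nm before sizing
  evap <- evaporation_model(0.99953)
  mmad_true <- 0.93
  liq <- eliquid(0.3, 0.7)
  cmd <- mmad_true / sqrt(liq$effective_density) * exp(-3 * log(1.43)^2)
  truth <- lognormal_psd(cmd, 1.43, basis = "number", diameter_kind = "physical")
  sc <- simulate_mobility_scan(truth, evap)
  expect_lt(mobility_mmad(sc, liq), 0.1)
})

test_that("the default study has the expected shape and a faithful ledger", {
  st <- simulate_study(study_design(seed = 5))
  expect_length(st$trials, 36)
  expect_length(st$scans, 108)
  expect_equal(nrow(st$truth), 36)
  expect_true(all(table(st$truth$formulation) == 6))
  # per-trial truths jitter around the formulation truths
  agg <- tapply(st$truth$true_mmad_um, st$truth$formulation, mean)
  fm <- reference_formulations()
  expect_equal(as.numeric(agg[fm$name]), fm$true_mmad, tolerance = 0.05)
})

test_that("fitted group means preserve the humectant-ratio ordering", {
  st <- simulate_study(study_design(seed = 21))
  fits <- lapply(st$trials, function(tr) {
    tryCatch(fit_probit_psd(tr), aerodose_degenerate_fit = function(e) NULL)
  })
  mmad <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$mmad,
                 numeric(1))
  means <- tapply(mmad, st$truth$formulation[match(names(fits), st$truth$id)],
                  mean, na.rm = TRUE)
  # within the additive-free pair, 70:30 PG:VG exceeds 30:70 PG:VG
  expect_gt(means[["70:30 PG:VG"]], means[["30:70 PG:VG"]])
  # humectant-only formulations exceed their nicotine counterparts
  expect_gt(means[["30:70 PG:VG"]], means[["30:70 PG:VG w/nicotine"]])
  expect_gt(means[["70:30 PG:VG"]], means[["70:30 PG:VG w/nicotine"]])
})

test_that("CSV round trips preserve trials and scans", {
  dir <- withr::local_tempdir()
  psd <- lognormal_psd(0.93, 1.43)
  tr <- simulate_impactor_trial(psd, 7, consumed_mass = 7.8, seed = 4,
                                id = "t1")
  p <- file.path(dir, "trial.csv")
  write_impactor_csv(tr, p, formulation = "30:70 PG:VG")
  back <- read_impactor_csv(p)
  expect_equal(back$stages, tr$stages)
  expect_equal(back$backup_filter_mass, tr$backup_filter_mass)
  expect_equal(attr(back, "formulation"), "30:70 PG:VG")
  expect_equal(consumed_per_puff(back), consumed_per_puff(tr))

  sc <- simulate_mobility_scan(
    lognormal_psd(0.08, 1.5, basis = "number", diameter_kind = "physical"),
    instrument = "smps")
  ps <- file.path(dir, "scan.csv")
  write_mobility_csv(sc, ps)
  back2 <- read_mobility_csv(ps)
  expect_equal(back2$channels, sc$channels)
  expect_equal(back2$instrument, "smps")
})
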