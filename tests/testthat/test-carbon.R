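test_that("carbon densities and CAR follow the unit conversions", {
  # one 1-cm increment: bulk 0.1 g/cm3, om fraction 1, dep time 100 yr/cm
  core <- core_table(0, 1, 0.1, 1)
  ens <- linear_ensemble(slope = 100, depth_max = 1)
  prof <- carbon_profile(core, ens)
  expect_equal(prof$om_density, 0.1)
  expect_equal(prof$c_density, 0.05)
  expect_equal(prof$car, 1e4 * 0.05 / 100, tolerance = 1e-9) # 5 g C m-2 yr-1
  expect_equal(prof$cumulative_stock, 10 * 0.05)
  # a non-default carbon fraction propagates
  prof2 <- carbon_profile(core, ens, site_config(carbon_fraction_peat = 0.4))
  expect_equal(prof2$c_density, 0.04)
})

test_that("CAR integrated against deposition time reproduces the stock", {
  curve <- synthetic_calcurve()
  sim <- generate_core(scenario_preset("cas50"), curve, seed = 23, noise_scale = 1)
  out <- run_peat_pipeline(sim, curve, n_iter = 400, seed = 6)
  prof <- out$profile
  thick <- prof$depth_bottom - prof$depth_top
  stock_from_car <- 10 * sum(prof$car * prof$dep_time * thick) / 1e4
  expect_equal(stock_from_car, total_stock(prof),
               tolerance = 1e-9 * total_stock(prof))
  expect_true(all(diff(prof$cumulative_stock) >= 0))
  expect_true(all(prof$car > 0, na.rm = TRUE))
})

test_that("merging adjacent increments leaves stock and LORCA unchanged", {
  bd <- seq(0.05, 0.24, length.out = 20)
  core <- core_table(0:19, 1:20, bd, rep(0.9, 20))
  ens <- linear_ensemble(slope = 50, depth_max = 20)
  prof <- carbon_profile(core, ens)
  # mass-weighted 2-cm re-binning of the same core
  bd2 <- (bd[seq(1, 19, 2)] + bd[seq(2, 20, 2)]) / 2
  core2 <- core_table(seq(0, 18, 2), seq(2, 20, 2), bd2,
                      rep(0.9, 10))
  prof2 <- carbon_profile(core2, ens)
  expect_equal(total_stock(prof2), total_stock(prof), tolerance = 1e-9)
  expect_equal(lorca(prof2, 933)$lorca, lorca(prof, 933)$lorca, tolerance = 1e-9)
})

test_that("LORCA worked examples and inverse identity", {
  l1 <- lorca(22.6, 1255, 57)
  expect_equal(round_half_away(l1$lorca), 18.0)
  expect_equal(round_half_away(l1$sigma), 0.8)
  l2 <- lorca(66.0, 7522, 69)
  expect_equal(round_half_away(l2$lorca), 8.8)
  expect_equal(lorca(0, 1000)$lorca, 0)
  # inverse identity: lorca * basal age reproduces the stock (g m-2)
  expect_equal(l1$lorca * 1255, 22.6 * 1000, tolerance = 1e-9)
  expect_error(lorca(10, -5), class = "validation_error")
})

test_that("RERCA reproduces the uniform-core hand computation", {
  # c density 0.0088 g/cm3, 1 cm/yr, coring 2017: 1950 horizon at 67 cm,
  # mass above = 0.5896 g/cm2 -> 88.0 g C m-2 yr-1
  core <- uniform_core(80, bulk_density = 0.0176, om_fraction = 1)
  ens <- linear_ensemble(slope = 1, depth_max = 80)
  prof <- carbon_profile(core, ens)
  expect_equal(prof$c_density[1], 0.0088)
  r <- rerca(prof, ens, 1950)
  expect_equal(r$depth, 67, tolerance = 1e-9)
  expect_equal(r$rerca, 88, tolerance = 1e-6)
  # boundary case: horizon one year before coring
  r1 <- rerca(prof, ens, 2016)
  expect_equal(r1$rerca, 1e4 * 0.0088 * 1 / 1, tolerance = 1e-6)
  expect_error(rerca(prof, ens, 2017), class = "validation_error")
})

test_that("post-fire stock integrates the section above the last layer", {
  core <- uniform_core(40, bulk_density = 0.046, om_fraction = 1,
                       charcoal = c(rep(0, 25), 8, rep(0, 14)))
  ens <- linear_ensemble(slope = 10, depth_max = 40)
  prof <- carbon_profile(core, ens)
  rec <- detect_layers(core)
  expect_equal(rec$last_fire_depth, 25)
  expect_equal(postfire_stock(prof, rec), 10 * 0.023 * 25, tolerance = 1e-9) # 5.75
  expect_lte(postfire_stock(prof, rec), total_stock(prof))
  # degenerate boundaries
  rec0 <- rec; rec0$last_fire_depth <- 0
  expect_equal(postfire_stock(prof, rec0), 0)
  recN <- detect_layers(uniform_core(40))
  expect_warning(ps <- postfire_stock(prof, recN), "total stock")
  expect_equal(ps, total_stock(prof))
})

test_that("post-fire stock ignores charcoal below the last fire horizon", {
  base <- c(rep(0, 25), 8, rep(0, 14))
  deep <- base; deep[35] <- 30 # extra deep layer must not matter
  core_a <- uniform_core(40, charcoal = base)
  core_b <- uniform_core(40, charcoal = deep)
  ens <- linear_ensemble(slope = 10, depth_max = 40)
  pa <- postfire_stock(carbon_profile(core_a, ens), detect_layers(core_a))
  pb <- postfire_stock(carbon_profile(core_b, ens), detect_layers(core_b))
  expect_equal(pa, pb, tolerance = 1e-12)
})

test_that("site summary bundles stocks and rates coherently", {
  curve <- synthetic_calcurve()
  sim <- generate_core(scenario_preset("cas0"), curve, seed = 29, noise_scale = 1)
  out <- run_peat_pipeline(sim, curve, n_iter = 400, seed = 4)
  s <- out$summary
  expect_equal(s$lorca, 1000 * s$total_stock / s$basal_age, tolerance = 1e-9)
  expect_lte(s$postfire_stock, s$total_stock)
  expect_gt(s$rerca_1950$rerca, s$rerca_1900$rerca) # less-decomposed surface
  expect_true(s$rerca_1950$lo <= s$rerca_1950$rerca &
                s$rerca_1950$rerca <= s$rerca_1950$hi)
})
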