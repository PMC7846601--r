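test_that("generation is deterministic for a fixed seed", {
  curve <- synthetic_calcurve()
  sc <- scenario_preset("cas0")
  a <- generate_core(sc, curve, seed = 7, noise_scale = 1)
  b <- generate_core(sc, curve, seed = 7, noise_scale = 1)
  expect_identical(a$core, b$core)
  expect_identical(a$dates, b$dates)
  expect_identical(a$activity, b$activity)
  c <- generate_core(sc, curve, seed = 8, noise_scale = 1)
  expect_false(identical(a$activity, c$activity))
  ta <- generate_trees(sc$cohort, seed = 7)
  tb <- generate_trees(sc$cohort, seed = 7)
  expect_identical(ta$rings, tb$rings)
  expect_identical(ta$census, tb$census)
})

test_that("scenario presets match their design conditions", {
  lengths <- c(cas0 = 38, cas50 = 69, cas100 = 95)
  basal <- c(cas0 = 1255, cas50 = 7667, cas100 = 7522)
  curve <- synthetic_calcurve()
  for (nm in names(lengths)) {
    sc <- scenario_preset(nm)
    sim <- generate_core(sc, curve, seed = 1, noise_scale = 0)
    expect_equal(nrow(sim$core), unname(lengths[nm]))
    expect_equal(sim$truth$basal_age, unname(basal[nm]), tolerance = 1e-4)
    expect_equal(sim$truth$surface_age, -67)
    # last fire in the 175-177 cal yr BP window of the study design
    last_fire <- min(sim$truth$fire_events$depth_top)
    age <- sim$truth$fire_events$true_age[sim$truth$fire_events$depth_top == last_fire]
    expect_gte(age, 175); expect_lte(age, 177)
  }
  expect_error(scenario_preset("nope"), class = "generation_error")
})

test_that("a noise-free site is recovered exactly end to end", {
  curve <- synthetic_calcurve()
  for (nm in c("cas0", "cas50", "cas100")) {
    sim <- generate_core(scenario_preset(nm), curve, seed = 3, noise_scale = 0)
    out <- run_peat_pipeline(sim, curve, n_iter = 200, seed = 5,
                             use_true_supported = TRUE)
    s <- out$summary
    expect_equal(s$lorca, sim$truth$lorca, tolerance = 1e-6 * sim$truth$lorca)
    expect_equal(s$total_stock, sim$truth$total_stock, tolerance = 1e-9)
    expect_equal(s$postfire_stock, sim$truth$postfire_stock, tolerance = 1e-9)
    expect_equal(out$fires$last_fire_depth, min(sim$truth$fire_events$depth_top))
    expect_equal(s$basal_age, sim$truth$basal_age, tolerance = 1e-6)
  }
})

test_that("study-like noise still recovers LORCA within 5%", {
  curve <- synthetic_calcurve()
  sim <- generate_core(scenario_preset("cas50"), curve, seed = 19, noise_scale = 1)
  out <- run_peat_pipeline(sim, curve, n_iter = 600, seed = 11)
  s <- out$summary
  expect_lt(abs(s$lorca - sim$truth$lorca) / sim$truth$lorca, 0.05)
  expect_equal(s$postfire_stock, sim$truth$postfire_stock, tolerance = 0.02)
})

test_that("synthetic cohorts honour their growth design", {
  # single tree, (near-)linear growth of 1 mm radial ring per year
  lin <- tree_cohort(n_trees = 1, establishment_year = 1839, last_year = 2018,
                     dbh_target = 36, dbh_sd_frac = 0, growth_k = 1e-9,
                     width_cv = 0)
  gen <- generate_trees(lin, seed = 1, noise_scale = 0)
  w <- gen$rings$T01A$widths
  expect_length(w, 180)
  expect_equal(w, rep(1, 180), tolerance = 1e-6)
  expect_equal(gen$census$trees$dbh, 36, tolerance = 1e-6)

  # 20-tree cohort hits its mean-DBH target within 2 standard errors
  gen20 <- generate_trees(tree_cohort(n_trees = 20, dbh_target = 10),
                          seed = 42, noise_scale = 1)
  dbhs <- gen20$census$trees$dbh
  se <- sd(dbhs) / sqrt(20)
  expect_lt(abs(mean(dbhs) - 10), 2 * se)

  # noise-free cohort: stand stocks equal the closed form exactly
  allo <- test_allometry()
  gen0 <- generate_trees(tree_cohort(n_trees = 5, dbh_target = 8,
                                     dbh_sd_frac = 0, width_cv = 0),
                         seed = 2, noise_scale = 0)
  st <- stand_stocks(gen0$census, allo)
  d <- gen0$census$trees$dbh
  expect_equal(st$agb_per_m2, sum(0.1 * d^2.4) / 100, tolerance = 1e-12)
})

test_that("generated rings survive a Tucson round trip", {
  gen <- generate_trees(tree_cohort(n_trees = 4), seed = 23, noise_scale = 1)
  p <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(gen$rings, p)
  back <- read_rwl(p)
  expect_equal(names(back), names(gen$rings))
  for (id in names(back))
    expect_equal(back[[id]]$widths, gen$rings[[id]]$widths, tolerance = 1e-9)
})

test_that("scenario validation rejects impossible designs", {
  expect_error(core_scenario("x", data.frame(thickness = 10, dep_time = -1,
                                             om_density = 0.1)),
               class = "generation_error")
  expect_error(core_scenario("x", data.frame(thickness = 10.5, dep_time = 2,
                                             om_density = 0.1)),
               class = "generation_error")
  expect_error(core_scenario("x", data.frame(thickness = 10, dep_time = 2,
                                             om_density = 0.1),
                             c14_depths = 50, c14_sigmas = 40),
               class = "generation_error")
})
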