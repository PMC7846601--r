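test_that("core CSV parsing validates structure and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("depth_top,depth_bottom,bulk_density,om_fraction,charcoal_count",
               "0,1,0.05,0.95,0"), path)
  core <- read_core_csv(path)
  expect_s3_class(core, "core_table")
  expect_equal(nrow(core), 1)
  expect_equal(core$bulk_density, 0.05)

  # a gap between increments is a validation error
  writeLines(c("depth_top,depth_bottom,bulk_density,om_fraction,charcoal_count",
               "0,1,0.05,0.95,0", "2,3,0.05,0.95,0"), path)
  expect_error(read_core_csv(path), class = "validation_error")

  # malformed cell names the line
  writeLines(c("depth_top,depth_bottom,bulk_density,om_fraction,charcoal_count",
               "0,1,0.05,0.95,0", "1,2,oops,0.95,0"), path)
  expect_error(read_core_csv(path), "line 3", class = "parse_error")

  # om_density may replace om_fraction, but not coexist with it
  writeLines(c("depth_top,depth_bottom,bulk_density,om_density",
               "0,1,0.10,0.05"), path)
  expect_equal(read_core_csv(path)$om_fraction, 0.5)
  writeLines(c("depth_top,depth_bottom,bulk_density,om_fraction,om_density",
               "0,1,0.10,0.5,0.05"), path)
  expect_error(read_core_csv(path), class = "parse_error")

  # a 95-increment contiguous core reads whole and round-trips exactly
  core95 <- uniform_core(95)
  write_core_csv(core95, path)
  back <- read_core_csv(path, site_id = "uniform")
  expect_equal(nrow(back), 95)
  expect_equal(as.data.frame(back), as.data.frame(core95), tolerance = 1e-9)
  # increment thicknesses sum to the covered span
  expect_equal(sum(back$depth_bottom - back$depth_top),
               back$depth_bottom[95] - back$depth_top[1])
})

test_that("date, activity and census CSVs round-trip", {
  dates <- date_table(c(0, 24, 38), c("surface", "c14", "c14"),
                      c(-67, 210, 1290), c(0, 45, 57),
                      label = c("surface", "fire", "basal"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_date_csv(dates, p)
  expect_equal(as.data.frame(read_date_csv(p)), as.data.frame(dates))
  expect_error(date_table(c(0, 0), c("surface", "surface"), c(-67, -67), c(0, 0)),
               class = "validation_error")
  expect_error(date_table(5, "c14", 500, 0), class = "validation_error")

  act <- activity_table(0:4, 1:5, c(310, 150, 70, 30, 16), rep(5, 5))
  write_activity_csv(act, p)
  expect_equal(as.data.frame(read_activity_csv(p)), as.data.frame(act))

  cen <- plot_census("site_x", 100, sprintf("T%02d", 1:5), c(10, 8, 12, 5, 1))
  write_census_csv(cen, p)
  back <- read_census_csv(p, site_id = "site_x", plot_area = 100)
  expect_equal(back$trees, cen$trees)
})

test_that("calibration curve files parse, sort and round-trip", {
  p <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# synthetic identity curve", "0,0,1", "10,10,1", "20,20,1"), p)
  cv <- read_calcurve(p)
  expect_s3_class(cv, "cal_curve")
  expect_equal(nrow(cv), 3)

  # row count equals non-comment line count
  n_body <- 37
  writeLines(c("## header", "# more comments",
               sprintf("%d %d 8", seq(0, by = 5, length.out = n_body),
                       seq(100, by = 5, length.out = n_body))), p)
  expect_equal(nrow(read_calcurve(p)), n_body)

  # reversed order is accepted, canonically sorted, and logged
  peatcarbon_log(clear = TRUE)
  writeLines(c("20,120,1", "10,110,1", "0,100,1"), p)
  cv <- read_calcurve(p)
  expect_equal(cv$cal_age, c(0, 10, 20))
  expect_match(paste(peatcarbon_log(), collapse = "\n"), "sorted")

  # duplicated cal age -> not strictly monotone
  writeLines(c("0,100,1", "0,101,1", "10,110,1"), p)
  expect_error(read_calcurve(p), class = "validation_error")

  cv <- synthetic_calcurve(0, 500, step = 5, sigma = 3)
  write_calcurve(cv, p)
  expect_equal(as.data.frame(read_calcurve(p)), as.data.frame(cv),
               tolerance = 1e-9)
})

test_that("curve_at interpolates linearly and enforces coverage", {
  cv <- cal_curve(c(0, 100), c(50, 250), c(2, 6))
  at <- curve_at(cv, 50)
  expect_equal(at$c14_age, 150)
  expect_equal(at$curve_sigma, 4)
  expect_error(curve_at(cv, 200), class = "coverage_error")
})

test_that("Tucson .rwl files parse, truncate at terminators and round-trip", {
  p <- withr::local_tempfile(fileext = ".rwl")
  # one series of ten 1.00 mm rings starting 1839, decade-aligned lines
  writeLines(c(paste0(sprintf("%-8s%4d", "T01A", 1839), sprintf("%6d", 100)),
               paste(c(sprintf("%-8s%4d", "T01A", 1840),
                       sprintf("%6d", c(rep(100, 9), 999))), collapse = "")), p)
  rs <- read_rwl(p)
  expect_equal(length(rs), 1)
  expect_equal(rs$T01A$first_year, 1839)
  expect_equal(length(rs$T01A$widths), 10)
  expect_equal(rs$T01A$widths, rep(1, 10))

  # empty file -> empty set
  writeLines(character(0), p)
  expect_equal(length(read_rwl(p)), 0)

  # terminator mid-decade: length equals the token count before it
  vals <- c(120, 80, 95, 101, 87, 140, 66)
  writeLines(c(paste(c(sprintf("%-8s%4d", "X1", 1990),
                       sprintf("%6d", vals[1:7]), sprintf("%6d", -9999)),
                     collapse = "")), p)
  rs <- read_rwl(p)
  expect_equal(length(rs$X1$widths), length(vals))
  expect_equal(rs$X1$widths, vals / 100)

  # misaligned continuation year is a parse error
  writeLines(c(paste(c(sprintf("%-8s%4d", "X1", 1990), sprintf("%6d", vals[1:7])),
                     collapse = ""),
               paste(c(sprintf("%-8s%4d", "X1", 1999),
                       sprintf("%6d", c(100, 999))), collapse = "")), p)
  expect_error(read_rwl(p), class = "parse_error")

  # write/read round trip over several series and decade boundaries
  set.seed(11)
  orig <- ring_series_set(list(
    A01A = list(first_year = 1843, widths = round(runif(60, 0.2, 3), 2),
                radius_count = 1L),
    A01B = list(first_year = 1843, widths = round(runif(60, 0.2, 3), 2),
                radius_count = 1L),
    B07A = list(first_year = 1901, widths = round(runif(25, 0.2, 3), 2),
                radius_count = 1L)))
  write_rwl(orig, p)
  back <- read_rwl(p)
  expect_equal(names(back), names(orig))
  for (id in names(orig)) {
    expect_equal(back[[id]]$first_year, orig[[id]]$first_year)
    expect_equal(back[[id]]$widths, orig[[id]]$widths, tolerance = 1e-9)
  }

  # radius averaging by shared id prefix
  comb <- combine_radii(back)
  expect_equal(names(comb), c("A01", "B07"))
  expect_equal(comb$A01$widths, (orig$A01A$widths + orig$A01B$widths) / 2)
  expect_equal(comb$A01$radius_count, 2L)
})

test_that("site configuration reads from YAML and validates", {
  cfg <- site_config()
  expect_equal(cfg$coring_year, 2017)
  expect_equal(cfg$lambda_pb210, log(2) / 22.3)
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("coring_year: 2019", "carbon_fraction_peat: 0.48",
               "mc_iterations: 500", "rng_seed: 99"), p)
  cfg <- read_site_config(p)
  expect_equal(cfg$coring_year, 2019)
  expect_equal(cfg$carbon_fraction_peat, 0.48)
  expect_equal(cfg$charcoal_threshold, 1) # untouched default
  writeLines("not_a_key: 1", p)
  expect_error(read_site_config(p), class = "parse_error")
  # write/read round trip: scalar settings and AGB coefficients survive
  orig <- site_config(coring_year = 2018, carbon_fraction_peat = 0.47,
                      rng_seed = 5L)
  write_site_config(orig, p)
  back <- read_site_config(p)
  for (key in c("coring_year", "lambda_pb210", "charcoal_threshold",
                "charcoal_min_gap", "carbon_fraction_peat",
                "carbon_fraction_wood", "mc_iterations", "rng_seed"))
    expect_equal(back[[key]], orig[[key]], tolerance = 1e-9)
  expect_equal(back$allometry$agb_components$beta1,
               orig$allometry$agb_components$beta1)
  expect_error(site_config(coring_year = 1800), class = "validation_error")
  expect_error(site_config(carbon_fraction_peat = 1.2), class = "validation_error")
})
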