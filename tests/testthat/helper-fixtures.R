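# Shared fixtures, built in code at test time.

# Identity calibration curve: c14 age == cal age, constant sigma.
identity_curve <- function(cal_min = -200, cal_max = 3000, step = 1, sigma = 1) {
  grid <- seq(cal_min, cal_max, by = step)
  cal_curve(grid, grid, rep(sigma, length(grid)))
}

# Uniform core: n 1-cm increments of constant density/fraction.
uniform_core <- function(n, bulk_density = 0.1, om_fraction = 0.9,
                         charcoal = 0, site_id = "uniform") {
  core_table(0:(n - 1), 1:n, rep(bulk_density, n), rep(om_fraction, n),
             charcoal_count = rep_len(charcoal, n), site_id = site_id)
}

# Deterministic linear chronology from exact endpoint dates:
# age(d) = surface + slope * d.
linear_ensemble <- function(slope, depth_max, surface = -67, n_iter = 200,
                            seed = 1) {
  basal <- gaussian_date_exact(surface + slope * depth_max, depth_max)
  build_ensemble(list(basal), crs = NULL, surface_age = surface,
                 n_iter = n_iter, seed = seed,
                 depths = seq(0, depth_max, by = 1))
}

# An exact (sigma = 0) calendar date at a depth, in calibrated_date form.
gaussian_date_exact <- function(age, depth) {
  structure(list(depth = depth, grid = age, posterior = 1, median = age,
                 sigma_equiv = 0, interval_95 = c(age, age)),
            class = "calibrated_date")
}

# Single-component allometry used wherever tests need known coefficients.
test_allometry <- function(beta1 = 0.1, beta2 = 2.4, ratio = 0.25) {
  allometry_set(
    agb_components = data.frame(name = "total", beta1 = beta1, beta2 = beta2),
    bgb_equations = list(
      lo = function(dbh, agb) 0.20 * sum(agb),
      mid = function(dbh, agb) ratio * sum(agb),
      hi = function(dbh, agb) 0.30 * sum(agb)),
    provenance = "test coefficients")
}
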