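#' Define a synthetic core scenario
#'
#' A scenario describes one synthetic peat core as observables, not process:
#' depth segments (surface downward) with a fixed deposition time
#' (yr cm^-1) and organic-matter density (g cm^-3), charcoal-spike fire
#' layers, depths selected for radiocarbon dating, and the constant-flux
#' 210Pb regime. Compaction history is not modelled — the segments specify
#' the final, post-compaction profile directly, because that is all any
#' pipeline stage consumes.
#'
#' @param site_id Scenario label.
#' @param segments Data frame with columns `thickness` (whole cm; the core
#'   is built in 1 cm increments), `dep_time` (yr cm^-1) and `om_density`
#'   (g cm^-3), ordered
#'   from the surface down.
#' @param fires Data frame `top`, `bottom`, `count`: charcoal layers
#'   (fragments cm^-3 deposited over `[top, bottom)`).
#' @param c14_depths,c14_sigmas Depths (cm) submitted for 14C dating and
#'   their quoted lab sigmas (yr).
#' @param pb210_depth Depth (cm) to which 210Pb activity is measured.
#' @param pb210_flux Constant unsupported 210Pb supply, Bq m^-2 yr^-1.
#' @param supported Supported 210Pb, Bq kg^-1.
#' @param pb210_cv Coefficient of variation of activity measurements.
#' @param om_fraction Organic-matter fraction (bulk density is
#'   `om_density / om_fraction`).
#' @param coring_year Coring year, CE.
#' @param cohort Optional tree-cohort parameter list (see [tree_cohort()]).
#' @return A `core_scenario` list.
#' @export
core_scenario <- function(site_id, segments, fires = NULL,
                          c14_depths = numeric(0), c14_sigmas = numeric(0),
                          pb210_depth = 26, pb210_flux = 160, supported = 15,
                          pb210_cv = 0.05, om_fraction = 0.95,
                          coring_year = 2017, cohort = NULL) {
  if (any(segments$dep_time <= 0) || any(segments$om_density <= 0))
    stop_pc("segments need positive dep_time and om_density",
            class = "generation_error")
  if (any(segments$thickness %% 1 != 0))
    stop_pc("segment thicknesses must be whole centimetres",
            class = "generation_error")
  depth_total <- sum(segments$thickness)
  if (length(c14_depths) != length(c14_sigmas))
    stop_pc("c14_depths and c14_sigmas differ in length", class = "generation_error")
  if (any(c14_depths > depth_total) || pb210_depth > depth_total)
    stop_pc("dated depths exceed the core length", class = "generation_error")
  structure(list(site_id = site_id, segments = segments,
                 fires = fires, c14_depths = c14_depths,
                 c14_sigmas = c14_sigmas, pb210_depth = pb210_depth,
                 pb210_flux = pb210_flux, supported = supported,
                 pb210_cv = pb210_cv, om_fraction = om_fraction,
                 coring_year = coring_year, cohort = cohort),
            class = "core_scenario")
}

#' Tree-cohort parameters for the synthetic stand
#'
#' An even-aged post-fire cohort: every tree establishes in the same year
#' and follows a logistic diameter-growth curve
#' `D(t) = D_final * (g(t) - g(0)) / (g(n) - g(0))` with
#' `g(t) = 1 / (1 + exp(-k (t - t0)))`; per-tree final diameters are
#' lognormal around the target mean. Ring widths carry multiplicative
#' Gaussian noise and are quantized to 0.01 mm (the Tucson file resolution).
#'
#' @param n_trees Number of trees (two measured radii each).
#' @param establishment_year First ring year, CE.
#' @param last_year Final ring year, CE.
#' @param dbh_target Target mean final DBH, cm.
#' @param dbh_sd_frac Lognormal sigma of per-tree final DBH (fraction).
#' @param growth_k Logistic rate, yr^-1.
#' @param growth_t0 Logistic midpoint, years after establishment.
#' @param width_cv Ring-width noise CV.
#' @param plot_area Census plot area, m^2.
#' @return A `tree_cohort` list.
#' @export
tree_cohort <- function(n_trees = 20, establishment_year = 1839,
                        last_year = 2018, dbh_target = 10,
                        dbh_sd_frac = 0.2, growth_k = 0.05, growth_t0 = 60,
                        width_cv = 0.1, plot_area = 100) {
  structure(list(n_trees = n_trees, establishment_year = establishment_year,
                 last_year = last_year, dbh_target = dbh_target,
                 dbh_sd_frac = dbh_sd_frac, growth_k = growth_k,
                 growth_t0 = growth_t0, width_cv = width_cv,
                 plot_area = plot_area),
            class = "tree_cohort")
}

#' Load a shipped scenario preset
#'
#' Presets `cas0`, `cas50` and `cas100` emulate a paludification gradient:
#' organic layers of 38, 69 and 95 cm with basal ages near 1255, 7667 and
#' 7522 cal yr BP, a last fire around 175-177 cal yr BP capping a
#' fast-accumulating Sphagnum acrotelm, dense slowly-accumulating woody
#' peat below, and even-aged 20-tree spruce cohorts established around
#' 1839 CE with mean DBH targets of 10.0, 9.1 and 5.6 cm.
#'
#' @param name One of `"cas0"`, `"cas50"`, `"cas100"`.
#' @return A [core_scenario()].
#' @export
scenario_preset <- function(name) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "peatcarbon")
  if (!nzchar(path))
    stop_pc("unknown scenario preset '%s'", name, class = "generation_error")
  raw <- yaml::read_yaml(path)
  core_scenario(
    site_id = raw$site_id,
    segments = do.call(rbind, lapply(raw$segments, as.data.frame)),
    fires = do.call(rbind, lapply(raw$fires, as.data.frame)),
    c14_depths = unlist(raw$c14_depths),
    c14_sigmas = unlist(raw$c14_sigmas),
    pb210_depth = raw$pb210_depth, pb210_flux = raw$pb210_flux,
    supported = raw$supported, pb210_cv = raw$pb210_cv,
    om_fraction = raw$om_fraction, coring_year = raw$coring_year,
    cohort = do.call(tree_cohort, raw$cohort))
}

# True age (cal yr BP) at every 1-cm boundary of a scenario.
scenario_truth_ages <- function(scenario) {
  dep_per_cm <- rep(scenario$segments$dep_time, scenario$segments$thickness)
  surface_age <- ce_to_bp(scenario$coring_year)
  c(surface_age, surface_age + cumsum(dep_per_cm))
}

#' Forward-generate a synthetic core with known truth
#'
#' Deposits peat according to the scenario's segments, spikes charcoal at
#' the fire layers, maps true calendar ages through the supplied
#' calibration curve to produce 14C lab ages (perturbed by
#' `noise_scale * sigma`), and lays down 210Pb from a constant flux decayed
#' by true age on top of the supported level (multiplicative Gaussian noise,
#' `noise_scale * pb210_cv`). The remaining unsupported inventory below the
#' deepest measured increment is assigned to that increment, so at
#' `noise_scale = 0` the constant-rate-of-supply inversion of the profile
#' is exact by construction.
#'
#' At `noise_scale = 0` the 14C horizons are emitted as exact known-age
#' (`event`) entries — the degenerate limit in which the whole pipeline
#' must reproduce the truth to numerical precision.
#'
#' @param scenario A [core_scenario()].
#' @param curve A [cal_curve()] spanning the scenario's age range.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param noise_scale Multiplier on all noise terms (0 = noise-free, 1 =
#'   study-like noise).
#' @return List with `core` ([core_table()]), `dates` ([date_table()]),
#'   `activity` ([activity_table()]) and `truth` (a `site_truth` list:
#'   boundary ages, fire events, flux, supported, true stocks and rates).
#' @export
generate_core <- function(scenario, curve, seed = 1L, noise_scale = 1) {
  set.seed(seed)
  seg <- scenario$segments
  n_cm <- sum(seg$thickness)
  om <- rep(seg$om_density, seg$thickness)
  dep <- rep(seg$dep_time, seg$thickness)
  rho <- om / scenario$om_fraction
  charcoal <- numeric(n_cm)
  if (!is.null(scenario$fires)) {
    for (i in seq_len(nrow(scenario$fires))) {
      idx <- (scenario$fires$top[i] + 1):(scenario$fires$bottom[i])
      charcoal[idx] <- scenario$fires$count[i]
    }
  }
  core <- core_table(0:(n_cm - 1), 1:n_cm, rho, scenario$om_fraction,
                     charcoal, site_id = scenario$site_id)
  bnd_age <- scenario_truth_ages(scenario)
  if (any(diff(bnd_age) <= 0))
    stop_pc("scenario produces a non-monotone age-depth history",
            class = "generation_error")
  surface_age <- bnd_age[1]
  age_at <- function(z) stats::approx(0:n_cm, bnd_age, xout = z)$y

  # 14C (or exact event) dates + surface
  kinds <- "surface"; depths <- 0; vals <- surface_age; sigmas <- 0
  labels <- "surface"
  for (i in seq_along(scenario$c14_depths)) {
    d <- scenario$c14_depths[i]
    true_age <- age_at(d)
    if (noise_scale == 0) {
      kinds <- c(kinds, "event"); vals <- c(vals, true_age); sigmas <- c(sigmas, 0)
    } else {
      mu <- curve_at(curve, true_age)$c14_age
      lab <- mu + noise_scale * stats::rnorm(1, 0, scenario$c14_sigmas[i])
      kinds <- c(kinds, "c14"); vals <- c(vals, lab)
      sigmas <- c(sigmas, scenario$c14_sigmas[i])
    }
    depths <- c(depths, d)
    labels <- c(labels, sprintf("synthetic_%gcm", d))
  }
  dates <- date_table(depths, kinds, vals, sigmas, labels)

  # 210Pb: constant flux decayed by true age before coring
  lambda <- log(2) / 22.3
  np <- scenario$pb210_depth
  t_before <- bnd_age[1:(np + 1)] - surface_age
  A <- (scenario$pb210_flux / lambda) * exp(-lambda * t_before)
  inv <- -diff(A)
  inv[np] <- A[np] # deepest measured increment absorbs the tail inventory
  a_unsup <- inv / (10 * rho[1:np] * 1)
  total_true <- a_unsup + scenario$supported
  sigma_act <- noise_scale * scenario$pb210_cv * total_true
  total_obs <- pmax(total_true + sigma_act * stats::rnorm(np), 0)
  activity <- activity_table(0:(np - 1), 1:np, total_obs, sigma_act)

  thick <- rep(1, n_cm)
  c_dens <- 0.5 * om
  fire_events <- NULL
  if (!is.null(scenario$fires))
    fire_events <- data.frame(depth_top = scenario$fires$top,
                              true_age = age_at(scenario$fires$top))
  last_fire_depth <- if (!is.null(fire_events)) min(fire_events$depth_top) else NA
  truth <- structure(list(
    boundary_depths = 0:n_cm, boundary_ages = bnd_age,
    surface_age = surface_age, basal_age = bnd_age[n_cm + 1],
    deposition_time = dep, om_density = om,
    fire_events = fire_events,
    pb210_flux = scenario$pb210_flux, supported = scenario$supported,
    true_c_deposited = c_dens * thick,
    total_stock = 10 * sum(c_dens * thick),
    postfire_stock = if (!is.na(last_fire_depth)) 10 * sum(c_dens[seq_len(last_fire_depth)]) else NA,
    lorca = 1000 * 10 * sum(c_dens * thick) / bnd_age[n_cm + 1],
    rng_seed = seed, noise_scale = noise_scale), class = "site_truth")
  list(core = core, dates = dates, activity = activity, truth = truth)
}

#' Forward-generate a synthetic even-aged tree cohort
#'
#' Produces two noisy measured radii per tree (Tucson-writable, quantized
#' to 0.01 mm) and a plot census whose DBHs equal the final synthetic
#' diameters (as reconstructed from the quantized mean-of-radii widths, so
#' census and rings are mutually consistent).
#'
#' @param cohort A [tree_cohort()].
#' @param seed RNG seed.
#' @param noise_scale Multiplier on ring-width noise (0 = deterministic).
#' @return List with `rings` (a [ring_series_set()], ids `T01A`, `T01B`,
#'   ...), `census` (a [plot_census()]) and `truth` (target diameters and
#'   growth parameters).
#' @export
generate_trees <- function(cohort, seed = 1L, noise_scale = 1) {
  set.seed(seed)
  n_yr <- cohort$last_year - cohort$establishment_year + 1L
  g <- function(t) 1 / (1 + exp(-cohort$growth_k * (t - cohort$growth_t0)))
  frac <- (g(0:n_yr) - g(0)) / (g(n_yr) - g(0))
  sdl <- cohort$dbh_sd_frac
  d_final <- cohort$dbh_target * exp(stats::rnorm(cohort$n_trees, 0, sdl) - sdl^2 / 2)
  series <- list()
  census_dbh <- numeric(cohort$n_trees)
  ids <- sprintf("T%02d", seq_len(cohort$n_trees))
  for (i in seq_len(cohort$n_trees)) {
    base_w <- 5 * d_final[i] * diff(frac) # mm radial increments
    radii <- lapply(1:2, function(r) {
      w <- base_w * (1 + noise_scale * cohort$width_cv * stats::rnorm(n_yr))
      round(pmax(w, 0) * 100) / 100
    })
    for (r in 1:2)
      series[[paste0(ids[i], c("A", "B")[r])]] <-
        list(first_year = cohort$establishment_year, widths = radii[[r]],
             radius_count = 1L)
    census_dbh[i] <- 2 * sum((radii[[1]] + radii[[2]]) / 2) / 10
  }
  census <- plot_census(site_id = "synthetic_stand", plot_area = cohort$plot_area,
                        tree_id = ids, dbh = census_dbh)
  truth <- list(establishment_year = cohort$establishment_year,
                d_final_target = stats::setNames(d_final, ids),
                census_dbh = stats::setNames(census_dbh, ids),
                cohort = cohort, rng_seed = seed, noise_scale = noise_scale)
  list(rings = ring_series_set(series), census = census, truth = truth)
}

#' Synthetic identity calibration curve
#'
#' A curve with `c14_age == cal_age` and constant sigma: useful for tests
#' (calibration reduces to a Gaussian) and as the mapping behind synthetic
#' lab ages.
#'
#' @param cal_min,cal_max Calendar range, cal yr BP.
#' @param step Grid step, yr.
#' @param sigma Constant curve sigma, yr.
#' @return A [cal_curve()].
#' @export
synthetic_calcurve <- function(cal_min = -100, cal_max = 9000, step = 5,
                               sigma = 5) {
  grid <- seq(cal_min, cal_max, by = step)
  cal_curve(grid, grid, rep(sigma, length(grid)))
}

#' Run the full peat pipeline on one generated site
#'
#' Convenience wrapper chaining calibration, supported-210Pb estimation,
#' CRS dating, ensemble age-depth modelling, charcoal detection, and carbon
#' accounting — the same calls a user makes one by one.
#'
#' @param sim Output of [generate_core()].
#' @param curve The [cal_curve()] used for generation.
#' @param cfg A [site_config()].
#' @param n_iter Ensemble iterations.
#' @param seed Ensemble seed.
#' @param crs_max_age Oldest CRS age (yr before coring) admitted into the
#'   age-depth model; CRS loses reliability beyond ~5 half-lives.
#' @param use_true_supported Use the generator's true supported activity
#'   instead of the deep-tail estimate (for exactness checks).
#' @return List with `cal_dates`, `crs`, `ens`, `fires`, `profile`,
#'   `summary`.
#' @export
run_peat_pipeline <- function(sim, curve, cfg = site_config(), n_iter = 1000,
                              seed = 1L, crs_max_age = 150,
                              use_true_supported = FALSE) {
  cal_dates <- summarize_dates(sim$dates, curve)
  supported <- if (use_true_supported) sim$truth$supported else
    estimate_supported(sim$activity, tail_n = 3)$supported
  crs <- crs_ages(sim$activity, sim$core, supported, lambda = cfg$lambda_pb210)
  crs$horizons <- crs$horizons[crs$horizons$age <= crs_max_age, ]
  surface_age <- ce_to_bp(cfg$coring_year)
  ens <- build_ensemble(cal_dates, crs, surface_age = surface_age,
                        n_iter = n_iter, seed = seed,
                        depths = seq(0, max(sim$core$depth_bottom), by = 1))
  fires <- detect_layers(sim$core, cfg$charcoal_threshold, cfg$charcoal_min_gap)
  fires <- date_last_fire(fires, ens)
  profile <- carbon_profile(sim$core, ens, cfg)
  summary <- site_summary(profile, ens, fires, cfg)
  list(cal_dates = cal_dates, crs = crs, ens = ens, fires = fires,
       profile = profile, summary = summary)
}
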