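#' Convert core measurements to a carbon-density and CAR profile
#'
#' Per increment: organic-matter density `om_density = bulk_density *
#' om_fraction` (g cm^-3), carbon density `c_density =
#' carbon_fraction_peat * om_density` (g C cm^-3, default fraction 0.5),
#' apparent carbon accumulation rate
#' `CAR = 1e4 * c_density / deposition_time` (g C m^-2 yr^-1), and the
#' cumulative carbon stock from the surface, `10 * cumsum(c_density *
#' thickness)` (kg C m^-2). CAR quantiles follow from the ensemble's
#' deposition-time quantiles (an increasing deposition time decreases CAR).
#'
#' @param core A [core_table()].
#' @param ens A `chronology_ensemble` covering the core depths.
#' @param cfg A [site_config()] (supplies `carbon_fraction_peat`).
#' @return A `carbon_profile` data frame, one row per increment, with
#'   attributes `site_id` and `carbon_fraction`.
#' @export
carbon_profile <- function(core, ens, cfg = site_config()) {
  if (max(core$depth_bottom) > max(ens$depths) + 1e-9)
    stop_pc("chronology does not cover the core (%g > %g cm)",
            max(core$depth_bottom), max(ens$depths), class = "coverage_error")
  thick <- core$depth_bottom - core$depth_top
  om <- core$bulk_density * core$om_fraction
  cdens <- cfg$carbon_fraction_peat * om
  # per-iteration increment slopes (yr/cm) at the core's own boundaries
  a_top <- apply(ens$realizations, 1, function(a)
    stats::approx(ens$depths, a, xout = core$depth_top)$y)
  a_bot <- apply(ens$realizations, 1, function(a)
    stats::approx(ens$depths, a, xout = core$depth_bottom)$y)
  if (is.null(dim(a_top))) { # single-increment core
    a_top <- matrix(a_top, nrow = 1)
    a_bot <- matrix(a_bot, nrow = 1)
  }
  slopes <- (a_bot - a_top) / thick
  dq <- apply(slopes, 1, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  dep_med <- dq[2, ]
  undated <- dep_med <= 0
  if (any(undated))
    pc_log("carbon_profile: %d increment(s) with non-positive deposition time, CAR undefined",
           sum(undated))
  car <- ifelse(undated, NA_real_, 1e4 * cdens / dep_med)
  df <- data.frame(depth_top = core$depth_top, depth_bottom = core$depth_bottom,
                   om_density = om, c_density = cdens,
                   dep_time = dep_med, dep_lo = dq[1, ], dep_hi = dq[3, ],
                   car = car,
                   car_lo = ifelse(dq[3, ] > 0, 1e4 * cdens / dq[3, ], NA_real_),
                   car_hi = ifelse(dq[1, ] > 0, 1e4 * cdens / dq[1, ], NA_real_),
                   cumulative_stock = 10 * cumsum(cdens * thick))
  structure(df, class = c("carbon_profile", "data.frame"),
            site_id = attr(core, "site_id"),
            carbon_fraction = cfg$carbon_fraction_peat)
}

#' @export
print.carbon_profile <- function(x, ...) {
  cat(sprintf("<carbon_profile> site %s: %d increments, total stock %.2f kg C m-2\n",
              attr(x, "site_id") %||% "?", nrow(x),
              x$cumulative_stock[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Carbon mass (g C cm^-2) above a depth, with linear interpolation inside a
# partially covered increment.
mass_above <- function(profile, depth) {
  thick <- profile$depth_bottom - profile$depth_top
  full <- pmin(pmax(depth - profile$depth_top, 0), thick)
  sum(profile$c_density * full)
}

#' Total carbon stock of a profile
#'
#' @param profile A [carbon_profile()].
#' @return Total cumulative stock, kg C m^-2.
#' @export
total_stock <- function(profile) {
  profile$cumulative_stock[nrow(profile)]
}

#' Long-term apparent rate of carbon accumulation (LORCA)
#'
#' Total peat carbon mass divided by the basal calibrated age at the
#' organic-mineral interface:
#' `LORCA = 1000 * stock_kg_m2 / basal_age` (g C m^-2 yr^-1). The basal cal
#' age itself is the denominator — peat initiation to present spans that
#' many years on the cal BP scale used for the basal date. The 1-sigma
#' uncertainty propagates the basal-age sigma to first order (the stock is
#' treated as exact).
#'
#' @param profile A [carbon_profile()], or a total stock in kg C m^-2.
#' @param basal_age Basal age, cal yr BP (> 0).
#' @param basal_sigma 1-sigma of the basal age, yr.
#' @return List with `lorca` and `sigma` (g C m^-2 yr^-1).
#' @examples
#' lorca(22.6, 1255, 57) # lorca 18.0, as for a 38 cm core
#' lorca(66.0, 7522, 69) # lorca 8.8
#' @export
lorca <- function(profile, basal_age, basal_sigma = 0) {
  stock <- if (inherits(profile, "carbon_profile")) total_stock(profile) else profile
  if (basal_age <= 0) stop_pc("basal_age must be > 0", class = "validation_error")
  val <- 1000 * stock / basal_age
  list(lorca = val, sigma = val * basal_sigma / basal_age)
}

#' Recent apparent rate of carbon accumulation (RERCA)
#'
#' Carbon mass accumulated above the depth of a recent calendar horizon
#' (e.g. 1900 CE or 1950 CE), divided by the elapsed time
#' `coring_year - horizon_year`. The horizon depth is the ensemble's
#' [depth_at_age()] at `1950 - horizon_year` cal yr BP; a partially covered
#' increment contributes mass by linear interpolation. The uncertainty
#' interval comes from the ensemble's 95% depth interval.
#'
#' @param profile A [carbon_profile()].
#' @param ens The `chronology_ensemble` the profile was built with.
#' @param horizon_year Horizon calendar year, CE (< coring year).
#' @param cfg A [site_config()] (supplies `coring_year`).
#' @return List with `rerca`, `lo`, `hi` (g C m^-2 yr^-1), `sigma`
#'   (interval half-width / 1.96), and `depth` (median horizon depth, cm).
#' @export
rerca <- function(profile, ens, horizon_year, cfg = site_config()) {
  if (horizon_year >= cfg$coring_year)
    stop_pc("horizon_year must precede the coring year", class = "validation_error")
  years <- cfg$coring_year - horizon_year
  d <- depth_at_age(ens, ce_to_bp(horizon_year))
  val <- 1e4 * mass_above(profile, d$median) / years
  lo <- 1e4 * mass_above(profile, d$interval_95[1]) / years
  hi <- 1e4 * mass_above(profile, d$interval_95[2]) / years
  list(rerca = val, lo = lo, hi = hi, sigma = (hi - lo) / (2 * 1.96),
       depth = d$median)
}

#' Post-fire carbon stock
#'
#' Cumulative carbon stock above the top of the most recent charcoal layer,
#' `[0, last_fire_depth)` — the section deposited since the last local fire.
#'
#' @param profile A [carbon_profile()].
#' @param fires A `fire_record` (see [detect_layers()]).
#' @return Stock in kg C m^-2. With no fire layer, the total stock is
#'   returned with a warning.
#' @export
postfire_stock <- function(profile, fires) {
  if (!nrow(fires$layers) || is.na(fires$last_fire_depth)) {
    warning("no fire layer: returning total stock")
    pc_log("postfire_stock: no fire layer, total stock returned")
    return(total_stock(profile))
  }
  10 * mass_above(profile, fires$last_fire_depth)
}

#' Site-level carbon accounting summary
#'
#' Bundles the stock and rate quantities of one core: total stock, basal
#' age, LORCA, RERCA for 1900 CE-present and 1950 CE-present, and the
#' post-fire stock. RERCA and LORCA are reported side by side but are not
#' comparable quantities: surface peat has undergone far less decomposition
#' than older peat, so recent apparent rates always exceed long-term ones.
#'
#' @param profile A [carbon_profile()].
#' @param ens The `chronology_ensemble` used for the profile.
#' @param fires A dated `fire_record`.
#' @param cfg A [site_config()].
#' @param basal_age,basal_sigma Basal age (cal yr BP) and 1-sigma; default
#'   to the ensemble's basal median and 95%-interval-derived sigma.
#' @return A `site_carbon_summary` list.
#' @export
site_summary <- function(profile, ens, fires, cfg = site_config(),
                         basal_age = NULL, basal_sigma = NULL) {
  nb <- length(ens$depths)
  basal_age <- basal_age %||% ens$median_age[nb]
  basal_sigma <- basal_sigma %||%
    ((ens$interval_95[nb, "hi"] - ens$interval_95[nb, "lo"]) / (2 * 1.96))
  lor <- lorca(profile, basal_age, basal_sigma)
  structure(list(site_id = attr(profile, "site_id"),
                 total_stock = total_stock(profile),
                 basal_age = basal_age, basal_sigma = basal_sigma,
                 lorca = lor$lorca, lorca_sigma = lor$sigma,
                 rerca_1900 = rerca(profile, ens, 1900, cfg),
                 rerca_1950 = rerca(profile, ens, 1950, cfg),
                 postfire_stock = postfire_stock(profile, fires),
                 last_fire_age = fires$last_fire_age),
            class = "site_carbon_summary")
}

#' @export
print.site_carbon_summary <- function(x, ...) {
  cat(sprintf("<site_carbon_summary> %s\n", x$site_id %||% "?"))
  cat(sprintf("  total stock    %.2f kg C m-2 (post-fire %.2f)\n",
              x$total_stock, x$postfire_stock))
  cat(sprintf("  basal age      %.0f +/- %.0f cal yr BP\n", x$basal_age, x$basal_sigma))
  cat(sprintf("  LORCA          %.1f +/- %.1f g C m-2 yr-1\n", x$lorca, x$lorca_sigma))
  cat(sprintf("  RERCA 1900 CE  %.1f [%.1f, %.1f] g C m-2 yr-1\n",
              x$rerca_1900$rerca, x$rerca_1900$lo, x$rerca_1900$hi))
  cat(sprintf("  RERCA 1950 CE  %.1f [%.1f, %.1f] g C m-2 yr-1\n",
              x$rerca_1950$rerca, x$rerca_1950$lo, x$rerca_1950$hi))
  cat("  (RERCA and LORCA are not comparable: surface peat has undergone\n")
  cat("   less decomposition than older peat.)\n")
  invisible(x)
}
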