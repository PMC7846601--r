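#' Construct an allometry set
#'
#' Aboveground biomass is modelled as a sum of power-law components
#' `m = beta1 * DBH^beta2` (kg, DBH in cm) — typically wood, bark, branches
#' and foliage. Belowground (root) biomass is given by one or more named
#' equations, each a function of the DBH vector and the per-tree AGB vector.
#'
#' @param agb_components Data frame with columns `name`, `beta1`, `beta2`
#'   (both betas > 0).
#' @param bgb_equations Named list of functions `function(dbh, agb) -> kg`.
#' @param provenance Free-text provenance of the coefficients. Coefficient
#'   sets must carry explicit provenance before results are used
#'   scientifically.
#' @return An `allometry_set`.
#' @export
allometry_set <- function(agb_components, bgb_equations, provenance) {
  if (!nrow(agb_components) || any(agb_components$beta1 <= 0) ||
      any(agb_components$beta2 <= 0))
    stop_pc("agb components need beta1 > 0 and beta2 > 0", class = "validation_error")
  if (!length(bgb_equations))
    stop_pc("at least one belowground equation is required", class = "validation_error")
  structure(list(agb_components = agb_components,
                 bgb_equations = bgb_equations,
                 provenance = provenance),
            class = "allometry_set")
}

#' Default black-spruce-like allometry
#'
#' Generic power-law magnitudes for a small-stature boreal conifer (wood,
#' bark, branches, foliage components; three root equations spanning a
#' DBH-based power law and two root:shoot ratios). These are documented
#' placeholders for pipeline development and testing: species- and
#' region-specific published coefficients must be supplied (with provenance)
#' for any scientific use.
#'
#' @return An [allometry_set()].
#' @export
default_allometry <- function() {
  allometry_set(
    agb_components = data.frame(
      name = c("wood", "bark", "branches", "foliage"),
      beta1 = c(0.0477, 0.0153, 0.0291, 0.1648),
      beta2 = c(2.5147, 2.2429, 2.0751, 1.4143)),
    bgb_equations = list(
      dbh_power = function(dbh, agb) sum(0.0239 * dbh^2.43),
      ratio_022 = function(dbh, agb) 0.222 * sum(agb),
      ratio_030 = function(dbh, agb) 0.30 * sum(agb)),
    provenance = paste("package default: generic boreal-conifer power laws;",
                       "NOT for scientific use without site-specific",
                       "published coefficients"))
}

#' Aboveground biomass of a tree from its DBH
#'
#' Sum of the allometry set's power-law components.
#'
#' @param dbh DBH values, cm (>= 0); vectorized.
#' @param allo An [allometry_set()].
#' @return Biomass, kg, same length as `dbh`.
#' @examples
#' allo <- allometry_set(data.frame(name = "total", beta1 = 0.1, beta2 = 2.4),
#'                       list(r = function(dbh, agb) 0.2 * sum(agb)), "example")
#' agb(10, allo) # 0.1 * 10^2.4 = 25.12
#' @export
agb <- function(dbh, allo) {
  if (any(dbh < 0)) stop_pc("dbh must be >= 0", class = "validation_error")
  comp <- allo$agb_components
  rowSums(outer(dbh, seq_len(nrow(comp)),
                function(d, i) comp$beta1[i] * d^comp$beta2[i]))
}

#' Reconstruct a tree's annual DBH series from ring widths
#'
#' The raw diameter series is twice the cumulative (mean-of-radii) ring
#' width; it is then rescaled multiplicatively so the final year matches the
#' measured field DBH, absorbing bark thickness and missed-pith bias that
#' ring measurements cannot see. Locally absent rings (width 0) are retained
#' as zero increments.
#'
#' @param series One entry of a [ring_series_set()]:
#'   `list(first_year, widths, radius_count)` with widths in mm.
#' @param final_dbh Measured DBH at coring, cm (> 0).
#' @return Data frame with columns `year` (CE) and `dbh` (cm), non-decreasing,
#'   last value equal to `final_dbh`.
#' @examples
#' s <- list(first_year = 2001, widths = c(5, 5, 5, 5), radius_count = 1)
#' dbh_series(s, final_dbh = 4)$dbh   # 1 2 3 4
#' dbh_series(s, final_dbh = 4.4)$dbh # 1.1 2.2 3.3 4.4
#' @export
dbh_series <- function(series, final_dbh) {
  if (final_dbh <= 0) stop_pc("final_dbh must be > 0", class = "validation_error")
  raw <- 2 * cumsum(series$widths) / 10 # mm radius increments -> cm diameter
  if (raw[length(raw)] <= 0)
    stop_pc("series has zero total ring width", class = "validation_error")
  scale <- final_dbh / raw[length(raw)]
  data.frame(year = series$first_year + seq_along(raw) - 1L,
             dbh = raw * scale)
}

#' Plot-level tree carbon stocks from a census
#'
#' Aboveground biomass per unit area is the summed allometric AGB of all
#' census stems divided by the plot area. Belowground biomass is evaluated
#' with every configured root equation: the central value is their mean,
#' the low/high bounds their min/max. Tree carbon is
#' `carbon_fraction_wood * (AGB + BGB_central)`. Stems below the 1 cm DBH
#' census limit are rejected with a log notice.
#'
#' @param census A [plot_census()].
#' @param allo An [allometry_set()]; defaults to the config's.
#' @param cfg A [site_config()].
#' @return A `stand_stocks` list: `agb_per_m2`, `bgb_per_m2`
#'   (central/lo/hi), `tree_c_stock` (kg C m^-2), `n_stems`, `site_id`.
#' @export
stand_stocks <- function(census, allo = NULL, cfg = site_config()) {
  allo <- allo %||% cfg$allometry
  trees <- census$trees
  small <- trees$dbh < 1
  if (any(small)) {
    pc_log("stand_stocks: %d stem(s) below the 1 cm DBH census limit rejected",
           sum(small))
    trees <- trees[!small, ]
  }
  if (!nrow(trees)) {
    warning("no stems left after DBH >= 1 cm filter: zero stocks")
    return(structure(list(site_id = census$site_id, agb_per_m2 = 0,
                          bgb_per_m2 = c(central = 0, lo = 0, hi = 0),
                          tree_c_stock = 0, n_stems = 0L),
                     class = "stand_stocks"))
  }
  agb_kg <- agb(trees$dbh, allo)
  bgb_each <- vapply(allo$bgb_equations, function(f) f(trees$dbh, agb_kg),
                     numeric(1))
  agb_m2 <- sum(agb_kg) / census$plot_area
  bgb_m2 <- bgb_each / census$plot_area
  central <- mean(bgb_m2)
  structure(list(site_id = census$site_id,
                 agb_per_m2 = agb_m2,
                 bgb_per_m2 = c(central = central, lo = min(bgb_m2), hi = max(bgb_m2)),
                 tree_c_stock = cfg$carbon_fraction_wood * (agb_m2 + central),
                 n_stems = nrow(trees)),
            class = "stand_stocks")
}

#' @export
print.stand_stocks <- function(x, ...) {
  cat(sprintf("<stand_stocks> %s: %d stems\n", x$site_id %||% "?", x$n_stems))
  cat(sprintf("  AGB %.2f kg m-2; BGB %.2f (%.2f-%.2f, mean/min/max of root equations)\n",
              x$agb_per_m2, x$bgb_per_m2["central"], x$bgb_per_m2["lo"],
              x$bgb_per_m2["hi"]))
  cat(sprintf("  tree C %.2f kg C m-2\n", x$tree_c_stock))
  invisible(x)
}

#' Mean annual cumulative aboveground biomass across trees
#'
#' Converts every ring-width series into an annual DBH and AGB trajectory
#' (see [dbh_series()]) and averages AGB across trees per calendar year,
#' over the trees present in that year.
#'
#' @param set A [ring_series_set()] (one series per tree; see
#'   [combine_radii()]).
#' @param final_dbhs Named numeric vector of measured DBHs (cm) keyed by
#'   tree id.
#' @param allo An [allometry_set()].
#' @return Data frame with columns `year`, `mean_agb` (kg per tree),
#'   `n_trees`.
#' @export
mean_cumulative_agb <- function(set, final_dbhs, allo) {
  if (!length(set)) stop_pc("empty ring series set", class = "validation_error")
  per_tree <- lapply(names(set), function(id) {
    d <- dbh_series(set[[id]], final_dbhs[[id]])
    d$agb <- agb(d$dbh, allo)
    d
  })
  years <- sort(unique(unlist(lapply(per_tree, `[[`, "year"))))
  acc <- matrix(NA_real_, length(per_tree), length(years))
  for (k in seq_along(per_tree)) {
    acc[k, match(per_tree[[k]]$year, years)] <- per_tree[[k]]$agb
  }
  data.frame(year = years,
             mean_agb = colMeans(acc, na.rm = TRUE),
             n_trees = colSums(!is.na(acc)))
}
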