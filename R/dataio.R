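#' Construct a validated peat-core table
#'
#' A core table holds the per-increment physical and charcoal measurements of
#' a single peat monolith: contiguous depth increments (cm, positive downward,
#' half-open `[top, bottom)`, surface at 0), dry bulk density (g cm^-3),
#' organic-matter fraction from loss-on-ignition (0-1), and macroscopic
#' charcoal counts (fragments cm^-3).
#'
#' @param depth_top,depth_bottom Increment boundaries in cm; strictly
#'   increasing and contiguous (`depth_bottom[i] == depth_top[i + 1]`).
#' @param bulk_density Dry bulk density, g cm^-3, strictly positive.
#' @param om_fraction Organic-matter mass fraction in `[0, 1]`.
#' @param charcoal_count Non-negative macroscopic charcoal counts
#'   (fragments cm^-3); defaults to zero.
#' @param site_id Site label stored as an attribute.
#' @return A `core_table`, a data frame with one row per increment.
#' @examples
#' core_table(0:2, 1:3, bulk_density = c(0.05, 0.06, 0.1),
#'            om_fraction = c(0.95, 0.95, 0.9))
#' @export
core_table <- function(depth_top, depth_bottom, bulk_density, om_fraction,
                       charcoal_count = 0, site_id = "core") {
  n <- length(depth_top)
  charcoal_count <- rep_len(charcoal_count, n)
  df <- data.frame(depth_top = as.numeric(depth_top),
                   depth_bottom = as.numeric(depth_bottom),
                   bulk_density = as.numeric(bulk_density),
                   om_fraction = as.numeric(om_fraction),
                   charcoal_count = as.numeric(charcoal_count))
  validate_core_table(df)
  structure(df, class = c("core_table", "data.frame"), site_id = site_id)
}

validate_core_table <- function(df) {
  if (nrow(df) == 0) stop_pc("core table has no increments", class = "validation_error")
  if (any(df$depth_bottom <= df$depth_top))
    stop_pc("increment with non-positive thickness", class = "validation_error")
  if (nrow(df) > 1) {
    gap <- df$depth_top[-1] - df$depth_bottom[-nrow(df)]
    bad <- which(abs(gap) > 1e-9)
    if (length(bad))
      stop_pc("non-contiguous increments at depth %.6g cm (gap/overlap of %.6g cm)",
              df$depth_bottom[bad[1]], gap[bad[1]], class = "validation_error")
  }
  if (any(df$bulk_density <= 0))
    stop_pc("bulk_density must be > 0", class = "validation_error")
  if (any(df$om_fraction < 0 | df$om_fraction > 1))
    stop_pc("om_fraction must lie in [0, 1]", class = "validation_error")
  if (any(df$charcoal_count < 0))
    stop_pc("charcoal_count must be >= 0", class = "validation_error")
  invisible(df)
}

#' @export
print.core_table <- function(x, ...) {
  cat(sprintf("<core_table> site %s: %d increments, %g-%g cm\n",
              attr(x, "site_id"), nrow(x), x$depth_top[1], x$depth_bottom[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a peat-core CSV
#'
#' Expects a UTF-8 CSV with header columns `depth_top, depth_bottom,
#' bulk_density, om_fraction, charcoal_count`. An `om_density` column
#' (g cm^-3) may replace `om_fraction` (exactly one of the two must be
#' present); the fraction is then recovered as `om_density / bulk_density`.
#' Depth gaps or overlaps are rejected.
#'
#' @param path Path to the CSV file.
#' @param site_id Optional site label; defaults to the file name.
#' @return A [core_table()].
#' @export
read_core_csv <- function(path, site_id = NULL) {
  df <- read_checked_csv(path, required = c("depth_top", "depth_bottom", "bulk_density"))
  has_frac <- "om_fraction" %in% names(df)
  has_dens <- "om_density" %in% names(df)
  if (has_frac == has_dens)
    stop_pc("%s: exactly one of om_fraction / om_density must be present", path,
            class = "parse_error")
  if (has_dens) df$om_fraction <- df$om_density / df$bulk_density
  if (!"charcoal_count" %in% names(df)) df$charcoal_count <- 0
  out <- core_table(df$depth_top, df$depth_bottom, df$bulk_density,
                    df$om_fraction, df$charcoal_count,
                    site_id = site_id %||% sub("\\.[^.]*$", "", basename(path)))
  pc_log("read_core_csv: %s -> %d increments", path, nrow(out))
  out
}

#' Write a peat-core table to CSV
#'
#' @param core A [core_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_core_csv <- function(core, path) {
  utils::write.csv(as.data.frame(core), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shared CSV reader: checks header, reports the first malformed (non-numeric)
# cell with its line number.
read_checked_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_pc("%s: missing column(s) %s", path, paste(missing, collapse = ", "),
            class = "parse_error")
  for (col in setdiff(names(df), c("kind", "label", "tree_id", "site_id"))) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop_pc("%s: malformed value '%s' in column %s, line %d",
                path, v[bad[1]], col, bad[1] + 1L, class = "parse_error")
      df[[col]] <- num
    }
  }
  df
}

#' Construct a dated-horizons table
#'
#' Holds every chronological anchor of a core: radiocarbon lab ages
#' (`kind = "c14"`, in 14C yr BP), lead-210-derived ages, the surface age,
#' and event markers — all non-c14 ages in cal yr BP.
#'
#' @param depth Horizon depth midpoints, cm.
#' @param kind One of `"c14"`, `"pb210"`, `"surface"`, `"event"` per entry.
#' @param age_value Age (14C yr BP for `c14`, cal yr BP otherwise).
#' @param age_sigma 1-sigma age uncertainty, yr; must be > 0 for `c14` and
#'   `pb210` entries.
#' @param label Free-text label per entry.
#' @return A `date_table` data frame.
#' @export
date_table <- function(depth, kind, age_value, age_sigma, label = "") {
  df <- data.frame(depth = as.numeric(depth), kind = as.character(kind),
                   age_value = as.numeric(age_value),
                   age_sigma = as.numeric(age_sigma),
                   label = rep_len(as.character(label), length(depth)))
  bad <- setdiff(df$kind, c("c14", "pb210", "surface", "event"))
  if (length(bad))
    stop_pc("unknown date kind '%s'", bad[1], class = "validation_error")
  if (sum(df$kind == "surface") > 1)
    stop_pc("a core admits at most one surface entry", class = "validation_error")
  if (any(df$kind %in% c("c14", "pb210") & df$age_sigma <= 0))
    stop_pc("age_sigma must be > 0 for c14/pb210 entries", class = "validation_error")
  structure(df, class = c("date_table", "data.frame"))
}

#' Read a dated-horizons CSV
#'
#' Header: `depth, kind, age_value, age_sigma, label` (label optional).
#'
#' @param path Path to the CSV file.
#' @return A [date_table()].
#' @export
read_date_csv <- function(path) {
  df <- read_checked_csv(path, required = c("depth", "kind", "age_value", "age_sigma"))
  out <- date_table(df$depth, df$kind, df$age_value, df$age_sigma,
                    label = df$label %||% "")
  pc_log("read_date_csv: %s -> %d entries", path, nrow(out))
  out
}

#' Write a dated-horizons table to CSV
#' @param dates A [date_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_date_csv <- function(dates, path) {
  utils::write.csv(as.data.frame(dates), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a lead-210 activity table
#'
#' Total 210Pb activity per unit dry mass, by depth increment, as measured
#' by alpha spectrometry of 210Po.
#'
#' @param depth_top,depth_bottom Increment boundaries, cm (contiguous as in
#'   [core_table()]).
#' @param total_activity Total 210Pb activity, Bq kg^-1 dry mass, >= 0.
#' @param activity_sigma 1-sigma measurement uncertainty, Bq kg^-1.
#' @return An `activity_table` data frame.
#' @export
activity_table <- function(depth_top, depth_bottom, total_activity, activity_sigma) {
  df <- data.frame(depth_top = as.numeric(depth_top),
                   depth_bottom = as.numeric(depth_bottom),
                   total_activity = as.numeric(total_activity),
                   activity_sigma = as.numeric(activity_sigma))
  if (any(df$depth_bottom <= df$depth_top))
    stop_pc("activity increment with non-positive thickness", class = "validation_error")
  if (nrow(df) > 1 && any(abs(df$depth_top[-1] - df$depth_bottom[-nrow(df)]) > 1e-9))
    stop_pc("activity increments must be contiguous", class = "validation_error")
  if (any(df$total_activity < 0))
    stop_pc("total_activity must be >= 0", class = "validation_error")
  structure(df, class = c("activity_table", "data.frame"))
}

#' Read a 210Pb activity CSV
#'
#' Header: `depth_top, depth_bottom, total_activity, activity_sigma`.
#'
#' @param path Path to the CSV file.
#' @return An [activity_table()].
#' @export
read_activity_csv <- function(path) {
  df <- read_checked_csv(path, required = c("depth_top", "depth_bottom",
                                            "total_activity", "activity_sigma"))
  out <- activity_table(df$depth_top, df$depth_bottom, df$total_activity,
                        df$activity_sigma)
  pc_log("read_activity_csv: %s -> %d rows", path, nrow(out))
  out
}

#' Write a 210Pb activity table to CSV
#' @param activity An [activity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  utils::write.csv(as.data.frame(activity), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a calibration curve
#'
#' An IntCal-style mapping from calendar age (cal yr BP) to conventional
#' radiocarbon age (14C yr BP) with the curve's own 1-sigma uncertainty.
#' The grid is stored sorted by calendar age and must be strictly monotone.
#'
#' @param cal_age Calendar ages, cal yr BP.
#' @param c14_age Radiocarbon ages, 14C yr BP.
#' @param curve_sigma Curve 1-sigma, yr, >= 0.
#' @return A `cal_curve` data frame.
#' @export
cal_curve <- function(cal_age, c14_age, curve_sigma) {
  o <- order(cal_age)
  df <- data.frame(cal_age = as.numeric(cal_age)[o],
                   c14_age = as.numeric(c14_age)[o],
                   curve_sigma = as.numeric(curve_sigma)[o])
  if (any(diff(df$cal_age) <= 0))
    stop_pc("calibration-curve cal ages must be strictly monotone",
            class = "validation_error")
  if (any(df$curve_sigma < 0))
    stop_pc("curve_sigma must be >= 0", class = "validation_error")
  structure(df, class = c("cal_curve", "data.frame"))
}

#' Evaluate a calibration curve at arbitrary calendar ages
#'
#' Linear interpolation of both the 14C age and the curve sigma.
#'
#' @param curve A [cal_curve()].
#' @param cal_age Calendar ages, cal yr BP (must lie within the grid).
#' @return A list with numeric vectors `c14_age` and `curve_sigma`.
#' @export
curve_at <- function(curve, cal_age) {
  rng <- range(curve$cal_age)
  if (any(cal_age < rng[1] - 1e-9 | cal_age > rng[2] + 1e-9))
    stop_pc("calendar age outside curve support [%g, %g]", rng[1], rng[2],
            class = "coverage_error")
  list(c14_age = stats::approx(curve$cal_age, curve$c14_age, cal_age)$y,
       curve_sigma = stats::approx(curve$cal_age, curve$curve_sigma, cal_age)$y)
}

#' Read an IntCal-style calibration-curve file
#'
#' Accepts comma- or whitespace-separated columns `cal_age, c14_age, sigma`;
#' lines starting with `#` are skipped. A file in descending calendar order
#' is accepted and sorted canonically (logged).
#'
#' @param path Path to the curve file.
#' @return A [cal_curve()].
#' @export
read_calcurve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- lapply(lines[keep], function(l) {
    toks <- strsplit(trimws(l), "[,\\s]+", perl = TRUE)[[1]]
    suppressWarnings(as.numeric(toks[1:3]))
  })
  m <- do.call(rbind, rows)
  if (is.null(m) || any(is.na(m)))
    stop_pc("%s: non-numeric calibration-curve line", path, class = "parse_error")
  if (is.unsorted(m[, 1]))
    pc_log("read_calcurve: %s not in ascending cal-age order; sorted", path)
  out <- cal_curve(m[, 1], m[, 2], m[, 3])
  pc_log("read_calcurve: %s -> %d grid points", path, nrow(out))
  out
}

#' Write a calibration curve to a text file
#' @param curve A [cal_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path) {
  writeLines(c("# cal_age,c14_age,sigma",
               sprintf("%.6g,%.6g,%.6g", curve$cal_age, curve$c14_age,
                       curve$curve_sigma)), path)
  invisible(path)
}

#' Construct a ring-width series set
#'
#' @param series Named list, one entry per measured series:
#'   `list(first_year = <CE>, widths = <mm per year>, radius_count = <int>)`.
#' @return A `ring_series_set`.
#' @export
ring_series_set <- function(series = list()) {
  for (id in names(series)) {
    s <- series[[id]]
    if (any(s$widths < 0))
      stop_pc("series %s: negative ring width", id, class = "validation_error")
  }
  structure(series, class = "ring_series_set")
}

#' @export
print.ring_series_set <- function(x, ...) {
  cat(sprintf("<ring_series_set> %d series\n", length(x)))
  for (id in utils::head(names(x), 8)) {
    s <- x[[id]]
    cat(sprintf("  %s: %d yr from %d CE (%d radius)\n", id, length(s$widths),
                s$first_year, s$radius_count))
  }
  invisible(x)
}

#' Read a Tucson-format (.rwl) ring-width file
#'
#' Parses the decadal Tucson layout: series id, decade start year, then up to
#' ten ring widths in units of 0.01 mm, ended by a `999` or `-9999`
#' terminator. Widths are returned in mm. Decade lines that do not follow on
#' from the previous line of the same series raise a parse error.
#'
#' @param path Path to the .rwl file.
#' @param combine_radii If `TRUE`, series whose ids differ only in their last
#'   character (e.g. `T01A`/`T01B`, two radii of one cross-section) are
#'   averaged year-by-year into one series per tree.
#' @return A [ring_series_set()].
#' @export
read_rwl <- function(path, combine_radii = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  open <- list() # id -> list(first_year, values, done)
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) < 2)
      stop_pc("%s: malformed line %d", path, i, class = "parse_error")
    id <- toks[1]
    year <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(year) || any(is.na(vals)))
      stop_pc("%s: non-numeric field on line %d", path, i, class = "parse_error")
    cur <- open[[id]]
    if (is.null(cur)) {
      cur <- list(first_year = year, values = numeric(0), done = FALSE)
    } else {
      if (cur$done)
        stop_pc("%s: line %d continues terminated series %s", path, i, id,
                class = "parse_error")
      expect <- cur$first_year + length(cur$values)
      if (year != expect)
        stop_pc("%s: line %d: series %s year %d, expected %d", path, i, id,
                year, expect, class = "parse_error")
    }
    term <- which(vals == 999 | vals == -9999)
    if (length(term)) {
      cur$values <- c(cur$values, vals[seq_len(term[1] - 1L)])
      cur$done <- TRUE
    } else {
      cur$values <- c(cur$values, vals)
    }
    open[[id]] <- cur
  }
  for (id in names(open)) {
    series[[id]] <- list(first_year = open[[id]]$first_year,
                         widths = open[[id]]$values / 100,
                         radius_count = 1L)
  }
  pc_log("read_rwl: %s -> %d series", path, length(series))
  out <- ring_series_set(series)
  if (combine_radii) out <- combine_radii(out)
  out
}

#' Average multi-radius ring series into per-tree series
#'
#' Series sharing an id prefix (id minus its final character) are averaged
#' year-by-year; years covered by only one radius keep that radius' width.
#'
#' @param set A [ring_series_set()].
#' @return A [ring_series_set()] with one series per tree.
#' @export
combine_radii <- function(set) {
  ids <- names(set)
  prefix <- ifelse(nchar(ids) > 1, substr(ids, 1, nchar(ids) - 1), ids)
  out <- list()
  for (p in unique(prefix)) {
    members <- set[ids[prefix == p]]
    if (length(members) == 1) {
      out[[p]] <- members[[1]]
      next
    }
    years <- unlist(lapply(members, function(s)
      seq(s$first_year, length.out = length(s$widths))))
    yr_range <- range(years)
    grid <- yr_range[1]:yr_range[2]
    acc <- matrix(NA_real_, length(members), length(grid))
    for (k in seq_along(members)) {
      s <- members[[k]]
      idx <- s$first_year - yr_range[1] + seq_along(s$widths)
      acc[k, idx] <- s$widths
    }
    out[[p]] <- list(first_year = yr_range[1],
                     widths = colMeans(acc, na.rm = TRUE),
                     radius_count = length(members))
  }
  pc_log("combine_radii: %d series -> %d trees", length(set), length(out))
  ring_series_set(out)
}

#' Write a ring-width set to a Tucson (.rwl) file
#'
#' Widths are written in 0.01 mm units with a `999` terminator.
#'
#' @param set A [ring_series_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(set, path) {
  out <- character(0)
  for (id in names(set)) {
    s <- set[[id]]
    vals <- c(round(s$widths * 100), 999)
    yr <- s$first_year
    i <- 1L
    while (i <= length(vals)) {
      # first line runs to the end of the decade, later lines are full decades
      n_line <- min(10L - (yr %% 10L), length(vals) - i + 1L)
      out <- c(out, paste(c(sprintf("%-8s%4d", id, yr),
                            sprintf("%6d", vals[i:(i + n_line - 1L)])),
                          collapse = ""))
      i <- i + n_line
      yr <- yr + n_line
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a plot census
#'
#' All stems with DBH >= 1 cm inside a fixed-area plot.
#'
#' @param site_id Site label.
#' @param plot_area Plot area, m^2 (> 0); the study design uses 100 m^2.
#' @param tree_id Stem identifiers.
#' @param dbh Diameter at breast height (1.3 m), cm.
#' @return A `plot_census` object.
#' @export
plot_census <- function(site_id, plot_area, tree_id, dbh) {
  if (plot_area <= 0) stop_pc("plot_area must be > 0", class = "validation_error")
  structure(list(site_id = site_id, plot_area = as.numeric(plot_area),
                 trees = data.frame(tree_id = as.character(tree_id),
                                    dbh = as.numeric(dbh))),
            class = "plot_census")
}

#' Read a plot-census CSV
#'
#' Header: `tree_id, dbh`.
#'
#' @param path Path to the CSV file.
#' @param site_id Site label.
#' @param plot_area Plot area in m^2.
#' @return A [plot_census()].
#' @export
read_census_csv <- function(path, site_id = NULL, plot_area = 100) {
  df <- read_checked_csv(path, required = c("tree_id", "dbh"))
  out <- plot_census(site_id %||% sub("\\.[^.]*$", "", basename(path)),
                     plot_area, df$tree_id, df$dbh)
  pc_log("read_census_csv: %s -> %d stems", path, nrow(df))
  out
}

#' Write a plot census to CSV
#' @param census A [plot_census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(census$trees, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Site configuration with study defaults
#'
#' Bundles every tunable constant of the pipeline. Defaults encode the study
#' conventions: coring in 2017 CE (surface age -67 cal yr BP), a 210Pb decay
#' constant of ln(2)/22.3 yr^-1, charcoal presence threshold of 1 fragment
#' cm^-3 with 2 cm layer-merging gap, and 50% carbon content for both peat
#' organic matter and tree biomass.
#'
#' @param coring_year Collection year, CE (> 1900).
#' @param lambda_pb210 210Pb decay constant, yr^-1.
#' @param charcoal_threshold Fire-layer detection threshold, fragments cm^-3.
#' @param charcoal_min_gap Merge charcoal runs separated by less than this, cm.
#' @param carbon_fraction_peat Carbon mass fraction of peat organic matter.
#' @param carbon_fraction_wood Carbon mass fraction of tree biomass.
#' @param allometry An [allometry_set()]; defaults to [default_allometry()].
#' @param mc_iterations Monte-Carlo iterations for the age-depth ensemble.
#' @param rng_seed Seed used by ensemble construction.
#' @return A `site_config` list.
#' @export
site_config <- function(coring_year = 2017,
                        lambda_pb210 = log(2) / 22.3,
                        charcoal_threshold = 1,
                        charcoal_min_gap = 2,
                        carbon_fraction_peat = 0.5,
                        carbon_fraction_wood = 0.5,
                        allometry = default_allometry(),
                        mc_iterations = 2000,
                        rng_seed = 1L) {
  if (coring_year <= 1900)
    stop_pc("coring_year must be > 1900", class = "validation_error")
  if (carbon_fraction_peat <= 0 || carbon_fraction_peat >= 1 ||
      carbon_fraction_wood <= 0 || carbon_fraction_wood >= 1)
    stop_pc("carbon fractions must lie in (0, 1)", class = "validation_error")
  structure(list(coring_year = coring_year, lambda_pb210 = lambda_pb210,
                 charcoal_threshold = charcoal_threshold,
                 charcoal_min_gap = charcoal_min_gap,
                 carbon_fraction_peat = carbon_fraction_peat,
                 carbon_fraction_wood = carbon_fraction_wood,
                 allometry = allometry, mc_iterations = mc_iterations,
                 rng_seed = rng_seed),
            class = "site_config")
}

#' Read a site configuration from a YAML `key: value` file
#'
#' Unknown keys are rejected; absent keys keep their defaults. Allometric
#' coefficients may be given as `allometry: {agb: {wood: [b1, b2], ...},
#' bgb_ratio_agb: r}`.
#'
#' @param path Path to the YAML file.
#' @return A [site_config()].
#' @export
read_site_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(site_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_pc("%s: unknown config key(s): %s", path, paste(extra, collapse = ", "),
            class = "parse_error")
  if (!is.null(raw$allometry)) {
    agb <- raw$allometry$agb
    allo <- allometry_set(
      agb_components = data.frame(name = names(agb),
                                  beta1 = vapply(agb, `[`, 0, 1),
                                  beta2 = vapply(agb, `[`, 0, 2)),
      bgb_equations = default_allometry()$bgb_equations,
      provenance = raw$allometry$provenance %||% paste("config:", path))
    raw$allometry <- allo
  }
  do.call(site_config, raw)
}

#' Write a site configuration to a YAML file
#'
#' Scalar settings are written as `key: value` pairs; the allometry's
#' aboveground components are written in the `allometry: {agb: ...}` form
#' that [read_site_config()] accepts (belowground equations are R
#' functions and do not serialize; a re-read configuration falls back to
#' the default root-equation set, which is noted in the file).
#'
#' @param cfg A [site_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_config <- function(cfg, path) {
  comp <- cfg$allometry$agb_components
  agb <- stats::setNames(lapply(seq_len(nrow(comp)), function(i)
    c(comp$beta1[i], comp$beta2[i])), comp$name)
  out <- list(coring_year = cfg$coring_year, lambda_pb210 = cfg$lambda_pb210,
              charcoal_threshold = cfg$charcoal_threshold,
              charcoal_min_gap = cfg$charcoal_min_gap,
              carbon_fraction_peat = cfg$carbon_fraction_peat,
              carbon_fraction_wood = cfg$carbon_fraction_wood,
              mc_iterations = cfg$mc_iterations, rng_seed = cfg$rng_seed,
              allometry = list(
                agb = agb,
                provenance = paste(cfg$allometry$provenance,
                                   "(bgb equations fall back to defaults on re-read)")))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
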