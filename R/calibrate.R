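#' Calibrate a radiocarbon lab age against a calibration curve
#'
#' Computes the posterior distribution of the calendar age given a
#' conventional radiocarbon age. On a regular calendar-age grid the
#' unnormalized posterior is
#' \deqn{p(\theta) \propto \exp\!\left(-\frac{(y - \mu(\theta))^2}
#'   {2(\sigma_y^2 + \sigma_c(\theta)^2)}\right)}
#' where \eqn{y \pm \sigma_y} is the lab age and \eqn{\mu, \sigma_c} the
#' interpolated curve. The grid is restricted to where posterior mass
#' exceeds 1e-12 of the maximum, then normalized to sum to one. Multimodal
#' posteriors are retained in full.
#'
#' @param lab_age Conventional radiocarbon age, 14C yr BP.
#' @param lab_sigma 1-sigma lab uncertainty, yr (> 0).
#' @param curve A [cal_curve()]; must cover the posterior support.
#' @param grid_step Calendar grid step, yr (default 1).
#' @param depth Optional depth (cm) carried through to the result.
#' @return A `calibrated_date`: list with `grid` (cal yr BP), `posterior`
#'   (probability mass, sums to 1), `median`, `sigma_equiv` (half the
#'   central 68.27% interval, a 1-sigma-equivalent spread) and `interval_95`
#'   (central 2.5-97.5% quantile interval).
#' @examples
#' curve <- cal_curve(0:2000, 0:2000, rep(1, 2001)) # identity curve
#' d <- calibrate(1000, 50, curve)
#' d$median       # 1000
#' d$interval_95  # about (902, 1098)
#' @export
calibrate <- function(lab_age, lab_sigma, curve, grid_step = 1, depth = NA_real_) {
  if (lab_sigma <= 0) stop_pc("lab_sigma must be > 0", class = "validation_error")
  grid <- seq(min(curve$cal_age), max(curve$cal_age), by = grid_step)
  cv <- curve_at(curve, grid)
  dens <- exp(-(lab_age - cv$c14_age)^2 / (2 * (lab_sigma^2 + cv$curve_sigma^2)))
  if (max(dens) <= 0)
    stop_pc("calibration curve does not cover lab age %g", lab_age,
            class = "coverage_error")
  keep <- dens > 1e-12 * max(dens)
  # posterior truncated by the curve edge -> the curve is too short
  idx <- range(which(keep))
  if ((idx[1] == 1 && dens[1] > 1e-4 * max(dens)) ||
      (idx[2] == length(grid) && dens[length(grid)] > 1e-4 * max(dens)))
    stop_pc("posterior support for lab age %g +/- %g truncated by curve edge",
            lab_age, lab_sigma, class = "coverage_error")
  grid <- grid[keep]
  post <- dens[keep] / sum(dens[keep])
  q <- weighted_quantile(grid, post, c(0.025, 0.15865, 0.5, 0.84135, 0.975))
  structure(list(depth = depth, grid = grid, posterior = post,
                 median = q[3], sigma_equiv = (q[4] - q[2]) / 2,
                 interval_95 = c(q[1], q[5])),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  cat(sprintf("<calibrated_date> median %.1f cal yr BP, 95%% [%.1f, %.1f], 1s-equiv %.1f%s\n",
              x$median, x$interval_95[1], x$interval_95[2], x$sigma_equiv,
              if (is.na(x$depth)) "" else sprintf(" (depth %g cm)", x$depth)))
  invisible(x)
}

#' Sample calendar ages from a calibrated date
#'
#' Draws from the discrete posterior with uniform jitter within grid steps,
#' so repeated draws fill the grid cells evenly.
#'
#' @param date A `calibrated_date`.
#' @param n Number of draws.
#' @return Numeric vector of cal yr BP ages.
#' @export
sample_calibrated <- function(date, n) {
  step <- if (length(date$grid) > 1) date$grid[2] - date$grid[1] else 0
  date$grid[sample.int(length(date$grid), n, replace = TRUE,
                       prob = date$posterior)] +
    stats::runif(n, -step / 2, step / 2)
}

#' Calibrate every entry of a dated-horizons table
#'
#' `c14` entries are calibrated against the curve; `pb210`, `surface` and
#' `event` entries are passed through as Gaussian dates on the calendar
#' scale (degenerate when sigma is 0). Order is preserved and the output has
#' one element per input entry.
#'
#' @param table A [date_table()] with at least one `c14` entry.
#' @param curve A [cal_curve()].
#' @param grid_step Calendar grid step for calibration, yr.
#' @return List of `calibrated_date` objects.
#' @export
summarize_dates <- function(table, curve, grid_step = 1) {
  lapply(seq_len(nrow(table)), function(i) {
    row <- table[i, ]
    if (row$kind == "c14")
      return(calibrate(row$age_value, row$age_sigma, curve,
                       grid_step = grid_step, depth = row$depth))
    gaussian_date(row$age_value, row$age_sigma, depth = row$depth,
                  grid_step = grid_step)
  })
}

# A Gaussian (or degenerate) calendar-scale date in calibrated_date form,
# used for 210Pb, surface and event horizons.
gaussian_date <- function(mean_age, sigma, depth = NA_real_, grid_step = 1) {
  if (sigma <= 0) {
    return(structure(list(depth = depth, grid = mean_age, posterior = 1,
                          median = mean_age, sigma_equiv = 0,
                          interval_95 = c(mean_age, mean_age)),
                     class = "calibrated_date"))
  }
  grid <- seq(mean_age - 5 * sigma, mean_age + 5 * sigma, by = grid_step)
  post <- stats::dnorm(grid, mean_age, sigma)
  post <- post / sum(post)
  structure(list(depth = depth, grid = grid, posterior = post,
                 median = mean_age, sigma_equiv = sigma,
                 interval_95 = mean_age + c(-1, 1) * stats::qnorm(0.975) * sigma),
            class = "calibrated_date")
}

#' Export a calibrated posterior as a two-column data frame
#'
#' @param date A `calibrated_date`.
#' @return Data frame with columns `cal_age`, `probability`.
#' @export
posterior_df <- function(date) {
  data.frame(cal_age = date$grid, probability = date$posterior)
}
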