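#' Estimate supported 210Pb activity from the deep tail of a profile
#'
#' Supported 210Pb (in equilibrium with in-situ 226Ra) is taken as the mean
#' total activity of the deepest `tail_n` increments, where unsupported
#' activity has decayed away; the standard error of that mean is returned
#' alongside.
#'
#' @param activity An [activity_table()].
#' @param tail_n Number of deepest rows to average (>= 2).
#' @return List with `supported` (Bq kg^-1) and `se` (standard error of the
#'   tail mean; measurement sigmas and tail scatter combined).
#' @export
estimate_supported <- function(activity, tail_n = 3) {
  if (tail_n < 2) stop_pc("tail_n must be >= 2", class = "validation_error")
  n <- nrow(activity)
  if (n < tail_n)
    stop_pc("activity table has %d rows, fewer than tail_n = %d", n, tail_n,
            class = "validation_error")
  tail_rows <- activity[(n - tail_n + 1):n, ]
  supported <- mean(tail_rows$total_activity)
  se_meas <- sqrt(sum(tail_rows$activity_sigma^2)) / tail_n
  se_scatter <- stats::sd(tail_rows$total_activity) / sqrt(tail_n)
  list(supported = supported, se = max(se_meas, se_scatter))
}

#' Date a profile with the constant-rate-of-supply (CRS) 210Pb model
#'
#' The CRS model assumes a constant atmospheric flux of unsupported 210Pb to
#' the peat surface. With \eqn{A(z)} the unsupported inventory (Bq m^-2)
#' below depth z, the age of depth z in years before coring is
#' \deqn{t(z) = \frac{1}{\lambda}\,\ln\frac{A(0)}{A(z)}}
#' Inventories are accumulated increment-wise from unsupported activity
#' (total minus supported) times dry mass per area; 1-sigma age
#' uncertainties follow by first-order propagation of the activity
#' measurement sigmas. Horizons where \eqn{A(z) \le 0} are beyond the
#' dateable range and are dropped with a log notice.
#'
#' @param activity An [activity_table()].
#' @param core A [core_table()] covering the activity depths (supplies bulk
#'   density for the mass conversion).
#' @param supported Supported activity, Bq kg^-1 (see [estimate_supported()]).
#' @param lambda 210Pb decay constant, yr^-1; default ln(2)/22.3.
#' @return A `crs_result`: data frame `horizons` (depth_bottom, age in yr
#'   before coring, age_sigma) plus `supported`, `inventory_total`
#'   (= A(0), Bq m^-2) and `flux` (= lambda * A(0), Bq m^-2 yr^-1).
#' @examples
#' core <- core_table(0:1, 1:2, c(0.05, 0.05), c(0.95, 0.95))
#' act <- activity_table(0:1, 1:2, c(300, 100), c(5, 5))
#' # equal unsupported inventories in both increments would give
#' # age at 1 cm = ln(2)/lambda = 22.3 yr
#' @export
crs_ages <- function(activity, core, supported, lambda = log(2) / 22.3) {
  nb <- nrow(core)
  rho <- stats::approx(x = c(core$depth_top, core$depth_bottom[nb]),
                       y = c(core$bulk_density, core$bulk_density[nb]),
                       xout = (activity$depth_top + activity$depth_bottom) / 2,
                       method = "constant", rule = 2)$y
  thick <- activity$depth_bottom - activity$depth_top
  unsup <- activity$total_activity - supported
  # Bq kg^-1 * g cm^-3 * cm = 1e-3 Bq cm^-2 -> *10 gives Bq m^-2
  inv <- 10 * unsup * rho * thick
  inv_sigma <- 10 * activity$activity_sigma * rho * thick
  n <- nrow(activity)
  # A at increment tops: A(top_i) = sum of inventories from i to bottom;
  # inventory below the deepest measured increment is taken as zero
  # (profiles must be measured to the unsupported tail).
  A_top <- rev(cumsum(rev(inv)))
  A0 <- A_top[1]
  if (A0 <= 0)
    stop_pc("no positive unsupported inventory: profile not CRS-dateable",
            class = "validation_error")
  ages <- numeric(n)
  sig <- numeric(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    Az <- if (i < n) A_top[i + 1] else 0
    if (Az <= 0) {
      keep[i] <- FALSE
      pc_log("crs_ages: horizon %g cm below dateable range, dropped",
             activity$depth_bottom[i])
      next
    }
    keep[i] <- TRUE
    ages[i] <- log(A0 / Az) / lambda
    # d age / d inv_j = (1/lambda) (1/A0 - [j > i] / Az); inventory sigmas
    # are independent across increments
    dj <- rep(1 / A0, n)
    dj[(i + 1):n] <- dj[(i + 1):n] - 1 / Az
    sig[i] <- sqrt(sum((dj * inv_sigma)^2)) / lambda
  }
  horizons <- data.frame(depth_bottom = activity$depth_bottom[keep],
                         age = ages[keep], age_sigma = sig[keep])
  structure(list(horizons = horizons, supported = supported,
                 inventory_total = A0, flux = lambda * A0, lambda = lambda),
            class = "crs_result")
}

#' @export
print.crs_result <- function(x, ...) {
  cat(sprintf("<crs_result> %d dated horizons, inventory %.1f Bq m-2, flux %.2f Bq m-2 yr-1\n",
              nrow(x$horizons), x$inventory_total, x$flux))
  print.data.frame(utils::head(x$horizons, 6))
  invisible(x)
}

#' Export a CRS chronology as a data frame
#'
#' Ages before coring are converted to calendar years CE and cal yr BP using
#' the coring year.
#'
#' @param crs A `crs_result`.
#' @param coring_year Coring year, CE.
#' @return Data frame with columns `depth`, `age_CE`, `age_calBP`, `sigma`.
#' @export
crs_table <- function(crs, coring_year) {
  data.frame(depth = crs$horizons$depth_bottom,
             age_CE = coring_year - crs$horizons$age,
             age_calBP = ce_to_bp(coring_year - crs$horizons$age),
             sigma = crs$horizons$age_sigma)
}

#' Convert CRS horizons into dated-horizon entries
#'
#' Expresses CRS ages (years before coring) as cal yr BP Gaussian dates that
#' can join radiocarbon dates in an age-depth model.
#'
#' @param crs A `crs_result`.
#' @param coring_year Coring year, CE.
#' @param min_sigma Floor on the age sigma, yr, so that near-surface CRS
#'   horizons do not enter the model as exact (default 1).
#' @return A [date_table()] of `pb210` entries.
#' @export
crs_to_dates <- function(crs, coring_year, min_sigma = 1) {
  h <- crs$horizons
  date_table(depth = h$depth_bottom, kind = "pb210",
             age_value = ce_to_bp(coring_year) + h$age,
             age_sigma = pmax(h$age_sigma, min_sigma),
             label = sprintf("crs_%g", h$depth_bottom))
}
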