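#' Build a Monte-Carlo combined 14C + 210Pb age-depth model
#'
#' Draws one age per dated horizon per iteration (14C horizons from their
#' calibrated posteriors, 210Pb and surface horizons from Gaussians),
#' rejects and redraws any iteration whose age sequence is not strictly
#' increasing with depth (up to `max_attempts`, after which the iteration is
#' discarded with a log notice), and interpolates each accepted draw
#' piecewise-linearly onto the depth grid. Per-depth medians, central 95%
#' bands and per-increment deposition times (yr cm^-1, as iteration-wise
#' slope quantiles) summarize the ensemble.
#'
#' This is a deliberately transparent interpolation model in the classical
#' Monte-Carlo (clam-style) tradition, not an autoregressive accumulation
#' prior: the chronology is used downstream only for deposition times and
#' horizon lookups, where the piecewise-linear model is well-posed and
#' reproducible.
#'
#' @param dates List of `calibrated_date` objects (depths set), e.g. from
#'   [summarize_dates()].
#' @param crs Optional `crs_result` contributing upper-core 210Pb horizons
#'   (ages in years before coring; anchored via `surface_age`).
#' @param surface_age Surface age, cal yr BP (e.g. -67 for a 2017 CE core).
#' @param n_iter Monte-Carlo iterations (>= 100).
#' @param seed RNG seed (mandatory: chronologies must be reproducible).
#' @param depths Depth grid, cm; default every cm from 0 to the deepest
#'   dated horizon.
#' @param surface_sigma Surface-age sigma, yr (0 = exact surface).
#' @param max_attempts Redraw budget per iteration before discarding.
#' @return A `chronology_ensemble`.
#' @export
build_ensemble <- function(dates, crs = NULL, surface_age = -67,
                           n_iter = 2000, seed = 1L, depths = NULL,
                           surface_sigma = 0, max_attempts = 1000) {
  if (n_iter < 100) stop_pc("n_iter must be >= 100", class = "validation_error")
  horizons <- list(gaussian_date(surface_age, surface_sigma, depth = 0))
  for (d in dates) if (d$depth > 0) horizons <- c(horizons, list(d))
  # CRS horizons enter last so that on a depth collision the direct
  # (calibrated) date is the one retained
  if (!is.null(crs)) {
    h <- crs$horizons
    for (i in seq_len(nrow(h)))
      horizons <- c(horizons, list(gaussian_date(surface_age + h$age[i],
                                                 max(h$age_sigma[i], 1e-9),
                                                 depth = h$depth_bottom[i])))
  }
  hd <- vapply(horizons, function(h) h$depth, numeric(1))
  if (anyDuplicated(hd)) {
    pc_log("build_ensemble: duplicate horizon depths, keeping first of each")
    horizons <- horizons[!duplicated(hd)]
    hd <- hd[!duplicated(hd)]
  }
  o <- order(hd)
  horizons <- horizons[o]
  hd <- hd[o]
  if (length(horizons) < 2)
    stop_pc("need >= 2 dated horizons including the surface", class = "validation_error")
  if (is.null(depths)) depths <- seq(0, max(hd), by = 1)
  if (max(depths) > max(hd) + 1e-9)
    stop_pc("depth grid extends below the deepest dated horizon",
            class = "validation_error")

  set.seed(seed)
  nh <- length(horizons)
  real <- matrix(NA_real_, n_iter, length(depths))
  accepted <- 0L
  for (it in seq_len(n_iter)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ages <- vapply(horizons, function(h) sample_calibrated(h, 1), numeric(1))
      if (all(diff(ages) > 0)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      pc_log("build_ensemble: iteration %d discarded after %d reversal redraws",
             it, max_attempts)
      next
    }
    accepted <- accepted + 1L
    real[accepted, ] <- stats::approx(hd, ages, xout = depths, rule = 2)$y
  }
  if (accepted < n_iter / 2)
    stop_pc("only %d/%d iterations accepted: inspect age reversals in the dates",
            accepted, n_iter, class = "reversal_error")
  real <- real[seq_len(accepted), , drop = FALSE]

  qs <- apply(real, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  slopes <- t(apply(real, 1, diff)) / rep(diff(depths), each = accepted)
  if (length(depths) == 2) slopes <- matrix(slopes, nrow = accepted)
  dq <- apply(slopes, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  deposition <- data.frame(depth_top = depths[-length(depths)],
                           depth_bottom = depths[-1],
                           dep_time = dq[2, ], dep_lo = dq[1, ], dep_hi = dq[3, ])
  structure(list(depths = depths, realizations = real,
                 median_age = qs[2, ],
                 interval_95 = cbind(lo = qs[1, ], hi = qs[3, ]),
                 deposition_time = deposition,
                 surface_age = surface_age,
                 n_iter = n_iter, n_accepted = accepted, seed = seed),
            class = "chronology_ensemble")
}

#' @export
print.chronology_ensemble <- function(x, ...) {
  cat(sprintf("<chronology_ensemble> %d depths (%g-%g cm), %d/%d iterations\n",
              length(x$depths), min(x$depths), max(x$depths),
              x$n_accepted, x$n_iter))
  cat(sprintf("  surface %.0f cal yr BP; basal median %.0f [%.0f, %.0f]\n",
              x$surface_age, x$median_age[length(x$depths)],
              x$interval_95[length(x$depths), 1], x$interval_95[length(x$depths), 2]))
  invisible(x)
}

#' Median age (with 95% band) at an arbitrary depth
#'
#' Per-iteration linear interpolation of the ensemble, summarized by
#' quantiles.
#'
#' @param ens A `chronology_ensemble`.
#' @param depth Depth, cm, within the modelled grid.
#' @return List with `median` and `interval_95` (cal yr BP).
#' @export
age_at_depth <- function(ens, depth) {
  rng <- range(ens$depths)
  if (depth < rng[1] - 1e-9 || depth > rng[2] + 1e-9)
    stop_pc("depth %g cm outside modelled range [%g, %g]", depth, rng[1], rng[2],
            class = "coverage_error")
  ages <- apply(ens$realizations, 1, function(a)
    stats::approx(ens$depths, a, xout = depth)$y)
  q <- stats::quantile(ages, c(0.025, 0.5, 0.975), names = FALSE)
  list(median = q[2], interval_95 = c(q[1], q[3]))
}

#' Depth at which the core reaches a target age
#'
#' Inverse interpolation per iteration (each realization is strictly
#' monotone), summarized by the median and central 95% interval of depths.
#' Ages younger than the surface map to depth 0.
#'
#' @param ens A `chronology_ensemble`.
#' @param target_age Target age, cal yr BP.
#' @return List with `median` and `interval_95` (cm).
#' @export
depth_at_age <- function(ens, target_age) {
  basal_median <- ens$median_age[length(ens$depths)]
  if (target_age > basal_median)
    stop_pc("target age %g cal yr BP is older than the basal median %g",
            target_age, basal_median, class = "span_error")
  d <- apply(ens$realizations, 1, function(a)
    stats::approx(a, ens$depths, xout = target_age, rule = 2)$y)
  q <- stats::quantile(d, c(0.025, 0.5, 0.975), names = FALSE)
  list(median = q[2], interval_95 = c(q[1], q[3]))
}

#' Summarize an age-depth ensemble as a data frame
#'
#' One row per grid depth: median and 95% band of age; deposition-time
#' quantiles are attached to the increment above each depth (NA at the
#' surface row).
#'
#' @param ens A `chronology_ensemble`.
#' @return Data frame with columns `depth`, `median`, `lo95`, `hi95`,
#'   `dep_time_median`, `dep_time_lo`, `dep_time_hi`.
#' @export
ensemble_summary <- function(ens) {
  dep <- ens$deposition_time
  data.frame(depth = ens$depths,
             median = ens$median_age,
             lo95 = ens$interval_95[, "lo"],
             hi95 = ens$interval_95[, "hi"],
             dep_time_median = c(NA, dep$dep_time),
             dep_time_lo = c(NA, dep$dep_lo),
             dep_time_hi = c(NA, dep$dep_hi))
}

#' Plot an age-depth ensemble
#'
#' Median chronology with its 95% band, depth increasing downward.
#'
#' @param x A `chronology_ensemble`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.chronology_ensemble <- function(x, ...) {
  plot(x$median_age, x$depths, type = "n", ylim = rev(range(x$depths)),
       xlab = "Age (cal yr BP)", ylab = "Depth (cm)", ...)
  graphics::polygon(c(x$interval_95[, "lo"], rev(x$interval_95[, "hi"])),
                    c(x$depths, rev(x$depths)), col = "grey85", border = NA)
  graphics::lines(x$median_age, x$depths, lwd = 2)
  invisible(x)
}
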