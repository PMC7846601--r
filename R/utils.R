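#' Convert calendar years CE to calibrated years BP
#'
#' The radiocarbon community anchors "before present" at 1950 CE, so
#' `BP = 1950 - CE`. Years after 1950 CE map to negative cal yr BP; a core
#' collected in 2017 CE has a surface age of -67 cal yr BP.
#'
#' @param year_ce Calendar year(s), CE.
#' @return Numeric vector of calibrated years BP.
#' @examples
#' ce_to_bp(2017) # -67
#' ce_to_bp(1950) # 0
#' @export
ce_to_bp <- function(year_ce) 1950 - year_ce

#' Convert calibrated years BP to calendar years CE
#'
#' @param age_bp Age(s) in calibrated years BP (BP = 1950 CE).
#' @return Numeric vector of calendar years CE.
#' @export
bp_to_ce <- function(age_bp) 1950 - age_bp

# Round half away from zero, the convention used in report tables so that
# e.g. 5.65 prints as 5.7 (base round() would give 5.6 under banker's
# rounding). Raw values are always retained alongside rounded ones.
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured run log: parsers and model steps append timestamped notices
# here; retrieve with peatcarbon_log(), clear with peatcarbon_log(clear =).
.pc_env <- new.env(parent = emptyenv())
.pc_env$log <- character(0)

pc_log <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  .pc_env$log <- c(.pc_env$log, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  invisible(msg)
}

#' Retrieve or clear the structured run log
#'
#' All readers and model-fitting steps record row counts, rejected rows and
#' numerical notices in a session-level log.
#'
#' @param clear If `TRUE`, empty the log after returning it.
#' @return Character vector of log lines, invisibly when clearing.
#' @export
peatcarbon_log <- function(clear = FALSE) {
  out <- .pc_env$log
  if (clear) {
    .pc_env$log <- character(0)
    return(invisible(out))
  }
  out
}

stop_pc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "peatcarbon_error")))
}

# Weighted quantile of a discrete distribution (grid values + probability
# masses), by inversion of the step CDF. Used for calibrated-date summaries.
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}
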