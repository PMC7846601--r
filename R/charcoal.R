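#' Detect charcoal layers in a core
#'
#' A fire layer is a maximal run of increments whose macroscopic charcoal
#' count reaches `threshold`; runs separated by less than `min_gap` cm of
#' sub-threshold peat are merged into one layer. The shallowest layer marks
#' the most recent fire; the post-fire section of the core is everything
#' above its top.
#'
#' @param core A [core_table()].
#' @param threshold Detection threshold, fragments cm^-3 (>= 1). Default 1:
#'   presence of any macroscopic fragment.
#' @param min_gap Merge gap, cm (default 2).
#' @return A `fire_record`: data frame `layers` (depth_top, depth_bottom,
#'   peak_count), `last_fire_depth` (top of the shallowest layer, or NA),
#'   and unset age fields (see [date_last_fire()]).
#' @examples
#' core <- core_table(0:6, 1:7, rep(0.1, 7), rep(0.9, 7),
#'                    charcoal_count = c(0, 0, 5, 7, 0, 0, 3))
#' detect_layers(core, threshold = 1, min_gap = 1)$layers
#' @export
detect_layers <- function(core, threshold = 1, min_gap = 2) {
  if (threshold < 1) stop_pc("threshold must be >= 1", class = "validation_error")
  hot <- core$charcoal_count >= threshold
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  layers <- data.frame(depth_top = core$depth_top[starts[runs$values]],
                       depth_bottom = core$depth_bottom[ends[runs$values]])
  if (nrow(layers) > 1) {
    merged <- layers[1, ]
    for (i in 2:nrow(layers)) {
      if (layers$depth_top[i] - merged$depth_bottom[nrow(merged)] < min_gap) {
        merged$depth_bottom[nrow(merged)] <- layers$depth_bottom[i]
      } else {
        merged <- rbind(merged, layers[i, ])
      }
    }
    layers <- merged
  }
  layers$peak_count <- vapply(seq_len(nrow(layers)), function(i) {
    inside <- core$depth_top >= layers$depth_top[i] &
      core$depth_bottom <= layers$depth_bottom[i]
    max(core$charcoal_count[inside])
  }, numeric(1))
  structure(list(layers = layers,
                 last_fire_depth = if (nrow(layers)) min(layers$depth_top) else NA_real_,
                 last_fire_age = NA_real_, last_fire_interval = c(NA_real_, NA_real_)),
            class = "fire_record")
}

#' @export
print.fire_record <- function(x, ...) {
  cat(sprintf("<fire_record> %d layer(s)", nrow(x$layers)))
  if (!is.na(x$last_fire_depth)) {
    cat(sprintf("; last fire above %g cm", x$last_fire_depth))
    if (!is.na(x$last_fire_age))
      cat(sprintf(", %.0f cal yr BP [%.0f, %.0f]",
                  x$last_fire_age, x$last_fire_interval[1], x$last_fire_interval[2]))
  }
  cat("\n")
  if (nrow(x$layers)) print.data.frame(x$layers)
  invisible(x)
}

#' Date the most recent fire from the chronology
#'
#' Sets `last_fire_age` to the ensemble median age at the top of the
#' shallowest charcoal layer, with its central 95% interval.
#'
#' @param rec A `fire_record` from [detect_layers()].
#' @param ens A `chronology_ensemble` covering the layer depth.
#' @return The updated `fire_record`.
#' @export
date_last_fire <- function(rec, ens) {
  if (!nrow(rec$layers)) {
    warning("fire record has no layers; nothing to date")
    pc_log("date_last_fire: empty record, unchanged")
    return(rec)
  }
  a <- age_at_depth(ens, rec$last_fire_depth)
  rec$last_fire_age <- a$median
  rec$last_fire_interval <- a$interval_95
  rec
}

#' Export a fire record as a data frame
#'
#' @param rec A `fire_record`.
#' @param ens Optional `chronology_ensemble` used to date every layer top.
#' @return Data frame with columns `layer_top`, `layer_bottom`,
#'   `peak_count`, `median_age`, `lo95`, `hi95`.
#' @export
fire_table <- function(rec, ens = NULL) {
  ly <- rec$layers
  out <- data.frame(layer_top = ly$depth_top, layer_bottom = ly$depth_bottom,
                    peak_count = ly$peak_count,
                    median_age = NA_real_, lo95 = NA_real_, hi95 = NA_real_)
  if (!is.null(ens)) {
    for (i in seq_len(nrow(out))) {
      a <- age_at_depth(ens, out$layer_top[i])
      out$median_age[i] <- a$median
      out$lo95[i] <- a$interval_95[1]
      out$hi95[i] <- a$interval_95[2]
    }
  }
  out
}
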