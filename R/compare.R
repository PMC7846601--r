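#' Compare peat and tree carbon pools at one site
#'
#' Produces the headline site comparison: ecosystem total (peat + tree
#' carbon), peat:tree ratios over the whole record and over the post-fire
#' window, and the factor by which aboveground tree carbon would have to be
#' multiplied to match the long-term peat store. The same tree carbon stock
#' enters both ratios: the even-aged stand postdates the last fire, so tree
#' biomass is entirely post-fire.
#'
#' @param summary A `site_carbon_summary` (see [site_summary()]), or a list
#'   with at least `site_id`, `total_stock`, `postfire_stock` (kg C m^-2).
#' @param trees A `stand_stocks` (see [stand_stocks()]), or a list with
#'   `agb_per_m2` and `tree_c_stock`.
#' @param cfg A [site_config()] (supplies `carbon_fraction_wood`).
#' @return A `site_comparison` list: `peat_total`, `peat_postfire`,
#'   `tree_c`, `ecosystem_total` (kg C m^-2), `ratio_total`,
#'   `ratio_postfire`, `agb_multiplier_to_match_peat`.
#' @examples
#' s <- list(site_id = "site_a", total_stock = 22.6, postfire_stock = 12.0)
#' t <- list(agb_per_m2 = 8.9,
#'           tree_c_stock = 0.5 * (8.9 + 2.4))
#' compare_site(s, t)$ratio_total # 4.0
#' @export
compare_site <- function(summary, trees, cfg = site_config()) {
  tree_c <- trees$tree_c_stock
  if (tree_c <= 0) {
    warning("tree carbon stock is zero: ratios undefined")
    ratio_total <- ratio_postfire <- NA_real_
  } else {
    ratio_total <- summary$total_stock / tree_c
    ratio_postfire <- summary$postfire_stock / tree_c
  }
  agb_c <- cfg$carbon_fraction_wood * trees$agb_per_m2
  structure(list(site_id = summary$site_id,
                 peat_total = summary$total_stock,
                 peat_postfire = summary$postfire_stock,
                 tree_c = tree_c,
                 ecosystem_total = summary$total_stock + tree_c,
                 ratio_total = ratio_total,
                 ratio_postfire = ratio_postfire,
                 agb_multiplier_to_match_peat =
                   if (agb_c > 0) summary$total_stock / agb_c else NA_real_),
            class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> %s\n", x$site_id %||% "?"))
  cat(sprintf("  peat %.1f kg C m-2 (post-fire %.1f); trees %.1f; ecosystem %.1f\n",
              round_half_away(x$peat_total), round_half_away(x$peat_postfire),
              round_half_away(x$tree_c), round_half_away(x$ecosystem_total)))
  cat(sprintf("  peat:tree ratio %.1f (post-fire window %.1f)\n",
              round_half_away(x$ratio_total), round_half_away(x$ratio_postfire)))
  invisible(x)
}

#' Cross-site comparison report
#'
#' Tabulates the per-site comparisons and appends cross-site means (mean
#' peat post-fire stock, mean tree carbon, mean ratios). Values are
#' reported raw in the returned data frame; the optional files round to one
#' decimal (half away from zero) in the text summary while the CSV keeps
#' full precision.
#'
#' @param comparisons List of `site_comparison` objects.
#' @param csv_path,txt_path Optional output paths for a CSV table and a
#'   plain-text summary.
#' @return A `comparison_report`: list with `table` (one row per site) and
#'   `means`.
#' @export
summary_report <- function(comparisons, csv_path = NULL, txt_path = NULL) {
  if (!length(comparisons))
    stop_pc("at least one site comparison is required", class = "validation_error")
  tab <- do.call(rbind, lapply(comparisons, function(x)
    data.frame(site_id = x$site_id, peat_total = x$peat_total,
               peat_postfire = x$peat_postfire, tree_c = x$tree_c,
               ecosystem_total = x$ecosystem_total,
               ratio_total = x$ratio_total,
               ratio_postfire = x$ratio_postfire)))
  means <- colMeans(tab[, -1])
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(txt_path)) {
    fmt <- function(v) sprintf("%.1f", round_half_away(v))
    lines <- c("Peat vs tree carbon stores",
               "==========================",
               sprintf("%-10s %10s %13s %8s %10s %7s", "site", "peat", "peat_postfire",
                       "tree_C", "ecosystem", "ratio"),
               sprintf("%-10s %10s %13s %8s %10s %7s", tab$site_id,
                       fmt(tab$peat_total), fmt(tab$peat_postfire),
                       fmt(tab$tree_c), fmt(tab$ecosystem_total),
                       fmt(tab$ratio_total)),
               "",
               sprintf("mean post-fire peat C: %s kg m-2", fmt(means["peat_postfire"])),
               sprintf("mean tree C:           %s kg m-2", fmt(means["tree_c"])),
               "",
               "Note: recent (RERCA) and long-term (LORCA) rates are not",
               "comparable; surface peat has undergone less decomposition",
               "than older peat.")
    writeLines(lines, txt_path)
  }
  structure(list(table = tab, means = means), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print.data.frame(x$table)
  cat("means:\n")
  print(round(x$means, 3))
  invisible(x)
}
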