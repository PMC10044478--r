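#' Plot an emission inventory
#'
#' Stacked bar of the characterized contribution of each emission source,
#' in the source categories of the inventory (enteric and manure methane,
#' manure and soil nitrous oxide, on-farm diesel, upstream inputs).
#'
#' @param object an `emission_inventory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @importFrom ggplot2 autoplot
autoplot.emission_inventory <- function(object, ...) {
  d <- object$sources
  ggplot2::ggplot(d, ggplot2::aes(x = object$farm_id, y = .data$co2eq,
                                  fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "kg CO2eq / yr", fill = "source",
                  title = "Cradle-to-farm-gate GHG inventory") +
    ggplot2::theme_minimal()
}

#' Plot indicator sets
#'
#' Dot plot of the four sustainability indicators per farm, faceted by
#' indicator with free scales (the indicators have different units).
#'
#' @param object an `indicator_set` tibble (possibly several rows).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.indicator_set <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("farm_id", "scenario", "gwp_per_kg", "net_hep",
               "wt_min_per_kg", "profit")],
    cols = c("gwp_per_kg", "net_hep", "wt_min_per_kg", "profit"),
    names_to = "indicator", values_to = "value")
  d <- d[is.finite(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$farm_id, y = .data$value,
                                  colour = .data$scenario)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~indicator, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Sustainability indicators") +
    ggplot2::theme_minimal()
}

#' Net HEP efficiency against stocking rate
#'
#' Scatter of net human-edible protein efficiency versus stocking rate
#' across sensitivity draws, with the Spearman rank correlation in the
#' subtitle.
#'
#' @param results a [run_sensitivity()] result (or any table with
#'   `net_hep` and `stocking_rate`).
#' @return a ggplot.
#' @export
plot_hep_stocking <- function(results) {
  hs <- hep_vs_stocking(results)
  ggplot2::ggplot(hs$pairs,
                  ggplot2::aes(x = .data$stocking_rate, y = .data$net_hep)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "stocking rate (LU / ha permanent grassland)",
                  y = "net HEP efficiency",
                  subtitle = sprintf("Spearman rho = %.2f (n = %d)",
                                     hs$rho, hs$n_used)) +
    ggplot2::theme_minimal()
}
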