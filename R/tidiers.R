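#' Tidy a farm solution
#'
#' Returns the primal decision variables of an optimal farm solution as one
#' long tibble: activity areas, herd scale, feed purchases, crop sales and
#' mineral fertilizer, each with its unit.
#'
#' @param x a `farm_solution`.
#' @param ... unused.
#' @return tibble: `term`, `kind`, `value`, `unit`.
#' @export
#' @importFrom generics tidy
tidy.farm_solution <- function(x, ...) {
  stopifnot(x$status == "optimal")
  dplyr::bind_rows(
    tibble::tibble(term = x$activities$activity, kind = "activity",
                   value = x$activities$ha, unit = "ha"),
    tibble::tibble(term = "herd_scale", kind = "herd",
                   value = x$scale, unit = "multiplier"),
    tibble::tibble(term = x$purchases$feed, kind = "purchase",
                   value = x$purchases$t_fresh, unit = "t fresh"),
    tibble::tibble(term = x$sales$crop, kind = "sale",
                   value = x$sales$t_fresh, unit = "t fresh"),
    tibble::tibble(term = "mineral_n", kind = "fertilizer",
                   value = x$fert_n, unit = "kg N"))
}

#' Glance at a farm solution
#'
#' One-row summary of a solved farm: solver status, objective, profit,
#' herd scale, carcass output and the number of binding constraints.
#'
#' @param x a `farm_solution`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
#' @importFrom generics glance
glance.farm_solution <- function(x, ...) {
  if (x$status != "optimal")
    return(tibble::tibble(farm_id = x$config$farm_id, status = x$status,
                          objective = NA_real_, profit = NA_real_,
                          herd_scale = NA_real_, carcass_kg = NA_real_,
                          n_binding = NA_integer_))
  po <- production_outputs(x$config, x$herd)
  tibble::tibble(farm_id = x$config$farm_id, status = x$status,
                 objective = x$objective, profit = x$profit,
                 herd_scale = x$scale, carcass_kg = sum(po$carcass_kg),
                 n_binding = sum(x$constraints$binding))
}

#' @export
#' @importFrom generics tidy
tidy.emission_inventory <- function(x, ...) {
  dplyr::mutate(x$sources, farm_id = x$farm_id, .before = 1)
}

#' @export
#' @importFrom generics glance
glance.emission_inventory <- function(x, ...) {
  tibble::tibble(farm_id = x$farm_id, total_co2eq = x$total_co2eq,
                 allocation_applied = x$allocation_applied,
                 n_stable = x$n_flows$stable, n_pasture = x$n_flows$pasture,
                 n_mineral = x$n_flows$mineral)
}
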