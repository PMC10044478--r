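#' Net human-edible protein efficiency
#'
#' Human-edible protein leaving the farm as beef divided by human-edible
#' protein in the feed used to produce that beef. Edible output is carcass
#' mass times the carcass protein content times its edible share; edible
#' input sums ration dry matter times crude protein times each feed's
#' human-edible fraction, restricted to the beef-allocated share on farms
#' that also sell milk. Grass and by-products carry no edible protein, so a
#' grass-and-by-product system can exceed one -- a net contribution to
#' human nutrition. A zero edible-protein input returns `Inf` (documented
#' sentinel), never an error.
#'
#' @param carcass_kg kg carcass sold per year.
#' @param ration tibble with `kg_dm`, `cp` (g/kg DM), `hep_fraction`.
#' @param beef_share economic allocation share of feed use attributed to
#'   beef (1 on pure beef farms).
#' @param params model parameters.
#' @return a single ratio (possibly `Inf`).
#' @export
#' @examples
#' r <- tibble::tibble(kg_dm = 1000, cp = 120, hep_fraction = 0.8)
#' net_hep_efficiency(500, r)  # edible out / edible in
net_hep_efficiency <- function(carcass_kg, ration, beef_share = 1,
                               params = default_params()) {
  h <- params$hep
  out <- carcass_kg * h$beef_protein_kg_per_kg_carcass * h$beef_edible_share
  inp <- sum(ration$kg_dm * ration$cp / 1000 * ration$hep_fraction) *
    beef_share
  if (inp <= 0) return(Inf)
  out / inp
}

#' Work time per kg carcass with task breakdown
#'
#' Farm work time split into the task categories of the study's reporting:
#' herd feeding (proportional to conserved feed distributed), caretaking
#' and calving, pasture management (grazing activity area, 10 % higher
#' under fast rotational grazing), fieldwork for feed production (fodder
#' crops and forage cutting; cash-crop hours stay with the crops), and
#' administration/maintenance. On dairy farms only the beef-allocated share
#' counts toward the beef work-time indicator; work time embodied in
#' purchased animals is added per head.
#'
#' @param solution an optimal `farm_solution`.
#' @param beef_share economic allocation share (1 for pure beef farms).
#' @param params model parameters.
#' @return list: `min_per_kg`, `total_h`, `carcass_kg` and `breakdown`
#'   (tibble task/hours that sums to `total_h` exactly).
#' @export
work_time_per_kg <- function(solution, beef_share = 1,
                             params = solution$config$params) {
  stopifnot(inherits(solution, "farm_solution"),
            solution$status == "optimal")
  config <- solution$config
  lb <- params$labor
  cs <- class_summary(config$herd)
  po <- production_outputs(config, solution$herd)
  carcass_kg <- sum(po$carcass_kg)
  if (carcass_kg <= 0) stop("farm sells no carcass mass; work time per kg ",
                            "carcass is undefined", call. = FALSE)
  grass_feeds <- unique(config$grass$product[config$grass$type == "graze"])
  fed_indoors_t <- sum(solution$ration$kg_dm[
    !solution$ration$feed %in% grass_feeds]) / 1000
  feeding <- lb$feeding_h_t_dm * fed_indoors_t

  care <- sum(cs$n_head * lb$caretaking_h_head_yr[cs$care_key]) *
    solution$scale
  calving <- sum(cs$calvings_yr) * solution$scale * lb$calving_h

  acts <- solution$activities
  gmeta <- config$grass |>
    dplyr::group_by(activity = .data$activity) |>
    dplyr::summarise(labor = dplyr::first(.data$labor),
                     type = dplyr::first(.data$type), .groups = "drop")
  pasture <- sum(acts$ha[match(gmeta$activity[gmeta$type == "graze"],
                               acts$activity)] *
                   gmeta$labor[gmeta$type == "graze"], na.rm = TRUE)
  cutting <- sum(acts$ha[match(gmeta$activity[gmeta$type == "cut"],
                               acts$activity)] *
                   gmeta$labor[gmeta$type == "cut"], na.rm = TRUE)
  fodder_crops <- config$crops[config$crops$use == "fodder", ]
  fieldwork <- cutting +
    sum(acts$ha[match(fodder_crops$crop, acts$activity)] *
          fodder_crops$labor, na.rm = TRUE)
  admin <- lb$admin_fixed_h +
    lb$admin_h_lu * sum(cs$lu * cs$n_head) * solution$scale

  breakdown <- tibble::tibble(
    task = c("feeding", "caretaking", "calving", "pasture_management",
             "fieldwork_feed", "admin_maintenance"),
    hours = c(feeding, care, calving, pasture, fieldwork, admin))
  total_h <- sum(breakdown$hours)
  embodied_min <- sum(solution$herd$purchases) *
    config$purchase_embodied_wt
  list(min_per_kg = (total_h * 60 * beef_share + embodied_min) / carcass_kg,
       total_h = total_h, carcass_kg = carcass_kg, breakdown = breakdown)
}

#' Farm profit and its decomposition
#'
#' Recomputes profit from the primal solution as revenues (beef carcass,
#' live animal sales, transferred animals, milk, cash and surplus crops,
#' coupled and decoupled subsidies) minus costs (activity variable and
#' input costs, indoor feed distribution, purchased feed, mineral
#' fertilizer, veterinary and other per-head costs, purchased animals,
#' depreciation). The total equals the optimizer objective plus the fixed
#' terms to numerical precision -- an identity check on the model, not a
#' second model.
#'
#' @param solution an optimal `farm_solution`.
#' @return list: `profit` (EUR/yr) and `components` (tibble item/eur, whose
#'   sum is the profit).
#' @export
farm_profit <- function(solution) {
  stopifnot(inherits(solution, "farm_solution"),
            solution$status == "optimal")
  config <- solution$config
  params <- config$params
  po <- production_outputs(config, solution$herd)
  cs <- class_summary(config$herd)
  acts <- solution$activities
  grass_feeds <- unique(config$grass$product[config$grass$type == "graze"])

  gmeta <- config$grass |>
    dplyr::group_by(activity = .data$activity) |>
    dplyr::summarise(variable_cost = dplyr::first(.data$variable_cost),
                     .groups = "drop")
  grass_cost <- sum(acts$ha[match(gmeta$activity, acts$activity)] *
                      gmeta$variable_cost, na.rm = TRUE)
  crop_cost <- sum(acts$ha[match(config$crops$crop, acts$activity)] *
                     config$crops$input_cost, na.rm = TRUE)
  cash_crops <- config$crops[config$crops$use == "cash", ]
  cash_rev <- sum(acts$ha[match(cash_crops$crop, acts$activity)] *
                    cash_crops$yield *
                    unlist(config$prices$crops[cash_crops$crop]),
                  na.rm = TRUE)
  sale_rev <- sum(solution$sales$t_fresh *
                    unlist(config$prices$crops[solution$sales$crop]))
  cat_feeds <- feed_catalogue()
  feed_cost <- sum(solution$purchases$t_fresh *
                     cat_feeds$price[match(solution$purchases$feed,
                                           cat_feeds$feed)])
  feed_out_cost <- params$prices$feed_out *
    sum(solution$ration$kg_dm[!solution$ration$feed %in% grass_feeds])
  vet <- sum(cs$n_head * cs$vet_cost) * solution$scale
  animal_purch <- sum(cs$in_purchase_yr *
                        dplyr::coalesce(cs$purchase_price, 0)) *
    solution$scale
  coupled <- sum(cs$n * cs$coupled_subsidy * (cs$ctype == "stock")) *
    solution$scale

  components <- tibble::tibble(
    item = c("beef_revenue", "live_sales", "transfers_out", "milk_revenue",
             "crop_revenue", "coupled_subsidy", "decoupled_subsidy",
             "grassland_costs", "crop_costs", "feed_purchase",
             "feed_distribution", "fertilizer", "vet_other",
             "animal_purchase", "depreciation"),
    eur = c(sum(po$carcass_revenue), sum(po$live_revenue),
            sum(po$heads_transferred) * (config$prices$weanling %||% 0),
            sum(po$milk_kg) * config$prices$milk,
            cash_rev + sale_rev, coupled, config$subsidy$decoupled,
            -grass_cost, -crop_cost, -feed_cost, -feed_out_cost,
            -solution$fert_n * params$prices$fert_n, -vet, -animal_purch,
            -config$depreciation))
  list(profit = sum(components$eur), components = components)
}

#' Stocking rate on permanent grassland
#'
#' Livestock units per hectare of permanent grassland; other land could in
#' principle produce human-edible food, so only permanent grassland enters
#' the denominator.
#'
#' @param config a `farm_config`.
#' @param herd monthly herd table (scaled); defaults to the configured herd.
#' @return LU per ha (single number).
#' @export
stocking_rate <- function(config, herd = cohort_progression(config)) {
  if (config$grassland_ha <= 0)
    stop("farm has no permanent grassland", call. = FALSE)
  cs <- class_summary(config$herd)
  avg_heads <- herd |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(heads = mean(.data$heads), .groups = "drop")
  lu <- sum(avg_heads$heads * cs$lu[match(avg_heads$class, cs$class)])
  lu / config$grassland_ha
}

#' All four sustainability indicators for one solved farm
#'
#' Convenience wrapper computing global warming potential per kg carcass,
#' net human-edible protein efficiency, work time per kg carcass and farm
#' profit (plus the stocking rate) from one optimal solution, applying
#' milk/beef economic allocation where the farm sells milk.
#'
#' @param solution an optimal `farm_solution`.
#' @param inventory optional precomputed [farm_inventory()].
#' @return a one-row tibble (class `indicator_set`).
#' @export
indicator_set <- function(solution, inventory = farm_inventory(solution)) {
  config <- solution$config
  po <- production_outputs(config, solution$herd)
  has_milk <- sum(po$milk_kg) > 0
  al <- if (has_milk) allocate_milk_beef(solution) else
    list(beef_share = 1, milk_share = 0)
  carcass <- sum(po$carcass_kg)
  gwp <- if (carcass > 0)
    inventory$total_co2eq * al$beef_share / carcass else NA_real_
  wt <- if (carcass > 0)
    work_time_per_kg(solution, beef_share = al$beef_share)$min_per_kg else
      NA_real_
  hep <- if (carcass > 0)
    net_hep_efficiency(carcass, solution$ration, al$beef_share,
                       config$params) else NA_real_
  sr <- if (config$grassland_ha > 0)
    stocking_rate(config, solution$herd) else NA_real_
  out <- tibble::tibble(
    farm_id = config$farm_id, system = config$system,
    scenario = config$scenario,
    gwp_per_kg = gwp, net_hep = hep, wt_min_per_kg = wt,
    profit = solution$profit, stocking_rate = sr,
    carcass_kg = carcass, beef_share = al$beef_share)
  class(out) <- c("indicator_set", class(out))
  out
}
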