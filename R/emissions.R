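#' Enteric methane from a ration
#'
#' Tier-2-style form: CH4 = GE_intake * Ym / 55.65 MJ/kg, with gross energy
#' intake taken as dry-matter intake times a fixed gross-energy density of
#' feed (default 18.45 MJ GE/kg DM, equivalent to a 10.1 MJ ME/kg DM ration
#' at an ME/GE ratio of 0.55). Because GE rides on dry matter while animal
#' needs are set in ME, a better-quality (higher ME density) ration meets
#' the same energy requirement with less DM and therefore emits less
#' methane -- the lever by which improved pasture quality cuts enteric
#' emissions.
#'
#' @param ration tibble with columns `kg_dm` and (optionally) `me`; only
#'   `kg_dm` enters the emission, `me` is carried for energy accounting.
#' @param params model parameters ([default_params()]); uses
#'   `enteric$ym`, `enteric$ch4_energy`, `enteric$ge_density`.
#' @return kg CH4 (single number).
#' @export
#' @examples
#' enteric_methane(tibble::tibble(kg_dm = 1000))
enteric_methane <- function(ration, params = default_params()) {
  if (nrow(ration) == 0) return(0)
  if (any(ration$kg_dm < 0)) stop("negative intake", call. = FALSE)
  e <- params$enteric
  ge <- sum(ration$kg_dm) * e$ge_density
  ge * e$ym / e$ch4_energy
}

#' Manure and soil emissions from nitrogen flows
#'
#' Linear factor model for the nitrogen pathway: methane from manure
#' storage (distinct factors for solid and liquid systems), nitrous oxide
#' from storage, and direct plus indirect (volatilisation, leaching)
#' nitrous oxide from field application of manure, pasture-deposited
#' excreta and mineral fertilizer. All factors live in
#' `default_params()$nitrogen` and can be zeroed to disable a pathway.
#'
#' @param n_stable kg N excreted in the stable (enters storage).
#' @param n_pasture kg N excreted on pasture.
#' @param n_mineral kg mineral fertilizer N applied.
#' @param manure_system `"solid"` or `"liquid"`.
#' @param params model parameters.
#' @return list: `manure_ch4`, `manure_n2o`, `soil_n2o` (kg of each gas).
#' @export
#' @examples
#' manure_soil_emissions(1000, 400, 2000, "solid")
manure_soil_emissions <- function(n_stable, n_pasture, n_mineral,
                                  manure_system = c("solid", "liquid"),
                                  params = default_params()) {
  manure_system <- match.arg(manure_system)
  stopifnot(n_stable >= 0, n_pasture >= 0, n_mineral >= 0)
  p <- params$nitrogen
  conv <- p$n2o_n_to_n2o
  manure_ch4 <- p$manure_ch4[[manure_system]] * n_stable
  manure_n2o <- p$ef_n2o_storage[[manure_system]] * n_stable * conv
  n_applied <- n_stable * (1 - p$storage_loss)
  direct <- p$ef_n2o_direct * (n_applied + n_pasture + n_mineral)
  indirect <- p$ef_n2o_volat * p$frac_volat * (n_stable + n_mineral) +
    p$ef_n2o_leach * p$frac_leach * (n_applied + n_pasture + n_mineral)
  list(manure_ch4 = unname(manure_ch4),
       manure_n2o = unname(manure_n2o),
       soil_n2o = unname((direct + indirect) * conv))
}

#' Upstream emissions of purchased inputs and field operations
#'
#' Sum of quantity times emission factor over a basket of bought inputs
#' (feed, fertilizer, purchased animals) and services. A missing emission
#' factor is an error, never a silent zero; negative quantities are
#' rejected.
#'
#' @param basket tibble with columns `item`, `quantity` and `ef`
#'   (kg CO2eq per unit of `quantity`).
#' @return kg CO2eq.
#' @export
#' @examples
#' upstream_emissions(tibble::tibble(item = c("soymeal", "fert_n"),
#'                                   quantity = c(10, 500),
#'                                   ef = c(1600, 5.5)))
upstream_emissions <- function(basket) {
  if (nrow(basket) == 0) return(0)
  if (any(basket$quantity < 0))
    stop("negative purchase quantity for: ",
         paste(basket$item[basket$quantity < 0], collapse = ", "),
         call. = FALSE)
  if (anyNA(basket$ef))
    stop("missing emission factor for: ",
         paste(basket$item[is.na(basket$ef)], collapse = ", "),
         call. = FALSE)
  sum(basket$quantity * basket$ef)
}

#' Characterize a gas inventory to global warming potential
#'
#' Exact linear combination of gas masses and characterization factors
#' (kg CO2eq per kg gas). Gases without a factor are an error.
#'
#' @param masses named numeric vector of gas masses, names among
#'   `names(factors)`; a `co2eq` entry passes through with factor 1.
#' @param factors named characterization factors; defaults to the package's
#'   GWP100-style set (CH4 34, N2O 298).
#' @return kg CO2eq.
#' @export
#' @examples
#' characterize_gwp(c(ch4 = 1, n2o = 1, co2 = 10))
characterize_gwp <- function(masses, factors = default_params()$gwp) {
  factors <- c(factors, co2eq = 1)
  miss <- setdiff(names(masses), names(factors))
  if (length(miss))
    stop("no characterization factor for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sum(masses * factors[names(masses)])
}

#' Cradle-to-farm-gate emission inventory of a solved farm
#'
#' Assembles per-source gas masses from an optimal [solve_farm()] solution:
#' enteric fermentation (CH4), manure storage (CH4, N2O), soil N2O from
#' applied and deposited nitrogen, on-farm diesel CO2, and upstream CO2eq
#' embodied in purchased feed, mineral fertilizer, field inputs and
#' purchased animals. Nitrogen flows are derived from the optimal rations
#' via [excreta_nitrogen()], with grazing days proportional to the grazed
#' share of ration dry matter.
#'
#' @param solution an optimal `farm_solution`.
#' @param params model parameters (defaults to the farm's).
#' @return object of class `emission_inventory`: a list with `sources`
#'   (tibble: source, gas, mass_kg, co2eq), `total_co2eq`,
#'   `n_flows` (kg N by location), and `allocation_applied` (1 until
#'   [allocate_milk_beef()] is applied).
#' @export
farm_inventory <- function(solution, params = solution$config$params) {
  stopifnot(inherits(solution, "farm_solution"),
            solution$status == "optimal")
  config <- solution$config
  ration <- solution$ration
  grass_feeds <- unique(config$grass$product[config$grass$type == "graze"])

  ent <- enteric_methane(ration, params)

  ret <- params$retention[config$herd$ret_key]
  names(ret) <- config$herd$class
  n_by_class <- ration |>
    dplyr::group_by(.data$class, .data$month) |>
    dplyr::summarise(
      n_in = sum(.data$kg_dm * .data$cp / 1000) * params$nitrogen$cp_to_n,
      graze_share = sum(.data$kg_dm[.data$feed %in% grass_feeds]) /
        sum(.data$kg_dm), .groups = "drop") |>
    dplyr::mutate(n_exc = .data$n_in * (1 - ret[.data$class]),
                  n_pasture = .data$n_exc * .data$graze_share,
                  n_stable = .data$n_exc * (1 - .data$graze_share))
  n_stable <- sum(n_by_class$n_stable)
  n_pasture <- sum(n_by_class$n_pasture)

  ms <- manure_soil_emissions(n_stable, n_pasture, solution$fert_n,
                              config$manure_system, params)

  acts <- solution$activities
  act_meta <- dplyr::bind_rows(
    config$grass |>
      dplyr::group_by(activity = .data$activity) |>
      dplyr::summarise(diesel = dplyr::first(.data$diesel),
                       upstream_ef = dplyr::first(.data$upstream_ef),
                       .groups = "drop"),
    config$crops |>
      dplyr::transmute(activity = .data$crop, diesel = .data$diesel,
                       upstream_ef = .data$upstream_ef))
  am <- dplyr::left_join(acts, act_meta, by = "activity")
  energy_co2 <- sum(am$ha * am$diesel, na.rm = TRUE) *
    params$upstream$diesel_ef

  cat_feeds <- feed_catalogue()
  feed_basket <- solution$purchases |>
    dplyr::left_join(cat_feeds[, c("feed", "upstream_ef")], by = "feed") |>
    dplyr::transmute(item = .data$feed, quantity = pmax(0, .data$t_fresh),
                     ef = .data$upstream_ef)
  heads_in <- sum(solution$herd$purchases)
  basket <- dplyr::bind_rows(
    feed_basket,
    tibble::tibble(item = "fert_n", quantity = solution$fert_n,
                   ef = params$upstream$fert_n_ef),
    tibble::tibble(item = "field_inputs",
                   quantity = sum(am$ha * am$upstream_ef, na.rm = TRUE),
                   ef = 1),
    tibble::tibble(item = "purchased_animals", quantity = heads_in,
                   ef = config$purchase_embodied_ef))
  up <- upstream_emissions(basket)

  sources <- tibble::tibble(
    source = c("enteric_ch4", "manure_ch4", "manure_n2o", "soil_n2o",
               "energy_co2", "upstream_co2eq"),
    gas = c("ch4", "ch4", "n2o", "n2o", "co2", "co2eq"),
    mass_kg = c(ent, ms$manure_ch4, ms$manure_n2o, ms$soil_n2o,
                energy_co2, up))
  sources$co2eq <- vapply(seq_len(nrow(sources)), function(i)
    characterize_gwp(stats::setNames(sources$mass_kg[i], sources$gas[i]),
                     params$gwp), numeric(1))
  structure(list(farm_id = config$farm_id, sources = sources,
                 total_co2eq = sum(sources$co2eq),
                 n_flows = list(stable = n_stable, pasture = n_pasture,
                                mineral = solution$fert_n),
                 allocation_applied = 1),
            class = "emission_inventory")
}

#' @export
print.emission_inventory <- function(x, ...) {
  cat("<emission_inventory> ", x$farm_id, ": ",
      format(round(x$total_co2eq)), " kg CO2eq (allocation ",
      round(x$allocation_applied, 3), ")\n", sep = "")
  invisible(x)
}

#' Economic allocation between milk and beef
#'
#' Splits a farm's burden between its milk and beef co-products in
#' proportion to their economic value. Beef value covers carcass sales,
#' live calf sales and transferred animals; milk value is milk quantity
#' times its market price, or times its shadow price from the optimization
#' when no market price is configured. Shares sum to one exactly.
#'
#' @param solution an optimal `farm_solution`.
#' @param milk_price overrides the milk valuation (EUR/kg); defaults to the
#'   configured market price, falling back to [shadow_price()].
#' @return list with `beef_share`, `milk_share`, `beef_value`,
#'   `milk_value`.
#' @export
allocate_milk_beef <- function(solution, milk_price = NULL) {
  po <- production_outputs(solution$config, solution$herd)
  beef_value <- sum(po$carcass_revenue) + sum(po$live_revenue) +
    sum(po$heads_transferred) * (solution$config$prices$weanling %||% 0)
  milk_kg <- sum(po$milk_kg)
  if (is.null(milk_price)) milk_price <- shadow_price(solution, "milk")
  milk_value <- milk_kg * milk_price
  tot <- beef_value + milk_value
  if (tot <= 0) stop("no product with positive value", call. = FALSE)
  list(beef_share = beef_value / tot, milk_share = milk_value / tot,
       beef_value = beef_value, milk_value = milk_value)
}

#' Embodied emissions and work time of transferred animals
#'
#' For a breeder (or dairy) farm selling live animals downstream, splits
#' the farm's beef-allocated burden across its animal outputs by economic
#' value and expresses the share carried by the transferred animals per kg
#' live weight. Implementing these as emission factors on the receiving
#' farm's purchases conserves the system total exactly: breeder plus
#' fattener own emissions equal the chain total, with no double counting.
#'
#' @param solution optimal `farm_solution` of the upstream farm.
#' @param inventory its [farm_inventory()].
#' @param work_time_h optional total farm work time (h/yr) to embody
#'   alongside emissions; 0 to skip.
#' @return list of class `transfer_record`: `kg_liveweight`, `heads`,
#'   `embodied_ef` (kg CO2eq/kg LW), `embodied_ef_head` (kg CO2eq/head),
#'   `embodied_wt_head` (min/head), `value_share`.
#' @export
transfer_embodied <- function(solution, inventory, work_time_h = 0) {
  po <- production_outputs(solution$config, solution$herd)
  kg_lw <- sum(po$transfer_live_kg)
  heads <- sum(po$heads_transferred)
  if (kg_lw <= 0) stop("farm ", solution$config$farm_id,
                       " transfers no animals", call. = FALSE)
  al <- allocate_milk_beef(solution)
  transfer_value <- heads * (solution$config$prices$weanling %||% 0)
  value_share <- transfer_value / al$beef_value
  gwp_beef <- inventory$total_co2eq * al$beef_share
  embodied <- gwp_beef * value_share
  structure(list(kg_liveweight = kg_lw, heads = heads,
                 embodied_ef = embodied / kg_lw,
                 embodied_ef_head = embodied / heads,
                 embodied_wt_head = work_time_h * al$beef_share *
                   value_share * 60 / max(heads, .Machine$double.eps),
                 value_share = value_share),
            class = "transfer_record")
}

#' System-level global warming potential per kg carcass
#'
#' The functional unit: total beef-allocated emissions of all farms of a
#' system divided by the total carcass mass sold by the system (culled
#' cows, heifers and bulls; transferred live animals are intermediate and
#' carry their burden downstream, not into the denominator).
#'
#' @param solutions list of optimal `farm_solution`s.
#' @param inventories list of matching [farm_inventory()] objects.
#' @param allocations optional list of [allocate_milk_beef()] results (or
#'   `NULL` entries for beef-only farms).
#' @return list: `gwp_per_kg` (kg CO2eq/kg carcass), `total_co2eq`,
#'   `carcass_kg`.
#' @export
system_gwp_per_kg_carcass <- function(solutions, inventories,
                                      allocations = NULL) {
  stopifnot(length(solutions) == length(inventories))
  tot <- 0; kg <- 0
  for (i in seq_along(solutions)) {
    sol <- solutions[[i]]
    po <- production_outputs(sol$config, sol$herd)
    share <- if (!is.null(allocations) && !is.null(allocations[[i]]))
      allocations[[i]]$beef_share else 1
    tot <- tot + inventories[[i]]$total_co2eq * share
    kg <- kg + sum(po$carcass_kg)
  }
  if (kg <= 0) stop("system sells no carcass mass", call. = FALSE)
  list(gwp_per_kg = tot / kg, total_co2eq = tot, carcass_kg = kg)
}
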