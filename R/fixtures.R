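#' Synthetic fixtures for the three stylised beef production systems
#'
#' `build_system_fixture()` produces complete, self-contained farm
#' configurations for the three studied systems -- a Belgian Blue
#' breeder/fattener pair (`BE`), a French suckler farm shipping weanlings to
#' an Italian fattener (`FR-IT`), and an integrated German dairy/cash-crop
#' farm fattening its own male calves (`GE`) -- under the baseline, the
#' fast-rotational-grazing scenario (`FRG`) and the system-redesign
#' scenario (`SR`, crossbreeding with sexed semen). Headline endowments
#' (cow numbers, male sales, land areas) follow the published system
#' overview; every other coefficient (feed composition, prices not printed,
#' requirement and emission factors) is a documented package default, so
#' absolute economic and emission levels are illustrative rather than a
#' reproduction of the original case studies.
#'
#' @param system `"BE"`, `"FR-IT"` or `"GE"`.
#' @param scenario `"base"`, `"FRG"` or `"SR"`.
#' @param seed integer seed controlling the within-season jitter of grass
#'   profiles; fixtures are bit-identical for equal seeds.
#' @param params model parameters, see [default_params()].
#' @return a named list of `farm_config` objects (one or two farms).
#' @export
#' @examples
#' fx <- build_system_fixture("BE", "base")
#' names(fx)
#' fx$`BE-B`$herd
build_system_fixture <- function(system = c("BE", "FR-IT", "GE"),
                                 scenario = c("base", "FRG", "SR"),
                                 seed = 1L, params = default_params()) {
  system <- match.arg(system)
  scenario <- match.arg(scenario)
  base <- switch(system,
    "BE" = list("BE-B" = farm_be_breeder(seed, params),
                "BE-F" = farm_be_fattener(seed, params)),
    "FR-IT" = list("FR-IT-B" = farm_fr_breeder(seed, params),
                   "FR-IT-F" = farm_it_fattener(seed, params)),
    "GE" = list("GE" = farm_ge_dairy(seed, params)))
  apply_scenario(base, scenario, seed = seed, params = params)
}

# ---- herd specification helper ---------------------------------------------

herd_row <- function(class, ctype, breed, n, entry_mo = NA, exit_mo = NA,
                     entry_kg = NA, exit_kg = NA, weight_kg = NA,
                     cy = NA, lu, milk_sold_kg_yr = 0, milk_req_kg_yr = 0,
                     suckle_me = 0, suckle_cp = 0, fiber_floor = 0.3,
                     graze_months = list(integer(0)),
                     out_carcass_yr = 0, price_carcass = NA,
                     out_live_yr = 0, live_price = NA,
                     out_transfer_yr = 0, transfer_kg = NA,
                     in_purchase_yr = 0, purchase_price = NA,
                     vet_cost = 80, coupled_subsidy = 0, calvings_yr = 0,
                     ret_key = class, care_key = class) {
  tibble::tibble(class = class, ctype = ctype, breed = breed, n = n,
                 entry_mo = entry_mo, exit_mo = exit_mo,
                 entry_kg = entry_kg, exit_kg = exit_kg,
                 weight_kg = weight_kg, cy = cy, lu = lu,
                 milk_sold_kg_yr = milk_sold_kg_yr,
                 milk_req_kg_yr = milk_req_kg_yr,
                 suckle_me = suckle_me, suckle_cp = suckle_cp,
                 fiber_floor = fiber_floor, graze_months = graze_months,
                 out_carcass_yr = out_carcass_yr,
                 price_carcass = price_carcass,
                 out_live_yr = out_live_yr, live_price = live_price,
                 out_transfer_yr = out_transfer_yr, transfer_kg = transfer_kg,
                 in_purchase_yr = in_purchase_yr,
                 purchase_price = purchase_price,
                 vet_cost = vet_cost, coupled_subsidy = coupled_subsidy,
                 calvings_yr = calvings_yr,
                 ret_key = ret_key, care_key = care_key)
}

#' Derived per-class quantities of a herd specification
#'
#' Adds average head count, mean live weight, daily gain, carcass weight per
#' head and class duration to a herd specification. Flow classes (`ctype ==
#' "flow"`) are assumed to enter uniformly over the year, so the average
#' stock is `inflow * duration / 12`; stock classes keep their head count.
#'
#' @param herd herd specification tibble (see [build_system_fixture()]).
#' @return the tibble with columns `n_head`, `inflow_yr`, `months`,
#'   `avg_kg`, `adg`, `carcass_kg` appended.
#' @export
class_summary <- function(herd) {
  herd |>
    dplyr::mutate(
      months = ifelse(.data$ctype == "flow",
                      .data$exit_mo - .data$entry_mo, NA),
      inflow_yr = ifelse(.data$ctype == "flow", .data$n, NA),
      n_head = ifelse(.data$ctype == "flow",
                      .data$n * .data$months / 12, .data$n),
      avg_kg = ifelse(.data$ctype == "flow",
                      (.data$entry_kg + .data$exit_kg) / 2, .data$weight_kg),
      adg = ifelse(.data$ctype == "flow",
                   (.data$exit_kg - .data$entry_kg) /
                     (.data$months * 30.4), 0),
      carcass_kg = ifelse(.data$out_carcass_yr > 0,
                          ifelse(.data$ctype == "flow",
                                 .data$exit_kg, .data$weight_kg) * .data$cy,
                          0))
}

new_farm_config <- function(farm_id, system, role, arable_ha, grassland_ha,
                            stable_places, herd, grass, crops, class_feeds,
                            prices, subsidy, manure_system, depreciation,
                            params, scenario = "base",
                            weanling_supply = Inf,
                            purchase_embodied_ef = 0,
                            purchase_embodied_wt = 0) {
  stopifnot(arable_ha >= 0, grassland_ha >= 0, stable_places >= 0)
  cfg <- structure(list(
    farm_id = farm_id, system = system, scenario = scenario, role = role,
    arable_ha = arable_ha, grassland_ha = grassland_ha,
    stable_places = stable_places, herd = herd, grass = grass,
    crops = crops, class_feeds = class_feeds, prices = prices,
    subsidy = subsidy, manure_system = manure_system,
    depreciation = depreciation, params = params,
    weanling_supply = weanling_supply,
    purchase_embodied_ef = purchase_embodied_ef,
    purchase_embodied_wt = purchase_embodied_wt),
    class = "farm_config")
  validate_farm_config(cfg)
  cfg
}

validate_farm_config <- function(cfg) {
  feeds <- feed_catalogue()
  grass_products <- unique(cfg$grass$product[cfg$grass$type == "graze"])
  known <- c(feeds$feed, grass_products)
  for (cl in names(cfg$class_feeds)) {
    bad <- setdiff(cfg$class_feeds[[cl]], known)
    if (length(bad))
      stop("farm ", cfg$farm_id, ": unknown feeds for class ", cl, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!cl %in% cfg$herd$class)
      stop("farm ", cfg$farm_id, ": class_feeds names unknown class ", cl,
           call. = FALSE)
  }
  for (cl in cfg$herd$class)
    if (is.null(cfg$class_feeds[[cl]]))
      stop("farm ", cfg$farm_id, ": no feed list for class ", cl,
           call. = FALSE)
  sellable <- cfg$crops$crop[cfg$crops$use %in% c("cash", "dual")]
  miss <- setdiff(sellable, names(cfg$prices$crops))
  if (length(miss))
    stop("farm ", cfg$farm_id, ": missing sale price for crop(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.farm_config <- function(x, ...) {
  cat("<farm_config> ", x$farm_id, " (", x$system, ", ", x$scenario,
      ", ", x$role, ")\n", sep = "")
  cat("  land: ", x$arable_ha, " ha arable, ", x$grassland_ha,
      " ha permanent grassland; stable ", x$stable_places, " LU places\n",
      sep = "")
  cat("  herd classes: ", paste(x$herd$class, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# ---- crop activity tables ---------------------------------------------------

crops_be <- function() tibble::tribble(
  ~crop,          ~use,     ~yield, ~input_cost, ~labor, ~n_removal, ~upstream_ef, ~diesel,
  "wheat",        "dual",   8.5,    620,         9,      180,        520,          85,
  "sugar_beet",   "cash",   85,     1450,        14,     160,        680,          110,
  "maize_silage", "fodder", 16,     750,         8,      170,        560,          95)

crops_ge <- function() tibble::tribble(
  ~crop,          ~use,     ~yield, ~input_cost, ~labor, ~n_removal, ~upstream_ef, ~diesel,
  "wheat",        "dual",   8.8,    560,         8,      175,        480,          80,
  "barley",       "dual",   7.8,    520,         8,      150,        460,          78,
  "sugar_beet",   "cash",   88,     1380,        13,     160,        650,          105,
  "maize_silage", "fodder", 17,     760,         8,      175,        570,          95)

crops_it <- function() tibble::tribble(
  ~crop,          ~use,     ~yield, ~input_cost, ~labor, ~n_removal, ~upstream_ef, ~diesel,
  "maize_silage", "fodder", 18,     820,         8,      185,        600,          100)

crops_none <- function() crops_be()[0, ]

# ---- baseline farms ---------------------------------------------------------

# Belgian Blue breeder: 155 suckler cows, 54 ha arable + 64 ha grassland,
# sells 78 male weanlings/yr plus culled cows and surplus heifers.
farm_be_breeder <- function(seed = 1L, params = default_params()) {
  cows <- 155; males_sold <- 78
  weaned <- 2 * males_sold          # net weaned calves per year
  repl <- 0.30 * cows               # replacement heifers entering per year
  herd <- dplyr::bind_rows(
    herd_row("suckler_cow", "stock", "Belgian Blue", cows, weight_kg = 700,
             cy = 0.55, lu = 1.0, milk_req_kg_yr = 1690,
             fiber_floor = 0.55, graze_months = list(4:10),
             out_carcass_yr = repl, price_carcass = 3.0, vet_cost = 120,
             coupled_subsidy = 110, calvings_yr = weaned,
             ret_key = "cow", care_key = "cow"),
    herd_row("calf", "flow", "Belgian Blue", weaned, 0, 8, 45, 300,
             lu = 0.4, suckle_me = 32, suckle_cp = 215, fiber_floor = 0.30,
             graze_months = list(4:10),
             out_transfer_yr = males_sold, transfer_kg = 300,
             vet_cost = 60, ret_key = "calf", care_key = "calf"),
    herd_row("heifer", "flow", "Belgian Blue", males_sold, 8, 30, 300, 620,
             cy = 0.58, lu = 0.6, fiber_floor = 0.50,
             graze_months = list(4:10),
             out_carcass_yr = males_sold - repl, price_carcass = 4.0,
             vet_cost = 70, ret_key = "heifer", care_key = "heifer"))
  grass_products <- c("grass_graze_cg")
  new_farm_config(
    "BE-B", "BE", "breeder", arable_ha = 54, grassland_ha = 64,
    stable_places = 290, herd = herd,
    grass = grassland_activities("BE", frg = FALSE, seed = seed),
    crops = crops_be(),
    class_feeds = list(
      suckler_cow = c(grass_products, "grass_silage", "hay",
                      "maize_silage", "barley", "soymeal"),
      calf = c(grass_products, "hay", "barley", "soymeal"),
      heifer = c(grass_products, "grass_silage", "hay", "maize_silage",
                 "barley")),
    prices = list(milk = 0.35, weanling = 870,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 280 * (54 + 64)),
    manure_system = "solid", depreciation = 35000, params = params)
}

# Belgian fattener: landless, buys the breeder's weanlings, fattens indoors
# on purchased maize silage and concentrates.
farm_be_fattener <- function(seed = 1L, params = default_params()) {
  herd <- herd_row("bull", "flow", "Belgian Blue", 78, 8, 19, 300, 710,
                   cy = 0.68, lu = 0.6, fiber_floor = 0.30,
                   out_carcass_yr = 78, price_carcass = 3.6,
                   in_purchase_yr = 78, purchase_price = 870,
                   vet_cost = 90, ret_key = "bull", care_key = "bull")
  new_farm_config(
    "BE-F", "BE", "fattener", arable_ha = 0, grassland_ha = 0,
    stable_places = 66, herd = herd,   # 120 bull places (Table-scale farm)
    grass = grassland_activities("BE", seed = seed)[0, ], crops = crops_none(),
    class_feeds = list(
      bull = c("maize_silage", "grass_silage", "hay", "wheat", "barley",
               "soymeal", "beet_pulp_pressed")),
    prices = list(milk = 0.35, weanling = 870,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 0),
    manure_system = "solid", depreciation = 20000, params = params,
    weanling_supply = 120)
}

# French suckler farm (Massif Central): 79 Charolais/Salers cows on 96 ha
# of permanent grassland, 38 male weanlings shipped to Italy per year.
farm_fr_breeder <- function(seed = 1L, params = default_params()) {
  cows <- 79; males_sold <- 38
  weaned <- 2 * males_sold
  repl <- 0.32 * cows
  herd <- dplyr::bind_rows(
    herd_row("suckler_cow", "stock", "Charolais/Salers", cows,
             weight_kg = 720, cy = 0.50, lu = 1.0, milk_req_kg_yr = 1750,
             fiber_floor = 0.60, graze_months = list(5:9),
             out_carcass_yr = repl, price_carcass = 2.8, vet_cost = 110,
             coupled_subsidy = 90, calvings_yr = weaned,
             ret_key = "cow", care_key = "cow"),
    herd_row("calf", "flow", "Charolais/Salers", weaned, 0, 9, 45, 320,
             lu = 0.4, suckle_me = 32, suckle_cp = 215, fiber_floor = 0.35,
             graze_months = list(5:9),
             out_transfer_yr = males_sold, transfer_kg = 320,
             vet_cost = 60, ret_key = "calf", care_key = "calf"),
    herd_row("heifer", "flow", "Charolais/Salers", males_sold, 9, 33,
             320, 600, cy = 0.55, lu = 0.6, fiber_floor = 0.55,
             graze_months = list(5:9),
             out_carcass_yr = males_sold - repl, price_carcass = 3.8,
             vet_cost = 70, ret_key = "heifer", care_key = "heifer"))
  new_farm_config(
    "FR-IT-B", "FR-IT", "breeder", arable_ha = 0, grassland_ha = 96,
    stable_places = 165, herd = herd,
    grass = grassland_activities("FR-IT", frg = FALSE, seed = seed),
    crops = crops_none(),
    class_feeds = list(
      suckler_cow = c("grass_graze_cg", "grass_silage", "hay", "barley"),
      calf = c("grass_graze_cg", "hay", "barley", "soymeal"),
      heifer = c("grass_graze_cg", "grass_silage", "hay", "barley")),
    prices = list(milk = 0.35, weanling = 960,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 280 * 96),
    manure_system = "solid", depreciation = 25000, params = params)
}

# Italian fattener (Veneto): 33 ha of irrigated maize, fattens the French
# weanlings indoors.
farm_it_fattener <- function(seed = 1L, params = default_params()) {
  herd <- herd_row("bull", "flow", "Charolais cross", 38, 9, 17, 320, 700,
                   cy = 0.60, lu = 0.6, fiber_floor = 0.30,
                   out_carcass_yr = 38, price_carcass = 3.9,
                   in_purchase_yr = 38, purchase_price = 960,
                   vet_cost = 90, ret_key = "bull", care_key = "bull")
  new_farm_config(
    "FR-IT-F", "FR-IT", "fattener", arable_ha = 33, grassland_ha = 0,
    stable_places = 91, herd = herd,   # 227 bull places (Table-scale farm)
    grass = grassland_activities("FR-IT", seed = seed)[0, ],
    crops = crops_it(),
    class_feeds = list(
      bull = c("maize_silage", "grass_silage", "hay", "wheat", "barley",
               "soymeal", "beet_pulp_pressed")),
    prices = list(milk = 0.35, weanling = 960,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 280 * 33),
    manure_system = "solid", depreciation = 28000, params = params,
    weanling_supply = 227)
}

# German integrated dairy/cash-crop farm: 130 Holstein cows, fattens its own
# 56 male calves per year; liquid manure system.
farm_ge_dairy <- function(seed = 1L, params = default_params()) {
  cows <- 130; males <- 56
  calvings <- 0.95 * cows            # 123.5 calves born per year
  repl <- 0.35 * cows                # 45.5 replacement heifers per year
  reared <- repl + males
  surplus <- calvings - reared       # calves sold at two weeks
  herd <- dplyr::bind_rows(
    herd_row("dairy_cow", "stock", "Holstein", cows, weight_kg = 650,
             cy = 0.50, lu = 1.0, milk_sold_kg_yr = 8500,
             milk_req_kg_yr = 8500, fiber_floor = 0.40,
             graze_months = list(4:10),
             out_carcass_yr = repl, price_carcass = 2.2, vet_cost = 250,
             out_live_yr = surplus, live_price = 150,
             coupled_subsidy = 0, calvings_yr = calvings,
             ret_key = "dairy_cow", care_key = "dairy_cow"),
    herd_row("dairy_calf", "flow", "Holstein", reared, 0, 2, 45, 65,
             lu = 0.4, fiber_floor = 0.10,
             vet_cost = 50, ret_key = "calf", care_key = "calf"),
    herd_row("heifer", "flow", "Holstein", repl, 2, 27, 65, 600,
             lu = 0.6, fiber_floor = 0.55, graze_months = list(4:10),
             vet_cost = 70, ret_key = "heifer", care_key = "heifer"),
    herd_row("bull", "flow", "Holstein", males, 2, 19, 65, 630,
             cy = 0.52, lu = 0.6, fiber_floor = 0.30,
             out_carcass_yr = males, price_carcass = 3.3,
             vet_cost = 90, ret_key = "bull", care_key = "bull"))
  new_farm_config(
    "GE", "GE", "integrated", arable_ha = 198, grassland_ha = 27,
    stable_places = 250, herd = herd,
    grass = grassland_activities("GE", frg = FALSE, seed = seed),
    crops = crops_ge(),
    class_feeds = list(
      dairy_cow = c("grass_graze_cg", "grass_silage", "maize_silage", "hay",
                    "wheat", "barley", "soymeal", "beet_pulp_pressed"),
      dairy_calf = c("milk_replacer", "barley", "soymeal", "hay"),
      heifer = c("grass_graze_cg", "grass_silage", "hay", "maize_silage",
                 "barley"),
      bull = c("maize_silage", "grass_silage", "hay", "wheat", "barley",
               "soymeal", "beet_pulp_pressed")),
    prices = list(milk = 0.35, weanling = 870,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 280 * (198 + 27)),
    manure_system = "liquid", depreciation = 60000, params = params)
}
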