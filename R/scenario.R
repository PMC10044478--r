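#' Scenario transforms: fast rotational grazing and system redesign
#'
#' `apply_scenario()` turns a set of baseline farm configurations into a
#' scenario variant. The baseline is the identity transform. The `FRG`
#' transform is purely additive: every farm with permanent grassland gains a
#' fast-rotational-grazing activity (37.5 EUR/ha/yr dearer and 10 % more
#' pasture work time than continuous grazing) and all grazing animal classes
#' may eat its grass; whether and where it is adopted is left to the
#' optimizer. The `SR` transform redesigns each system:
#' \itemize{
#'   \item \strong{BE}: the fattening farm is removed; the breeder becomes a
#'     growing-fattening farm on its repurposed stables, buying
#'     Belgian Blue x Holstein calves at three weeks of age for EUR 200 and
#'     selling bulls at 19 months with a 330 kg carcass (yield 55 %) at
#'     EUR 3.4/kg; a 70-cow Holstein dairy farm using sexed semen is added
#'     as the calf supplier. The suckler-cow coupled subsidy disappears with
#'     the cows.
#'   \item \strong{FR-IT}: the Italian fattener is removed; the French farm
#'     finishes Angus-cross bulls itself at 14 months, 300 kg carcass,
#'     EUR 4.18/kg (including a 0.40 EUR/kg premium).
#'   \item \strong{GE}: sexed semen limits pure-bred heifer calves to the
#'     replacement need and adds Belgian Blue x Holstein bulls sold at 21
#'     months with a 413 kg carcass at EUR 3.8/kg.
#' }
#' FRG availability carries over into `SR`.
#'
#' @param fixtures named list of `farm_config` (a baseline system).
#' @param scenario `"base"`, `"FRG"` or `"SR"`.
#' @param seed integer, forwarded to grass-profile generation.
#' @param params model parameters.
#' @return a named list of transformed `farm_config` objects.
#' @export
apply_scenario <- function(fixtures, scenario = c("base", "FRG", "SR"),
                           seed = 1L, params = default_params()) {
  scenario <- match.arg(scenario)
  system <- fixtures[[1]]$system
  bad <- vapply(fixtures, function(f) f$system != system, logical(1))
  if (any(bad)) stop("fixtures mix farms from different systems",
                     call. = FALSE)
  if (scenario == "base") return(fixtures)
  if (scenario == "FRG") return(lapply(fixtures, add_frg, seed = seed))
  sr <- switch(system,
    "BE" = scenario_sr_be(fixtures, seed, params),
    "FR-IT" = scenario_sr_fr(fixtures, seed, params),
    "GE" = scenario_sr_ge(fixtures, seed, params),
    stop("no system-redesign scenario defined for system ", system,
         call. = FALSE))
  lapply(sr, add_frg, seed = seed)   # FRG option carries over into SR
}

# add the FRG grazing activity and extend grazing classes' feed lists
add_frg <- function(cfg, seed) {
  if (cfg$grassland_ha <= 0) {
    cfg$scenario <- if (cfg$scenario == "base") "FRG" else cfg$scenario
    return(cfg)
  }
  cfg$grass <- grassland_activities(cfg$system, frg = TRUE, seed = seed)
  grazing <- cfg$herd$class[vapply(cfg$herd$graze_months, length,
                                   integer(1)) > 0]
  for (cl in grazing) {
    if ("grass_graze_cg" %in% cfg$class_feeds[[cl]])
      cfg$class_feeds[[cl]] <- union(cfg$class_feeds[[cl]],
                                     "grass_graze_frg")
  }
  cfg$scenario <- if (cfg$scenario == "base") "FRG" else
    paste0(cfg$scenario, "+FRG")
  validate_farm_config(cfg)
}

scenario_sr_be <- function(fixtures, seed, params) {
  breeder <- fixtures[["BE-B"]]
  if (is.null(breeder)) stop("BE system redesign needs farm BE-B",
                             call. = FALSE)
  dairy <- farm_be_dairy_supplier(seed, params)
  gf <- breeder
  gf$farm_id <- "BE-GF"; gf$role <- "growing_fattener"
  gf$scenario <- "SR"
  # suckler herd replaced by dairy-beef bulls reared from 3-week calves
  gf$herd <- herd_row("bull", "flow", "BB x Holstein", 300,
                      0.75, 19, 50, 600, cy = 0.55, lu = 0.55,
                      fiber_floor = 0.30, graze_months = list(4:10),
                      out_carcass_yr = 300, price_carcass = 3.4,
                      in_purchase_yr = 300, purchase_price = 200,
                      vet_cost = 80, ret_key = "bull", care_key = "bull")
  gf$class_feeds <- list(
    bull = c("grass_graze_cg", "grass_silage", "hay", "maize_silage",
             "barley", "soymeal", "beet_pulp_pressed", "milk_replacer"))
  gf$weanling_supply <- Inf   # calf market beyond the modelled supplier
  validate_farm_config(gf)
  list("BE-GF" = gf, "BE-D" = dairy)
}

scenario_sr_fr <- function(fixtures, seed, params) {
  b <- fixtures[["FR-IT-B"]]
  if (is.null(b)) stop("FR-IT system redesign needs farm FR-IT-B",
                       call. = FALSE)
  b$scenario <- "SR"
  males <- b$herd$out_transfer_yr[b$herd$class == "calf"]
  # weaned males stay on farm and are finished as Angus-cross bulls
  b$herd$out_transfer_yr[b$herd$class == "calf"] <- 0
  b$herd$breed[b$herd$class == "calf"] <- "Angus x Charolais"
  b$herd <- dplyr::bind_rows(
    b$herd,
    herd_row("bull", "flow", "Angus x Charolais", males, 9, 14, 320,
             300 / 0.55, cy = 0.55, lu = 0.6, fiber_floor = 0.40,
             graze_months = list(5:9),
             out_carcass_yr = males, price_carcass = 4.18,
             vet_cost = 80, ret_key = "bull", care_key = "bull"))
  b$class_feeds$bull <- c("grass_graze_cg", "grass_silage", "hay", "barley",
                          "soymeal")
  b$stable_places <- b$stable_places + 15   # winter places for the bulls
  validate_farm_config(b)
  list("FR-IT-B" = b)
}

scenario_sr_ge <- function(fixtures, seed, params) {
  g <- fixtures[["GE"]]
  if (is.null(g)) stop("GE system redesign needs farm GE", call. = FALSE)
  g$scenario <- "SR"
  cows <- g$herd$n[g$herd$class == "dairy_cow"]
  calvings <- g$herd$calvings_yr[g$herd$class == "dairy_cow"]
  fl <- calf_flows(cows, calving_rate = calvings / cows, calf_mortality = 0,
                   share_sexed_female = 0.368, share_bb_male = 0.45)
  repl <- g$herd$n[g$herd$class == "heifer"]
  # sexed female share tuned to the replacement need; conventional calves
  # are sold at two weeks
  g$herd$out_live_yr[g$herd$class == "dairy_cow"] <- fl$conventional
  g$herd$n[g$herd$class == "dairy_calf"] <- fl$female + fl$bb_male
  g$herd <- g$herd[g$herd$class != "bull", ]
  g$herd <- dplyr::bind_rows(
    g$herd,
    herd_row("bull", "flow", "BB x Holstein", fl$bb_male, 2, 21, 65,
             413 / 0.58, cy = 0.58, lu = 0.6, fiber_floor = 0.30,
             out_carcass_yr = fl$bb_male, price_carcass = 3.8,
             vet_cost = 90, ret_key = "bull", care_key = "bull"))
  g$class_feeds$bull <- c("maize_silage", "grass_silage", "hay", "wheat",
                          "barley", "soymeal", "beet_pulp_pressed")
  validate_farm_config(g)
  list("GE" = g)
}

# 70-cow Holstein dairy farm supplying three-week crossbred calves (BE-SR)
farm_be_dairy_supplier <- function(seed = 1L, params = default_params()) {
  cows <- 70
  fl <- calf_flows(cows, calving_rate = 0.95, calf_mortality = 0,
                   share_sexed_female = 0.5, share_bb_male = 0.5)
  repl <- 0.35 * cows
  herd <- dplyr::bind_rows(
    herd_row("dairy_cow", "stock", "Holstein", cows, weight_kg = 650,
             cy = 0.50, lu = 1.0, milk_sold_kg_yr = 8500,
             milk_req_kg_yr = 8500, fiber_floor = 0.40,
             graze_months = list(4:10),
             out_carcass_yr = repl, price_carcass = 2.2, vet_cost = 250,
             out_live_yr = fl$female - repl, live_price = 150,
             out_transfer_yr = fl$bb_male, transfer_kg = 50,
             calvings_yr = fl$total, ret_key = "dairy_cow",
             care_key = "dairy_cow"),
    herd_row("dairy_calf", "flow", "Holstein", repl, 0, 2, 45, 65,
             lu = 0.4, fiber_floor = 0.10, vet_cost = 50,
             ret_key = "calf", care_key = "calf"),
    herd_row("heifer", "flow", "Holstein", repl, 2, 27, 65, 600,
             lu = 0.6, fiber_floor = 0.55, graze_months = list(4:10),
             vet_cost = 70, ret_key = "heifer", care_key = "heifer"))
  new_farm_config(
    "BE-D", "BE", "dairy_supplier", arable_ha = 15, grassland_ha = 45,
    stable_places = 130, herd = herd,
    grass = grassland_activities("BE", frg = FALSE, seed = seed),
    crops = crops_be()[crops_be()$crop == "maize_silage", ],
    class_feeds = list(
      dairy_cow = c("grass_graze_cg", "grass_silage", "maize_silage", "hay",
                    "barley", "soymeal", "beet_pulp_pressed"),
      dairy_calf = c("milk_replacer", "barley", "soymeal", "hay"),
      heifer = c("grass_graze_cg", "grass_silage", "hay", "maize_silage",
                 "barley")),
    prices = list(milk = 0.35, weanling = 200, calf = 200,
                  crops = c(wheat = 165, barley = 150, sugar_beet = 38)),
    subsidy = list(decoupled = 280 * 60),
    manure_system = "liquid", depreciation = 45000, params = params,
    scenario = "SR")
}

#' Calf streams of a dairy herd under sexed-semen breeding
#'
#' Splits a dairy herd's annual calf crop into pure-bred female calves
#' (sexed female semen, destined for replacement), crossbred male calves
#' (male-sexed beef-sire semen) and conventional calves, after calf losses.
#'
#' @param cows cow count.
#' @param calving_rate calvings per cow per year.
#' @param calf_mortality fraction of calves lost before two weeks.
#' @param share_sexed_female,share_bb_male insemination shares; the
#'   remainder is conventional semen. Shares must sum to at most 1.
#' @return list with `total`, `female`, `bb_male`, `conventional`
#'   (calves/yr, surviving).
#' @export
#' @examples
#' calf_flows(70, 0.95, 0, share_sexed_female = 0.5, share_bb_male = 0.5)
calf_flows <- function(cows, calving_rate, calf_mortality = 0,
                       share_sexed_female, share_bb_male) {
  stopifnot(share_sexed_female >= 0, share_bb_male >= 0,
            share_sexed_female + share_bb_male <= 1 + 1e-9)
  born <- cows * calving_rate
  surv <- born * (1 - calf_mortality)
  list(total = surv,
       female = surv * share_sexed_female,
       bb_male = surv * share_bb_male,
       conventional = surv * (1 - share_sexed_female - share_bb_male))
}
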