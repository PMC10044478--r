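#' Monthly herd demographics at annual steady state
#'
#' Expands a farm's herd specification into a monthly head-count and flow
#' table. The model is an average-year, steady-state herd: calvings and
#' cohort entries are spread uniformly over the calendar year, so stocks are
#' constant month to month and every month's entries equal its exits. Head
#' counts are continuous (fractional animals are allowed), as is usual in
#' linear-programming herd models. The monthly flow balance
#' `heads[m+1] = heads[m] + entries[m] - exits[m]` therefore holds exactly
#' and December closes back onto January.
#'
#' @param config a `farm_config`.
#' @param scale herd multiplier (1 = the configured herd).
#' @return tibble: `class`, `month`, `heads`, `entries`, `exits`,
#'   `calvings`, `sales_carcass`, `sales_live`, `transfers_out`,
#'   `purchases` (all heads or heads/month).
#' @export
#' @examples
#' fx <- build_system_fixture("BE", "base")
#' herd <- cohort_progression(fx$`BE-B`)
#' subset(herd, month == 6)
cohort_progression <- function(config, scale = 1) {
  stopifnot(inherits(config, "farm_config"), scale >= 0)
  cs <- class_summary(config$herd)
  bad <- with(cs, out_carcass_yr + out_live_yr + out_transfer_yr -
                ifelse(ctype == "flow", inflow_yr, n) > 1e-9 &
                ctype == "flow")
  if (any(bad))
    stop("infeasible demography: class(es) ",
         paste(cs$class[bad], collapse = ", "),
         " sell more animals than flow through them", call. = FALSE)
  out <- tidyr::crossing(class = cs$class, month = 1:12) |>
    dplyr::left_join(cs, by = "class") |>
    dplyr::transmute(
      class = .data$class, month = .data$month,
      heads = scale * .data$n_head,
      entries = scale * ifelse(.data$ctype == "flow",
                               .data$inflow_yr, .data$out_carcass_yr) / 12,
      exits = .data$entries,
      calvings = scale * .data$calvings_yr / 12,
      sales_carcass = scale * .data$out_carcass_yr / 12,
      sales_live = scale * .data$out_live_yr / 12,
      transfers_out = scale * .data$out_transfer_yr / 12,
      purchases = scale * .data$in_purchase_yr / 12)
  out
}

#' Nutrient requirements of an animal at a given age
#'
#' Evaluates the package's linear-in-weight requirement functions for one
#' animal class at a month of age: metabolizable energy, crude protein and
#' dry-matter intake capacity per month. Weight is interpolated linearly
#' along the class's growth trajectory; requirements are strictly
#' increasing in live weight. Milk production (dairy) and milk suckled by a
#' calf at foot enter as linear terms; a suckling calf's requirement from
#' solid feed is net of the milk it receives from its dam.
#'
#' @param class_row one row of a herd specification (see
#'   [build_system_fixture()]), e.g. `herd[herd$class == "bull", ]`.
#' @param month_of_age age in months; must lie inside the class's age range.
#' @param params model parameters.
#' @return tibble with `me` (MJ/month), `cp` (g/month), `dmi_cap`
#'   (fill units/month) and `live_weight` (kg).
#' @export
animal_requirements <- function(class_row, month_of_age = NULL,
                                params = default_params()) {
  stopifnot(nrow(class_row) == 1)
  r <- params$requirements
  cs <- class_summary(class_row)
  if (cs$ctype == "flow") {
    if (is.null(month_of_age))
      stop("month_of_age required for a growing class", call. = FALSE)
    if (month_of_age < cs$entry_mo || month_of_age > cs$exit_mo)
      stop("age ", month_of_age, " outside class range [", cs$entry_mo,
           ", ", cs$exit_mo, "]", call. = FALSE)
    w <- cs$entry_kg + cs$adg * (month_of_age - cs$entry_mo) * 30.4
    adg <- cs$adg
  } else {
    w <- cs$weight_kg
    adg <- 0
  }
  milk_d <- cs$milk_req_kg_yr / 365
  d <- r$days_per_month
  me_d <- r$me_maint * w + r$me_gain * adg + r$me_milk * milk_d -
    cs$suckle_me
  cp_d <- r$cp_maint * w + r$cp_gain * adg + r$cp_milk * milk_d -
    cs$suckle_cp
  cap_d <- r$dmi_cap * w + r$dmi_milk * milk_d
  tibble::tibble(me = pmax(0, me_d) * d, cp = pmax(0, cp_d) * d,
                 dmi_cap = cap_d * d, live_weight = w)
}

# cohort-average monthly requirement per head for every class of a farm;
# linear requirements make the mean-weight animal exactly representative
class_requirements <- function(config, params = config$params) {
  cs <- class_summary(config$herd)
  r <- params$requirements
  d <- r$days_per_month
  cs |>
    dplyr::transmute(
      class = .data$class,
      me = pmax(0, r$me_maint * .data$avg_kg + r$me_gain * .data$adg +
                  r$me_milk * .data$milk_req_kg_yr / 365 -
                  .data$suckle_me) * d,
      cp = pmax(0, r$cp_maint * .data$avg_kg + r$cp_gain * .data$adg +
                  r$cp_milk * .data$milk_req_kg_yr / 365 -
                  .data$suckle_cp) * d,
      dmi_cap = (r$dmi_cap * .data$avg_kg +
                   r$dmi_milk * .data$milk_req_kg_yr / 365) * d,
      fiber_floor = .data$fiber_floor)
}

#' Products of a herd over one year
#'
#' Aggregates a monthly herd state into annual product streams: carcass mass
#' by class (heads sold times live weight at sale times carcass yield),
#' milk, live sales, and live weight transferred to a downstream farm.
#'
#' @param config a `farm_config`.
#' @param herd monthly herd table from [cohort_progression()]; defaults to
#'   the configured herd at scale 1.
#' @return tibble: `class`, `heads_sold_carcass`, `carcass_kg`,
#'   `heads_sold_live`, `live_revenue`, `heads_transferred`,
#'   `transfer_live_kg`, `milk_kg`, `carcass_revenue`.
#' @export
production_outputs <- function(config, herd = cohort_progression(config)) {
  cs <- class_summary(config$herd)
  ann <- herd |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(heads_sold_carcass = sum(.data$sales_carcass),
                     heads_sold_live = sum(.data$sales_live),
                     heads_transferred = sum(.data$transfers_out),
                     heads = dplyr::first(.data$heads),
                     .groups = "drop")
  ann |>
    dplyr::left_join(cs, by = "class") |>
    dplyr::transmute(
      class = .data$class,
      heads_sold_carcass = .data$heads_sold_carcass,
      carcass_kg = .data$heads_sold_carcass * .data$carcass_kg,
      carcass_revenue = .data$carcass_kg *
        dplyr::coalesce(.data$price_carcass, 0),
      heads_sold_live = .data$heads_sold_live,
      live_revenue = .data$heads_sold_live *
        dplyr::coalesce(.data$live_price, 0),
      heads_transferred = .data$heads_transferred,
      transfer_live_kg = .data$heads_transferred *
        dplyr::coalesce(.data$transfer_kg, 0),
      milk_kg = .data$heads * .data$milk_sold_kg_yr)
}

#' Nitrogen excretion from a ration
#'
#' Mass balance: N excreted equals N ingested minus N retained in body
#' tissue and milk, split between pasture and stable in proportion to
#' grazing days. The farm model derives grazing days from the share of
#' ration dry matter coming from grazed grass (days = days-in-month times
#' that share), which makes this function's split and the optimizer's
#' per-feed attribution coincide exactly.
#'
#' @param ration tibble with columns `feed`, `kg_dm` and `cp`
#'   (g CP/kg DM).
#' @param retention fraction of ingested N retained in products (0-1).
#' @param grazing_days days of the period spent grazing.
#' @param days_total length of the period in days.
#' @param params model parameters.
#' @return list: `n_intake`, `n_retained`, `n_excreted`, `n_pasture`,
#'   `n_stable` (kg N).
#' @export
#' @examples
#' r <- tibble::tibble(feed = c("grass", "barley"), kg_dm = c(300, 60),
#'                     cp = c(190, 115))
#' excreta_nitrogen(r, retention = 0.1, grazing_days = 20, days_total = 30)
excreta_nitrogen <- function(ration, retention, grazing_days = 0,
                             days_total = 30.4, params = default_params()) {
  stopifnot(retention >= 0, retention <= 1,
            grazing_days >= 0, grazing_days <= days_total + 1e-9)
  n_in <- sum(ration$kg_dm * ration$cp / 1000) * params$nitrogen$cp_to_n
  n_ret <- n_in * retention
  n_exc <- n_in - n_ret
  share <- if (days_total > 0) grazing_days / days_total else 0
  list(n_intake = n_in, n_retained = n_ret, n_excreted = n_exc,
       n_pasture = n_exc * share, n_stable = n_exc * (1 - share))
}
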