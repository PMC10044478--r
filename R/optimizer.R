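#' Build the farm profit-maximisation problem
#'
#' Assembles the annual linear programme of one farm: choose crop and
#' grassland activity areas, the herd scale, monthly rations per animal
#' class, feed purchases and sales, and mineral fertilizer, to maximise
#' profit subject to
#' land balances (arable and permanent grassland), the stable-capacity
#' limit, per-class-and-month feed balances in dry matter (intake-capacity
#' ceiling with feed fill values), metabolizable energy, crude protein and a
#' fibre floor, month-by-month availability of grazed grass (no
#' carry-over), storable pools for conserved forage and grains, an optional
#' cap on the downstream supply of purchased animals, and a nitrogen
#' balance requiring total nutrient removal by crops and consumed or
#' harvested grass to be covered by stable manure, plant-available pasture
#' excreta and purchased mineral nitrogen. Supplementary feeding on pasture
#' is allowed; the herd is scaled continuously. Decoupled subsidies and
#' depreciation are constants added to the LP objective in the reported
#' profit.
#'
#' @param config a `farm_config`.
#' @return a list of class `farm_model`: `problem` (an [lp_problem()]),
#'   `config`, `constant` (EUR/yr added to the LP objective),
#'   `feed_comp` (per feed-and-month composition lookup).
#' @export
build_farm_model <- function(config) {
  stopifnot(inherits(config, "farm_config"))
  params <- config$params
  cs <- class_summary(config$herd)
  req <- class_requirements(config)
  cat_feeds <- feed_catalogue()
  validate_feeds(cat_feeds,
                 setdiff(unique(unlist(config$class_feeds)),
                         config$grass$product[config$grass$type == "graze"]))

  graze_acts <- unique(config$grass$activity[config$grass$type == "graze"])
  cut_acts <- unique(config$grass$activity[config$grass$type == "cut"])
  crops <- config$crops

  # composition lookup: feed x month
  gr <- config$grass |>
    dplyr::filter(.data$type == "graze") |>
    dplyr::transmute(feed = .data$product, month = .data$month,
                     me = .data$me, cp = .data$cp, fill = 1,
                     hep_fraction = 0, dm_fraction = 0.18,
                     forage = TRUE, storable = FALSE, purchasable = FALSE,
                     price = NA_real_, upstream_ef = 0)
  st <- tidyr::crossing(cat_feeds, month = 1:12) |>
    dplyr::select("feed", "month", "me", "cp", "fill", "hep_fraction",
                  "dm_fraction", "forage", "storable", "purchasable",
                  "price", "upstream_ef")
  comp <- dplyr::bind_rows(gr, st)

  # ration variables: feed x class x month, only where feedable
  rv <- purrr::imap_dfr(config$class_feeds, function(feeds, cl) {
    gm <- config$herd$graze_months[[match(cl, config$herd$class)]]
    purrr::map_dfr(feeds, function(f) {
      months <- 1:12
      if (f %in% unique(gr$feed)) {
        avail <- gr$month[gr$feed == f & gr$me > 0]
        months <- intersect(intersect(avail, gm), 1:12)
      }
      if (length(months) == 0) return(NULL)
      tibble::tibble(feed = f, class = cl, month = months)
    })
  })
  if (nrow(rv) == 0)
    rv <- tibble::tibble(feed = character(), class = character(),
                         month = integer())
  rv <- rv |>
    dplyr::left_join(comp, by = c("feed", "month")) |>
    dplyr::mutate(var = paste("r", .data$feed, .data$class, .data$month,
                              sep = "|"))

  buyable <- intersect(unique(rv$feed),
                       cat_feeds$feed[cat_feeds$purchasable])
  sellable <- crops$crop[crops$use == "dual"]

  pfx <- function(p, x) if (length(x)) paste0(p, x) else character(0)
  vars <- c(pfx("act|", graze_acts), pfx("act|", cut_acts),
            pfx("crop|", crops$crop), "scale", rv$var,
            pfx("buy|", buyable), pfx("sell|", sellable), "fertn")
  nv <- length(vars)
  vi <- stats::setNames(seq_len(nv), vars)

  obj <- stats::setNames(numeric(nv), vars)
  ga_meta <- config$grass |>
    dplyr::group_by(.data$activity) |>
    dplyr::summarise(variable_cost = dplyr::first(.data$variable_cost),
                     .groups = "drop")
  for (a in c(graze_acts, cut_acts))
    obj[paste0("act|", a)] <-
      -ga_meta$variable_cost[ga_meta$activity == a]
  for (i in seq_len(nrow(crops))) {
    cr <- crops[i, ]
    rev <- if (cr$use == "cash")
      config$prices$crops[[cr$crop]] * cr$yield else 0
    obj[paste0("crop|", cr$crop)] <- rev - cr$input_cost
  }
  # herd margin per unit scale (animal sales, milk, coupled support, less
  # per-head costs and animal purchases)
  herd_rev <- sum(cs$out_carcass_yr * cs$carcass_kg *
                    dplyr::coalesce(cs$price_carcass, 0)) +
    sum(cs$out_live_yr * dplyr::coalesce(cs$live_price, 0)) +
    sum(cs$out_transfer_yr * (config$prices$weanling %||% 0)) +
    sum(cs$n_head * cs$milk_sold_kg_yr * config$prices$milk) +
    sum(cs$n * cs$coupled_subsidy * (cs$ctype == "stock"))
  herd_cost <- sum(cs$n_head * cs$vet_cost) +
    sum(cs$in_purchase_yr * dplyr::coalesce(cs$purchase_price, 0))
  obj["scale"] <- herd_rev - herd_cost
  for (f in buyable)
    obj[paste0("buy|", f)] <- -cat_feeds$price[cat_feeds$feed == f]
  for (f in sellable)
    obj[paste0("sell|", f)] <- config$prices$crops[[f]]
  obj["fertn"] <- -params$prices$fert_n
  # distributing conserved feed indoors costs machinery and diesel;
  # grazed grass is self-harvested
  obj[rv$var] <- obj[rv$var] -
    ifelse(rv$feed %in% gr$feed, 0, params$prices$feed_out)

  rows <- list(); dirs <- c(); rhs <- c(); groups <- c()
  add_con <- function(coef_idx, coef_val, dir, b, name, group) {
    row <- numeric(nv); row[coef_idx] <- coef_val
    rows[[name]] <<- row; dirs[name] <<- dir; rhs[name] <<- b
    groups[name] <<- group
  }

  if (length(crops$crop) > 0)
    add_con(vi[paste0("crop|", crops$crop)], rep(1, nrow(crops)), "<=",
            config$arable_ha, "land_arable", "land")
  if (length(c(graze_acts, cut_acts)) > 0)
    add_con(vi[paste0("act|", c(graze_acts, cut_acts))],
            rep(1, length(graze_acts) + length(cut_acts)), "<=",
            config$grassland_ha, "land_grass", "land")
  add_con(vi["scale"], sum(cs$lu * cs$n_head), "<=", config$stable_places,
          "stable", "stable")
  tot_purch <- sum(cs$in_purchase_yr)
  if (is.finite(config$weanling_supply) && tot_purch > 0)
    add_con(vi["scale"], tot_purch, "<=", config$weanling_supply,
            "weanling_supply", "supply")

  # grazed grass usable only in its growth month
  for (a in graze_acts) {
    prod <- config$grass$product[config$grass$activity == a][1]
    for (m in 1:12) {
      y <- config$grass$dm_yield[config$grass$activity == a &
                                   config$grass$month == m]
      users <- rv$var[rv$feed == prod & rv$month == m]
      if (y <= 0 || length(users) == 0) next
      add_con(c(vi[users], vi[paste0("act|", a)]),
              c(rep(1, length(users)), -1000 * y), "<=", 0,
              paste0("graze|", a, "|m", m), "grass")
    }
  }

  # storable pools (kg DM): use + sales <= production + purchases
  storables <- unique(rv$feed[rv$storable])
  for (f in union(storables, sellable)) {
    idx <- c(); val <- c()
    users <- rv$var[rv$feed == f]
    if (length(users)) { idx <- c(idx, vi[users])
                         val <- c(val, rep(1, length(users))) }
    dmf <- cat_feeds$dm_fraction[cat_feeds$feed == f]
    if (f %in% sellable) { idx <- c(idx, vi[paste0("sell|", f)])
                           val <- c(val, 1000 * dmf) }
    if (f %in% crops$crop) {
      cr <- crops[crops$crop == f, ]
      prod_dm <- if (f == "maize_silage") 1000 * cr$yield else
        1000 * cr$yield * dmf
      idx <- c(idx, vi[paste0("crop|", f)]); val <- c(val, -prod_dm)
    }
    cut_src <- config$grass[config$grass$type == "cut" &
                              config$grass$product == f, ]
    if (nrow(cut_src) > 0)
      for (a in unique(cut_src$activity)) {
        idx <- c(idx, vi[paste0("act|", a)])
        val <- c(val, -1000 * sum(cut_src$dm_yield[cut_src$activity == a]))
      }
    if (f %in% buyable) { idx <- c(idx, vi[paste0("buy|", f)])
                          val <- c(val, -1000 * dmf) }
    if (length(idx) == 0) next
    add_con(idx, val, "<=", 0, paste0("pool|", f), "feed_pool")
  }

  # nutrition: per class and month
  for (cl in cs$class) {
    nh <- cs$n_head[cs$class == cl]
    rq <- req[req$class == cl, ]
    for (m in 1:12) {
      rvm <- rv[rv$class == cl & rv$month == m, ]
      if (nrow(rvm) == 0) next
      add_con(c(vi[rvm$var], vi["scale"]), c(rvm$fill, -rq$dmi_cap * nh),
              "<=", 0, paste0("cap|", cl, "|m", m), "intake_capacity")
      add_con(c(vi[rvm$var], vi["scale"]), c(-rvm$me, rq$me * nh),
              "<=", 0, paste0("me|", cl, "|m", m), "energy")
      add_con(c(vi[rvm$var], vi["scale"]), c(-rvm$cp, rq$cp * nh),
              "<=", 0, paste0("cp|", cl, "|m", m), "protein")
      add_con(vi[rvm$var], rq$fiber_floor - as.numeric(rvm$forage),
              "<=", 0, paste0("fib|", cl, "|m", m), "fiber")
    }
  }

  # nitrogen balance: removal by harvested/consumed products covered by
  # manure, plant-available pasture excreta and mineral N
  nidx <- c(); nval <- c()
  if (nrow(crops) > 0) {
    nidx <- c(nidx, vi[paste0("crop|", crops$crop)])
    nval <- c(nval, crops$n_removal)
  }
  for (a in cut_acts) {
    cut_src <- config$grass[config$grass$activity == a, ]
    nrem <- sum(cut_src$dm_yield * cut_src$cp) / 6.25  # kg N/ha
    nidx <- c(nidx, vi[paste0("act|", a)]); nval <- c(nval, nrem)
  }
  ret <- params$retention[cs$ret_key]; names(ret) <- cs$class
  loss <- params$nitrogen$storage_loss
  pav <- params$nitrogen$pasture_avail
  grass_feeds <- unique(gr$feed)
  ncoef <- rv$cp / 1000 * params$nitrogen$cp_to_n *
    ifelse(rv$feed %in% grass_feeds,
           1 - pav * (1 - ret[rv$class]),          # removal less returns
           -(1 - loss) * (1 - ret[rv$class]))      # stable manure credit
  nidx <- c(nidx, vi[rv$var]); nval <- c(nval, ncoef)
  nidx <- c(nidx, vi["fertn"]); nval <- c(nval, -1)
  add_con(nidx, nval, "<=", 0, "n_balance", "nitrogen")

  A <- do.call(rbind, rows)
  colnames(A) <- vars
  problem <- lp_problem(obj, A, unname(dirs), unname(rhs), maximize = TRUE,
                        con_names = names(rows), groups = unname(groups))
  structure(list(problem = problem, config = config,
                 constant = config$subsidy$decoupled - config$depreciation,
                 feed_comp = comp, ration_vars = rv),
            class = "farm_model")
}

#' Solve a farm model
#'
#' Runs the simplex on a farm's linear programme and assembles a
#' `farm_solution`: optimal profit, chosen activity areas and herd scale,
#' monthly rations, purchases, sales, fertilizer, and the dual value of
#' every balance constraint.
#'
#' @param x a `farm_config` or `farm_model`.
#' @param ... unused.
#' @return an object of class `farm_solution` with fields `status`,
#'   `objective` (LP value), `profit` (objective plus decoupled subsidy
#'   minus depreciation), `scale`, `activities`, `ration`, `purchases`,
#'   `sales`, `fert_n`, `duals`, `constraints`, `herd`, `config`.
#' @export
#' @examples
#' \donttest{
#' fx <- build_system_fixture("BE", "base")
#' sol <- solve_farm(fx$`BE-B`)
#' sol$profit
#' }
solve_farm <- function(x, ...) {
  model <- if (inherits(x, "farm_model")) x else build_farm_model(x)
  config <- model$config
  s <- solve_lp(model$problem)
  if (s$status != "optimal") {
    out <- list(status = s$status, config = config,
                violated_groups = s$violated_groups)
    class(out) <- "farm_solution"
    return(out)
  }
  xx <- s$x
  pick <- function(prefix) {
    v <- xx[startsWith(names(xx), prefix)]
    v <- pmax(v, 0)  # clear solver-tolerance negatives
    stats::setNames(v, substring(names(v), nchar(prefix) + 1))
  }
  scale <- unname(xx["scale"])
  ration <- model$ration_vars |>
    dplyr::mutate(kg_dm = unname(xx[.data$var])) |>
    dplyr::filter(.data$kg_dm > 1e-9) |>
    dplyr::select("feed", "class", "month", "kg_dm", "me", "cp", "fill",
                  "hep_fraction", "forage")
  out <- list(
    status = "optimal",
    objective = s$objective,
    profit = s$objective + model$constant,
    scale = scale,
    activities = tibble::tibble(
      activity = names(pick("act|")), ha = unname(pick("act|"))) |>
      dplyr::bind_rows(tibble::tibble(
        activity = names(pick("crop|")), ha = unname(pick("crop|")))),
    ration = ration,
    purchases = tibble::tibble(feed = names(pick("buy|")),
                               t_fresh = unname(pick("buy|"))),
    sales = tibble::tibble(crop = names(pick("sell|")),
                           t_fresh = unname(pick("sell|"))),
    fert_n = max(0, unname(xx["fertn"])),
    duals = s$duals,
    constraints = s$constraints,
    herd = cohort_progression(config, scale = scale),
    config = config,
    constant = model$constant)
  class(out) <- "farm_solution"
  out
}

#' @export
print.farm_solution <- function(x, ...) {
  cat("<farm_solution> ", x$config$farm_id, " [", x$status, "]", sep = "")
  if (x$status == "optimal")
    cat("  profit:", format(round(x$profit)), "EUR/yr  herd scale:",
        format(round(x$scale, 3)))
  cat("\n")
  invisible(x)
}

#' Shadow price of a commodity
#'
#' Returns the internal valuation of a commodity at the optimum: the market
#' price when the farm trades it on a market, otherwise the dual value of
#' its balance constraint (the marginal profit of one more unit appearing
#' on-farm). Feeds are valued per kg dry matter, milk per kg.
#'
#' @param solution an optimal `farm_solution`.
#' @param commodity `"milk"`, a feed name, or the name of any constraint.
#' @return a single numeric (EUR per unit).
#' @export
shadow_price <- function(solution, commodity) {
  stopifnot(inherits(solution, "farm_solution"))
  if (solution$status != "optimal")
    stop("shadow prices require an optimal solution", call. = FALSE)
  if (commodity == "milk") {
    p <- solution$config$prices$milk
    if (!is.null(p) && is.finite(p) && p > 0) return(p)
  }
  nm <- paste0("pool|", commodity)
  d <- solution$duals
  if (nm %in% names(d)) return(unname(d[nm]))
  if (commodity %in% names(d)) return(unname(d[commodity]))
  stop("no balance constraint or market price for commodity '",
       commodity, "'", call. = FALSE)
}
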