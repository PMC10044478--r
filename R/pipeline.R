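#' Run the full analysis pipeline for one system and scenario
#'
#' End-to-end orchestration: builds the system fixtures, solves the farms
#' in supply-chain order (the breeding or dairy farm first, so the
#' emissions and work time embodied in transferred animals can enter the
#' receiving farm's accounting), assembles emission inventories, applies
#' milk/beef economic allocation where relevant, computes the indicator
#' set per farm and the system-level GWP per kg carcass, and optionally
#' writes everything to disk (farm configurations as YAML, tabular results
#' as CSV, a run manifest as JSON). Reruns with identical inputs and seed
#' reproduce identical outputs.
#'
#' @param system,scenario as in [build_system_fixture()].
#' @param seed integer seed (grass profile jitter).
#' @param out_dir optional output directory; created if missing.
#' @param perturb optional function `farm_config -> farm_config` applied to
#'   every farm before solving (used by the sensitivity analysis).
#' @param params model parameters.
#' @return a list of class `pipeline_result`: `fixtures`, `solutions`,
#'   `inventories`, `allocations`, `transfer` (a `transfer_record` or
#'   `NULL`), `indicators` (tibble), `system_gwp`, `farm_of_interest`,
#'   `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline("GE", "base")
#' res$indicators
#' }
run_pipeline <- function(system, scenario = "base", seed = 1L,
                         out_dir = NULL, perturb = NULL,
                         params = default_params()) {
  fixtures <- build_system_fixture(system, scenario, seed = seed,
                                   params = params)
  if (!is.null(perturb)) fixtures <- lapply(fixtures, perturb)

  chain <- chain_order(fixtures)
  upstream_id <- chain$upstream; downstream_id <- chain$downstream

  solutions <- list(); inventories <- list(); allocations <- list()
  transfer <- NULL
  sol_up <- solve_farm(fixtures[[upstream_id]])
  if (sol_up$status != "optimal")
    stop("farm ", upstream_id, " did not solve: ", sol_up$status,
         if (!is.null(sol_up$violated_groups))
           paste0(" (constraint groups: ",
                  paste(sol_up$violated_groups, collapse = ", "), ")"),
         call. = FALSE)
  solutions[[upstream_id]] <- sol_up
  inventories[[upstream_id]] <- farm_inventory(sol_up)
  po_up <- production_outputs(sol_up$config, sol_up$herd)
  allocations[[upstream_id]] <-
    if (sum(po_up$milk_kg) > 0) allocate_milk_beef(sol_up) else NULL

  if (!is.null(downstream_id)) {
    cfg_dn <- fixtures[[downstream_id]]
    if (sum(po_up$transfer_live_kg) > 0) {
      wt_up <- work_time_per_kg(
        sol_up, beef_share = allocations[[upstream_id]]$beef_share %||% 1)
      transfer <- transfer_embodied(sol_up, inventories[[upstream_id]],
                                    work_time_h = wt_up$total_h)
      cfg_dn$purchase_embodied_ef <- transfer$embodied_ef_head
      cfg_dn$purchase_embodied_wt <- transfer$embodied_wt_head
      # a finite supply marks a within-system-only animal source: the
      # receiver can then take no more than the chain provides. An infinite
      # supply (BE-SR calf market) stays open.
      if (is.finite(cfg_dn$weanling_supply))
        cfg_dn$weanling_supply <- min(cfg_dn$weanling_supply,
                                      transfer$heads)
    }
    sol_dn <- solve_farm(cfg_dn)
    if (sol_dn$status != "optimal")
      stop("farm ", downstream_id, " did not solve: ", sol_dn$status,
           call. = FALSE)
    solutions[[downstream_id]] <- sol_dn
    inventories[[downstream_id]] <- farm_inventory(sol_dn)
    allocations[[downstream_id]] <- NULL
  }

  indicators <- purrr::map_dfr(names(solutions), function(id)
    indicator_set(solutions[[id]], inventories[[id]]))

  # system total: each farm's own beef-allocated emissions. The receiver's
  # inventory carries the emissions embodied in purchased animals, already
  # counted at the upstream farm, so they are removed here (no double
  # counting; the chain conserves mass exactly).
  own <- purrr::map_dbl(names(solutions), function(id) {
    share <- allocations[[id]]$beef_share %||% 1
    tot <- inventories[[id]]$total_co2eq * share
    if (!is.null(transfer) && identical(id, downstream_id))
      tot <- tot - transfer$embodied_ef_head *
        min(sum(solutions[[id]]$herd$purchases), transfer$heads)
    tot
  })
  carcass <- purrr::map_dbl(solutions, function(s)
    sum(production_outputs(s$config, s$herd)$carcass_kg))
  system_gwp <- list(total_co2eq = sum(own), carcass_kg = sum(carcass))
  system_gwp$gwp_per_kg <- system_gwp$total_co2eq / system_gwp$carcass_kg

  foi <- farm_of_interest(system, scenario, names(solutions))
  manifest <- list(system = system, scenario = scenario, seed = seed,
                   version = tryCatch(
                     as.character(utils::packageVersion("beefsys")),
                     error = function(e) "dev"),
                   farms = names(solutions),
                   farm_of_interest = foi,
                   timestamp = NA)   # filled only when writing to disk
  out <- structure(list(fixtures = fixtures, solutions = solutions,
                        inventories = inventories,
                        allocations = allocations, transfer = transfer,
                        indicators = indicators, system_gwp = system_gwp,
                        farm_of_interest = foi, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

chain_order <- function(fixtures) {
  ids <- names(fixtures)
  buys <- purrr::map_dbl(fixtures, function(f)
    sum(f$herd$in_purchase_yr))
  sells <- purrr::map_dbl(fixtures, function(f)
    sum(f$herd$out_transfer_yr))
  if (length(ids) == 1) return(list(upstream = ids, downstream = NULL))
  up <- ids[which.max(sells)]
  dn <- setdiff(ids[buys > 0], up)
  list(upstream = up, downstream = if (length(dn)) dn[1] else
    setdiff(ids, up)[1])
}

farm_of_interest <- function(system, scenario, ids) {
  cand <- switch(system,
    "BE" = if (scenario == "SR") "BE-GF" else "BE-B",
    "FR-IT" = "FR-IT-B",
    "GE" = "GE")
  if (cand %in% ids) cand else ids[1]
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$manifest$system, "/", x$manifest$scenario,
      "  farms: ", paste(x$manifest$farms, collapse = ", "), "\n", sep = "")
  cat("  system GWP: ", round(x$system_gwp$gwp_per_kg, 2),
      " kg CO2eq/kg carcass over ", round(x$system_gwp$carcass_kg),
      " kg\n", sep = "")
  invisible(x)
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(res$fixtures)) {
    cfg <- res$fixtures[[id]]
    y <- cfg[setdiff(names(cfg), "params")]
    y <- purrr::map(y, function(el)
      if (inherits(el, "data.frame")) purrr::map(el, function(col)
        if (is.list(col)) purrr::map(col, identity) else col) else el)
    yaml::write_yaml(y, file.path(out_dir, paste0("farm_", id, ".yaml")))
  }
  utils::write.csv(res$indicators,
                   file.path(out_dir, "indicators.csv"), row.names = FALSE)
  inv <- purrr::map_dfr(res$inventories, function(iv)
    dplyr::mutate(iv$sources, farm_id = iv$farm_id))
  utils::write.csv(inv, file.path(out_dir, "inventory.csv"),
                   row.names = FALSE)
  rat <- purrr::map_dfr(res$solutions, function(s)
    dplyr::mutate(s$ration, farm_id = s$config$farm_id))
  utils::write.csv(rat, file.path(out_dir, "rations.csv"),
                   row.names = FALSE)
  m <- res$manifest
  m$outputs <- c(paste0("farm_", names(res$fixtures), ".yaml"),
                 "indicators.csv", "inventory.csv", "rations.csv",
                 "manifest.json")
  m$system_gwp_per_kg <- res$system_gwp$gwp_per_kg
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarise one or two pipeline runs
#'
#' Builds the reporting tables: the per-source GWP breakdown and the
#' work-time task breakdown per farm and, when a second (baseline) run is
#' given, scenario-versus-baseline percentage deltas of the headline
#' indicators of the farm of interest.
#'
#' @param result a `pipeline_result` (the scenario run).
#' @param baseline optional `pipeline_result` to compare against.
#' @return list: `gwp_sources` (tibble), `work_time` (tibble), and -- with
#'   a baseline -- `deltas` (tibble with percent changes).
#' @export
report_run <- function(result, baseline = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  gwp_sources <- purrr::map_dfr(result$inventories, function(iv)
    dplyr::mutate(iv$sources, farm_id = iv$farm_id)) |>
    dplyr::select("farm_id", "source", "gas", "mass_kg", "co2eq")
  work_time <- purrr::map_dfr(names(result$solutions), function(id) {
    sol <- result$solutions[[id]]
    share <- result$allocations[[id]]$beef_share %||% 1
    wt <- work_time_per_kg(sol, beef_share = share)
    dplyr::mutate(wt$breakdown, farm_id = id)
  })
  out <- list(gwp_sources = gwp_sources, work_time = work_time)
  if (!is.null(baseline)) {
    a <- result$indicators[
      result$indicators$farm_id == result$farm_of_interest, ]
    b <- baseline$indicators[
      baseline$indicators$farm_id == baseline$farm_of_interest, ]
    pick <- c("gwp_per_kg", "net_hep", "wt_min_per_kg", "profit")
    out$deltas <- tibble::tibble(
      indicator = c(pick, "system_gwp_per_kg"),
      scenario = c(unlist(a[1, pick]),
                   result$system_gwp$gwp_per_kg),
      baseline = c(unlist(b[1, pick]),
                   baseline$system_gwp$gwp_per_kg)) |>
      dplyr::mutate(delta_pct = 100 * (.data$scenario - .data$baseline) /
                      abs(.data$baseline))
  }
  out
}
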