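#' Latin-Hypercube design over the three sensitivity parameters
#'
#' Draws a Latin-Hypercube sample of multiplicative perturbations for the
#' stable capacity (range 0.8--1.2), the yield of grassland under fast
#' rotational grazing (0.9--1.1) and the bull slaughter age (0.9--1.1),
#' uniform and uncorrelated, with 100 draws by default. Each column
#' partitions its range into `n_draws` equiprobable strata with exactly one
#' sample per stratum; the design is deterministic for a fixed seed.
#'
#' @param n_draws number of draws (default 100).
#' @param seed integer seed.
#' @param ranges named list of `c(lo, hi)` ranges; defaults to the study's.
#' @return tibble of class `lhs_design`: `draw` plus one column per
#'   parameter.
#' @export
#' @examples
#' d <- lhs_design(n_draws = 10, seed = 7)
#' range(d$stable_capacity)
lhs_design <- function(n_draws = 100, seed = 1L,
                       ranges = list(stable_capacity = c(0.8, 1.2),
                                     frg_yield = c(0.9, 1.1),
                                     slaughter_age = c(0.9, 1.1))) {
  stopifnot(n_draws >= 1, length(ranges) >= 1)
  u <- with_seed(seed, lhs::randomLHS(n_draws, length(ranges)))
  cols <- purrr::imap(ranges, function(rg, nm) {
    stopifnot(length(rg) == 2, rg[2] >= rg[1])
    rg[1] + (rg[2] - rg[1]) * u[, match(nm, names(ranges))]
  })
  out <- tibble::tibble(draw = seq_len(n_draws), !!!cols)
  class(out) <- c("lhs_design", class(out))
  out
}

#' Apply one sensitivity draw to a farm configuration
#'
#' Multiplies the stable capacity, the fast-rotational-grazing dry-matter
#' yields (baseline grassland is left untouched) and the slaughter age of
#' fattening-bull classes by the draw's factors. The perturbed slaughter
#' age is rounded to whole months (the model's time grid) and the exit
#' weight follows the class's original daily gain, so shorter fattening
#' sells lighter bulls.
#'
#' @param config a `farm_config`.
#' @param draw a one-row slice of an [lhs_design()] (or any list with
#'   elements `stable_capacity`, `frg_yield`, `slaughter_age`).
#' @return the perturbed `farm_config`.
#' @export
apply_draw <- function(config, draw) {
  stopifnot(inherits(config, "farm_config"))
  m_st <- draw$stable_capacity %||% 1
  m_fy <- draw$frg_yield %||% 1
  m_sa <- draw$slaughter_age %||% 1
  config$stable_places <- config$stable_places * m_st
  frg <- config$grass$activity == "graze_frg"
  if (any(frg)) config$grass$dm_yield[frg] <-
      config$grass$dm_yield[frg] * m_fy
  bulls <- which(config$herd$class == "bull" & config$herd$ctype == "flow")
  for (i in bulls) {
    h <- config$herd[i, ]
    adg <- (h$exit_kg - h$entry_kg) / ((h$exit_mo - h$entry_mo) * 30.4)
    new_exit <- max(round(h$exit_mo * m_sa), ceiling(h$entry_mo) + 1)
    config$herd$exit_mo[i] <- new_exit
    config$herd$exit_kg[i] <- h$entry_kg +
      adg * (new_exit - h$entry_mo) * 30.4
  }
  config
}

#' Run the sensitivity analysis
#'
#' For every draw of the design, perturbs all farms of the system, re-runs
#' the profit optimization for each, and records the indicator set of the
#' farm of interest (the farm implementing the innovation: the breeder
#' farm in the two-farm systems, the dairy farm in the German system).
#' Infeasible or otherwise failed draws are flagged in the `status` column
#' and kept in the table, never silently dropped.
#'
#' @param system,scenario system and scenario identifiers as in
#'   [build_system_fixture()].
#' @param design an [lhs_design()].
#' @param seed fixture seed.
#' @return tibble: one row per draw with the draw's multipliers, `status`,
#'   and the indicator columns of [indicator_set()].
#' @export
run_sensitivity <- function(system, scenario, design = lhs_design(),
                            seed = 1L) {
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    dr <- design[i, ]
    res <- tryCatch({
      bundle <- run_pipeline(system, scenario, seed = seed,
                             perturb = function(cfg) apply_draw(cfg, dr))
      ind <- bundle$indicators[
        bundle$indicators$farm_id == bundle$farm_of_interest, ]
      dplyr::bind_cols(dr, tibble::tibble(status = "optimal"), ind)
    }, error = function(e) {
      dplyr::bind_cols(dr, tibble::tibble(status = paste("failed:",
                                                         conditionMessage(e))))
    })
    res
  })
}

#' Net HEP efficiency as a function of the stocking rate
#'
#' Pairs the net human-edible protein efficiency with the stocking rate
#' across sensitivity draws (or any indicator table) and summarises their
#' association with a Spearman rank correlation. Draws with infinite
#' efficiency (zero edible-protein input) or failed status are excluded
#' from the correlation and counted.
#'
#' @param results tibble with columns `net_hep` and `stocking_rate` (e.g.
#'   from [run_sensitivity()]).
#' @return list: `pairs` (tibble), `rho` (Spearman; `NA` when degenerate),
#'   `n_used`, `n_excluded`.
#' @export
hep_vs_stocking <- function(results) {
  if (!all(c("net_hep", "stocking_rate") %in% names(results)))
    stop("results must contain net_hep and stocking_rate", call. = FALSE)
  ok <- is.finite(results$net_hep) & is.finite(results$stocking_rate)
  if ("status" %in% names(results)) ok <- ok & results$status == "optimal"
  pairs <- tibble::tibble(stocking_rate = results$stocking_rate[ok],
                          net_hep = results$net_hep[ok])
  if (nrow(pairs) < 2)
    stop("need at least two finite draws", call. = FALSE)
  rho <- if (stats::sd(pairs$net_hep) == 0 ||
             stats::sd(pairs$stocking_rate) == 0) NA_real_ else
    suppressWarnings(stats::cor(pairs$stocking_rate, pairs$net_hep,
                                method = "spearman"))
  list(pairs = pairs, rho = rho, n_used = nrow(pairs),
       n_excluded = sum(!ok))
}
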