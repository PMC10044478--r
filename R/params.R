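#' Default model parameters
#'
#' One nested list holding every configurable coefficient that is not
#' farm-specific: energy partitioning and the enteric methane conversion
#' factor, characterization factors, nitrogen pathway emission factors,
#' animal requirement coefficients, human-edible protein coefficients and
#' economy-wide prices. All values are package defaults in the style of
#' IPCC Tier-2 inventories and standard livestock requirement tables; the
#' vignette documents each choice. Everything here can be overridden by
#' passing a modified copy to the functions that take `params`.
#'
#' Units are annotated field by field: energy in MJ, masses in kg, protein
#' in g CP per kg DM unless stated otherwise.
#'
#' @return a named list.
#' @export
#' @examples
#' p <- default_params()
#' p$enteric$ym    # methane conversion factor, fraction of gross energy
default_params <- function() {
  list(
    enteric = list(
      ym = 0.065,              # CH4 conversion factor, fraction of GE intake
      me_ge_ratio = 0.55,      # MJ ME per MJ GE of an average ration
      ge_density = 18.45,      # MJ GE per kg feed DM
      ch4_energy = 55.65       # MJ per kg CH4
    ),
    gwp = c(ch4 = 34, n2o = 298, co2 = 1),  # kg CO2eq/kg, GWP100-style
    nitrogen = list(
      cp_to_n = 1 / 6.25,            # kg N per kg crude protein
      ef_n2o_direct = 0.01,          # kg N2O-N per kg N applied/excreted
      ef_n2o_storage = c(solid = 0.005, liquid = 0.001),
      frac_volat = 0.20,             # fraction of managed N volatilised
      frac_leach = 0.10,             # fraction of applied N leached
      ef_n2o_volat = 0.010,          # indirect, per kg N volatilised
      ef_n2o_leach = 0.0075,         # indirect, per kg N leached
      n2o_n_to_n2o = 44 / 28,
      manure_ch4 = c(solid = 0.25, liquid = 0.65),  # kg CH4/kg N in storage
      storage_loss = 0.25,           # fraction of stored N lost before field
      pasture_avail = 0.60           # fraction of pasture-excreted N
                                     #  counted as plant-available
    ),
    requirements = list(
      me_maint = 0.105,   # MJ ME/d per kg live weight
      me_gain = 30,       # MJ ME per kg daily gain
      me_milk = 5.3,      # MJ ME per kg milk
      cp_maint = 0.60,    # g CP/d per kg live weight
      cp_gain = 300,      # g CP per kg daily gain
      cp_milk = 85,       # g CP per kg milk
      dmi_cap = 0.021,    # intake capacity, fill units/d per kg live weight
      dmi_milk = 0.32,    # extra fill units/d per kg daily milk
      days_per_month = 30.4
    ),
    retention = c(cow = 0.05, dairy_cow = 0.25, calf = 0.20,
                  heifer = 0.12, bull = 0.15),  # N retained / N intake
    hep = list(
      beef_protein_kg_per_kg_carcass = 0.138,  # crude protein in carcass
      beef_edible_share = 0.80                 # human-edible fraction of it
    ),
    upstream = list(
      fert_n_ef = 5.5,    # kg CO2eq per kg mineral N provided
      diesel_ef = 3.17    # kg CO2 per litre diesel burnt (incl. provision)
    ),
    prices = list(fert_n = 1.10,   # EUR per kg mineral N
                  feed_out = 0.012),  # EUR per kg DM of conserved feed fed
    labor = list(
      feeding_h_t_dm = 0.8,        # indoor feeding, h per t DM distributed
      caretaking_h_head_yr = c(cow = 12, dairy_cow = 20, calf = 8,
                               heifer = 6, bull = 5),
      calving_h = 1.5,             # h per calving
      admin_fixed_h = 400,         # admin + stable maintenance, h/yr
      admin_h_lu = 1.5
    ),
    solver = list(tol = 1e-9)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG state so fixtures never disturb the caller's
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
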