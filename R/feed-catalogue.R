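#' Catalogue of feedstuffs
#'
#' Returns the package's default feed table: composition per kg dry matter,
#' fill value (intake-capacity units per kg DM), the human-edible protein
#' fraction of the crude protein, a market price per tonne fresh matter and
#' a synthetic upstream emission factor for purchased lots. The human-edible
#' fractions follow the convention of the feed-food-competition literature:
#' cereal grains carry a large edible share, forages and wet by-products
#' (pressed sugar beet pulp) none, milk powder almost all.
#'
#' All columns are plain data; nothing in the model logic hard-codes a feed,
#' so rows can be edited or added before building a farm.
#'
#' @return a tibble with one row per feedstuff and columns
#'   `feed`, `dm_fraction` (kg DM/kg fresh), `me` (MJ ME/kg DM),
#'   `cp` (g CP/kg DM), `fill` (fill units/kg DM), `hep_fraction` (0-1),
#'   `price` (EUR/t fresh, `NA` = not traded), `upstream_ef`
#'   (kg CO2eq/t fresh, synthetic default), `forage` (counts toward the
#'   fibre floor), `storable` (can be conserved across months) and
#'   `purchasable`.
#' @export
#' @examples
#' feed_catalogue()
feed_catalogue <- function() {
  tibble::tribble(
    ~feed,            ~dm_fraction, ~me,  ~cp, ~fill, ~hep_fraction, ~price, ~upstream_ef, ~forage, ~storable, ~purchasable,
    "grazed_grass",   0.18,         10.8, 190, 1.00,  0,             NA,     0,            TRUE,    FALSE,     FALSE,
    "grass_silage",   0.35,         10.2, 160, 1.00,  0,             55,     45,           TRUE,    TRUE,      TRUE,
    "hay",            0.86,         8.8,  120, 1.05,  0,             110,    50,           TRUE,    TRUE,      TRUE,
    "maize_silage",   0.33,         10.8, 75,  0.95,  0,             42,     40,           TRUE,    TRUE,      TRUE,
    "wheat",          0.87,         13.3, 121, 0.55,  0.80,          180,    450,          FALSE,   TRUE,      TRUE,
    "barley",         0.87,         12.9, 115, 0.55,  0.80,          165,    430,          FALSE,   TRUE,      TRUE,
    "soymeal",        0.88,         13.0, 510, 0.50,  0.65,          350,    1600,         FALSE,   TRUE,      TRUE,
    "beet_pulp_pressed", 0.25,      11.2, 95,  0.85,  0,             28,     30,           FALSE,   TRUE,      TRUE,
    "milk_replacer",  0.96,         16.5, 220, 0.30,  0.90,          1900,   1200,         FALSE,   TRUE,      TRUE
  )
}

# check a feed table covers the feeds a config refers to
validate_feeds <- function(feeds, needed) {
  missing <- setdiff(needed, feeds$feed)
  if (length(missing) > 0)
    stop("feed catalogue is missing entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
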