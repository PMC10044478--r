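# small problem generators shared across tests

# random LP with <= / >= / = rows, non-negative variables
random_lp <- function(n = NULL, m = NULL) {
  if (is.null(n)) n <- sample(2:6, 1)
  if (is.null(m)) m <- sample(2:6, 1)
  A <- matrix(round(stats::runif(m * n, -2, 4), 2), m, n)
  b <- round(stats::runif(m, 0.5, 10), 2)
  dir <- sample(c("<=", ">=", "="), m, replace = TRUE,
                prob = c(0.7, 0.2, 0.1))
  obj <- round(stats::runif(n, -3, 5), 2)
  lp_problem(obj, A, dir, b, maximize = TRUE)
}

# minimal one-class toy farm: a ha of grassland, one grazing + one cutting
# activity, one animal class sold for slaughter
toy_farm <- function(cows = 20, grass_ha = 30, stable = 40,
                     seed = 1L) {
  cfg <- build_system_fixture("FR-IT", "base", seed = seed)[["FR-IT-B"]]
  f <- cfg$herd$class == "suckler_cow"
  cfg$herd <- cfg$herd[f, ]
  cfg$herd$n <- cows
  cfg$herd$calvings_yr <- 0
  cfg$herd$out_carcass_yr <- 0.3 * cows
  cfg$class_feeds <- cfg$class_feeds["suckler_cow"]
  cfg$grassland_ha <- grass_ha
  cfg$stable_places <- stable
  cfg
}

# two-farm toy chain built from the BE fixtures at reduced scale
toy_chain <- function(seed = 1L) {
  fx <- build_system_fixture("BE", "base", seed = seed)
  fx
}

expect_rel_equal <- function(got, want, tol) {
  expect_lt(abs(got - want) / max(1, abs(want)), tol)
}
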