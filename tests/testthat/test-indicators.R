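test_that("net HEP efficiency matches its definition and sentinel", {
  p <- default_params()
  # choose a carcass mass whose edible output is exactly 100 kg protein
  carcass <- 100 / (p$hep$beef_protein_kg_per_kg_carcass *
                      p$hep$beef_edible_share)
  # and a ration contributing exactly 250 kg edible protein
  ration <- tibble::tibble(kg_dm = 250 / (0.5 * 0.120), cp = 120,
                           hep_fraction = 0.5)
  expect_equal(net_hep_efficiency(carcass, ration, 1, p), 100 / 250,
               tolerance = 1e-12)
  # all-grass and by-product ration: zero edible input, Inf sentinel
  grassy <- tibble::tibble(kg_dm = c(4000, 1500), cp = c(190, 95),
                           hep_fraction = c(0, 0))
  expect_identical(net_hep_efficiency(carcass, grassy, 1, p), Inf)
})

test_that("a mixed ration reproduces the spreadsheet oracle", {
  p <- default_params()
  ration <- tibble::tibble(
    feed = c("grass", "maize_silage", "wheat", "soymeal"),
    kg_dm = c(2500, 1800, 600, 250),
    cp = c(190, 75, 121, 510),
    hep_fraction = c(0, 0, 0.80, 0.65))
  carcass <- 5000
  # hand computation, independently of the implementation path
  edible_in <- 600 * 121 / 1000 * 0.80 + 250 * 510 / 1000 * 0.65
  edible_out <- 5000 * 0.138 * 0.80
  expect_equal(net_hep_efficiency(carcass, ration, 1, p),
               edible_out / edible_in, tolerance = 1e-12)
  # beef-allocated share scales the denominator only
  expect_equal(net_hep_efficiency(carcass, ration, 0.5, p),
               2 * edible_out / edible_in, tolerance = 1e-12)
})

test_that("substituting human-edible concentrate by grass raises net HEP", {
  p <- default_params()
  carcass <- 5000
  base <- tibble::tibble(kg_dm = c(2000, 1000), cp = c(190, 121),
                         hep_fraction = c(0, 0.8))
  # same output, 400 kg DM of wheat replaced by grass
  subst <- tibble::tibble(kg_dm = c(2400, 600), cp = c(190, 121),
                          hep_fraction = c(0, 0.8))
  expect_gt(net_hep_efficiency(carcass, subst, 1, p),
            net_hep_efficiency(carcass, base, 1, p))
})

test_that("work time breakdown is exhaustive and guards zero output", {
  fx <- build_system_fixture("BE", "base")
  sol <- solve_farm(fx$`BE-B`)
  wt <- work_time_per_kg(sol)
  expect_equal(sum(wt$breakdown$hours), wt$total_h, tolerance = 1e-12)
  expect_equal(wt$min_per_kg, wt$total_h * 60 / wt$carcass_kg,
               tolerance = 1e-12)
  expect_setequal(wt$breakdown$task,
                  c("feeding", "caretaking", "calving",
                    "pasture_management", "fieldwork_feed",
                    "admin_maintenance"))
  cfg0 <- toy_farm(cows = 0)
  sol0 <- solve_farm(cfg0)
  expect_error(work_time_per_kg(sol0), "no carcass")
})

test_that("fast rotational grazing raises pasture labor per hectare and total work time", {
  base <- solve_farm(build_system_fixture("BE", "base", seed = 1)$`BE-B`)
  frg <- solve_farm(build_system_fixture("BE", "FRG", seed = 1)$`BE-B`)
  wt_b <- work_time_per_kg(base)
  wt_f <- work_time_per_kg(frg)
  pm <- function(sol, w) {
    ha <- sum(sol$activities$ha[sol$activities$activity %in%
                                  c("graze_cg", "graze_frg")])
    w$breakdown$hours[w$breakdown$task == "pasture_management"] / ha
  }
  # per grazed hectare the FRG sward takes 10% more work ...
  expect_equal(pm(frg, wt_f) / pm(base, wt_b), 1.10, tolerance = 1e-6)
  # ... and the farm as a whole works more per kg carcass
  expect_gt(wt_f$min_per_kg, wt_b$min_per_kg)
})

test_that("profit decomposes into the documented revenue and cost lines", {
  for (sys in c("BE", "FR-IT", "GE")) {
    fx <- build_system_fixture(sys, "base")
    sol <- solve_farm(fx[[1]])
    fp <- farm_profit(sol)
    expect_equal(sum(fp$components$eur), fp$profit, tolerance = 1e-9)
    expect_lt(abs(fp$profit - sol$profit) / max(1, abs(sol$profit)), 1e-6)
    expect_true(all(c("beef_revenue", "milk_revenue", "coupled_subsidy",
                      "decoupled_subsidy", "feed_purchase", "fertilizer",
                      "depreciation") %in% fp$components$item))
  }
})

test_that("a subsidy-only farm earns exactly its subsidy", {
  cfg <- toy_farm(cows = 0)
  cfg$herd <- cfg$herd[0, ]
  cfg$class_feeds <- list()
  cfg$grassland_ha <- 0
  cfg$grass <- cfg$grass[0, ]
  cfg$depreciation <- 0
  sol <- solve_farm(cfg)
  expect_equal(sol$profit, cfg$subsidy$decoupled, tolerance = 1e-9)
})

test_that("stocking rate is LU per hectare of permanent grassland", {
  cfg <- build_system_fixture("GE", "base")$GE
  h <- cohort_progression(cfg)
  cs <- class_summary(cfg$herd)
  lu <- sum(cs$lu * cs$n_head)
  expect_equal(stocking_rate(cfg, h), lu / 27, tolerance = 1e-12)
  cfg2 <- cfg
  cfg2$grassland_ha <- 54
  expect_equal(stocking_rate(cfg2, h), stocking_rate(cfg, h) / 2,
               tolerance = 1e-12)
  h0 <- cohort_progression(cfg, scale = 0)
  expect_equal(stocking_rate(cfg, h0), 0)
  cfg$grassland_ha <- 0
  expect_error(stocking_rate(cfg), "no permanent grassland")
})

test_that("indicators are pure functions of the solution", {
  cfg <- build_system_fixture("GE", "base")$GE
  sol <- solve_farm(cfg)
  i1 <- indicator_set(sol)
  i2 <- indicator_set(sol)
  expect_identical(i1, i2)
})
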