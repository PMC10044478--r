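test_that("grass profiles hit the stated annual totals exactly", {
  cases <- tibble::tribble(
    ~system, ~mgmt,                     ~dm,  ~cp,
    "BE",    "continuous_grazing",      8.0,  NA,
    "FR-IT", "continuous_grazing",      4.0,  NA,
    "GE",    "continuous_grazing",      9.0,  NA,
    "BE",    "fast_rotational_grazing", 9.0,  1.9,
    "FR-IT", "fast_rotational_grazing", 4.4,  0.9,
    "GE",    "fast_rotational_grazing", 9.9,  2.1)
  for (i in seq_len(nrow(cases))) {
    p <- grass_profile(cases$system[i], cases$mgmt[i], seed = 11)
    expect_equal(sum(p$dm_yield), cases$dm[i], tolerance = 1e-12)
    if (!is.na(cases$cp[i]))
      expect_equal(sum(p$dm_yield * p$cp) / 1000, cases$cp[i],
                   tolerance = 1e-12)
  }
})

test_that("growth is zero outside the regional grazing window", {
  for (s in c("BE", "GE")) {
    p <- grass_profile(s, "continuous_grazing", seed = 2)
    expect_true(all(p$dm_yield[c(1:3, 11:12)] == 0))
    expect_true(all(p$dm_yield[4:10] > 0))
  }
  p <- grass_profile("FR-IT", "fast_rotational_grazing", seed = 2)
  expect_true(all(p$dm_yield[c(1:4, 10:12)] == 0))  # mountainous: May-Sep
})

test_that("profiles are bit-identical under a fixed seed and vary across seeds", {
  a <- grass_profile("BE", "fast_rotational_grazing", seed = 5)
  b <- grass_profile("BE", "fast_rotational_grazing", seed = 5)
  c <- grass_profile("BE", "fast_rotational_grazing", seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$dm_yield, c$dm_yield)))
  fx1 <- build_system_fixture("BE", "FRG", seed = 9)
  fx2 <- build_system_fixture("BE", "FRG", seed = 9)
  expect_identical(fx1, fx2)
})

test_that("FRG dominates continuous grazing with the same seasonal support", {
  for (s in c("BE", "FR-IT", "GE")) {
    cg <- grass_profile(s, "continuous_grazing", seed = 3)
    fr <- grass_profile(s, "fast_rotational_grazing", seed = 3)
    expect_gt(sum(fr$dm_yield), sum(cg$dm_yield))
    expect_gt(sum(fr$dm_yield * fr$me), sum(cg$dm_yield * cg$me))
    expect_gt(sum(fr$dm_yield * fr$cp), sum(cg$dm_yield * cg$cp))
    expect_identical(fr$dm_yield > 0, cg$dm_yield > 0)
  }
})

test_that("FRG costs 37.5 EUR/ha more and takes 10% more pasture labor", {
  for (s in c("BE", "FR-IT", "GE")) {
    ga <- grassland_activities(s, frg = TRUE, seed = 1)
    cg <- ga[ga$activity == "graze_cg", ][1, ]
    fr <- ga[ga$activity == "graze_frg", ][1, ]
    expect_equal(fr$variable_cost - cg$variable_cost, 37.5)
    expect_equal(fr$labor / cg$labor, 1.10, tolerance = 1e-12)
  }
})

test_that("fixtures carry the published system endowments", {
  be <- build_system_fixture("BE", "base")
  b <- be$`BE-B`
  expect_equal(b$herd$n[b$herd$class == "suckler_cow"], 155)
  expect_equal(b$arable_ha, 54)
  expect_equal(b$grassland_ha, 64)
  expect_equal(b$herd$out_transfer_yr[b$herd$class == "calf"], 78)

  ge <- build_system_fixture("GE", "base")$GE
  expect_equal(ge$herd$n[ge$herd$class == "dairy_cow"], 130)
  expect_equal(ge$arable_ha, 198)
  expect_equal(ge$grassland_ha, 27)
  expect_equal(ge$herd$n[ge$herd$class == "bull"], 56)

  fr <- build_system_fixture("FR-IT", "base")$`FR-IT-B`
  expect_equal(fr$herd$n[fr$herd$class == "suckler_cow"], 79)
  expect_equal(fr$grassland_ha, 96)
  expect_equal(fr$herd$out_transfer_yr[fr$herd$class == "calf"], 38)
})

test_that("unknown system or scenario is an explicit error", {
  expect_error(build_system_fixture("XX", "base"))
  expect_error(build_system_fixture("BE", "weird"))
})

test_that("feed catalogue covers the required feeds with sane fractions", {
  fc <- feed_catalogue()
  needed <- c("grazed_grass", "grass_silage", "hay", "maize_silage",
              "wheat", "barley", "soymeal", "beet_pulp_pressed",
              "milk_replacer")
  expect_true(all(needed %in% fc$feed))
  expect_true(all(fc$hep_fraction >= 0 & fc$hep_fraction <= 1))
  expect_true(all(fc$dm_fraction > 0 & fc$dm_fraction <= 1))
  expect_true(all(fc$me >= 0 & fc$cp >= 0))
  # grass and wet by-products carry no human-edible protein
  expect_equal(fc$hep_fraction[fc$feed == "grazed_grass"], 0)
  expect_equal(fc$hep_fraction[fc$feed == "beet_pulp_pressed"], 0)
  expect_gt(fc$hep_fraction[fc$feed == "wheat"], 0.5)
})

test_that("the FRG fixture differs from baseline only by the added activity", {
  base <- build_system_fixture("BE", "base", seed = 4)$`BE-B`
  frg <- build_system_fixture("BE", "FRG", seed = 4)$`BE-B`
  expect_setequal(setdiff(unique(frg$grass$activity),
                          unique(base$grass$activity)), "graze_frg")
  expect_identical(base$herd, frg$herd)
  expect_identical(base$crops, frg$crops)
  expect_identical(
    base$grass[base$grass$activity != "graze_frg", ],
    frg$grass[frg$grass$activity != "graze_frg", ])
})
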