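# Physiology registries, baselines and pre-dose calibrations.

test_that("human registry carries the published patient parameters", {
  hp <- load_physiology("human")
  expect_equal(hp$tissues$bone_marrow$plasma_flow, 0.88)
  expect_equal(hp$tissues$bone_marrow$lymph_flow, 0.0155)
  expect_equal(hp$tissues$lymph_node$total_volume, 0.00386)
  expect_equal(hp$blood$shed_nM, 100)
  expect_equal(hp$receptors$cd3_per_cell, 1e5)
  # tissue lymph flows sum to the lymph-node inflow
  lsum <- sum(vapply(hp$tissues[c("bone_marrow", "spleen", "other_tissue")],
                     `[[`, 0, "lymph_flow"))
  expect_equal(lsum, hp$tissues$lymph_node$lymph_flow, tolerance = 2e-3)
  # lumped central blood = plasma + tissue vascular spaces
  expect_equal(hp$blood$volume, 0.044 + 0.0032 + 0.0004 + 0.021)
  expect_error(load_physiology("rat"), "arg")
})

test_that("effector-to-target ratios follow from the baselines", {
  hp <- load_physiology("human")
  expect_equal(effector_target_ratio(hp, "bone_marrow"), 0.555,
               tolerance = 1e-3)
  # equal cell concentrations give unity
  hp2 <- hp
  hp2$tissues$bone_marrow$cd3_nM <-
    hp$tissues$bone_marrow$taa_nM / 12590 * 1e5
  expect_equal(effector_target_ratio(hp2, "bone_marrow"), 1)
  expect_error(effector_target_ratio(hp, "nowhere"), "unknown")
})

test_that("shed synthesis calibration reproduces and holds the blood level", {
  hp <- load_physiology("human")
  cal <- calibrate_shed_synthesis(shed_target_spec(), hp)
  expect_equal(unname(cal$steady_state["blood"]), 100)
  # elimination at steady state equals synthesis (only sink is blood CL)
  expect_equal(cal$synthesis, 1.55 * 100, tolerance = 1e-10)
  # bone marrow, the synthesis site, runs above blood
  expect_gt(cal$steady_state[["bone_marrow"]], 100)
  # linearity: doubling CL at fixed synthesis halves the plasma level,
  # i.e. doubling the CL doubles the synthesis needed for the same level
  cal2 <- calibrate_shed_synthesis(shed_target_spec(cl = 2 * 1.55), hp)
  expect_equal(cal2$synthesis, 2 * cal$synthesis, tolerance = 1e-10)
  expect_error(calibrate_shed_synthesis(shed_target_spec(cl = 0), hp),
               "positive")
})

test_that("stationary cell balances make the printed baselines steady", {
  hp <- load_physiology("human")
  for (ent in c("taa", "cd3")) {
    bal <- stationary_cell_balance(ent, hp)
    expect_true(all(bal$k_return >= 0))
    expect_true(bal$source >= 0)
    # spleen and other tissue carry the printed 0.03/day degradation
    expect_equal(unname(bal$k_deg[c("spleen", "other_tissue")]),
                 c(0.03, 0.03))
    expect_equal(unname(bal$k_deg["bone_marrow"]), 0)
  }
  # an absent population implies zero fluxes everywhere
  hp0 <- hp
  hp0$blood$cd3_nM <- 0
  for (tn in c("bone_marrow", "spleen", "other_tissue", "lymph_node"))
    hp0$tissues[[tn]]$cd3_nM <- 0
  bal0 <- stationary_cell_balance("cd3", hp0)
  expect_equal(unname(bal0$influx * hp0$blood$cd3_nM), rep(0, 3))
  expect_equal(bal0$source, 0)
  # a populated tissue with no feeding influx is flagged as inconsistent
  hp1 <- hp
  hp1$blood$cd3_nM <- 0
  expect_error(stationary_cell_balance("cd3", hp1), "inconsistent")
})

test_that("registry JSON round-trip is numerically exact", {
  hp <- load_physiology("human")
  f <- tempfile(fileext = ".json")
  write_physiology(hp, f)
  back <- read_physiology(f)
  expect_identical(back$blood, hp$blood)
  expect_identical(back$tissues, hp$tissues)
  expect_identical(back$receptors, hp$receptors)
  expect_identical(unclass(back$geometry), unclass(hp$geometry))
})

test_that("mouse registry is flagged synthetic and supports both lymph sets", {
  ms <- load_physiology("mouse", "sepp")
  mh <- load_physiology("mouse", "shah")
  expect_true(ms$synthetic)
  expect_equal(mh$tissues$bone_marrow$lymph_flow,
               0.002 * mh$tissues$bone_marrow$plasma_flow)
  expect_true(ms$tissues$bone_marrow$lymph_flow !=
              mh$tissues$bone_marrow$lymph_flow)
})
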