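# Platform assembly and simulation.

test_that("assembly passes its dimension self-check and reports counts", {
  asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
  expect_equal(asm$n_state, 45L)
  expect_equal(length(asm$state_names), 45L)
  expect_equal(asm$n_reactions, nrow(asm$reactions))
  expect_gt(asm$n_parameters, 50)
  expect_output(print(asm), "45 state variables")
})

test_that("zero-dose simulation holds every baseline stationary", {
  asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
  res <- simulate_regimen(asm, NULL, t_end = 70, dt = 1)
  nm <- asm$state_names
  first <- res$states[1, nm]
  last <- res$states[nrow(res$states), nm]
  keep <- first > 0
  expect_lt(max(abs(last[keep] / first[keep] - 1)), 1e-3)
  # complexes stay identically absent without drug
  expect_lt(max(res$states[, grep("(tri|d_taa|d_cd3|d_shed)",
                                  colnames(res$states))]), 1e-12)
})

test_that("drug mass balance closes for every dosing route", {
  asm <- assemble_platform(molecule_pf06863135(), load_physiology("human"))
  r_sc <- simulate_regimen(asm, dose_regimen("sc", 0.5, n_doses = 4),
                           t_end = 28, dt = 0.25)
  expect_lt(abs(r_sc$mass_balance_residual), 0.005)
  r_iv <- simulate_regimen(asm, dose_regimen("iv_bolus", 0.5, n_doses = 2,
                                             interval = 14),
                           t_end = 28, dt = 0.25)
  expect_lt(abs(r_iv$mass_balance_residual), 0.005)
  asm2 <- assemble_platform(molecule_amg420(), load_physiology("human"))
  r_inf <- simulate_regimen(asm2, dose_regimen("iv_infusion", 0.04,
                                               duration = 28),
                            t_end = 35, dt = 0.25)
  expect_lt(abs(r_inf$mass_balance_residual), 0.005)
})

test_that("weekly subcutaneous dosing shows a sawtooth with a 3-7 day Tmax", {
  asm <- assemble_platform(molecule_pf06863135(), load_physiology("human"))
  res <- simulate_regimen(asm, dose_regimen("sc", 1, n_doses = 10),
                          t_end = 70, dt = 0.1)
  conc <- res$states[, "blood.tce"]
  first_week <- res$times <= 7
  tmax <- res$times[first_week][which.max(conc[first_week])]
  expect_gte(tmax, 2.5)
  expect_lte(tmax, 7)
  # sawtooth: each weekly trough is followed by a rise
  troughs <- vapply(1:9, function(w)
    min(conc[res$times > 7 * (w - 1) & res$times <= 7 * w]), 0)
  expect_true(all(diff(troughs) > 0))   # accumulating IgG
})

test_that("a non-binding infusion approaches the rate/CL plateau linearly", {
  inert <- molecule_spec("inert", 54000,
                         binding_params(1, 1e6, Inf, kon = 0,
                                        kon_target = 0),
                         cl = 0.5, route = "iv_infusion")
  asm <- assemble_platform(inert, load_physiology("human"), shed = NULL)
  res <- simulate_regimen(asm, dose_regimen("iv_infusion", 0.7,
                                            duration = 28),
                          t_end = 28, dt = 0.25)
  rate <- 0.7 / 7 / 54000 * 1e6        # nmol/kg/day
  plateau <- res$states[nrow(res$states), "blood.tce"]
  expect_equal(unname(plateau), rate / 0.5, tolerance = 1e-3)
  # doubling CL halves the plateau
  inert2 <- inert
  inert2$cl <- 1
  asm2 <- assemble_platform(inert2, load_physiology("human"), shed = NULL)
  res2 <- simulate_regimen(asm2, dose_regimen("iv_infusion", 0.7,
                                              duration = 28),
                           t_end = 28, dt = 0.25)
  expect_equal(unname(res2$states[nrow(res2$states), "blood.tce"]),
               rate / 1, tolerance = 1e-3)
})

test_that("a target-blind molecule forms no TAA complexes", {
  asm <- assemble_platform(molecule_amg211(), load_physiology("human"),
                           shed = NULL)
  res <- simulate_regimen(asm, dose_regimen("iv_infusion", 0.1,
                                            duration = 3),
                          t_end = 3, dt = 0.05)
  taa_cols <- grep("\\.(d_taa|tri)$", colnames(res$states))
  expect_lt(max(abs(res$states[, taa_cols])), 1e-9)
  # CD3 binding still happens
  expect_gt(max(res$states[, "blood.d_cd3"]), 0)
})

test_that("solver results are stable to loosening the tolerances", {
  asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
  reg <- dose_regimen("iv_infusion", 0.04, duration = 28)
  tight <- simulate_regimen(asm, reg, t_end = 28, dt = 0.5)
  loose <- simulate_regimen(asm, reg, t_end = 28, dt = 0.5,
                            rtol = 1e-7, atol = 1e-11)
  expect_equal(average_synapse(loose, "bone_marrow", c(0, 28)),
               average_synapse(tight, "bone_marrow", c(0, 28)),
               tolerance = 1e-4)
})

test_that("window averaging validates its window and handles constants", {
  asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
  res <- simulate_regimen(asm, NULL, t_end = 10, dt = 0.5)
  expect_equal(average_synapse(res, "bone_marrow", c(0, 10)), 0)
  expect_error(average_synapse(res, "bone_marrow", c(5, 20)), "span")
})

test_that("mouse biodistribution is size-ordered and lymph-set sensitive", {
  mab <- mouse_biodistribution(150000, cl = 0.1, t_end = 2)
  dab <- mouse_biodistribution(25600, cl = 1.5, t_end = 2)
  i24 <- which.min(abs(mab$time - 1))
  expect_lt(mab$bone_marrow_ratio[i24], dab$bone_marrow_ratio[i24])
  expect_lt(mab$spleen_ratio[i24], dab$spleen_ratio[i24])
  shah <- mouse_biodistribution(25600, cl = 1.5, lymph_set = "shah",
                                t_end = 2)
  expect_false(isTRUE(all.equal(shah$bone_marrow[i24],
                                dab$bone_marrow[i24])))
})

test_that("flat daily infusion dose converts to the weekly per-kg unit", {
  expect_equal(ug_day_to_mg_kg_week(400, 70), 0.04)
})
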