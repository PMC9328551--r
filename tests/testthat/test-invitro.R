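# In vitro cytotoxicity simulation and fitting.

test_that("assay-implied receptor concentrations match the reference setup", {
  expect_equal(expression_from_assay(25000, 1e5, 1e-4), 0.0415,
               tolerance = 2e-3)
  expect_equal(expression_from_assay(5000, 12590, 1e-4), 0.00105,
               tolerance = 5e-3)
  expect_equal(expression_from_assay(0, 1e5, 1e-4), 0)
  expect_error(expression_from_assay(100, 100, 0), "volume")
})

test_that("drug-free and kill-free limits of the assay are exact", {
  cfg <- assay_config()
  b <- pf_binding()
  k <- pf_cytotox()
  expect_equal(simulate_assay(cfg, b, k, 0), k$baseline_fraction,
               tolerance = 1e-6)
  k0 <- cytotox_params(kg = 0.291, kkillmax = 0, kkill50 = 12, hill = 5.89,
                       baseline_fraction = 1)
  v <- simulate_assay(cfg, b, k0, c(0, 0.1, 10))
  expect_equal(v, rep(1, 3), tolerance = 1e-6)
})

test_that("added shed target shifts the potency curve rightward", {
  cfg <- assay_config(baseline_shed_nM = 0.321)
  b <- pf_binding()
  k <- pf_cytotox()
  concs <- 10^seq(-3, 1, by = 0.5)
  ly0 <- 1 - simulate_assay(cfg, b, k, concs, added_shed_nM = 0)
  ly20 <- 1 - simulate_assay(cfg, b, k, concs, added_shed_nM = 20)
  # at every concentration the shed-added curve kills no more
  expect_true(all(ly20 <= ly0 + 1e-8))
  # the quarter-lysis concentration moves right
  quarter <- function(ly) concs[which(ly > 0.25)[1]]
  expect_gt(quarter(ly20), quarter(ly0))
})

test_that("cytotoxicity collapses onto the synapse-count axis", {
  cfg <- assay_config(baseline_shed_nM = 0.321)
  b <- pf_binding()
  k <- pf_cytotox()
  concs <- 10^seq(-3, 1.2, by = 0.35)
  lt0 <- lysis_vs_trimers(cfg, b, k, concs, added_shed_nM = 0)
  lt20 <- lysis_vs_trimers(cfg, b, k, concs, added_shed_nM = 20)
  # interpolate the shed curve onto the shed-free trimer grid: the two
  # relations overlay regardless of the added shed level
  ok <- lt0$avg_trimers_per_cell >=
    min(lt20$avg_trimers_per_cell) &
    lt0$avg_trimers_per_cell <= max(lt20$avg_trimers_per_cell)
  pred <- approx(lt20$avg_trimers_per_cell, lt20$lysis,
                 xout = lt0$avg_trimers_per_cell[ok])$y
  expect_equal(pred, lt0$lysis[ok], tolerance = 0.05)
  # killing switched off produces no lysis at any synapse count
  k0 <- cytotox_params(kg = 0.291, kkillmax = 0, kkill50 = 12, hill = 5.89,
                       baseline_fraction = 1)
  lt <- lysis_vs_trimers(cfg, b, k0, c(0.01, 1))
  expect_equal(lt$lysis, c(0, 0), tolerance = 1e-6)
})

test_that("synapse count at half lysis approaches kkill50 for steep Hill", {
  cfg <- assay_config(baseline_shed_nM = 0.321)
  lt <- lysis_vs_trimers(cfg, pf_binding(), pf_cytotox(),
                         10^seq(-3, 1.2, by = 0.15))
  ts50 <- approx(lt$lysis[1:which.max(lt$lysis)],
                 lt$avg_trimers_per_cell[1:which.max(lt$lysis)],
                 xout = 0.5)$y
  expect_equal(ts50, 12, tolerance = 0.35)
})

test_that("zero-noise data are recovered exactly by the fit", {
  cfg <- assay_config(baseline_shed_nM = 0.321)
  b <- pf_binding()
  k <- pf_cytotox()
  ds <- generate_invitro(cfg, b, k, tce_concs = 10^seq(-3, 1, by = 0.75),
                         shed_levels = c(0, 5, 20), replicates = 1,
                         error = error_model(1e-12, 1e-12), seed = 1)
  fit <- fit_invitro(ds, free = "kd_shed", start = list(kd_shed = 0.08),
                     config = cfg, binding = b, cytotox = k)
  expect_equal(unname(fit$estimates["kd_shed"]), 0.0319, tolerance = 1e-3)
  expect_false(fit$identifiability_flag)
})

test_that("single-shed-level designs flag kd/baseline non-identifiability", {
  cfg <- assay_config()
  b <- amg420_binding()
  k <- amg420_cytotox()
  ds <- generate_invitro(cfg, b, k, tce_concs = 10^seq(-3, 0, by = 1),
                         shed_levels = c(0, 23),
                         error = error_model(1e-12, 0.025), seed = 2)
  expect_warning(
    fit <- fit_invitro(ds, free = c("kd_shed", "baseline_shed"),
                       start = list(kd_shed = 5, baseline_shed = 0.3),
                       config = cfg, binding = b, cytotox = k,
                       error = error_model(0, 0.025)),
    "separately"
  )
  expect_true(fit$identifiability_flag)
})

test_that("fit rejects unknown parameters and incomplete starts", {
  ds <- data.frame(conc_nM = 1, shed_nM = 0, fraction = 0.5, replicate = 1)
  cfg <- assay_config()
  expect_error(fit_invitro(ds, free = "banana", start = list(banana = 1),
                           config = cfg, binding = pf_binding(),
                           cytotox = pf_cytotox()), "unknown free")
  expect_error(fit_invitro(ds, free = "kd_shed", start = list(),
                           config = cfg, binding = pf_binding(),
                           cytotox = pf_cytotox()), "start values")
})

test_that("assay CSV schema round-trips", {
  ds <- data.frame(conc_nM = c(0.1, 1), shed_nM = 0, fraction = c(0.9, 0.2),
                   replicate = 1L)
  f <- tempfile(fileext = ".csv")
  write_assay_csv(ds, f)
  back <- read_assay_csv(f)
  expect_equal(back, ds)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_assay_csv(bad), "columns")
})
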