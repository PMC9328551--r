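# YAML run configs and the end-to-end runner.

write_cfg <- function(lines) {
  f <- tempfile(fileext = ".yml")
  writeLines(lines, f)
  f
}

test_that("configs validate keys, tasks and doses before any computation", {
  f <- write_cfg(c("task: simulate", "molecule: AMG420", "banana: 1"))
  expect_error(read_run_config(f), "unknown config key")
  f2 <- write_cfg(c("task: dance", "molecule: AMG420"))
  expect_error(read_run_config(f2), "task")
  f3 <- write_cfg(c("task: simulate", "molecule: AMG420", "regimen:",
                    "  dose_mg_kg: -1"))
  expect_error(read_run_config(f3), "dose")
  f4 <- write_cfg(c("task: simulate", "molecule:", "  name: custom",
                    "  mw_da: 54000"))
  expect_error(read_run_config(f4), "requires keys")
})

test_that("built-in molecules resolve with provenance strings", {
  f <- write_cfg(c("task: simulate", "molecule: PF-06863135",
                   "regimen:", "  dose_mg_kg: 1"))
  cfg <- read_run_config(f)
  expect_equal(cfg$molecule$mw, 150000)
  expect_true(any(grepl("built-in", cfg$provenance)))
  expect_true(any(grepl("registry 'human'", cfg$provenance)))
})

test_that("the bundled example config validates and resolves", {
  f <- system.file("extdata", "pf_weekly_sc_example.yml",
                   package = "tcesim")
  expect_true(nzchar(f))
  cfg <- read_run_config(f)
  expect_equal(cfg$task, "simulate")
  expect_equal(cfg$molecule$name, "PF-06863135")
  expect_equal(cfg$regimen$n_doses, 10)
})

test_that("the simulate task writes trajectories, report and log", {
  out <- file.path(tempdir(), "runA")
  f <- write_cfg(c("task: simulate", "molecule: AMG420",
                   "regimen:", "  route: iv_infusion",
                   "  dose_mg_kg: 0.04", "  duration_days: 14",
                   "solver:", "  t_end_days: 14", "  dt_days: 0.5",
                   paste0("output: ", out)))
  rep <- run_from_config(f)
  expect_equal(rep$n_states, 45L)
  expect_lt(abs(rep$mass_balance_residual), 0.005)
  traj <- read.csv(paste0(out, "_trajectories.csv"))
  expect_named(traj, c("time", "compartment", "species", "value"))
  expect_equal(sort(unique(traj$species)), sort(binding_species()))
  expect_true(file.exists(paste0(out, "_report.json")))
  log <- readLines(paste0(out, "_run.log"))
  expect_true(any(grepl("mass-balance", log)))
  # rerun of the identical config is byte-identical
  out2 <- file.path(tempdir(), "runB")
  f2 <- write_cfg(sub(out, out2, readLines(f)))
  run_from_config(f2)
  expect_identical(readLines(paste0(out, "_trajectories.csv")),
                   readLines(paste0(out2, "_trajectories.csv")))
})

test_that("synth and fit tasks chain through the CSV schema", {
  out <- file.path(tempdir(), "runC")
  ds_path <- paste0(out, "_invitro.csv")
  f <- write_cfg(c("task: synth", "molecule: AMG420", "seed: 4",
                   "synth:",
                   "  tce_concs_nM: [0.001, 0.01, 0.1, 1]",
                   "  shed_levels_nM: [0, 23]",
                   paste0("  dataset_csv: ", ds_path),
                   paste0("output: ", out)))
  rep <- run_from_config(f)
  expect_true(file.exists(ds_path))
  expect_equal(rep$n_rows, 8)
  f2 <- write_cfg(c("task: fit", "molecule: AMG420",
                    "fit:",
                    paste0("  dataset_csv: ", ds_path),
                    "  free: [kd_shed]",
                    "  start:", "    kd_shed: 4",
                    paste0("output: ", out, "_fit")))
  rep2 <- run_from_config(f2)
  expect_true(is.finite(rep2$estimates$kd_shed))
  expect_true(is.finite(rep2$objective))
  # missing dataset errors with the path
  f3 <- write_cfg(c("task: fit", "molecule: AMG420",
                    "fit:", "  dataset_csv: /nonexistent.csv",
                    paste0("output: ", out)))
  expect_error(run_from_config(f3), "nonexistent")
})
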