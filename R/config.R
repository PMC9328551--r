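# YAML run configuration binding the modules into a scriptable tool. A
# config names the task (simulate / fit / sweep / sensitivity / dosematch /
# synth), the molecule (a built-in name or explicit parameters with units in
# the key names), the physiology species, the regimen and the outputs.
# Validation rejects unknown keys before any computation, and every resolved
# numeric carries a provenance string (registry default or user override) in
# the run log.

.CONFIG_TASKS <- c("simulate", "fit", "sweep", "sensitivity", "dosematch",
                   "synth")

.CONFIG_KEYS <- list(
  top = c("task", "molecule", "physiology", "shed", "regimen", "output",
          "seed", "solver", "sensitivity", "sweep", "dosematch", "fit",
          "synth"),
  molecule = c("name", "mw_da", "kd_target_nM", "kd_cd3_nM", "kd_shed_nM",
               "kon_per_nM_day", "cl_L_per_day_per_kg", "route",
               "ka_per_day", "f_bio"),
  shed = c("enabled", "mw_da", "cl_L_per_day_per_kg", "blood_nM"),
  regimen = c("route", "dose_mg_kg", "n_doses", "interval_days",
              "duration_days", "start_day"),
  solver = c("rtol", "atol", "t_end_days", "dt_days"),
  sensitivity = c("parameters", "tissues", "rel_step"),
  sweep = c("p1", "p2", "p1_values", "p2_values", "tissue", "window_days"),
  dosematch = c("reference_synapses_per_cell", "tissue", "window_days",
                "bracket_mg_kg_week"),
  fit = c("dataset_csv", "free", "start", "proportional_error",
          "additive_error", "readout", "baseline_shed_nM"),
  synth = c("tce_concs_nM", "shed_levels_nM", "replicates",
            "proportional_error", "additive_error", "dataset_csv")
)

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0)
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "))
}

#' Read and validate a run configuration
#'
#' Parses a YAML run config, rejects unknown keys, resolves the molecule
#' (built-in `PF-06863135`, `AMG420`, `AMG211`, or explicit parameters) and
#' assembles the task inputs. Unit conventions are embedded in the key names
#' (e.g. `cl_L_per_day_per_kg`).
#'
#' @param path YAML file path.
#' @return An object of class `run_config`: the validated config plus
#'   resolved `molecule`, `physiology`, `shed`, `regimen` objects and a
#'   `provenance` character vector recording where each value came from.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .CONFIG_KEYS$top, "top level")
  if (is.null(cfg$task) || !cfg$task %in% .CONFIG_TASKS)
    stop("config must set task to one of: ",
         paste(.CONFIG_TASKS, collapse = ", "))
  prov <- character(0)
  note <- function(key, src) prov <<- c(prov, sprintf("%s: %s", key, src))

  phys_name <- cfg$physiology %||% "human"
  physiology <- load_physiology(phys_name)
  note("physiology", paste0("registry '", phys_name, "'"))

  mol_cfg <- cfg$molecule
  if (is.character(mol_cfg)) mol_cfg <- list(name = mol_cfg)
  if (!is.null(mol_cfg)) .check_keys(mol_cfg, .CONFIG_KEYS$molecule,
                                     "molecule")
  builtin <- list("PF-06863135" = molecule_pf06863135,
                  "AMG420" = molecule_amg420, "AMG211" = molecule_amg211)
  if (!is.null(mol_cfg$name) && mol_cfg$name %in% names(builtin)) {
    molecule <- builtin[[mol_cfg$name]]()
    note("molecule", paste0("built-in '", mol_cfg$name, "'"))
  } else if (!is.null(mol_cfg)) {
    need <- c("mw_da", "kd_target_nM", "kd_cd3_nM", "cl_L_per_day_per_kg")
    if (!all(need %in% names(mol_cfg)))
      stop("explicit molecule requires keys: ", paste(need, collapse = ", "))
    molecule <- molecule_spec(
      mol_cfg$name %||% "custom", mol_cfg$mw_da,
      binding_params(mol_cfg$kd_target_nM, mol_cfg$kd_cd3_nM,
                     mol_cfg$kd_shed_nM %||% Inf,
                     kon = mol_cfg$kon_per_nM_day %||% 86),
      cl = mol_cfg$cl_L_per_day_per_kg,
      route = mol_cfg$route %||% "sc",
      ka = mol_cfg$ka_per_day %||% 0.7,
      f_bio = mol_cfg$f_bio %||% 1)
    note("molecule", "user-specified parameters")
  } else molecule <- NULL

  shed <- shed_target_spec()
  note("shed", "default (5 kDa, CL 1.55 L/day/kg, blood 100 nM)")
  if (!is.null(cfg$shed)) {
    .check_keys(cfg$shed, .CONFIG_KEYS$shed, "shed")
    if (isFALSE(cfg$shed$enabled)) {
      shed <- NULL
      note("shed", "disabled by config")
    } else {
      shed <- shed_target_spec(
        mw = cfg$shed$mw_da %||% 5000,
        cl = cfg$shed$cl_L_per_day_per_kg %||% 1.55,
        target_blood_nM = cfg$shed$blood_nM %||% 100)
      note("shed", "user override")
    }
  }

  regimen <- NULL
  if (!is.null(cfg$regimen)) {
    .check_keys(cfg$regimen, .CONFIG_KEYS$regimen, "regimen")
    if (is.null(cfg$regimen$dose_mg_kg) || cfg$regimen$dose_mg_kg < 0)
      stop("regimen requires a non-negative dose_mg_kg")
    regimen <- dose_regimen(
      route = cfg$regimen$route %||% molecule$route %||% "sc",
      dose = cfg$regimen$dose_mg_kg,
      n_doses = cfg$regimen$n_doses %||% 1,
      interval = cfg$regimen$interval_days %||% 7,
      duration = cfg$regimen$duration_days %||% 28,
      start = cfg$regimen$start_day %||% 0)
    note("regimen", sprintf("%s %g mg/kg", regimen$route, regimen$dose))
  }

  solver <- cfg$solver %||% list()
  .check_keys(solver, .CONFIG_KEYS$solver, "solver")
  structure(list(task = cfg$task, raw = cfg, molecule = molecule,
                 physiology = physiology, shed = shed, regimen = regimen,
                 solver = solver, seed = cfg$seed %||% 1,
                 output = cfg$output %||% "tcesim_out",
                 provenance = prov),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# published in vitro cytotoxicity parameter sets for the built-in molecules
.default_cytotox <- function(name) {
  if (identical(name, "AMG420"))
    cytotox_params(kg = 0.291, kkillmax = 2.93, kkill50 = 0.0229, hill = 1,
                   baseline_fraction = 1)
  else
    cytotox_params(kg = 0.291, kkillmax = 2.38, kkill50 = 12, hill = 5.89,
                   baseline_fraction = 1.01)
}

#' Execute a run configuration
#'
#' Dispatches on the config task and writes the result files next to the
#' configured output stem: tidy trajectories CSV (`<out>_trajectories.csv`),
#' a JSON report (`<out>_report.json`) and a run log with the resolved
#' provenance (`<out>_run.log`).
#'
#' @param config A [read_run_config()] object or a path to a YAML config.
#' @return The report list, invisibly.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$output
  t_end <- config$solver$t_end_days %||% 70
  dt <- config$solver$dt_days %||% 0.25
  report <- list(task = config$task, seed = config$seed)
  log_lines <- c(sprintf("tcesim run: task=%s", config$task),
                 config$provenance)

  if (config$task == "simulate") {
    asm <- assemble_platform(config$molecule, config$physiology, config$shed)
    res <- simulate_regimen(asm, config$regimen, t_end = t_end, dt = dt,
                            rtol = config$solver$rtol %||%
                              platform_defaults()$rtol,
                            atol = config$solver$atol %||%
                              platform_defaults()$atol)
    traj <- result_to_long(res)
    utils::write.csv(traj, paste0(out, "_trajectories.csv"),
                     row.names = FALSE)
    report$n_states <- asm$n_state
    report$n_reactions <- asm$n_reactions
    report$mass_balance_residual <- res$mass_balance_residual
    report$synapse_day_avg <- lapply(
      stats::setNames(nm = .COMPARTMENTS),
      function(k) average_synapse(res, k, c(0, t_end)))
    log_lines <- c(log_lines,
                   sprintf("mass-balance residual: %.3e",
                           res$mass_balance_residual))
  } else if (config$task == "synth") {
    sy <- config$raw$synth %||% list()
    .check_keys(sy, .CONFIG_KEYS$synth, "synth")
    ds <- generate_invitro(
      assay_config(), config$molecule$binding,
      .default_cytotox(config$molecule$name),
      tce_concs = unlist(sy$tce_concs_nM) %||% 10^seq(-5, 2, by = 0.5),
      shed_levels = unlist(sy$shed_levels_nM) %||% c(0, 1.2, 5, 20),
      replicates = sy$replicates %||% 1,
      error = error_model(sy$proportional_error %||% 0.0732,
                          sy$additive_error %||% 0.00593),
      seed = config$seed)
    path <- sy$dataset_csv %||% paste0(out, "_invitro.csv")
    write_assay_csv(ds, path)
    report$dataset <- path
    report$n_rows <- nrow(ds)
  } else if (config$task == "fit") {
    ft <- config$raw$fit %||% list()
    .check_keys(ft, .CONFIG_KEYS$fit, "fit")
    if (is.null(ft$dataset_csv) || !file.exists(ft$dataset_csv))
      stop("fit task: dataset file not found: ",
           ft$dataset_csv %||% "<missing>")
    ds <- read_assay_csv(ft$dataset_csv)
    cfg_assay <- assay_config(
      baseline_shed_nM = ft$baseline_shed_nM %||% 0,
      readout = ft$readout %||% "viability")
    free <- unlist(ft$free) %||% "kd_shed"
    start <- ft$start %||% stats::setNames(as.list(rep(1, length(free))),
                                           free)
    fit <- fit_invitro(ds, free = free, start = start, config = cfg_assay,
                       binding = config$molecule$binding,
                       cytotox = .default_cytotox(config$molecule$name),
                       error = error_model(ft$proportional_error %||% 0.0732,
                                           ft$additive_error %||% 0.00593))
    report$estimates <- as.list(fit$estimates)
    report$rse_percent <- as.list(fit$rse_percent)
    report$objective <- fit$objective
    report$identifiability_flag <- fit$identifiability_flag
  } else if (config$task == "sensitivity") {
    se <- config$raw$sensitivity %||% list()
    .check_keys(se, .CONFIG_KEYS$sensitivity, "sensitivity")
    asm <- assemble_platform(config$molecule, config$physiology, config$shed)
    sens <- local_sensitivity(
      asm, config$regimen,
      parameters = unlist(se$parameters) %||%
        c("kd_target", "kd_cd3", "kd_shed", "cl"),
      tissues = unlist(se$tissues) %||% c("blood", "bone_marrow",
                                          "lymph_node"),
      t_end = t_end, dt = dt,
      rel_step = se$rel_step %||% 0.01)
    utils::write.csv(sens, paste0(out, "_sensitivity.csv"),
                     row.names = FALSE)
    report$indices <- sens
  } else if (config$task == "sweep") {
    sw <- config$raw$sweep %||% list()
    .check_keys(sw, .CONFIG_KEYS$sweep, "sweep")
    asm <- assemble_platform(config$molecule, config$physiology, config$shed)
    grid <- sweep_2d(asm, config$regimen,
                     p1 = sw$p1 %||% "kd_target", p2 = sw$p2 %||% "kd_cd3",
                     p1_values = unlist(sw$p1_values) %||% 10^seq(-2, 1),
                     p2_values = unlist(sw$p2_values) %||% 10^seq(-2, 1),
                     tissue = sw$tissue %||% "blood",
                     window = unlist(sw$window_days) %||% c(56, 70),
                     t_end = t_end, dt = dt)
    utils::write.csv(grid$long, paste0(out, "_sweep.csv"),
                     row.names = FALSE)
    report$grid_dim <- dim(grid$matrix)
  } else if (config$task == "dosematch") {
    dm <- config$raw$dosematch %||% list()
    .check_keys(dm, .CONFIG_KEYS$dosematch, "dosematch")
    dose <- dose_match(
      reference = dm$reference_synapses_per_cell %||%
        stop("dosematch task requires reference_synapses_per_cell"),
      molecule = config$molecule, physiology = config$physiology,
      shed = config$shed,
      tissue = dm$tissue %||% "bone_marrow",
      window = unlist(dm$window_days) %||% c(56, 70),
      bracket = unlist(dm$bracket_mg_kg_week) %||% c(1e-4, 100))
    report$matched_dose_mg_kg_week <- as.numeric(dose)
    report$achieved_synapses_per_cell <- attr(dose, "achieved")
  }

  jsonlite::write_json(report, paste0(out, "_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, paste0(out, "_run.log"))
  invisible(report)
}

#' Tidy long-format trajectories from a platform result
#'
#' @param result A [simulate_regimen()] result.
#' @return A data.frame with `time`, `compartment`, `species`, `value`.
#' @export
result_to_long <- function(result) {
  st <- result$states[, result$assembly$state_names, drop = FALSE]
  cn <- colnames(st)
  comp <- sub("\\..*$", "", cn)
  spec <- sub("^[^.]*\\.", "", cn)
  data.frame(
    time = rep(result$times, times = ncol(st)),
    compartment = rep(comp, each = nrow(st)),
    species = rep(spec, each = nrow(st)),
    value = as.vector(st)
  )
}
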