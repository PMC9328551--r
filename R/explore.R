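# Model exploration: local sensitivity with dedimensionalized indices, 2D
# parameter sweeps, dose-response scans and cross-format dose matching.

# Apply a named parameter perturbation to the ingredients of an assembly and
# rebuild it. Understood names: kd_target, kd_cd3, kd_shed, kon, cl,
# shed_level (blood shed target), shed_cl (shed elimination), taa_<tissue>,
# cd3_<tissue>, taa_blood, cd3_blood, ps_scale.
.perturbed_assembly <- function(assembly, param, factor) {
  mol <- assembly$molecule
  phys <- assembly$physiology
  shed <- assembly$shed
  ps <- assembly$ps_scale
  b <- mol$binding
  if (param %in% c("kd_target", "kd_cd3", "kd_shed", "kon")) {
    b[[param]] <- b[[param]] * factor
    mol$binding <- binding_params(b$kd_target, b$kd_cd3, b$kd_shed,
                                  kon = b$kon,
                                  kon_target = if (mol$binding$kon_target ==
                                                   mol$binding$kon) b$kon
                                               else mol$binding$kon_target)
  } else if (param == "cl") {
    mol$cl <- mol$cl * factor
  } else if (param == "shed_level") {
    shed$target_blood_nM <- shed$target_blood_nM * factor
  } else if (param == "shed_cl") {
    shed$cl <- shed$cl * factor
  } else if (param == "ps_scale") {
    ps <- ps * factor
  } else if (grepl("^(taa|cd3)_", param)) {
    ent <- sub("_.*$", "", param)
    comp <- sub("^(taa|cd3)_", "", param)
    field <- paste0(ent, "_nM")
    # an expression perturbation changes receptors per cell at fixed cell
    # numbers: freeze the tumor-cell concentration before scaling the marker
    if (comp == "blood") {
      if (ent == "taa" && is.null(phys$blood$cells_nM))
        phys$blood$cells_nM <- phys$blood$taa_nM /
          phys$receptors$taa_per_cell
      phys$blood[[field]] <- phys$blood[[field]] * factor
    } else if (comp %in% names(phys$tissues)) {
      if (ent == "taa" && is.null(phys$tissues[[comp]]$cells_nM))
        phys$tissues[[comp]]$cells_nM <- phys$tissues[[comp]]$taa_nM /
          phys$receptors$taa_per_cell
      phys$tissues[[comp]][[field]] <- phys$tissues[[comp]][[field]] * factor
    } else stop("unknown compartment in parameter: ", param)
  } else stop("unknown sensitivity parameter: ", param)
  assemble_platform(mol, phys, shed, ps_scale = ps)
}

#' Local parameter sensitivity of immune synapse formation
#'
#' Dedimensionalized local sensitivity indices by central finite differences:
#' the baseline simulation is perturbed by `+/- rel_step` in each parameter,
#' the normalized time-dependent index `(dy/dp) (p/y)` is formed on the
#' synapse-per-cell trajectory, and the index is integrated over the
#' simulated span (trapezoid, divided by the span). Signs are preserved
#' (no absolute value), so a positively correlated parameter yields a
#' positive index.
#'
#' @param assembly A [assemble_platform()] object.
#' @param regimen A [dose_regimen()].
#' @param parameters Character vector of parameter names; see Details.
#' @param tissues Output compartments.
#' @param t_end,dt Simulation span and output spacing (days).
#' @param rel_step Relative perturbation (default 1%).
#' @details Understood parameter names: `kd_target`, `kd_cd3`, `kd_shed`,
#'   `kon`, `cl` (drug clearance), `shed_level` (pre-dose blood shed
#'   concentration), `shed_cl` (shed elimination), `taa_<compartment>` and
#'   `cd3_<compartment>` baseline expressions (e.g. `taa_bone_marrow`,
#'   `cd3_blood`), and `ps_scale`.
#' @return A data.frame with `parameter`, `tissue` and `index`; an index is
#'   `NA` when the baseline output is essentially zero throughout.
#' @export
local_sensitivity <- function(assembly, regimen, parameters,
                              tissues = c("blood", "bone_marrow",
                                          "lymph_node"),
                              t_end = 70, dt = 0.25, rel_step = 0.01) {
  base <- simulate_regimen(assembly, regimen, t_end = t_end, dt = dt)
  tt <- base$times
  span <- max(tt) - min(tt)
  trap <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2) / span
  rows <- list()
  for (p in parameters) {
    up <- simulate_regimen(.perturbed_assembly(assembly, p, 1 + rel_step),
                           regimen, t_end = t_end, dt = dt)
    dn <- simulate_regimen(.perturbed_assembly(assembly, p, 1 - rel_step),
                           regimen, t_end = t_end, dt = dt)
    for (k in tissues) {
      y0 <- base$synapse_per_cell[, k]
      if (max(abs(y0)) < 1e-300) {
        idx <- NA_real_
      } else {
        dy <- (up$synapse_per_cell[, k] - dn$synapse_per_cell[, k]) /
          (2 * rel_step)
        # (dy/dp)(p/y) with p-relative step: dy/dlog(p) / y
        rel <- ifelse(y0 > 0, dy / y0, 0)
        idx <- trap(rel)
      }
      rows[[length(rows) + 1L]] <- data.frame(parameter = p, tissue = k,
                                              index = idx)
    }
  }
  do.call(rbind, rows)
}

#' Two-dimensional parameter sweep
#'
#' Window-averaged synapse-per-cell response over a log-spaced grid of two
#' parameters, one independent deterministic simulation per grid point.
#' Failed points are recorded as `NA`, not fatal.
#'
#' @param assembly Baseline assembly (template).
#' @param regimen A [dose_regimen()].
#' @param p1,p2 Parameter names (as in [local_sensitivity()]).
#' @param p1_values,p2_values Absolute parameter values for the grid axes
#'   (strictly monotone).
#' @param tissue Output compartment.
#' @param window Averaging window (days).
#' @param t_end,dt Simulation span and output spacing.
#' @return An object of class `sweep_grid`: list with the axes and the
#'   response `matrix` (rows = p1, cols = p2), plus a long-format
#'   data.frame `long` with columns `p1`, `p2`, `tissue`, `response`.
#' @export
sweep_2d <- function(assembly, regimen, p1, p2, p1_values, p2_values,
                     tissue = "blood", window = c(56, 70), t_end = 70,
                     dt = 0.25) {
  stopifnot(length(p1_values) >= 2, length(p2_values) >= 1,
            all(diff(p1_values) > 0) || all(diff(p1_values) < 0))
  base1 <- .param_baseline(assembly, p1)
  base2 <- .param_baseline(assembly, p2)
  M <- matrix(NA_real_, length(p1_values), length(p2_values))
  for (i in seq_along(p1_values)) {
    a1 <- .perturbed_assembly(assembly, p1, p1_values[i] / base1)
    for (j in seq_along(p2_values)) {
      aij <- .perturbed_assembly(a1, p2, p2_values[j] / base2)
      M[i, j] <- tryCatch({
        res <- simulate_regimen(aij, regimen, t_end = t_end, dt = dt)
        average_synapse(res, tissue, window)
      }, error = function(e) NA_real_)
    }
  }
  long <- expand.grid(p1 = p1_values, p2 = p2_values)
  long$tissue <- tissue
  long$response <- as.vector(M)
  structure(list(p1 = p1, p2 = p2, p1_values = p1_values,
                 p2_values = p2_values, matrix = M, long = long,
                 tissue = tissue),
            class = "sweep_grid")
}

.param_baseline <- function(assembly, param) {
  if (param %in% c("kd_target", "kd_cd3", "kd_shed", "kon"))
    assembly$molecule$binding[[param]]
  else if (param == "cl") assembly$molecule$cl
  else if (param == "shed_level") assembly$shed$target_blood_nM
  else if (param == "shed_cl") assembly$shed$cl
  else if (param == "ps_scale") assembly$ps_scale
  else if (grepl("^(taa|cd3)_", param)) {
    ent <- sub("_.*$", "", param)
    comp <- sub("^(taa|cd3)_", "", param)
    field <- paste0(ent, "_nM")
    if (comp == "blood") assembly$physiology$blood[[field]]
    else assembly$physiology$tissues[[comp]][[field]]
  } else stop("unknown parameter: ", param)
}

#' One-dimensional sweep of the CD3 dissociation constant
#'
#' Convenience wrapper around the platform used to examine the CD3-affinity
#' "sweet spot": the synapse response in a compartment across kd_CD3 values,
#' optionally with CD3 expression forced uniform across all compartments
#' (which removes the tissue trapping gradient) or with the platform
#' collapsed to a single well-mixed compartment.
#'
#' @param kd_values kd_CD3 grid (nM).
#' @param molecule,physiology,shed,regimen Platform ingredients.
#' @param tissue Output compartment.
#' @param window,t_end,dt Averaging window and simulation span (days).
#' @param uniform_cd3 If `TRUE`, set every compartment's CD3 baseline to the
#'   blood value.
#' @param one_compartment If `TRUE`, use a closed one-compartment binding
#'   model (blood baselines, dose into the blood volume) instead of the
#'   platform.
#' @return A data.frame with `kd_cd3` and `response`.
#' @export
kd_cd3_sweep <- function(kd_values, molecule = molecule_pf06863135(),
                         physiology = load_physiology("human"),
                         shed = shed_target_spec(),
                         regimen = dose_regimen("sc", 1, n_doses = 10),
                         tissue = "blood", window = c(56, 70), t_end = 70,
                         dt = 0.25, uniform_cd3 = FALSE,
                         one_compartment = FALSE) {
  if (uniform_cd3) {
    cb <- physiology$blood$cd3_nM
    for (tn in exchanging_tissues(physiology))
      physiology$tissues[[tn]]$cd3_nM <- cb
    physiology$tissues$lymph_node$cd3_nM <- cb
  }
  out <- vapply(kd_values, function(kd) {
    b <- molecule$binding
    mol <- molecule
    mol$binding <- binding_params(b$kd_target, kd, b$kd_shed, kon = b$kon,
                                  kon_target = b$kon_target)
    if (one_compartment) {
      .one_compartment_response(mol, physiology, shed, regimen, window,
                                t_end, dt)
    } else {
      asm <- assemble_platform(mol, physiology, shed)
      res <- simulate_regimen(asm, regimen, t_end = t_end, dt = dt)
      average_synapse(res, tissue, window)
    }
  }, 0)
  data.frame(kd_cd3 = kd_values, response = out)
}

# closed one-compartment analogue: blood baselines, drug input and CL, no
# tissues; synapse per tumor cell from blood cell concentration
.one_compartment_response <- function(molecule, physiology, shed, regimen,
                                      window, t_end, dt) {
  vb <- physiology$blood$volume
  cells <- physiology$blood$taa_nM / physiology$receptors$taa_per_cell
  shed0 <- shed$target_blood_nM
  kel_shed <- shed$cl / vb
  syn_shed <- kel_shed * shed0                     # keeps shed stationary
  binding <- molecule$binding
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    s <- as.list(y[.SPECIES])
    r <- .step_rates(s, binding)
    d <- c(-r$r1 - r$r2 - r$r3, -r$r1 - r$r5, -r$r2 - r$r4 - r$r6,
           -r$r3 - r$r7, r$r1 - r$r4, r$r2 - r$r5 - r$r7, r$r3 - r$r6,
           r$r4 + r$r5, r$r6 + r$r7)
    d[1] <- d[1] - molecule$cl / vb * y[1] + p$ka * y[10] / vb
    d[4] <- d[4] + syn_shed - kel_shed * y[4]
    list(c(d, -p$ka * y[10]))
  }
  y <- c(0, physiology$blood$taa_nM, physiology$blood$cd3_nM, shed0,
         0, 0, 0, 0, 0, 0)
  names(y) <- c(.SPECIES, "depot")
  times <- seq(0, t_end, by = dt)
  dose_times <- regimen$start + regimen$interval *
    (seq_len(regimen$n_doses) - 1)
  dose_times <- dose_times[dose_times < t_end]
  amt <- regimen$dose / molecule$mw * 1e6 * molecule$f_bio
  evt <- data.frame(var = "depot", time = dose_times, value = amt,
                    method = "add")
  out <- deSolve::lsoda(y, times, rhs, list(ka = molecule$ka),
                        events = list(data = evt),
                        rtol = 1e-8, atol = 1e-12, maxsteps = 20000)
  idx <- out[, 1] >= window[1] & out[, 1] <= window[2]
  mean(out[idx, "tri"]) / cells
}

#' Dose-response scan
#'
#' Window-averaged synapse per tumor cell in every compartment across a
#' weekly dose grid, with the shed target present or absent.
#'
#' @param molecule A [molecule_spec()].
#' @param doses Weekly doses (mg/kg/week).
#' @param physiology A physiology registry.
#' @param shed_on Include the shed target at its calibrated level?
#' @param regimen_for Function mapping a weekly dose to a [dose_regimen()];
#'   defaults to the molecule's native schedule (weekly SC for `"sc"`
#'   molecules, 28-day infusion otherwise).
#' @param window,t_end,dt Averaging window and simulation span (days).
#' @return A data.frame with `dose`, one column per compartment.
#' @export
dose_response <- function(molecule, doses,
                          physiology = load_physiology("human"),
                          shed_on = TRUE, regimen_for = NULL,
                          window = NULL, t_end = NULL, dt = 0.25) {
  stopifnot(all(doses > 0))
  if (is.null(regimen_for)) {
    regimen_for <- if (molecule$route == "sc")
      function(d) dose_regimen("sc", d, n_doses = 10, interval = 7)
    else
      function(d) dose_regimen("iv_infusion", d, duration = 28)
  }
  if (is.null(window))
    window <- if (molecule$route == "sc") c(56, 70) else c(0, 28)
  if (is.null(t_end)) t_end <- max(window)
  shed <- if (shed_on) shed_target_spec() else NULL
  asm <- assemble_platform(molecule, physiology, shed)
  rows <- lapply(doses, function(d) {
    res <- simulate_regimen(asm, regimen_for(d), t_end = t_end, dt = dt)
    vals <- vapply(.COMPARTMENTS, function(k)
      average_synapse(res, k, window), 0)
    c(dose = d, vals)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Match a dose to a reference synapse level
#'
#' Bisection on the logarithm of the weekly dose so that the window-averaged
#' synapse count in the given tissue equals a reference level; returns the
#' lowest matching dose when the dose-response is non-monotone. If the level
#' is unreachable, an error is raised carrying the achievable maximum.
#'
#' @param reference Synapses per tumor cell to match (> 0; a reference of 0
#'   returns dose 0).
#' @param molecule A [molecule_spec()].
#' @param physiology A physiology registry.
#' @param shed A [shed_target_spec()] or `NULL`.
#' @param regimen_for Function mapping a weekly dose to a [dose_regimen()].
#' @param tissue Output compartment.
#' @param window,t_end,dt Averaging window and simulation span (days).
#' @param bracket Initial dose bracket (mg/kg/week).
#' @param tol Relative dose tolerance (default 1%).
#' @return Matched dose (mg/kg/week) with attribute `achieved`.
#' @export
dose_match <- function(reference, molecule = molecule_pf06863135(),
                       physiology = load_physiology("human"),
                       shed = shed_target_spec(),
                       regimen_for = function(d)
                         dose_regimen("sc", d, n_doses = 10, interval = 7),
                       tissue = "bone_marrow", window = c(56, 70),
                       t_end = 70, dt = 0.25,
                       bracket = c(1e-4, 100), tol = 0.01) {
  if (reference < 0) stop("reference level must be non-negative")
  if (reference == 0) return(structure(0, achieved = 0))
  asm <- assemble_platform(molecule, physiology, shed)
  f <- function(d) {
    res <- simulate_regimen(asm, regimen_for(d), t_end = t_end, dt = dt)
    average_synapse(res, tissue, window)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo)
  if (flo >= reference)
    stop("reference already reached at the lower bracket; lower it")
  # walk up until the reference is crossed on the ascending limb
  fhi <- f(hi)
  if (fhi < reference) {
    # response may be non-monotone; scan for the maximum
    grid <- exp(seq(log(lo), log(hi), length.out = 9))
    vals <- vapply(grid, f, 0)
    if (max(vals, fhi, flo) < reference)
      stop(sprintf("reference level %.4g unreachable; maximum achievable %.4g",
                   reference, max(vals, fhi, flo)))
    hi <- grid[which(vals >= reference)[1]]
    lo <- if (which(vals >= reference)[1] > 1)
      grid[which(vals >= reference)[1] - 1] else lo
  }
  while (hi / lo - 1 > tol) {
    mid <- sqrt(lo * hi)
    if (f(mid) >= reference) hi <- mid else lo <- mid
  }
  dose <- sqrt(lo * hi)
  structure(dose, achieved = f(dose))
}
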