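# Synthetic datasets with the statistical structure the fitting code
# assumes: in vitro cytotoxicity curves under the combined
# proportional+additive error model, and sparse plasma PK samples with
# proportional (lognormal-style) noise. Both are fully reproducible given a
# seed.

#' Generate a synthetic in vitro cytotoxicity dataset
#'
#' Simulates the truth curves with [simulate_assay()] and adds combined
#' error: `obs = pred (1 + proportional e1) + additive e2`, with independent
#' standard-normal draws per well.
#'
#' @param config An [assay_config()].
#' @param binding A [binding_params()] (truth).
#' @param cytotox A [cytotox_params()] (truth).
#' @param tce_concs TCE concentration grid (nM).
#' @param shed_levels Added shed-target levels (nM).
#' @param replicates Wells per (concentration, shed) combination.
#' @param error An [error_model()].
#' @param seed Integer seed.
#' @return A data.frame with columns `conc_nM`, `shed_nM`, `fraction`,
#'   `replicate` (the CSV schema of [fit_invitro()]).
#' @export
#' @examples
#' ds <- generate_invitro(assay_config(),
#'   binding_params(0.04, 17, 0.0319),
#'   cytotox_params(kkillmax = 2.38, kkill50 = 12, hill = 5.89,
#'                  baseline_fraction = 1.01),
#'   tce_concs = 10^seq(-4, 1, 1), shed_levels = c(0, 20), seed = 1)
generate_invitro <- function(config, binding, cytotox,
                             tce_concs = 10^seq(-5, 2, by = 0.5),
                             shed_levels = c(0, 1.2, 5, 20),
                             replicates = 1,
                             error = error_model(0.0732, 0.00593),
                             seed = 1) {
  stopifnot(replicates >= 1)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  rows <- list()
  for (sh in shed_levels) {
    pred <- simulate_assay(config, binding, cytotox, tce_concs,
                           added_shed_nM = sh)
    for (r in seq_len(replicates)) {
      e1 <- stats::rnorm(length(pred))
      e2 <- stats::rnorm(length(pred))
      obs <- pred * (1 + error$proportional * e1) + error$additive * e2
      rows[[length(rows) + 1L]] <- data.frame(
        conc_nM = tce_concs, shed_nM = sh, fraction = obs, replicate = r)
    }
  }
  do.call(rbind, rows)
}

#' Generate sparse synthetic plasma PK samples
#'
#' Platform-simulated blood free-TCE concentrations at the sampling times,
#' with proportional lognormal-style noise `obs = pred exp(prop e)`.
#'
#' @param molecule A [molecule_spec()].
#' @param regimen A [dose_regimen()].
#' @param times Sampling times (days), within the simulated span.
#' @param proportional Proportional error magnitude.
#' @param seed Integer seed.
#' @param physiology,shed Platform ingredients.
#' @param t_end Simulation end (defaults to the last sampling time).
#' @return A data.frame with `time` and `conc_nM`.
#' @export
generate_pk <- function(molecule, regimen, times, proportional = 0.458,
                        seed = 1, physiology = load_physiology("human"),
                        shed = shed_target_spec(), t_end = max(times)) {
  if (any(times < 0) || any(times > t_end))
    stop("sampling times must lie within [0, t_end]")
  asm <- assemble_platform(molecule, physiology, shed)
  res <- simulate_regimen(asm, regimen, t_end = t_end, dt = min(0.1, t_end / 50))
  pred <- stats::approx(res$times, res$states[, "blood.tce"], xout = times)$y
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  obs <- pred * exp(proportional * stats::rnorm(length(pred)))
  data.frame(time = times, conc_nM = obs)
}

#' Fit systemic clearance to plasma PK samples
#'
#' One-dimensional least squares on the log concentration scale, simulating
#' the platform at candidate clearance values. Mirrors the calibration of a
#' TCE's clearance against sparse clinical PK.
#'
#' @param data A data.frame with `time` and `conc_nM`.
#' @param molecule Molecule with the starting clearance.
#' @param regimen Dosing regimen used for the data.
#' @param physiology,shed Platform ingredients.
#' @param interval Multiplicative search interval around the starting CL.
#' @return Estimated clearance (L/day/kg).
#' @export
fit_pk_cl <- function(data, molecule, regimen,
                      physiology = load_physiology("human"),
                      shed = shed_target_spec(), interval = c(0.1, 10)) {
  stopifnot(all(data$conc_nM > 0))
  obj <- function(lcl) {
    mol <- molecule
    mol$cl <- exp(lcl)
    asm <- assemble_platform(mol, physiology, shed)
    res <- simulate_regimen(asm, regimen, t_end = max(data$time),
                            dt = max(data$time) / 100)
    pred <- stats::approx(res$times, res$states[, "blood.tce"],
                          xout = data$time)$y
    if (any(pred <= 0)) return(1e10)
    sum((log(pred) - log(data$conc_nM))^2)
  }
  opt <- stats::optimize(obj, log(molecule$cl * interval), tol = 1e-4)
  exp(opt$minimum)
}

# Seed scoping helper: sets the RNG seed and returns a restore function.
.with_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1)
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
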