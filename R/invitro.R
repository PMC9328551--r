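# In vitro cytotoxicity assays: a closed co-incubation of tumor cells and T
# cells with the TCE, in the absence or presence of added shed target. The
# binding network is coupled to a normalized tumor burden B with exponential
# growth and Hill-type synapse-driven killing; TAA totals scale with the
# burden. Viability is normalized to a drug-free control grown under
# identical conditions.

#' In vitro assay configuration
#'
#' Cell numbers, well volume and incubation time of a cytotoxicity
#' co-culture. Receptor concentrations are derived from the cell counts via
#' [expression_from_assay()]. The default well volume (100 uL) reconciles
#' the standard 25000-T-cell setup at 1e5 CD3/cell with a 0.0415 nM CD3
#' concentration.
#'
#' @param effector_count Number of T cells per well.
#' @param tumor_count Number of tumor cells per well.
#' @param well_volume Well volume (L).
#' @param incubation Incubation time (days).
#' @param baseline_shed_nM Shed target present before any addition (nM).
#' @param taa_per_cell,cd3_per_cell Receptor copies per cell.
#' @param readout `"viability"` (fraction surviving vs control) or
#'   `"lysis"` (1 - viability).
#' @return An object of class `assay_config`.
#' @export
#' @examples
#' assay_config() # the 5:1 E:T myeloma setup
assay_config <- function(effector_count = 25000, tumor_count = 5000,
                         well_volume = 1e-4, incubation = 2,
                         baseline_shed_nM = 0,
                         taa_per_cell = 12590, cd3_per_cell = 100000,
                         readout = c("viability", "lysis")) {
  readout <- match.arg(readout)
  stopifnot(effector_count >= 0, tumor_count > 0, well_volume > 0,
            incubation > 0, baseline_shed_nM >= 0)
  structure(list(
    effector_count = effector_count, tumor_count = tumor_count,
    well_volume = well_volume, incubation = incubation,
    baseline_shed_nM = baseline_shed_nM,
    taa_per_cell = taa_per_cell, cd3_per_cell = cd3_per_cell,
    readout = readout,
    et_ratio = effector_count / tumor_count
  ), class = "assay_config")
}

#' Receptor concentration implied by assay conditions
#'
#' `cells * receptors_per_cell / (Avogadro * volume) * 1e9` nM.
#'
#' @param cell_count Cells per well.
#' @param receptors_per_cell Receptor copies per cell.
#' @param well_volume Well volume (L).
#' @return Concentration (nM).
#' @export
#' @examples
#' expression_from_assay(25000, 1e5, 1e-4) # ~0.0415 nM CD3
expression_from_assay <- function(cell_count, receptors_per_cell,
                                  well_volume) {
  cells_to_nM(cell_count, receptors_per_cell, well_volume)
}

#' Combined residual error model
#'
#' Observation error `obs = pred (1 + proportional e1) + additive e2` with
#' independent standard-normal draws per well.
#'
#' @param proportional Proportional error magnitude (dimensionless).
#' @param additive Additive error magnitude (fraction).
#' @return An object of class `error_model`.
#' @export
error_model <- function(proportional = 0, additive = 0) {
  stopifnot(proportional >= 0, additive >= 0)
  if (proportional == 0 && additive == 0)
    warning("error model with both components zero")
  structure(list(proportional = proportional, additive = additive),
            class = "error_model")
}

# one closed-well integration; returns full trajectory of the 9 binding
# species plus burden, and the synapse-per-cell series
.simulate_well <- function(tce0, config, binding, cytotox, shed_nM,
                           rtol = 1e-8, atol = 1e-12) {
  taa0 <- expression_from_assay(config$tumor_count, config$taa_per_cell,
                                config$well_volume)
  cd30 <- expression_from_assay(config$effector_count, config$cd3_per_cell,
                                config$well_volume)
  cells0 <- taa0 / config$taa_per_cell           # nM of tumor cells
  b0 <- cytotox$baseline_fraction
  y0 <- c(tce = tce0, taa = taa0, cd3 = cd30, shed = shed_nM,
          d_taa = 0, d_cd3 = 0, d_shed = 0, tri = 0, tri_shed = 0,
          burden = b0)
  # index-based right-hand side (hot path for fitting)
  konT <- binding$kon_target; koffT <- binding$koff_target
  kon <- binding$kon; koffC <- binding$koff_cd3
  konS <- if (is.finite(binding$kd_shed)) binding$kon else 0
  koffS <- if (is.finite(binding$koff_shed)) binding$koff_shed else 0
  kg <- cytotox$kg; kmax <- cytotox$kkillmax; k50h <- cytotox$kkill50^cytotox$hill
  hill <- cytotox$hill
  rhs <- function(t, y, p) {
    y <- pmax(y, 0)
    r1 <- konT * y[1] * y[2] - koffT * y[5]
    r2 <- kon * y[1] * y[3] - koffC * y[6]
    r3 <- konS * y[1] * y[4] - koffS * y[7]
    r4 <- kon * y[5] * y[3] - koffC * y[8]
    r5 <- konT * y[6] * y[2] - koffT * y[8]
    r6 <- kon * y[7] * y[3] - koffC * y[9]
    r7 <- konS * y[6] * y[4] - koffS * y[9]
    cells <- cells0 * y[10] / b0
    ts <- if (cells > 0) y[8] / cells else 0
    tsh <- ts^hill
    kill <- kmax * tsh / (k50h + tsh)
    taa_tot <- y[2] + y[5] + y[8]
    # growth adds fresh free TAA on new cells; death removes TAA-bearing
    # species proportionally, releasing the non-TAA parts of complexes
    list(c(-r1 - r2 - r3 + kill * y[5],
           -r1 - r5 + kg * taa_tot - kill * y[2],
           -r2 - r4 - r6,
           -r3 - r7,
           r1 - r4 - kill * y[5],
           r2 - r5 - r7 + kill * y[8],
           r3 - r6,
           r4 + r5 - kill * y[8],
           r6 + r7,
           (kg - kill) * y[10]))
  }
  times <- if (isTRUE(config$trajectory))
    seq(0, config$incubation, length.out = 101)
  else c(0, config$incubation / 2, config$incubation)
  out <- deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol,
                        maxsteps = 20000)
  if (attr(out, "istate")[1] < 0)
    stop("in vitro integration failed at TCE = ", tce0, " nM")
  cells <- cells0 * out[, "burden"] / b0
  ts <- ifelse(cells > 0, out[, "tri"] / cells, 0)
  list(times = out[, 1], states = out, synapse_per_cell = ts,
       burden_end = out[nrow(out), "burden"])
}

#' Simulate an in vitro cytotoxicity assay
#'
#' For each TCE concentration, integrates the closed-well binding network
#' coupled to the tumor burden and returns the predicted readout fraction,
#' normalized against a drug-free control grown at the same rate.
#'
#' @param config An [assay_config()].
#' @param binding A [binding_params()].
#' @param cytotox A [cytotox_params()].
#' @param tce_concs TCE concentrations (nM).
#' @param added_shed_nM Shed target added on top of the configured baseline
#'   (nM).
#' @return Numeric vector of predicted fractions (viability or lysis per
#'   `config$readout`).
#' @export
#' @examples
#' cfg <- assay_config()
#' b <- binding_params(kd_target = 0.04, kd_cd3 = 17, kd_shed = 0.0319)
#' k <- cytotox_params(kkillmax = 2.38, kkill50 = 12, hill = 5.89,
#'                     baseline_fraction = 1.01)
#' simulate_assay(cfg, b, k, c(0.001, 0.1, 10))
simulate_assay <- function(config, binding, cytotox, tce_concs,
                           added_shed_nM = 0) {
  stopifnot(all(tce_concs >= 0), added_shed_nM >= 0)
  shed <- config$baseline_shed_nM + added_shed_nM
  b_control <- exp(cytotox$kg * config$incubation)   # burden from B(0) = 1
  vapply(tce_concs, function(cc) {
    w <- .simulate_well(cc, config, binding, cytotox, shed)
    viab <- w$burden_end / b_control
    if (config$readout == "viability") viab else 1 - viab
  }, 0)
}

#' Lysis versus average synapse count
#'
#' Pairs the time-averaged immune synapse count per tumor cell over the
#' incubation with the final lysis fraction, per TCE concentration. Curves
#' for different shed-target levels collapse onto a single relation, because
#' killing depends on the TCE concentration only through the synapse count.
#'
#' @inheritParams simulate_assay
#' @return A data.frame with `conc_nM`, `avg_trimers_per_cell` and `lysis`.
#' @export
lysis_vs_trimers <- function(config, binding, cytotox, tce_concs,
                             added_shed_nM = 0) {
  shed <- config$baseline_shed_nM + added_shed_nM
  b_control <- exp(cytotox$kg * config$incubation)
  config$trajectory <- TRUE             # dense output for the time average
  rows <- lapply(tce_concs, function(cc) {
    w <- .simulate_well(cc, config, binding, cytotox, shed)
    ts <- w$synapse_per_cell
    tt <- w$times
    avg <- sum(diff(tt) * (head(ts, -1) + tail(ts, -1)) / 2) /
      (max(tt) - min(tt))
    data.frame(conc_nM = cc, avg_trimers_per_cell = avg,
               lysis = 1 - w$burden_end / b_control)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# parameters that may be estimated by fit_invitro
.FITTABLE <- c("kd_shed", "baseline_shed", "kg", "kkillmax", "kkill50",
               "hill", "baseline_fraction")

.predict_dataset <- function(data, config, binding, cytotox) {
  key <- interaction(data$conc_nM, data$shed_nM, drop = TRUE)
  uniq <- !duplicated(key)
  preds <- mapply(function(cc, sh)
    simulate_assay(config, binding, cytotox, cc, added_shed_nM = sh),
    data$conc_nM[uniq], data$shed_nM[uniq])
  preds[match(key, key[uniq])]
}

.apply_theta <- function(theta, config, binding, cytotox) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm == "kd_shed") {
      binding <- binding_params(binding$kd_target, binding$kd_cd3, v,
                                kon = binding$kon,
                                kon_target = binding$kon_target)
    } else if (nm == "baseline_shed") {
      config$baseline_shed_nM <- v
    } else {
      cytotox[[nm]] <- v
    }
  }
  list(config = config, binding = binding, cytotox = cytotox)
}

#' Fit the in vitro cytotoxicity model
#'
#' Weighted least squares under the combined error model (weights
#' `1 / (proportional * pred + additive)`), with a derivative-free simplex
#' search followed by gradient refinement, both on the log scale of the
#' (positive) parameters. Relative standard errors come from the
#' inverse-Hessian covariance approximation at the optimum.
#'
#' If both `kd_shed` and `baseline_shed` are requested free but the design
#' contains fewer than two distinct non-zero added-shed levels, the two are
#' not separately identifiable and a warning is raised (the fit proceeds and
#' is flagged for profile-likelihood inspection).
#'
#' @param data A data.frame with columns `conc_nM`, `shed_nM` (added shed),
#'   `fraction` and `replicate`.
#' @param free Character vector naming the free parameters, a subset of
#'   `kd_shed`, `baseline_shed`, `kg`, `kkillmax`, `kkill50`, `hill`,
#'   `baseline_fraction`.
#' @param start Named numeric start values for the free parameters.
#' @param config An [assay_config()] (fixed design).
#' @param binding A [binding_params()] holding the fixed binding constants.
#' @param cytotox A [cytotox_params()] holding the fixed cytotoxicity values.
#' @param error An [error_model()] used for weighting.
#' @return An object of class `invitro_fit`: estimates, `%RSE`, objective
#'   value, residuals and an `identifiability_flag`.
#' @export
fit_invitro <- function(data, free, start, config, binding, cytotox,
                        error = error_model(0.0732, 0.00593)) {
  stopifnot(is.data.frame(data), nrow(data) > 0,
            all(c("conc_nM", "shed_nM", "fraction") %in% names(data)))
  if (!all(free %in% .FITTABLE))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, .FITTABLE), collapse = ", "))
  if (!all(free %in% names(start)))
    stop("start values required for every free parameter")
  flag <- FALSE
  if (all(c("kd_shed", "baseline_shed") %in% free) &&
      length(unique(data$shed_nM[data$shed_nM > 0])) < 2) {
    warning("kd_shed and baseline_shed cannot be separately estimated from ",
            "a single added-shed level; flagging for profile likelihood")
    flag <- TRUE
  }
  obj <- function(lpar) {
    theta <- as.list(exp(lpar))
    names(theta) <- free
    mm <- .apply_theta(theta, config, binding, cytotox)
    pred <- tryCatch(
      .predict_dataset(data, mm$config, mm$binding, mm$cytotox),
      error = function(e) rep(NA_real_, nrow(data)))
    if (any(!is.finite(pred))) return(1e10)
    w <- 1 / (error$proportional * abs(pred) + error$additive)
    sum((w * (data$fraction - pred))^2)
  }
  lp0 <- log(unlist(start[free]))
  if (length(free) == 1L) {
    # golden-section on the log scale, then a quadratic hessian estimate
    opt <- stats::optimize(obj, lp0 + c(-3, 3), tol = 1e-6)
    par <- opt$minimum
    val <- opt$objective
    h <- 1e-3
    hess <- matrix((obj(par + h) - 2 * val + obj(par - h)) / h^2, 1, 1)
    fit2 <- list(par = par, value = val, hessian = hess, convergence = 0L)
  } else {
    fit1 <- stats::optim(lp0, obj, method = "Nelder-Mead",
                         control = list(maxit = 400, reltol = 1e-9))
    fit2 <- stats::optim(fit1$par, obj, method = "BFGS", hessian = TRUE,
                         control = list(maxit = 200, reltol = 1e-10))
  }
  est <- exp(fit2$par)
  names(est) <- free
  n <- nrow(data)
  p <- length(free)
  s2 <- fit2$value / max(n - p, 1)
  rse <- rep(NA_real_, p)
  covm <- tryCatch(2 * s2 * solve(fit2$hessian), error = function(e) NULL)
  if (!is.null(covm)) {
    dg <- diag(covm)
    rse <- ifelse(dg > 0, 100 * sqrt(dg), NA_real_)   # log-scale sd ~ CV%
  }
  names(rse) <- free
  mm <- .apply_theta(as.list(est), config, binding, cytotox)
  pred <- .predict_dataset(data, mm$config, mm$binding, mm$cytotox)
  structure(list(
    estimates = est, rse_percent = rse, objective = fit2$value,
    residuals = data$fraction - pred, fitted = pred,
    identifiability_flag = flag, free = free, n = n,
    convergence = fit2$convergence
  ), class = "invitro_fit")
}

#' @export
print.invitro_fit <- function(x, ...) {
  cat("<invitro_fit> weighted least squares,", x$n, "observations\n")
  for (nm in x$free)
    cat(sprintf("  %-18s %.4g  (%%RSE %.1f)\n", nm, x$estimates[[nm]],
                x$rse_percent[[nm]]))
  cat(sprintf("  objective %.6g%s\n", x$objective,
              if (x$identifiability_flag) "  [identifiability flag]" else ""))
  invisible(x)
}

#' Read and write the assay dataset CSV schema
#'
#' Columns: `conc_nM`, `shed_nM`, `fraction`, `replicate`.
#'
#' @param data Dataset data.frame.
#' @param path File path.
#' @return `read_assay_csv()` returns the data.frame.
#' @export
write_assay_csv <- function(data, path) {
  utils::write.csv(data[, c("conc_nM", "shed_nM", "fraction", "replicate")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("conc_nM", "shed_nM", "fraction", "replicate")
  if (!all(need %in% names(df)))
    stop("assay CSV must have columns: ", paste(need, collapse = ", "))
  df
}
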