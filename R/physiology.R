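# Physiological parameter registries and pre-dose baseline calibration.
# The human registry transcribes the published patient physiology for a
# five-compartment multiple-myeloma platform: central blood (plasma plus
# lumped tissue vascular spaces), bone marrow (the tumor site), spleen, a
# lumped "other tissue", and lymph node. Baseline receptor concentrations are
# marker concentrations in nM; per-cell expression converts them to cell
# concentrations.

.TISSUE_NAMES <- c("bone_marrow", "spleen", "other_tissue")

#' Load a physiology registry
#'
#' Returns the per-tissue volumes, plasma and lymph flows, transmigration
#' rates and baseline receptor concentrations for the supported species.
#' Human values are transcribed from published patient physiology. The mouse
#' registry is a synthetic stand-in assembled from literature-typical
#' allometric values (see `vignette("tcesim-methods")`); it supports the
#' qualitative mouse biodistribution mode, with lymph flows switchable
#' between a directly estimated set (`"sepp"`) and a set fixed at 0.2% of
#' plasma flow (`"shah"`).
#'
#' @param species `"human"` or `"mouse"`.
#' @param lymph_set For mouse only: `"sepp"` (estimated lymph flows) or
#'   `"shah"` (0.2% of plasma flow).
#' @return An object of class `physiology`: a list with `species`,
#'   `body_weight` (kg), `blood` (volume and baselines) and `tissues` (a
#'   named list of per-tissue parameter lists). All volumes are L/kg and all
#'   flows L/day/kg.
#' @export
#' @examples
#' hp <- load_physiology("human")
#' hp$tissues$bone_marrow$plasma_flow
load_physiology <- function(species = c("human", "mouse"),
                            lymph_set = c("sepp", "shah")) {
  species <- match.arg(species)
  lymph_set <- match.arg(lymph_set)
  if (species == "human") .human_physiology() else .mouse_physiology(lymph_set)
}

.human_physiology <- function() {
  tissue <- function(total_volume, plasma_volume, interstitial_volume,
                     plasma_flow, lymph_flow, sigma_lymph, transmigration,
                     taa_nM, cd3_nM, degradation) {
    list(total_volume = total_volume, plasma_volume = plasma_volume,
         interstitial_volume = interstitial_volume, plasma_flow = plasma_flow,
         lymph_flow = lymph_flow, sigma_lymph = sigma_lymph,
         transmigration = transmigration, taa_nM = taa_nM, cd3_nM = cd3_nM,
         degradation = degradation)
  }
  tissues <- list(
    bone_marrow = tissue(0.0423, 0.0032, 0.0266, 0.88, 0.0155, 0.2, 11.4,
                         8.30e-01, 3.66, NA_real_),
    spleen = tissue(0.0031, 0.0004, 0.00062, 2.14, 0.00018, 0.2, 1.88,
                    3.49e-02, 98.26, 0.03),
    other_tissue = tissue(0.818, 0.021, 0.133, 58.5, 0.240, 0.2, 89.2,
                          3.82e-04, 2.21, 0.03),
    lymph_node = list(total_volume = 0.00386, lymph_flow = 0.256,
                      taa_nM = 1.47e-02, cd3_nM = 64.5)
  )
  plasma_volume <- 0.044
  structure(list(
    species = "human",
    body_weight = 70,
    geometry = pore_geometry(),
    blood = list(
      plasma_volume = plasma_volume,
      # tissue vascular spaces are lumped into central blood (quasi-equilibrium)
      volume = plasma_volume + sum(vapply(tissues[.TISSUE_NAMES],
                                          `[[`, 0, "plasma_volume")),
      plasma_flow = 61.5,
      taa_nM = 4.87e-05, cd3_nM = 0.393, shed_nM = 100
    ),
    receptors = list(taa_per_cell = 12590, cd3_per_cell = 100000),
    tissues = tissues
  ), class = "physiology")
}

# SYNTHETIC mouse registry: order-of-magnitude allometric values (flows
# roughly 10x human per kg, volume fractions as human), not a transcription
# of any published mouse table. Intended only for the drug-only
# biodistribution mode and its qualitative size-ordering behaviour.
.mouse_physiology <- function(lymph_set = "sepp") {
  lf <- function(sepp, q) if (lymph_set == "sepp") sepp else 0.002 * q
  tissue <- function(total_volume, plasma_volume, interstitial_volume,
                     plasma_flow, lymph_sepp) {
    list(total_volume = total_volume, plasma_volume = plasma_volume,
         interstitial_volume = interstitial_volume, plasma_flow = plasma_flow,
         lymph_flow = lf(lymph_sepp, plasma_flow), sigma_lymph = 0.2,
         transmigration = 0, taa_nM = 0, cd3_nM = 0, degradation = NA_real_)
  }
  tissues <- list(
    bone_marrow = tissue(0.045, 0.0034, 0.028, 9.1, 0.16),
    spleen = tissue(0.0035, 0.00045, 0.0007, 21.5, 0.04),
    other_tissue = tissue(0.82, 0.021, 0.135, 590, 6.0),
    lymph_node = list(total_volume = 0.004,
                      lymph_flow = NA_real_, taa_nM = 0, cd3_nM = 0)
  )
  tissues$lymph_node$lymph_flow <- sum(vapply(tissues[.TISSUE_NAMES],
                                              `[[`, 0, "lymph_flow"))
  plasma_volume <- 0.05
  structure(list(
    species = "mouse",
    body_weight = 0.025,
    geometry = pore_geometry(),
    synthetic = TRUE,
    lymph_set = lymph_set,
    blood = list(
      plasma_volume = plasma_volume,
      volume = plasma_volume + sum(vapply(tissues[.TISSUE_NAMES],
                                          `[[`, 0, "plasma_volume")),
      plasma_flow = 620,
      taa_nM = 0, cd3_nM = 0, shed_nM = 0
    ),
    receptors = list(taa_per_cell = 12590, cd3_per_cell = 100000),
    tissues = tissues
  ), class = "physiology")
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s (body weight %g kg)%s\n", x$species,
              x$body_weight,
              if (isTRUE(x$synthetic)) " [synthetic registry]" else ""))
  cat(sprintf("  blood volume %.4g L/kg; tissues: %s\n", x$blood$volume,
              paste(names(x$tissues), collapse = ", ")))
  invisible(x)
}

# names of tissues with a blood<->interstitium exchange interface
exchanging_tissues <- function(physiology) .TISSUE_NAMES

#' Effector-to-target cell ratio in a compartment
#'
#' Converts the baseline CD3 and TAA marker concentrations to cell
#' concentrations using the per-cell expression levels and returns their
#' ratio (T cells per tumor cell).
#'
#' @param physiology A [load_physiology()] registry.
#' @param tissue Compartment name (`"blood"` or a tissue name).
#' @return Dimensionless E:T ratio.
#' @export
#' @examples
#' effector_target_ratio(load_physiology("human"), "bone_marrow") # ~0.555
effector_target_ratio <- function(physiology, tissue) {
  comp <- if (tissue == "blood") physiology$blood
          else physiology$tissues[[tissue]]
  if (is.null(comp)) stop("unknown compartment: ", tissue)
  if (is.null(comp$cd3_nM) || is.null(comp$taa_nM) ||
      is.na(comp$cd3_nM) || is.na(comp$taa_nM) || comp$taa_nM <= 0)
    stop("compartment ", tissue, " lacks CD3 and/or TAA baselines")
  (comp$cd3_nM / physiology$receptors$cd3_per_cell) /
    (comp$taa_nM / physiology$receptors$taa_per_cell)
}

#' Shed-target specification
#'
#' The soluble shed ectodomain of the TAA: a small (5 kDa) species generated
#' in bone marrow, distributed by the two-pore machinery and eliminated from
#' blood (renal excretion). Its synthesis rate is calibrated so that the
#' pre-dose blood concentration matches `target_blood_nM`.
#'
#' @param mw Molecular weight (Da).
#' @param cl Systemic (blood) clearance (L/day/kg).
#' @param target_blood_nM Pre-dose blood steady-state concentration (nM).
#' @param kd_complex_nM Unused placeholder kept for config compatibility.
#' @return An object of class `shed_target_spec`.
#' @export
shed_target_spec <- function(mw = 5000, cl = 1.55, target_blood_nM = 100) {
  stopifnot(mw > 0, cl >= 0, target_blood_nM >= 0)
  structure(list(mw = mw, cl = cl, target_blood_nM = target_blood_nM),
            class = "shed_target_spec")
}

#' Molecule specification for a TCE
#'
#' @param name Molecule label.
#' @param mw Molecular weight (Da).
#' @param binding A [binding_params()].
#' @param cl Systemic clearance from blood (L/day/kg).
#' @param route Default dosing route.
#' @param ka First-order absorption rate (1/day, subcutaneous only).
#' @param f_bio Bioavailability in (0, 1].
#' @return An object of class `molecule_spec`.
#' @export
#' @examples
#' molecule_pf06863135()
molecule_spec <- function(name, mw, binding, cl,
                          route = c("iv_bolus", "iv_infusion", "sc"),
                          ka = 0.7, f_bio = 1) {
  route <- match.arg(route)
  stopifnot(mw > 0, cl >= 0, f_bio > 0, f_bio <= 1)
  if (route == "sc" && ka <= 0) stop("sc dosing requires ka > 0")
  structure(list(name = name, mw = mw, binding = binding, cl = cl,
                 route = route, ka = ka, f_bio = f_bio),
            class = "molecule_spec")
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat(sprintf("<molecule_spec> %s: %g kDa, CL %g L/day/kg, route %s\n",
              x$name, x$mw / 1000, x$cl, x$route))
  invisible(x)
}

#' Built-in clinical-stage molecule specifications
#'
#' `molecule_pf06863135()`: the 150 kDa IgG-format BCMA TCE (weekly
#' subcutaneous dosing). `molecule_amg420()`: the 54 kDa BiTE-format BCMA TCE
#' (continuous intravenous infusion). `molecule_amg211()`: the 54 kDa
#' CEA-targeting BiTE used for biodistribution verification; its target is
#' absent from the modelled compartments, so TAA binding is switched off
#' (`kon_target = 0`).
#'
#' @return A [molecule_spec()].
#' @export
molecule_pf06863135 <- function() {
  molecule_spec("PF-06863135", 150000,
                binding_params(kd_target = 0.04, kd_cd3 = 17,
                               kd_shed = 0.0319),
                cl = 0.00372, route = "sc", ka = 0.7, f_bio = 1)
}

#' @rdname molecule_pf06863135
#' @export
molecule_amg420 <- function() {
  molecule_spec("AMG420", 54000,
                binding_params(kd_target = 0.1, kd_cd3 = 20, kd_shed = 5.36),
                cl = 0.540, route = "iv_infusion")
}

#' @rdname molecule_pf06863135
#' @export
molecule_amg211 <- function() {
  molecule_spec("AMG211", 54000,
                binding_params(kd_target = 5.5, kd_cd3 = 310, kd_shed = Inf,
                               kon_target = 0),
                cl = 0.164, route = "iv_infusion")
}

#' Calibrate the shed-target synthesis rate
#'
#' Solves the linear pre-dose steady state of the shed-target
#' distribution/elimination system (synthesis in bone marrow, two-pore
#' exchange with every tissue, lymphatic return through the lymph node,
#' first-order elimination from blood) such that the blood concentration
#' equals the specification target.
#'
#' @param spec A [shed_target_spec()].
#' @param physiology A [load_physiology()] registry.
#' @param ps_scale Diffusive-capacity scale passed to [tissue_transport()].
#' @return A list with `synthesis` (nmol/day/kg) and `steady_state` (named
#'   nM vector over blood, tissues and lymph node).
#' @export
calibrate_shed_synthesis <- function(spec, physiology,
                                     ps_scale = platform_defaults()$ps_scale) {
  if (spec$cl <= 0)
    stop("shed target clearance must be positive for a finite steady state")
  tiss <- exchanging_tissues(physiology)
  tr <- lapply(tiss, function(tn) {
    tp <- physiology$tissues[[tn]]
    tissue_transport(spec$mw, tp$plasma_flow, tp$lymph_flow,
                     physiology$geometry, ps_scale)
  })
  names(tr) <- tiss
  cb <- spec$target_blood_nM
  ln <- physiology$tissues$lymph_node
  # unknowns: C_bm, C_sp, C_ot, C_ln, synthesis s  (flows in nmol/day/kg)
  A <- matrix(0, 5, 5)
  b <- numeric(5)
  for (i in seq_along(tiss)) {
    tp <- physiology$tissues[[tiss[i]]]
    out_i <- tr[[i]]$q_out + tp$lymph_flow * (1 - tp$sigma_lymph)
    A[i, i] <- -out_i
    if (tiss[i] == "bone_marrow") A[i, 5] <- 1
    b[i] <- -tr[[i]]$q_in * cb
  }
  # lymph node balance
  for (i in seq_along(tiss)) {
    tp <- physiology$tissues[[tiss[i]]]
    A[4, i] <- tp$lymph_flow * (1 - tp$sigma_lymph)
  }
  A[4, 4] <- -ln$lymph_flow
  # blood balance
  for (i in seq_along(tiss)) A[5, i] <- tr[[i]]$q_out
  A[5, 4] <- ln$lymph_flow
  b[5] <- (spec$cl + sum(vapply(tr, `[[`, 0, "q_in"))) * cb
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("shed steady-state system is singular: ", conditionMessage(e)))
  if (sol[5] <= 0)
    stop("calibrated synthesis rate is non-positive; inconsistent physiology")
  ss <- c(blood = cb, stats::setNames(sol[1:3], tiss), lymph_node = sol[4])
  list(synthesis = sol[5], steady_state = ss, transport = tr)
}

#' Stationary trafficking balance for a cell population
#'
#' Given the printed transmigration rates and degradation rates, computes the
#' first-order tissue loss rates (degradation where printed, lymph-borne
#' return to blood otherwise), the lymph-node entry rate, and the blood
#' source rate that together make the registry baselines an exact pre-dose
#' steady state. The same balance applies to T cells (CD3 marker) and tumor
#' cells (TAA marker).
#'
#' @param entity `"taa"` (tumor cells) or `"cd3"` (T cells).
#' @param physiology A [load_physiology()] registry.
#' @return A list with per-tissue `influx` rate constants (L/day/kg, applied
#'   to the blood concentration), per-tissue total loss rates `k_loss`
#'   (1/day) split into `k_deg` and `k_return`, lymph-node entry
#'   (`ln_entry`, L/day/kg) and exit (`ln_exit`, 1/day) rates, and the blood
#'   `source` (nmol/day/kg).
#' @export
stationary_cell_balance <- function(entity = c("taa", "cd3"), physiology) {
  entity <- match.arg(entity)
  conc_name <- paste0(entity, "_nM")
  cb <- physiology$blood[[conc_name]]
  tiss <- exchanging_tissues(physiology)
  k_deg <- k_return <- influx <- numeric(length(tiss))
  names(k_deg) <- names(k_return) <- names(influx) <- tiss
  deg_balance <- 0
  for (tn in tiss) {
    tp <- physiology$tissues[[tn]]
    cj <- tp[[conc_name]]
    if (is.null(cj) || is.na(cj))
      stop("missing ", entity, " baseline for tissue ", tn)
    influx[tn] <- tp$transmigration
    vol <- tp$interstitial_volume
    k_total <- if (cj > 0) tp$transmigration * cb / (cj * vol) else 0
    kd <- if (is.na(tp$degradation)) 0 else tp$degradation
    if (cj > 0 && k_total < kd - 1e-12)
      stop("inconsistent baselines: implied return rate negative in ", tn)
    if (cj == 0) kd <- 0               # empty pool: no turnover at all
    k_deg[tn] <- kd
    k_return[tn] <- max(k_total - kd, 0)
    deg_balance <- deg_balance + kd * cj * vol
  }
  ln <- physiology$tissues$lymph_node
  ln_exit <- ln$lymph_flow / ln$total_volume     # 1/day
  cl_ln <- ln[[conc_name]]
  ln_entry <- if (cb > 0) ln_exit * cl_ln * ln$total_volume / cb else 0
  # Per-compartment receptor turnover implied by the trafficking balance:
  # constant source (zeroth order, nM/day) against first-order loss on the
  # free pool, with the loss rate set by the transmigration turnover. Under
  # treatment the supply is undisturbed (cell trafficking is held at its
  # baseline; treatment-induced T cell dynamics are outside the model).
  vols <- c(blood = physiology$blood$volume,
            vapply(physiology$tissues[tiss], `[[`, 0,
                   "interstitial_volume"),
            lymph_node = ln$total_volume)
  k_loss <- c(blood = (sum(influx) + ln_entry) / vols[["blood"]],
              k_deg + k_return,
              lymph_node = ln_exit)
  base <- c(blood = cb,
            vapply(physiology$tissues[tiss], `[[`, 0, conc_name),
            lymph_node = cl_ln)
  list(influx = influx, k_deg = k_deg, k_return = k_return,
       ln_entry = ln_entry, ln_exit = ln_exit,
       source = deg_balance,
       k_loss = k_loss, source_conc = k_loss * base, baseline = base)
}

#' Write and read a physiology registry
#'
#' Serializes the registry to JSON with full double precision, so a
#' write-then-read round trip reproduces every numeric value bit-exactly.
#'
#' @param physiology A [load_physiology()] registry.
#' @param path File path.
#' @return `read_physiology()` returns the registry.
#' @export
write_physiology <- function(physiology, path) {
  x <- unclass(physiology)
  x$geometry <- unclass(x$geometry)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_physiology
#' @export
read_physiology <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # whole numbers come back as integers; restore doubles throughout
  x <- rapply(x, function(v)
    if (is.integer(v)) as.double(v) else v, how = "replace")
  fix_na <- function(v) if (is.null(v)) NA_real_ else v
  x$tissues <- lapply(x$tissues, function(t) {
    if (!is.null(t$degradation) || "degradation" %in% names(t))
      t$degradation <- fix_na(t$degradation)
    t
  })
  x$geometry <- do.call(pore_geometry, x$geometry)
  structure(x, class = "physiology")
}
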