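# Sequential bispecific mass-action binding network. A TCE binds membrane
# target (TAA), CD3 on T cells, or soluble shed target with a single shared
# association rate constant; selectivity enters through the equilibrium
# dissociation constants (koff = kon * kd). The TAA-TCE-CD3 trimer is the
# immune synapse bridging a tumor cell and a T cell; the shed-TCE-CD3 trimer
# is the non-productive soluble analogue.

.AVOGADRO <- 6.02214076e23

# canonical species order used by every compartment state vector
.SPECIES <- c("tce", "taa", "cd3", "shed",
              "d_taa", "d_cd3", "d_shed", "tri", "tri_shed")

#' Species names of the binding network
#'
#' The nine species tracked per compartment: free TCE, free TAA, free CD3,
#' free shed target, the three dimers (TAA-TCE, TCE-CD3, shed-TCE) and the
#' two trimers (TAA-TCE-CD3, the immune synapse, and shed-TCE-CD3).
#'
#' @return Character vector of length 9.
#' @export
binding_species <- function() .SPECIES

#' Binding rate parameters
#'
#' One association rate constant is shared by all binding steps; each
#' interaction's dissociation rate is `koff = kon * kd`. Setting
#' `kon_target = 0` renders every TAA-containing binding reaction inert
#' (used to simulate a TCE whose target is absent from the modelled tissues).
#'
#' @param kd_target Equilibrium dissociation constant to membrane TAA (nM).
#' @param kd_cd3 Equilibrium dissociation constant to CD3 (nM).
#' @param kd_shed Equilibrium dissociation constant to shed target (nM).
#' @param kon Association rate constant (1/nM/day), shared by all steps.
#' @param kon_target Association rate for TAA-containing steps; defaults to
#'   `kon`.
#' @return An object of class `binding_params` carrying the derived `koff`
#'   values.
#' @export
#' @examples
#' binding_params(kd_target = 0.04, kd_cd3 = 17, kd_shed = 0.0319)
binding_params <- function(kd_target, kd_cd3, kd_shed = Inf, kon = 86,
                           kon_target = kon) {
  stopifnot(kd_target > 0, kd_cd3 > 0, kd_shed > 0, kon >= 0,
            kon_target >= 0)
  structure(list(
    kon = kon, kon_target = kon_target,
    kd_target = kd_target, kd_cd3 = kd_cd3, kd_shed = kd_shed,
    koff_target = kon_target * kd_target,
    koff_cd3 = kon * kd_cd3,
    koff_shed = if (is.finite(kd_shed)) kon * kd_shed else Inf
  ), class = "binding_params")
}

# Net mass-action rate of each of the 7 reversible steps, given species
# concentrations as equal-length vectors (one element per compartment).
# Steps: 1 tce+taa<->d_taa, 2 tce+cd3<->d_cd3, 3 tce+shed<->d_shed,
# 4 d_taa+cd3<->tri, 5 d_cd3+taa<->tri, 6 d_shed+cd3<->tri_shed,
# 7 d_cd3+shed<->tri_shed.
.step_rates <- function(s, p) {
  koff_shed <- if (is.finite(p$koff_shed)) p$koff_shed else 0
  kon_shed <- if (is.finite(p$kd_shed)) p$kon else 0
  list(
    r1 = p$kon_target * s$tce * s$taa - p$koff_target * s$d_taa,
    r2 = p$kon * s$tce * s$cd3 - p$koff_cd3 * s$d_cd3,
    r3 = kon_shed * s$tce * s$shed - koff_shed * s$d_shed,
    r4 = p$kon * s$d_taa * s$cd3 - p$koff_cd3 * s$tri,
    r5 = p$kon_target * s$d_cd3 * s$taa - p$koff_target * s$tri,
    # r6 forms/breaks the TCE-CD3 bond of the shed trimer
    r6 = p$kon * s$d_shed * s$cd3 - p$koff_cd3 * s$tri_shed,
    r7 = kon_shed * s$d_cd3 * s$shed - koff_shed * s$tri_shed
  )
}

#' Net binding fluxes for one compartment
#'
#' Mass-action net production rate (nM/day) for each of the nine species of
#' the sequential bispecific binding network. The summed rates conserve the
#' totals of TCE, TAA, CD3 and shed target.
#'
#' @param state Named numeric vector (or list) of the nine species
#'   concentrations (nM), names as in [binding_species()].
#' @param params A [binding_params()].
#' @return Named numeric vector of net rates (nM/day).
#' @export
binding_fluxes <- function(state, params) {
  s <- as.list(state[.SPECIES])
  if (any(!is.finite(unlist(s))) || any(unlist(s) < -1e-12))
    stop("species concentrations must be finite and non-negative")
  r <- .step_rates(s, params)
  out <- c(
    tce = -r$r1 - r$r2 - r$r3,
    taa = -r$r1 - r$r5,
    cd3 = -r$r2 - r$r4 - r$r6,
    shed = -r$r3 - r$r7,
    d_taa = r$r1 - r$r4,
    d_cd3 = r$r2 - r$r5 - r$r7,
    d_shed = r$r3 - r$r6,
    tri = r$r4 + r$r5,
    tri_shed = r$r6 + r$r7
  )
  out[.SPECIES]
}

#' Entity totals of a binding state
#'
#' Sums free and bound forms of each conserved entity.
#'
#' @inheritParams binding_fluxes
#' @return Named vector with totals of `tce`, `taa`, `cd3`, `shed` (nM).
#' @export
binding_totals <- function(state) {
  s <- as.list(state[.SPECIES])
  c(tce = s$tce + s$d_taa + s$d_cd3 + s$d_shed + s$tri + s$tri_shed,
    taa = s$taa + s$d_taa + s$tri,
    cd3 = s$cd3 + s$d_cd3 + s$tri + s$tri_shed,
    shed = s$shed + s$d_shed + s$tri_shed)
}

#' Equilibrium composition of a closed compartment
#'
#' Solves the mass-action equilibrium of the binding network for given entity
#' totals, using a damped Newton iteration on the logarithms of the free
#' concentrations. Complex concentrations follow from detailed balance, e.g.
#' `tri = tce * taa * cd3 / (kd_target * kd_cd3)`. Agrees with long-time
#' integration of [binding_fluxes()].
#'
#' @param totals Named vector with non-negative totals `tce`, `taa`, `cd3`,
#'   `shed` (nM).
#' @param params A [binding_params()].
#' @param tol Relative residual tolerance of the conservation equations.
#' @param max_iter Iteration cap before a non-convergence error.
#' @return Named vector over [binding_species()] (nM).
#' @export
#' @examples
#' p <- binding_params(kd_target = 0.1, kd_cd3 = 20, kd_shed = 5.36)
#' equilibrium_complexes(c(tce = 1, taa = 0.8, cd3 = 3.7, shed = 100), p)
equilibrium_complexes <- function(totals, params, tol = 1e-12,
                                  max_iter = 200) {
  tot <- unlist(totals)[c("tce", "taa", "cd3", "shed")]
  if (any(!is.finite(tot)) || any(tot < 0))
    stop("totals must be finite and non-negative")
  active <- tot > 0
  # inactive entities stay at zero; drop them from the solve
  kt <- params$kd_target
  kc <- params$kd_cd3
  ks <- params$kd_shed
  # kon_target = 0 means TAA complexes cannot form at all
  taa_on <- params$kon_target > 0 && active[["taa"]]
  shed_on <- is.finite(ks) && active[["shed"]]
  cd3_on <- active[["cd3"]]
  tce_on <- active[["tce"]]

  comp <- function(f) {
    # f: free tce, taa, cd3, shed
    d_taa <- if (taa_on && tce_on) f[1] * f[2] / kt else 0
    d_cd3 <- if (cd3_on && tce_on) f[1] * f[3] / kc else 0
    d_shed <- if (shed_on && tce_on) f[1] * f[4] / ks else 0
    tri <- if (taa_on && cd3_on && tce_on) f[1] * f[2] * f[3] / (kt * kc) else 0
    tri_s <- if (shed_on && cd3_on && tce_on) f[1] * f[4] * f[3] / (ks * kc) else 0
    c(tce = f[1] + d_taa + d_cd3 + d_shed + tri + tri_s,
      taa = f[2] + d_taa + tri,
      cd3 = f[3] + d_cd3 + tri + tri_s,
      shed = f[4] + d_shed + tri_s)
  }

  f <- pmax(tot, 0)
  idx <- which(active)
  if (length(idx) > 0 && tot[["tce"]] > 0 || any(active)) {
    x <- log(pmax(tot[idx], 1e-300))
    for (it in seq_len(max_iter)) {
      f_full <- numeric(4)
      f_full[idx] <- exp(x)
      g <- comp(f_full)[idx] - tot[idx]
      if (all(abs(g) <= tol * pmax(tot[idx], 1e-30))) break
      # numerical Jacobian wrt log-free concentrations
      J <- matrix(0, length(idx), length(idx))
      h <- 1e-7
      for (k in seq_along(idx)) {
        xk <- x
        xk[k] <- xk[k] + h
        fk <- numeric(4)
        fk[idx] <- exp(xk)
        J[, k] <- (comp(fk)[idx] - tot[idx] - g) / h
      }
      step <- tryCatch(solve(J, g), error = function(e)
        stop("equilibrium solver: singular Jacobian; residual = ",
             format(max(abs(g)))))
      # damp to keep the log step bounded
      step <- pmin(pmax(step, -4), 4)
      lam <- 1
      repeat {
        xn <- x - lam * step
        fn <- numeric(4)
        fn[idx] <- exp(xn)
        gn <- comp(fn)[idx] - tot[idx]
        if (sum(gn^2) <= sum(g^2) || lam < 1e-4) break
        lam <- lam / 2
      }
      x <- xn
      if (it == max_iter)
        stop("equilibrium solver did not converge; residual = ",
             format(max(abs(gn))))
    }
    f <- numeric(4)
    f[idx] <- exp(x)
  } else f <- rep(0, 4)

  d_taa <- if (taa_on) f[1] * f[2] / kt else 0
  d_cd3 <- if (cd3_on) f[1] * f[3] / kc else 0
  d_shed <- if (shed_on) f[1] * f[4] / ks else 0
  tri <- if (taa_on && cd3_on) f[1] * f[2] * f[3] / (kt * kc) else 0
  tri_s <- if (shed_on && cd3_on) f[1] * f[4] * f[3] / (ks * kc) else 0
  out <- c(f[1], f[2], f[3], f[4], d_taa, d_cd3, d_shed, tri, tri_s)
  names(out) <- .SPECIES
  out
}

#' Immune synapses per tumor cell
#'
#' Divides the immune-synapse (TAA-TCE-CD3 trimer) concentration by the tumor
#' cell concentration; both in nM, giving a per-cell synapse count.
#'
#' @param trimer Trimer concentration (nM). Vectorised.
#' @param tumor_cells Tumor cell concentration (nM of cells); must be > 0.
#' @return Synapses per tumor cell (dimensionless).
#' @export
trimers_per_tumor_cell <- function(trimer, tumor_cells) {
  if (any(tumor_cells <= 0)) stop("tumor cell concentration must be positive")
  trimer / tumor_cells
}

#' Cytotoxicity (tumor killing) parameters
#'
#' Hill-type killing driven by the per-cell immune synapse count, applied as a
#' first-order rate on the normalized tumor burden together with exponential
#' growth.
#'
#' @param kg Tumor growth rate (1/day).
#' @param kkillmax Maximum killing rate at synapse saturation (1/day).
#' @param kkill50 Synapses per tumor cell at half-maximal killing.
#' @param hill Hill coefficient.
#' @param baseline_fraction Initial normalized tumor burden.
#' @return An object of class `cytotox_params`.
#' @export
cytotox_params <- function(kg = 0.291, kkillmax, kkill50, hill = 1,
                           baseline_fraction = 1) {
  stopifnot(kg >= 0, kkillmax >= 0, kkill50 > 0, hill > 0,
            baseline_fraction > 0)
  structure(list(kg = kg, kkillmax = kkillmax, kkill50 = kkill50,
                 hill = hill, baseline_fraction = baseline_fraction),
            class = "cytotox_params")
}

#' Hill-type killing rate from the synapse count
#'
#' `kkillmax * ts^hill / (kkill50^hill + ts^hill)` where `ts` is the immune
#' synapse count per tumor cell.
#'
#' @param ts_per_cell Synapses per tumor cell (>= 0). Vectorised.
#' @param params A [cytotox_params()].
#' @return Killing rate (1/day).
#' @export
hill_kill_rate <- function(ts_per_cell, params) {
  stopifnot(all(ts_per_cell >= 0))
  th <- ts_per_cell^params$hill
  params$kkillmax * th / (params$kkill50^params$hill + th)
}

#' Convert cell counts to molar receptor concentration
#'
#' `cells * receptors_per_cell / (Avogadro * volume) * 1e9` nM.
#'
#' @param cells Number of cells.
#' @param receptors_per_cell Receptor copies per cell.
#' @param volume Volume (L); must be > 0.
#' @return Concentration (nM).
#' @export
cells_to_nM <- function(cells, receptors_per_cell, volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  stopifnot(all(cells >= 0), all(receptors_per_cell >= 0))
  cells * receptors_per_cell / (.AVOGADRO * volume) * 1e9
}

#' @rdname cells_to_nM
#' @param conc Concentration (nM).
#' @export
nM_to_cells <- function(conc, receptors_per_cell, volume) {
  if (any(receptors_per_cell <= 0)) stop("receptors per cell must be positive")
  conc * .AVOGADRO * volume / (receptors_per_cell * 1e9)
}

# Integrate the closed-compartment binding network (no transport, no
# killing); used as the slow oracle against the equilibrium solver.
integrate_closed_binding <- function(state0, params, t_end,
                                     rtol = 1e-10, atol = 1e-14) {
  y0 <- unlist(state0[.SPECIES])
  rhs <- function(t, y, p) {
    names(y) <- .SPECIES
    list(binding_fluxes(pmax(y, 0), params))
  }
  out <- deSolve::lsoda(y0, c(0, t_end), rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  st <- out[nrow(out), -1]
  names(st) <- .SPECIES
  st
}
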