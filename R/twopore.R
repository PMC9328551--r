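# Molecular-size-dependent transport under the two-pore theory of capillary
# exchange. The capillary wall is modelled as many small pores (~4.44 nm) and
# few large pores (~22.85 nm); a solute of hydrodynamic radius a_e crosses by
# diffusion (PS, hindered by the accessible-area fraction A/A0) and by
# convection (J, rejected by the reflection coefficient sigma). Blood <->
# interstitium exchange is then lumped into two saturating rate constants
# (q_in, q_out) under a quasi-steady-state treatment of the vascular space.

# Boltzmann constant x 310 K, in mmHg * nm^3, times 4/(3*pi). Used to convert
# pore hydraulic conductance into diffusive permeability for a cylindrical
# pore: PS_i = afrac_i * alpha_i * (L/Starling) * KT_FACTOR / (a_e * r_i^2).
.KT_FACTOR <- 4 / (3 * pi) * 1.380649e-23 * 310 * 1e27 / 133.322

# Power law a_e = c * mw^b fixed by least squares through the three anchor
# pairs (5 kDa, 1.29 nm), (54 kDa, 3.24 nm), (150 kDa, 4.81 nm); the three
# residuals are < 0.01 nm so the fit is effectively exact.
.AE_POWER <- local({
  mw <- c(5000, 54000, 150000)
  ae <- c(1.29, 3.24, 4.81)
  ft <- stats::lm.fit(cbind(1, log(mw)), log(ae))
  c(c = exp(ft$coefficients[[1]]), b = ft$coefficients[[2]])
})

#' Pore geometry of the capillary wall
#'
#' Bundles the two-pore geometry constants: pore radii, fractional hydraulic
#' conductances, the isogravimetric-flow coefficient and the net Starling
#' force. Defaults are the standard two-pore values used for human and mouse
#' capillaries.
#'
#' @param r_large Large-pore radius (nm).
#' @param r_small Small-pore radius (nm).
#' @param alpha_large Fractional hydraulic conductance of large pores.
#' @param alpha_small Fractional hydraulic conductance of small pores.
#' @param x_iso Coefficient for the isogravimetric (circular) lymph flow.
#' @param starling Net Starling force (mmHg) driving transcapillary filtration.
#' @return An object of class `pore_geometry`.
#' @export
#' @examples
#' pore_geometry()
pore_geometry <- function(r_large = 22.85, r_small = 4.44,
                          alpha_large = 0.042, alpha_small = 0.958,
                          x_iso = 0.38, starling = 1) {
  stopifnot(r_large > r_small, r_small > 0, x_iso >= 0, x_iso <= 1,
            starling > 0)
  if (abs(alpha_large + alpha_small - 1) > 1e-10)
    stop("alpha_large + alpha_small must equal 1")
  structure(list(r_large = r_large, r_small = r_small,
                 alpha_large = alpha_large, alpha_small = alpha_small,
                 x_iso = x_iso, starling = starling),
            class = "pore_geometry")
}

#' Stokes-Einstein radius of a protein
#'
#' Hydrodynamic radius from molecular weight via the power law
#' `a_e = c * mw^b`, with the constants fixed by an (effectively exact) fit
#' through three anchor radii: 1.29 nm at 5 kDa, 3.24 nm at 54 kDa and
#' 4.81 nm at 150 kDa.
#'
#' @param mw Molecular weight (Da). Vectorised.
#' @return Radius in nm.
#' @export
#' @examples
#' stokes_einstein_radius(54000) # ~3.24 nm
stokes_einstein_radius <- function(mw) {
  if (any(!is.finite(mw)) || any(mw <= 0))
    stop("molecular weight must be positive and finite")
  unname(.AE_POWER["c"] * mw^.AE_POWER["b"])
}

#' Osmotic reflection coefficient of a pore
#'
#' Quartic reflection polynomial in the radius ratio `lambda = a_e / r_pore`:
#' `sigma = (16/3) lambda^2 - (20/3) lambda^3 + (7/3) lambda^4`, clipped to
#' `[0, 1]`; a solute larger than the pore (`lambda >= 1`) is fully reflected.
#'
#' @param a_e Solute hydrodynamic radius (nm). Vectorised.
#' @param r_pore Pore radius (nm).
#' @return Dimensionless reflection coefficient in `[0, 1]`.
#' @export
reflection_coefficient <- function(a_e, r_pore) {
  stopifnot(all(a_e > 0), all(r_pore > 0))
  lam <- pmin(a_e / r_pore, 1)
  pmin(pmax(16 / 3 * lam^2 - 20 / 3 * lam^3 + 7 / 3 * lam^4, 0), 1)
}

#' Fractional accessible pore area
#'
#' Renkin-type hindered-diffusion area fraction
#' `(1 - lambda)^2 (1 - 2.104 lambda + 2.09 lambda^3 - 0.95 lambda^5)` with
#' `lambda = a_e / r_pore`. For `lambda >= 1` the fraction is floored at a
#' small positive epsilon rather than zero, so that a near-pore-sized solute
#' retains a vanishing but finite diffusive pathway.
#'
#' @inheritParams reflection_coefficient
#' @param floor Lower bound applied for `lambda >= 1` (default `1e-9`).
#' @return Dimensionless area fraction in `(0, 1]`.
#' @export
accessible_area_fraction <- function(a_e, r_pore, floor = 1e-9) {
  stopifnot(all(a_e > 0), all(r_pore > 0))
  lam <- a_e / r_pore
  out <- (1 - lam)^2 * (1 - 2.104 * lam + 2.09 * lam^3 - 0.95 * lam^5)
  out[lam >= 1] <- floor
  pmin(pmax(out, floor), 1)
}

#' Size coefficients of a molecule
#'
#' All per-molecule two-pore quantities: hydrodynamic radius, radius ratios,
#' reflection coefficients and accessible-area fractions for both pore
#' classes.
#'
#' @param mw Molecular weight (Da).
#' @param geometry A [pore_geometry()].
#' @return An object of class `size_coefficients`.
#' @export
#' @examples
#' size_coefficients(150000)
size_coefficients <- function(mw, geometry = pore_geometry()) {
  a_e <- stokes_einstein_radius(mw)
  structure(list(
    mw = mw, a_e = a_e,
    lambda_large = a_e / geometry$r_large,
    lambda_small = a_e / geometry$r_small,
    sigma_large = reflection_coefficient(a_e, geometry$r_large),
    sigma_small = reflection_coefficient(a_e, geometry$r_small),
    afrac_large = accessible_area_fraction(a_e, geometry$r_large),
    afrac_small = accessible_area_fraction(a_e, geometry$r_small)
  ), class = "size_coefficients")
}

#' @export
print.size_coefficients <- function(x, ...) {
  cat(sprintf("Two-pore size coefficients (MW %.0f Da, a_e %.3f nm)\n",
              x$mw, x$a_e))
  cat(sprintf("  large pore: lambda %.4f  sigma %.4g  A/A0 %.4g\n",
              x$lambda_large, x$sigma_large, x$afrac_large))
  cat(sprintf("  small pore: lambda %.4f  sigma %.4g  A/A0 %.4g\n",
              x$lambda_small, x$sigma_small, x$afrac_small))
  invisible(x)
}

#' Per-pore-class fluid flows
#'
#' Splits the tissue lymph flow between the two pore classes and adds the
#' circular isogravimetric flow `J_iso = x_iso * L`, which leaves through the
#' large pores and re-enters through the small pores, so that
#' `j_large + j_small = L` exactly.
#'
#' @param lymph_flow Tissue lymph flow L (L/day/kg).
#' @param geometry A [pore_geometry()].
#' @return A list with `j_large`, `j_small` and `j_iso` (L/day/kg).
#' @export
pore_flows <- function(lymph_flow, geometry = pore_geometry()) {
  if (!is.finite(lymph_flow) || lymph_flow < 0)
    stop("lymph flow must be non-negative")
  j_iso <- geometry$x_iso * lymph_flow
  list(j_large = geometry$alpha_large * lymph_flow + j_iso,
       j_small = geometry$alpha_small * lymph_flow - j_iso,
       j_iso = j_iso)
}

#' Permeability-surface-area products per pore class
#'
#' Diffusive exchange capacity of a tissue for a given solute. The tissue's
#' hydraulic conductance is obtained from the printed lymph flow and Starling
#' force (`LpS = L / starling`), split between the pore classes by their
#' hydraulic-conductance fractions, and converted to diffusive permeability
#' through the cylindrical-pore relation, which makes `PS` proportional to the
#' accessible-area fraction and to the free diffusivity (`1/a_e`,
#' Stokes-Einstein):
#' `PS_i = afrac_i * alpha_i * LpS * (4 kT)/(3 pi a_e r_i^2)`.
#'
#' A dimensionless `scale` multiplies both products; the platform default is
#' calibrated against the clinical bone-marrow benchmark (see
#' [platform_defaults()]).
#'
#' @param coeffs A [size_coefficients()].
#' @param lymph_flow Tissue lymph flow (L/day/kg).
#' @param geometry A [pore_geometry()].
#' @param scale Dimensionless scaling of the diffusive capacity.
#' @return A list with `ps_large` and `ps_small` (L/day/kg).
#' @export
permeability_surface <- function(coeffs, lymph_flow,
                                 geometry = pore_geometry(), scale = 1) {
  if (!is.finite(lymph_flow) || lymph_flow < 0)
    stop("lymph flow must be non-negative")
  lps <- lymph_flow / geometry$starling
  kfac <- .KT_FACTOR / coeffs$a_e
  list(
    ps_large = scale * coeffs$afrac_large * geometry$alpha_large * lps *
      kfac / geometry$r_large^2,
    ps_small = scale * coeffs$afrac_small * geometry$alpha_small * lps *
      kfac / geometry$r_small^2
  )
}

#' Simplified blood-to-interstitium exchange rate constants
#'
#' Lumps perfusion, diffusion and convection into one influx and one efflux
#' rate constant per tissue:
#' `q_in  = Q (PS_tot + J_tot) / ((Q - L) + PS_tot + J_tot)` and
#' `q_out = (Q - L) PS_tot / ((Q - L) + PS_tot + J_tot)`,
#' where `PS_tot` sums both pore classes and `J_tot` sums the sieved
#' convective flows `j_i (1 - sigma_i)`. Both constants saturate: `q_in < Q`
#' (perfusion-limited ceiling) and `q_out < (Q - L)`.
#'
#' @param q Tissue plasma (arterial) flow Q (L/day/kg).
#' @param lymph_flow Tissue lymph flow L (L/day/kg); must satisfy `q > L`.
#' @param ps_total Summed permeability-surface products (L/day/kg).
#' @param j_total Summed sieved convective flows (L/day/kg).
#' @return A list with `q_in` and `q_out` (L/day/kg).
#' @export
simplified_exchange <- function(q, lymph_flow, ps_total, j_total) {
  if (!is.finite(q) || !is.finite(lymph_flow) || lymph_flow < 0 ||
      q <= lymph_flow)
    stop("requires Q > L >= 0 (venous flow must be positive)")
  stopifnot(ps_total >= 0, j_total >= 0)
  den <- (q - lymph_flow) + ps_total + j_total
  list(q_in = q * (ps_total + j_total) / den,
       q_out = (q - lymph_flow) * ps_total / den)
}

#' Full tissue transport coefficients for one molecule in one tissue
#'
#' Convenience wrapper combining [size_coefficients()], [pore_flows()],
#' [permeability_surface()] and [simplified_exchange()].
#'
#' @param mw Molecular weight (Da).
#' @param q Tissue plasma flow (L/day/kg).
#' @param lymph_flow Tissue lymph flow (L/day/kg).
#' @param geometry A [pore_geometry()].
#' @param ps_scale Dimensionless scaling of diffusive capacity.
#' @return An object of class `tissue_transport` with elements `ps_large`,
#'   `ps_small`, `j_large`, `j_small`, `j_iso`, `j_eff_large`, `j_eff_small`
#'   (sieved flows), `q_in` and `q_out`, all in L/day/kg.
#' @export
#' @examples
#' tissue_transport(54000, q = 0.88, lymph_flow = 0.0155)
tissue_transport <- function(mw, q, lymph_flow, geometry = pore_geometry(),
                             ps_scale = 1) {
  sc <- size_coefficients(mw, geometry)
  fl <- pore_flows(lymph_flow, geometry)
  ps <- permeability_surface(sc, lymph_flow, geometry, scale = ps_scale)
  j_eff_large <- fl$j_large * (1 - sc$sigma_large)
  j_eff_small <- fl$j_small * (1 - sc$sigma_small)
  ex <- simplified_exchange(q, lymph_flow,
                            ps$ps_large + ps$ps_small,
                            j_eff_large + j_eff_small)
  structure(c(ps, fl,
              list(j_eff_large = j_eff_large, j_eff_small = j_eff_small,
                   q_in = ex$q_in, q_out = ex$q_out, mw = mw,
                   coeffs = sc)),
            class = "tissue_transport")
}

#' Transport coefficient table for molecules across tissues
#'
#' Tabulates the two-pore transport quantities for every (molecule, tissue)
#' pair, suitable for CSV export.
#'
#' @param mws Named numeric vector of molecular weights (Da).
#' @param physiology A physiology registry from [load_physiology()].
#' @param geometry A [pore_geometry()].
#' @param ps_scale Dimensionless scaling of diffusive capacity.
#' @return A data.frame keyed by molecule and tissue.
#' @export
transport_table <- function(mws, physiology = load_physiology("human"),
                            geometry = pore_geometry(),
                            ps_scale = platform_defaults()$ps_scale) {
  tissues <- exchanging_tissues(physiology)
  rows <- lapply(names(mws), function(mn) {
    do.call(rbind, lapply(tissues, function(tn) {
      tp <- physiology$tissues[[tn]]
      tr <- tissue_transport(mws[[mn]], tp$plasma_flow, tp$lymph_flow,
                             geometry, ps_scale)
      data.frame(molecule = mn, tissue = tn,
                 ps_large = tr$ps_large, ps_small = tr$ps_small,
                 j_large = tr$j_large, j_small = tr$j_small,
                 j_iso = tr$j_iso, q_in = tr$q_in, q_out = tr$q_out)
    }))
  })
  do.call(rbind, rows)
}
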