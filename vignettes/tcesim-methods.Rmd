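---
title: "Model and methods behind tcesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind tcesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tcesim` simulates bispecific T cell engagers (TCEs) — antibodies or
antibody fragments with one arm against a tumor-associated antigen (TAA,
here BCMA on multiple myeloma cells) and one arm against CD3 on T cells.
The efficacy-driving quantity is the ternary TAA·TCE·CD3 complex (the
immune synapse) bridging a tumor cell and a T cell, reported per tumor
cell. This vignette documents the model, its parameters and units, the
numerical choices, and the limits of what the synthetic-data tests show.

## The binding network

Seven reversible mass-action steps connect nine species per compartment:
free TCE, free TAA, free CD3, free shed target, three dimers (TAA·TCE,
TCE·CD3, shed·TCE) and two trimers (the immune synapse and the
non-productive shed·TCE·CD3 complex). One association rate constant
(`kon = 86 /nM/day`) is shared by all steps; selectivity enters only
through the equilibrium dissociation constants, `koff = kon * kd`. The
second binding event of a trimer uses the same `kd` as the first: no
avidity or cross-arm cooperativity is modelled, and complexes are not
internalized or down-modulated. Shed target — the soluble ectodomain of the
TAA, present at high concentrations in myeloma patients — competes for the
TAA-binding arm, so the network exhibits both the classic hook effect
(synapse formation is bell-shaped in TCE concentration, because excess TCE
saturates each arm separately) and shed-mediated right-shift of potency.

A damped-Newton equilibrium solver (`equilibrium_complexes()`) works on the
logarithms of the four free concentrations with complexes given by detailed
balance. It is used as an independent cross-check of the kinetic
integration: the test suite requires agreement within 1e-6 relative after
integrating the mass-action fluxes to `t = 1e4` days.

## In vitro cytotoxicity

A closed co-culture (default: 25 000 T cells and 5 000 myeloma cells in
100 µL, a 5:1 E:T ratio) couples the binding network to a normalized tumor
burden `B`:

    dB/dt = (kg - kkill(ts)) * B,
    kkill(ts) = kkillmax * ts^hill / (kkill50^hill + ts^hill),

where `ts` is the current synapse count per tumor cell. TAA totals scale
with the burden: growth adds fresh free TAA, death removes TAA-bearing
species proportionally and releases the non-TAA parts of their complexes
(a killed synapse leaves a TCE·CD3 dimer). Viability divides by a drug-free
control grown at the same `kg`, so the growth rate influences predictions
only through burden-dependent TAA totals. The well volume is not part of
the published assay descriptions; 100 µL is fixed because it exactly
reconciles the reported 0.0415 nM CD3 concentration with 25 000 T cells at
1e5 CD3/cell, and it is exposed in `assay_config()`.

Fitting (`fit_invitro()`) is weighted least squares under the combined
error model `obs = pred (1 + prop * e1) + add * e2`, weights
`1/(prop * pred + add)`, with a log-scale golden-section search for single
parameters and simplex-then-BFGS refinement otherwise; %RSE comes from the
inverse-Hessian approximation. When both the shed-target affinity and the
baseline shed level are requested from a design with fewer than two
distinct non-zero added-shed levels, the pair is structurally
non-identifiable; the fit warns and flags itself. Two readout modes
(`viability`, `lysis`) cover luminescence-type and depletion-type assays.

## Two-pore biodistribution

Capillary walls are treated as a population of small pores (radius 4.44 nm,
fractional hydraulic conductance 0.958) and large pores (22.85 nm, 0.042).
A solute of hydrodynamic radius `a_e` — from the power law
`a_e = 0.0478 * MW^0.387` nm, an effectively exact fit through the anchors
1.29 nm at 5 kDa, 3.24 nm at 54 kDa and 4.81 nm at 150 kDa — crosses by
diffusion, hindered by the Renkin accessible-area fraction, and by
convection, sieved by the quartic osmotic reflection polynomial
`sigma(lambda) = (16/3)lambda^2 - (20/3)lambda^3 + (7/3)lambda^4` with
`lambda = a_e/r_pore` clipped at 1. The accessible-area fraction is floored
at 1e-9 for `lambda >= 1` so that a near-pore-sized solute keeps a
vanishing but finite diffusive pathway. Tissue lymph flow `L` splits into
the per-pore-class flows `j_L = alpha_L L + J_iso`,
`j_S = alpha_S L - J_iso`, with the circular isogravimetric flow
`J_iso = 0.38 L`.

Diffusive capacities are derived from printed quantities only: the tissue
hydraulic conductance is `LpS = L / (Starling force)` with the net Starling
force at 1 mmHg, split by pore-class conductance fraction, and converted to
a permeability-surface product through the cylindrical-pore relation

    PS_i = afrac_i * alpha_i * LpS * (4 kT) / (3 pi a_e r_i^2),

which makes `PS` proportional to the accessible area and to the
Stokes-Einstein free diffusivity (`1/a_e`). A single dimensionless scale on
all `PS` values (`ps_scale`) is the one calibrated constant of the
platform: it is set (once, by bisection; `calibrate_ps_scale()`) so that
the BiTE-format BCMA TCE at its clinically efficacious dose reproduces the
benchmark window-averaged 55.0 synapses per tumor cell in bone marrow. The
calibrated value, 0.781, sits close to the kT-derived reference of 1; all
IgG-format predictions (dose matching, the efficacious-range synapse
levels) follow with no further adjustment.

Blood-to-interstitium exchange is lumped into two saturating rate constants
per tissue,

    q_in  = Q (PS_tot + J_tot) / ((Q - L) + PS_tot + J_tot)
    q_out = (Q - L) PS_tot / ((Q - L) + PS_tot + J_tot),

with `J_tot` the sieved convective flows `j_i (1 - sigma_i)`; `q_in < Q`
(perfusion-limited ceiling) and `q_out < Q - L` always.

## The five-compartment platform

Compartments: central blood (plasma plus the lumped tissue vascular
spaces, 0.0686 L/kg), bone marrow (the myeloma site), spleen, a lumped
"other tissue", and lymph node — each carrying the nine binding species,
45 state variables in all (the assembly self-checks this count). Mobility
rules:

* free TCE and the soluble shed·TCE dimer move with the drug's size
  coefficients and are cleared from blood with the drug's systemic
  clearance (the TCE is the complex's largest constituent);
* free shed target moves with its own (5 kDa) coefficients and is cleared
  renally from blood (1.55 L/day/kg);
* cell-bound species ride their cells: the tumor-cell group (free TAA,
  TAA·TCE, synapse) and the T-cell group (free CD3, TCE·CD3, shed trimer)
  migrate through the transmigration network at the printed rates, with
  first-order tissue losses chosen so the printed baselines are an exact
  pre-dose steady state (degradation where printed, lymph-borne return
  otherwise; the synapse is anchored to its tumor cell). Cell sources are
  held at baseline throughout — treatment-induced T cell proliferation or
  trafficking changes are outside the model.

Letting cell-bound complexes traffic is load-bearing: a TCE bound tightly
to CD3 redistributes into the T-cell spatial distribution, whose volume is
more than an order of magnitude larger than blood. That trapping, combined
with the tissue CD3 gradient, produces the nonmonotonic dependence of
synapse formation on CD3 affinity (the "sweet spot"): tightening `kd_CD3`
below ~0.1 nM reduces synapse formation, and the effect disappears when
CD3 expression is forced uniform across compartments or when the platform
is collapsed to one compartment (`kd_cd3_sweep()` exposes all three
variants).

Shed target is synthesized in the bone-marrow interstitium; the synthesis
rate is the solution of the linear pre-dose steady state that puts blood
shed at 100 nM (the average level reported in myeloma patients), which
places bone-marrow shed several-fold above blood — one of the two reasons
(with the 0.555 E:T ratio) that bone-marrow synapse counts run below other
compartments.

Dosing: IV bolus, zero-order infusion windows (doses quoted per week;
400 µg/day at 70 kg is 0.04 mg/kg/week), and subcutaneous first-order
absorption (`ka = 0.7 /day`, chosen to match a 3-7 day Tmax; bioavailability
fixed at 1). Dosed-drug mass balance (residual + eliminated =
administered × F) is tracked by bookkeeping states and closes to well
under 0.5%.

## Numerics

`deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-12` nM; results are
required (by test) to be stable to one order looser settings. The time axis
is segmented at dose events; boluses are state jumps, infusions are
piecewise-constant inputs. Concentrations are clamped at zero inside the
right-hand side to guard against solver undershoot. Window averages are
trapezoidal on the output grid (0.25-day spacing for the benchmark runs,
0.5 day for sweeps and sensitivities — the coarser grid changes the
benchmark quantities by well under 1%).

Local sensitivity uses central finite differences (±1%) on the
dedimensionalized index `(dy/dp)(p/y)`, integrated over the simulated span
without taking absolute values, so signs survive. Expression-level
perturbations change receptors per cell at fixed cell numbers (the
per-cell synapse readout would otherwise cancel them). Perturbing the shed
elimination rate re-calibrates synthesis to hold the blood level, so its
index is negative: faster elimination at a fixed blood level means more
synthesis flux through bone marrow and more competition at the tumor site.
Dose matching is bisection on log-dose to 1% and returns the lowest
matching dose on a nonmonotone response.

## Synthetic data and what the tests show

`generate_invitro()` adds combined proportional+additive Gaussian noise to
simulated assay curves (the published magnitudes: proportional 0.0732,
additive 0.00593 or 0.025 by assay); `generate_pk()` adds proportional
lognormal-style noise (`pred * exp(prop * e)`) to sparse blood free-TCE
samples. The distributional choice is the package's own — only error
magnitudes, not distributions, are published. Parameter-recovery tests
(shed affinity within 15% median over 20 seeds; clearance within 20%)
demonstrate that the fitting machinery is consistent under the model's own
error structure. They do not validate the model against real assay data:
real curves carry plate effects, donor-to-donor T cell variability and
readout nonlinearities that the generator does not emulate, and published
in vitro potencies for the two clinical molecules differ by orders of
magnitude across laboratories.

The mouse physiology registry is a synthetic stand-in assembled from
literature-typical allometric values, clearly flagged in
`load_physiology()`. It supports the qualitative drug-only biodistribution
mode (size ordering of tissue:plasma ratios; estimated vs
fraction-of-plasma-flow lymph parameterizations) and is not a transcription
of any published mouse table.

## Design choices made where the design was open

* Benchmark calibration: only `ps_scale` is fitted, to a single clinical
  observable; every other number is printed physiology or printed binding
  kinetics. Simulations at 0.215 and 1 mg/kg/week then reproduce the
  reported bone-marrow synapse range (58.3-73.9 per cell) to within 10%,
  which we read as support for the transport structure.
* The shed·TCE dimer takes the drug's size and clearance (its largest
  constituent); the shed trimer contains CD3 and therefore follows the
  T-cell group instead.
* Reaction-inventory granularity is the package's own (one entry per
  reversible binding step, per transport edge, per trafficking edge); the
  self-check validates the inventory against the assembled architecture.
* Printed values that could not be reconciled exactly — the small-pore
  accessible-area fractions, which no standard hindrance polynomial
  reproduces at the printed radii — follow the Renkin form, and the
  affected quantities enter only through the calibrated diffusive capacity.
* Trimers per tumor cell divide by baseline tumor-cell concentrations
  (marker concentration over per-cell copies); tumor burden does not change
  in vivo within the model.

## Known limitations

Format-dependent binding avidity is absent (one `kon`, kd-derived
dissociation only). Cell populations are static: no treatment-induced T
cell activation, proliferation, or tumor depletion, hence no feedback of
killing on shed-target production. There is no solid-tumor compartment and
no FcRn/endosomal recycling — clearance differences between formats enter
only through the systemic clearance values. Blood and lymph-node cell
pools are treated as conservatively exchanging (no degradation printed for
them), which the pre-dose stationarity test pins but which is a modeling
choice, as is assigning the printed transmigration column to tumor cells
and T cells alike.
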