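# tcesim

A physiologically-based simulation platform for **bispecific T cell
engagers (TCEs)** — molecules with one arm binding a tumor-associated
antigen (TAA) and one arm binding CD3 on T cells, bridging the two cells
into a cytolytic **immune synapse** (the TAA·TCE·CD3 ternary complex). The
package is aimed at quantitative pharmacologists and protein engineers who
need to compare TCE formats of different molecular size (a 54 kDa BiTE vs
a 150 kDa IgG), anticipate the impact of soluble **shed target** that
competes for the TAA arm, and translate in vitro potency into clinically
meaningful target engagement in the tumor tissue — here bone marrow, the
site of multiple myeloma.

## What it computes

* **Molecular-size-dependent biodistribution** under the two-pore theory
  of capillary exchange: hydrodynamic radius `a_e = c·MW^b`, osmotic
  reflection coefficients `σ(λ) = (16/3)λ² − (20/3)λ³ + (7/3)λ⁴`,
  Renkin-hindered accessible pore areas, and lumped blood↔interstitium
  exchange constants

  `q_in = Q(ΣPS + ΣJ)/((Q−L) + ΣPS + ΣJ)`,
  `q_out = (Q−L)ΣPS/((Q−L) + ΣPS + ΣJ)`.

* **Mechanistic bispecific binding**: seven reversible mass-action steps
  over nine species per compartment (free TCE/TAA/CD3/shed target, three
  dimers, two trimers), a single shared `kon` with `koff = kon·kd`, plus
  an independent equilibrium solver for cross-checks.

* **In vitro cytotoxicity**: closed co-culture with Hill-type
  synapse-driven killing of a growing tumor burden,
  `kkill = kkillmax·ts^h/(kkill50^h + ts^h)`, simulation and weighted
  least-squares fitting under a combined error model (with %RSE and
  identifiability diagnostics).

* **A five-compartment human platform** (blood, bone marrow, spleen,
  other tissue, lymph node; 45 state variables) with T cell / tumor cell
  trafficking baselines, bone-marrow shed-target synthesis calibrated to a
  100 nM blood level, and IV bolus / continuous infusion / subcutaneous
  dosing.

* **Exploration tools**: dedimensionalized local sensitivity indices
  `∫(∂y/∂p)(p/y)dt`, 2D log-spaced parameter sweeps, dose–response scans,
  and cross-format dose matching by bisection.

* **I/O**: YAML run configs, tidy CSV trajectories, JSON reports, SBML
  export/import of the assembled reaction network, and synthetic
  in vitro / PK data generators for testing.

## Worked example

Simulate the BiTE-format BCMA TCE (54 kDa, `kd` 0.1 nM to BCMA, 20 nM to
CD3, 5.36 nM to shed BCMA) at its clinically efficacious dose — a 28-day
continuous infusion of 0.04 mg/kg/week — and read out immune synapses per
tumor cell in bone marrow:

```r
library(tcesim)

asm <- assemble_platform(molecule_amg420(), load_physiology("human"))
asm
#> <platform_assembly> AMG420 in human physiology
#>   45 state variables, 132 reactions, 84 parameters
#>   shed synthesis 155 nmol/day/kg (blood 100 nM)

res <- simulate_regimen(asm, dose_regimen("iv_infusion", 0.04, duration = 28),
                        t_end = 28, dt = 0.25)
average_synapse(res, "bone_marrow", c(0, 28))
#> [1] 55.00001
```

About 55 synapses per tumor cell — a tiny fraction of the ~12 590 BCMA
copies per myeloma cell — suffices at the clinically efficacious dose.
Matching that engagement level with the IgG-format TCE (150 kDa, weekly
subcutaneous dosing, much tighter shed binding at 0.0319 nM) asks: what
weekly dose gives the same bone-marrow synapse level at steady state
(days 56–70)?

```r
dose_match(55.0, molecule = molecule_pf06863135(), bracket = c(0.02, 2))
#> [1] 0.1836203
#> attr(,"achieved")
#> [1] 54.97004
```

≈0.2 mg/kg/week — at the bottom of the IgG's reported efficacious range
(0.215–1 mg/kg/week), across which the simulated bone-marrow engagement
runs from ≈57 to ≈67 synapses/cell. Despite an ~150-fold difference in
clearance and a qualitatively different shed-target selectivity, the two
formats meet the clinic at the same target engagement — the platform's
central translational claim.

The in vitro side, with the published PF-06863135 assay parameters:

```r
cfg <- assay_config(baseline_shed_nM = 0.321)
b   <- binding_params(kd_target = 0.04, kd_cd3 = 17, kd_shed = 0.0319)
k   <- cytotox_params(kg = 0.291, kkillmax = 2.38, kkill50 = 12,
                      hill = 5.89, baseline_fraction = 1.01)
round(1 - simulate_assay(cfg, b, k, c(0.01, 0.1, 1, 10), added_shed_nM = 0), 3)
#> [1] -0.010  0.134  0.991  0.989
round(1 - simulate_assay(cfg, b, k, c(0.01, 0.1, 1, 10), added_shed_nM = 20), 3)
#> [1] -0.01 -0.01 -0.01  0.35
```

(The −0.01 lysis at sub-potent concentrations is the fitted baseline tumor
fraction of 1.01 showing through the control normalization.)

Twenty nM of added shed BCMA shifts the lysis curve more than an order of
magnitude to the right — the competitive inhibition that the platform
propagates to the tissue level.

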