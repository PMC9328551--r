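# Shared fixtures: the two clinical-stage molecules' in vitro parameter
# sets and small concentration grids used across tests.

pf_binding <- function() binding_params(kd_target = 0.04, kd_cd3 = 17,
                                        kd_shed = 0.0319)

amg420_binding <- function() binding_params(kd_target = 0.1, kd_cd3 = 20,
                                            kd_shed = 5.36)

pf_cytotox <- function() cytotox_params(kg = 0.291, kkillmax = 2.38,
                                        kkill50 = 12, hill = 5.89,
                                        baseline_fraction = 1.01)

amg420_cytotox <- function() cytotox_params(kg = 0.291, kkillmax = 2.93,
                                            kkill50 = 0.0229, hill = 1,
                                            baseline_fraction = 1)

# AMG420-like co-culture: E:T 6:1, lysis readout, 1-day incubation
amg420_assay <- function() assay_config(effector_count = 30000,
                                        tumor_count = 5000,
                                        incubation = 1, readout = "lysis")

coarse_concs <- function() 10^seq(-4, 1.5, by = 0.75)

# state used in several binding tests: representative in vivo-like totals
rep_totals <- function() c(tce = 1, taa = 0.8, cd3 = 3.7, shed = 100)
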