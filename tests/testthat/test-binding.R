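# Sequential bispecific binding network and the Hill killing law.

test_that("koff values derive from the shared kon and the kd values", {
  p <- binding_params(kd_target = 0.1, kd_cd3 = 17, kd_shed = 5.36)
  expect_equal(p$koff_cd3, 86 * 17)   # 1462/day
  expect_equal(p$koff_target / p$kon, 0.1)
  expect_equal(p$koff_shed / p$kon, 5.36)
  expect_error(binding_params(-1, 1, 1), "kd_target")
})

test_that("all-zero state gives all-zero fluxes; negatives are rejected", {
  p <- amg420_binding()
  z <- setNames(numeric(9), binding_species())
  expect_equal(unname(binding_fluxes(z, p)), numeric(9))
  bad <- z
  bad["tce"] <- -1
  expect_error(binding_fluxes(bad, p), "non-negative")
})

test_that("closed-compartment integration conserves every entity total", {
  p <- amg420_binding()
  st <- setNames(c(1, 0.8, 3.7, 100, 0.1, 0.2, 5, 0.01, 0.3),
                 binding_species())
  tot0 <- binding_totals(st)
  end <- tcesim:::integrate_closed_binding(st, p, t_end = 100)
  tot1 <- binding_totals(end)
  expect_equal(unname(tot1), unname(tot0), tolerance = 1e-10)
  # also for the tight-binder parameter set
  p2 <- pf_binding()
  end2 <- tcesim:::integrate_closed_binding(st, p2, t_end = 100)
  expect_equal(unname(binding_totals(end2)), unname(tot0),
               tolerance = 1e-10)
})

test_that("equilibrium solver agrees with long-time ODE integration", {
  for (p in list(amg420_binding(), pf_binding())) {
    tot <- rep_totals()
    eq <- equilibrium_complexes(tot, p)
    expect_equal(unname(binding_totals(eq)), unname(tot), tolerance = 1e-9)
    st0 <- setNames(c(tot["tce"], tot["taa"], tot["cd3"], tot["shed"],
                      0, 0, 0, 0, 0), binding_species())
    ode <- tcesim:::integrate_closed_binding(st0, p, t_end = 1e4)
    expect_equal(unname(eq), unname(ode), tolerance = 1e-6)
  }
})

test_that("equilibrium edge cases: absent entities and weak shed binding", {
  p <- amg420_binding()
  eq0 <- equilibrium_complexes(c(tce = 0, taa = 1, cd3 = 2, shed = 3), p)
  expect_equal(unname(eq0[c("taa", "cd3", "shed")]), c(1, 2, 3))
  expect_equal(sum(eq0[c("tce", "d_taa", "d_cd3", "d_shed", "tri",
                         "tri_shed")]), 0)
  # kd_shed -> Inf removes all shed-bound species
  pinf <- binding_params(0.1, 20, Inf)
  eqi <- equilibrium_complexes(rep_totals(), pinf)
  expect_equal(unname(eqi["d_shed"] + eqi["tri_shed"]), 0)
  expect_equal(unname(eqi["shed"]), 100)
})

test_that("trimer formation is bell-shaped in total TCE (hook effect)", {
  p <- pf_binding()
  tces <- 10^seq(-3, 3, by = 0.25)
  tri <- vapply(tces, function(tt)
    equilibrium_complexes(c(tce = tt, taa = 0.83, cd3 = 3.66, shed = 0),
                          p)[["tri"]], 0)
  peak <- which.max(tri)
  expect_gt(peak, 1)
  expect_lt(peak, length(tri))
  expect_gt(tri[peak], 10 * tri[1])
  expect_gt(tri[peak], 10 * tri[length(tri)])
})

test_that("trimer count is non-increasing in the shed-target total", {
  p <- amg420_binding()
  sheds <- c(0, 1, 10, 100, 1000)
  tri <- vapply(sheds, function(s)
    equilibrium_complexes(c(tce = 0.5, taa = 0.83, cd3 = 3.66, shed = s),
                          p)[["tri"]], 0)
  expect_true(all(diff(tri) <= 1e-12))
  expect_lt(tri[5], tri[1])
})

test_that("hill killing rate has the stated half-maximum and limits", {
  k <- pf_cytotox()
  expect_equal(hill_kill_rate(12, k), 2.38 / 2)
  expect_equal(hill_kill_rate(0, k), 0)
  expect_equal(hill_kill_rate(24, k), 2.341, tolerance = 1e-3)
  expect_lt(hill_kill_rate(1e6, k), 2.38 + 1e-9)
})

test_that("trimers per tumor cell is a plain concentration ratio", {
  expect_equal(trimers_per_tumor_cell(0, 1e-5), 0)
  expect_equal(trimers_per_tumor_cell(2e-5, 2e-5), 1)
  expect_error(trimers_per_tumor_cell(1, 0), "positive")
  # bone-marrow cell concentration implied by marker and per-cell copies
  cells <- 0.830 / 12590
  expect_equal(cells, 6.59e-5, tolerance = 1e-3)
})

test_that("cell-count <-> concentration conversion is linear and invertible", {
  x <- cells_to_nM(5000, 12590, 1e-4)
  expect_equal(nM_to_cells(x, 12590, 1e-4), 5000)
  expect_equal(cells_to_nM(2 * 5000, 12590, 1e-4), 2 * x)
  expect_error(cells_to_nM(10, 100, 0), "volume")
})
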