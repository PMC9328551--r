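# Two-pore size-dependent transport quantities.

test_that("Stokes-Einstein power law reproduces the anchor radii", {
  expect_equal(stokes_einstein_radius(5000), 1.29, tolerance = 1e-3)
  expect_equal(stokes_einstein_radius(54000), 3.24, tolerance = 1e-3)
  expect_equal(stokes_einstein_radius(150000), 4.81, tolerance = 1e-3)
  expect_error(stokes_einstein_radius(-1), "positive")
  expect_error(stokes_einstein_radius(0), "positive")
})

test_that("reflection coefficients match the published two-pore table", {
  # printed (mw, sigma_large, sigma_small) triplets; 5% relative tolerance
  anchors <- data.frame(
    mw = c(5000, 54000, 150000),
    sigma_large = c(0.0157, 0.0865, 0.18),
    sigma_small = c(0.305, 0.902, 0.998)
  )
  for (i in seq_len(nrow(anchors))) {
    a_e <- stokes_einstein_radius(anchors$mw[i])
    expect_equal(reflection_coefficient(a_e, 22.85), anchors$sigma_large[i],
                 tolerance = 0.05)
    expect_equal(reflection_coefficient(a_e, 4.44), anchors$sigma_small[i],
                 tolerance = 0.05)
  }
  # a point particle is not reflected; the polynomial reaches exactly 1 at
  # lambda = 1 and is clipped there for larger solutes
  expect_equal(reflection_coefficient(1e-12, 4.44), 0, tolerance = 1e-12)
  expect_equal(reflection_coefficient(4.44, 4.44), 1)
  expect_equal(reflection_coefficient(50, 4.44), 1)
})

test_that("accessible-area fractions are Renkin-hindered with a floor", {
  expect_equal(accessible_area_fraction(3.24, 22.85), 0.524,
               tolerance = 0.05)
  expect_equal(accessible_area_fraction(1.29, 4.44), 0.21, tolerance = 0.05)
  # unhindered point particle
  expect_equal(accessible_area_fraction(1e-12, 22.85), 1, tolerance = 1e-9)
  # solutes at or above the pore radius keep a vanishing positive pathway
  expect_equal(accessible_area_fraction(4.81, 4.44), 1e-9)
})

test_that("size monotonicity: a_e grows, afrac and (1 - sigma) shrink", {
  mws <- 10^seq(3.2, 5.6, length.out = 25)
  sc <- lapply(mws, size_coefficients)
  a_e <- vapply(sc, `[[`, 0, "a_e")
  expect_true(all(diff(a_e) > 0))
  for (f in c("afrac_large", "afrac_small")) {
    v <- vapply(sc, `[[`, 0, f)
    expect_true(all(diff(v) <= 0))
  }
  for (f in c("sigma_large", "sigma_small")) {
    v <- vapply(sc, `[[`, 0, f)
    expect_true(all(diff(v) >= 0))
  }
})

test_that("pore flows split lymph flow exactly and include the circular flow", {
  fl <- pore_flows(0.0155)
  expect_equal(fl$j_iso, 0.00589)
  expect_equal(fl$j_large, 0.006541)
  expect_equal(fl$j_small, 0.008959)
  expect_equal(fl$j_large + fl$j_small, 0.0155)
  z <- pore_flows(0)
  expect_equal(unlist(z), c(j_large = 0, j_small = 0, j_iso = 0))
  for (L in c(0.00018, 0.0155, 0.24, 3)) {
    f <- pore_flows(L)
    expect_equal(f$j_large + f$j_small, L)
  }
  expect_error(pore_flows(-0.1), "non-negative")
})

test_that("permeability-surface products follow afrac and 1/a_e", {
  sc <- size_coefficients(54000)
  ps <- permeability_surface(sc, 0.0155)
  expect_gt(ps$ps_large, 0)
  expect_gt(ps$ps_small, 0)
  # doubling the radius at fixed afrac halves ps
  sc2 <- sc
  sc2$a_e <- 2 * sc$a_e
  ps2 <- permeability_surface(sc2, 0.0155)
  expect_equal(ps2$ps_large, ps$ps_large / 2)
  # a fully excluded molecule does not diffuse
  sc0 <- sc
  sc0$afrac_large <- 0
  sc0$afrac_small <- 0
  ps0 <- permeability_surface(sc0, 0.0155)
  expect_equal(ps0$ps_large + ps0$ps_small, 0)
  # size ordering holds in every tissue of the mouse registry
  tab <- transport_table(c(dAb2 = 25600, mAb = 150000),
                         load_physiology("mouse"), ps_scale = 1)
  for (tn in unique(tab$tissue)) {
    sub <- tab[tab$tissue == tn, ]
    expect_gt(sub$ps_small[sub$molecule == "dAb2"],
              sub$ps_small[sub$molecule == "mAb"])
    expect_gt(sub$ps_large[sub$molecule == "dAb2"],
              sub$ps_large[sub$molecule == "mAb"])
  }
})

test_that("simplified exchange matches the closed form and saturates", {
  ex <- simplified_exchange(1, 0.1, 0.2, 0.05)
  expect_equal(ex$q_in, 0.21739, tolerance = 1e-4)
  expect_equal(ex$q_out, 0.15652, tolerance = 1e-4)
  z <- simplified_exchange(1, 0.1, 0, 0)
  expect_equal(z$q_in, 0)
  expect_equal(z$q_out, 0)
  # perfusion-limited ceiling
  big <- simplified_exchange(1, 0.1, 1e9, 1e9)
  expect_equal(big$q_in, 1, tolerance = 1e-6)
  expect_lt(big$q_in, 1)
  expect_lt(big$q_out, 0.9)
  # saturation holds over random admissible inputs
  set.seed(42)
  for (i in 1:50) {
    q <- runif(1, 0.1, 60)
    l <- runif(1, 0, q * 0.9)
    ps <- runif(1, 0, 50)
    j <- runif(1, 0, 5)
    e <- simplified_exchange(q, l, ps, j)
    expect_lt(e$q_in, q)
    expect_lte(e$q_out, q - l)
  }
  expect_error(simplified_exchange(0.1, 0.2, 1, 1), "Q > L")
})
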