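# Bundled physics parameterizations: photon coefficients, proton stopping,
# multiple scattering.

test_that("materials are normalized and the required set is present", {
  mats <- pd_materials()
  need <- c("soft_tissue", "bone", "lung", "skin", "air", "water", "pmma",
    "brass", "polyethylene")
  expect_true(all(need %in% names(mats)))
  for (m in mats) {
    expect_gt(m$density, 0)
    expect_lt(abs(sum(m$composition) - 1), 1e-6)
  }
  expect_error(material("x", -1, c(H = 1)), "positive")
  expect_error(material("x", 1, c(H = 0.5, O = 0.6)), "sum to 1")
  expect_error(material("x", 1, c(Xx = 1)), "unsupported")
})

test_that("photon coefficient grid satisfies its construction identities", {
  tab <- photon_coefficients()
  expect_true(all(tab$mu_compton >= 0 & tab$mu_photoelectric >= 0 &
    tab$mu_pair >= 0))
  # total = sum of processes at every node
  expect_lt(max(abs(tab$mu_total -
    (tab$mu_compton + tab$mu_photoelectric + tab$mu_pair)) /
    tab$mu_total), 1e-9)
  # pair production vanishes below threshold
  expect_true(all(tab$mu_pair[tab$energy_MeV < 1.022] == 0))
  expect_identical(photon_mu("water", 1.0, "pair"), 0)
  # energy-transfer coefficient bounded by the attenuation coefficient
  mats <- pd_materials()
  for (nm in unique(tab$material)) {
    sub <- tab[tab$material == nm, ]
    expect_true(all(sub$muen_over_rho <=
      sub$mu_total / mats[[nm]]$density + 1e-12), info = nm)
  }
  expect_error(photon_mu("water", 8), "grid")
  expect_error(photon_mu("water", 0.005), "grid")
  expect_error(photon_mu("unobtainium", 1), "unknown material")
})

test_that("Compton coefficients equal the closed-form Klein-Nishina total", {
  w <- pd_materials()$water
  ne <- pedidose:::.pd_electrons_per_gram(w) * w$density
  for (E in c(0.1, 1, 6)) {
    expect_equal(photon_mu("water", E, "compton") / ne,
      klein_nishina_total(E), tolerance = 0.01)
  }
  # differential cross section integrates to the closed-form total
  for (E in c(0.05, 0.5, 3)) {
    k <- E / 0.51099895
    got <- stats::integrate(klein_nishina_diff, 1 / (1 + 2 * k), 1, E = E,
      rel.tol = 1e-10)$value
    expect_equal(got, klein_nishina_total(E), tolerance = 1e-6)
  }
})

test_that("bundled tables verify their checksums and match regeneration", {
  expect_true(all(physics_table_checksums_ok()))
  ph_b <- photon_coefficients()
  ph_r <- photon_coefficients(regenerate = TRUE)
  expect_equal(ph_b$mu_total, ph_r$mu_total, tolerance = 1e-5)
  expect_equal(ph_b$muen_over_rho, ph_r$muen_over_rho, tolerance = 1e-5)
  pr_b <- proton_tables()
  pr_r <- proton_tables(regenerate = TRUE)
  expect_equal(pr_b$S_MeV_per_cm, pr_r$S_MeV_per_cm, tolerance = 1e-5)
  expect_equal(pr_b$csda_range_cm, pr_r$csda_range_cm, tolerance = 1e-5)
})

test_that("proton stopping powers and ranges behave physically", {
  # 1/beta^2 dominance: S decreases from 10 to 200 MeV
  expect_gt(proton_stopping_power("water", 10),
    proton_stopping_power("water", 200))
  # monotone decrease over the grid above 2 MeV
  E <- exp(seq(log(2), log(250), length.out = 60))
  expect_true(all(diff(proton_stopping_power("water", E)) < 0))
  # range strictly increasing
  expect_true(all(diff(csda_range("water", E)) > 0))
  # range ordering by density at 240 MeV
  r <- vapply(c("lung", "water", "bone"), csda_range, 0, E = 240)
  expect_true(r[["lung"]] > r[["water"]] && r[["water"]] > r[["bone"]])
  expect_error(proton_stopping_power("water", 0.5), "grid")
  expect_error(csda_range("water", 300), "grid")
})

test_that("CSDA range equals quadrature of 1/S to 0.1%", {
  trapz <- function(mat) {
    e <- exp(seq(log(1), log(240), length.out = 20000))
    y <- 1 / proton_stopping_power(mat, e)
    sum(diff(e) * (y[-1] + y[-length(y)]) / 2)
  }
  for (mat in c("water", "pmma", "soft_tissue")) {
    expect_equal(csda_range(mat, 240), trapz(mat), tolerance = 0.001)
  }
  # range-table inversion is consistent
  for (E in c(50, 120, 240)) {
    expect_equal(csda_energy_from_range("pmma", csda_range("pmma", E)), E,
      tolerance = 1e-3)
  }
})

test_that("Highland angle has the right limits and composes over substeps", {
  expect_identical(highland_theta0(100, 0, "water"), 0)
  # decreases with energy at fixed step
  th <- vapply(c(20, 60, 120, 240), highland_theta0, 0, step = 0.5,
    mat = "water")
  expect_true(all(diff(th) < 0))
  expect_error(highland_theta0(100, -1, "water"), "non-negative")
  expect_error(highland_theta0(0.5, 1, "water"), "cutoff")
  # quadrature composition over N substeps matches the single-step angle
  X0 <- pedidose:::.pd_radiation_length(pd_materials()$water)
  for (t_rel in c(1e-3, 1e-2, 1e-1)) {
    step <- t_rel * X0
    single <- highland_theta0(150, step, "water")
    nsub <- 4
    comp <- sqrt(sum(rep(highland_theta0(150, step / nsub, "water")^2, nsub)))
    expect_equal(comp, single, tolerance = 0.10)
  }
})
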