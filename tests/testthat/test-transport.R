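# Monte Carlo transport engine: Compton sampling, attenuation, Bragg curve,
# energy bookkeeping, estimator agreement, reproducibility.

test_that("Klein-Nishina samples satisfy Compton kinematics and bounds", {
  for (E in c(0.1, 1, 6)) {
    smp <- sample_klein_nishina(E, 500000, seed = 3)
    eps <- smp$E_scattered / E
    k <- E / 0.51099895
    # kinematic identity 1/E' - 1/E = (1 - cos theta)/m_e c^2
    cos_pred <- 1 - 0.51099895 * (1 / smp$E_scattered - 1 / E)
    expect_lt(max(abs(cos_pred - smp$cos_theta)), 1e-9)
    # backscatter bound
    expect_gte(min(eps), 1 / (1 + 2 * k))
    expect_lte(max(eps), 1 + 1e-12)
    # mean scattered fraction matches the quadrature expectation
    m_exp <- stats::integrate(function(x) x * klein_nishina_diff(x, E),
      1 / (1 + 2 * k), 1, rel.tol = 1e-10)$value / klein_nishina_total(E)
    expect_equal(mean(eps), m_exp, tolerance = 0.005)
  }
})

test_that("sampled Klein-Nishina distribution matches the analytic shape", {
  p <- pedidose:::.pd_kn_chisq_p(E = 1.0, n = 100000, seed = 17)
  expect_gt(p, 0.01)
})

test_that("photons through vacuum-only geometry score nothing", {
  ph <- water_slab(thickness = 5, half_width = 10)
  beam <- pencil_photon(ph, 2.0)
  beam$aim_point <- c(25, 0, 0)   # axis misses the slab entirely
  beam$source <- c(25, 100, 0)
  res <- run_histories(2000, beam, ph, seed = 1)
  expect_true(all(res$dose_Gy_per_primary == 0))
  l <- attr(res, "ledger")
  expect_equal(l$escaped, l$primary, tolerance = 1e-12)
})

test_that("uncollided fraction through a water slab follows exp(-mu t)", {
  t_cm <- 10
  ph <- water_slab(thickness = t_cm)
  beam <- pencil_photon(ph, 1.0)
  n <- 30000
  res <- run_histories(n, beam, ph, transport_config(track_cap = 500000L),
    seed = 13, tracks = TRUE)
  frac <- pedidose:::.pd_uncollided_fraction(res, 0, -t_cm)
  expect_gt(nrow(attr(res, "tracks")), 0)
  mu <- photon_mu("water", 1.0, "total")
  expect_mc <- exp(-mu * t_cm)
  se <- sqrt(expect_mc * (1 - expect_mc) / n)
  expect_lt(abs(frac - expect_mc), 3 * se)
})

test_that("proton transport conserves energy and follows the CSDA range", {
  ph <- water_slab(thickness = 45, half_width = 40)
  beam <- pencil_proton(E = 240)
  res <- run_histories(50, beam, ph, transport_config(track_cap = 100000L),
    seed = 4, tracks = TRUE)
  # conservation: everything stops inside, deposit equals emitted energy
  expect_lt(ledger_imbalance(res), 1e-9)
  l <- attr(res, "ledger")
  expect_equal(l$deposited, l$primary, tolerance = 1e-12)
  # Bragg stopping depth equals csda_range within one step
  td <- attr(res, "tracks")
  stops <- td[td$event == "stop", ]
  expect_equal(mean(-stops$y1), csda_range("water", 240), tolerance = 0.01)
  # with scattering off the proton never leaves the entry axis
  cfg <- transport_config(scatter = FALSE, track_cap = 10000L)
  res2 <- run_histories(5, beam, ph, cfg, seed = 4, tracks = TRUE)
  td2 <- attr(res2, "tracks")
  expect_lt(max(abs(td2$x1)), 1e-9)
  expect_lt(max(abs(td2$z1)), 1e-9)
})

test_that("runs are seed-reproducible and scale errors as 1/sqrt(n)", {
  ph <- water_slab(thickness = 10)
  beam <- pencil_photon(ph, 1.0)
  a <- run_histories(4000, beam, ph, seed = 99)
  b <- run_histories(4000, beam, ph, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- run_histories(4000, beam, ph, seed = 100)
  expect_false(identical(a$dose_Gy_per_primary, c_$dose_Gy_per_primary))
  # relative error shrinks like 1/sqrt(2) when n doubles (mean of 10 repeats)
  ratios <- vapply(1:10, function(s) {
    r1 <- run_histories(1500, beam, ph, seed = 1000 + s)
    r2 <- run_histories(3000, beam, ph, seed = 2000 + s)
    r2$rel_error[r2$organ == "slab"] / r1$rel_error[r1$organ == "slab"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / sqrt(2)), 0.2 / sqrt(2))
  expect_error(run_histories(0, beam, ph), "positive")
})

test_that("energy ledger closes on full phantom runs for both modalities", {
  ph <- test_phantom("5y")
  r_ph <- run_histories(4000, aim_at_target(ph, "liver", "photon"), ph,
    seed = 31)
  expect_lt(ledger_imbalance(r_ph), 1e-6)
  r_pr <- run_histories(500, aim_at_target(ph, "liver", "proton"), ph,
    seed = 32)
  expect_lt(ledger_imbalance(r_pr), 1e-6)
})

test_that("track-length and collision estimators agree on a toy phantom", {
  z <- pedidose:::.pd_estimator_agreement(n = 100000, seed = 41)
  expect_lt(z, 3)
})

test_that("a photon run at P4 reaches all nine organs", {
  ph <- test_phantom("newborn")
  res <- run_histories(100000, aim_at_target(ph, "left_lung", "photon"), ph,
    seed = 77)
  organs <- c("skeleton", "skin", "brain", "spine", "left_lung",
    "right_lung", "testes", "colon", "liver")
  doses <- res$dose_Gy_per_primary[match(organs, res$organ)]
  expect_true(all(doses > 0))
})

test_that("protons disperse less energy outside the target than photons", {
  for (age in c("newborn", "15y")) {
    ph <- test_phantom(age)
    fr_ph <- dispersed_energy_fraction(
      run_histories(15000, aim_at_target(ph, "left_lung", "photon"), ph,
        seed = 8))
    fr_pr <- dispersed_energy_fraction(
      run_histories(6000, aim_at_target(ph, "left_lung", "proton"), ph,
        seed = 9))
    expect_lt(fr_pr, fr_ph)
  }
})

test_that("track export writes capped per-segment CSV rows", {
  ph <- test_phantom("5y")
  res <- run_histories(50, aim_at_target(ph, "brain", "photon"), ph,
    transport_config(track_cap = 300L), seed = 2, tracks = TRUE)
  td <- attr(res, "tracks")
  expect_lte(nrow(td), 300)
  expect_true(all(c("history", "kind", "region", "x0", "y1",
    "energy_MeV", "event") %in% names(td)))
  csv <- tempfile(fileext = ".csv")
  write_tracks_csv(res, csv)
  expect_identical(nrow(read.csv(csv)), nrow(td))
  expect_error(write_tracks_csv(run_histories(5,
    aim_at_target(ph, "brain", "photon"), ph, seed = 2), csv), "tracks")
})
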