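# Conversion coefficients, F matrix assembly, CHART case study, paired test.

test_that("conversion coefficients follow F = Dd/Dt with propagated error", {
  expect_identical(conversion_coefficient(2e-16, 2e-16)$F, 1)
  z <- conversion_coefficient(0, 3e-16)
  expect_identical(z$F, 0)
  expect_true(is.na(z$se))
  # dispersed dose at 79.2% of the target dose
  f <- conversion_coefficient(0.792 * 3e-16, 3e-16)
  expect_equal(f$F, 0.792)
  # first-order propagation
  g <- conversion_coefficient(2e-17, 4e-16, se_d = 1e-18, se_t = 8e-18)
  expect_equal(g$se,
    (2e-17 / 4e-16) * sqrt((1e-18 / 2e-17)^2 + (8e-18 / 4e-16)^2))
  expect_error(conversion_coefficient(1e-17, 0), "positive")
  expect_error(conversion_coefficient(-1e-18, 1e-16), "negative")
})

test_that("F matrix has unit diagonal, 28 free cells and order invariance", {
  runs <- fake_grid("5y")
  fm <- build_F_matrix(runs)
  for (mod in c("photon", "proton")) {
    sub <- fm[fm$modality == mod, ]
    expect_identical(nrow(sub), 30L)             # 6 organs x 5 positions
    expect_identical(sum(sub$targeted), 2L)      # left lung @ P4, brain @ P5
    expect_identical(sub$F[sub$targeted], c(1, 1))
    expect_identical(length(f_vector(fm, "5y", mod)), 28L)
  }
  # permuting the input leaves the matrix unchanged
  fm2 <- build_F_matrix(rev(runs))
  expect_identical(fm, fm2)
  # cells equal the direct dose ratios
  r <- runs[[1]]$result
  dt <- r$dose_Gy_per_primary[r$organ == "testes"]
  dd <- r$dose_Gy_per_primary[r$organ == "spine"]
  expect_equal(fm$F[fm$modality == "photon" & fm$position == "P1" &
    fm$organ == "spine"], dd / dt)
  # missing combination is rejected with its name
  expect_error(build_F_matrix(runs[-3]), "missing dose result")
  expect_error(build_F_matrix(c(runs, runs[1])), "duplicate")
})

test_that("F matrix cells match hand-computed ratios on a layered body", {
  ph <- layered_body()
  beam <- pencil_proton(E = 120, x = 0, z = 0, radius = 0)
  beam$aim <- "P3"; beam$target <- "liver"
  res <- run_histories(40, beam, ph, transport_config(scatter = FALSE),
    seed = 55)
  runs <- list(list(age = "5y", modality = "proton", position = "P3",
    result = res))
  fm <- build_F_matrix(runs)
  dt <- organ_dose(res, "liver")
  for (org in pd_reported_organs()) {
    dd <- organ_dose(res, org)
    expect_equal(fm$F[fm$organ == org], dd$dose / dt$dose, tolerance = 1e-12)
  }
  # per-particle normalization independence: rescaling both doses by a
  # common constant leaves F unchanged
  expect_equal(conversion_coefficient(2 * 3e-18, 2 * 1e-16)$F,
    conversion_coefficient(3e-18, 1e-16)$F)
})

test_that("CHART doses are the prescription times F on the fixed schedule", {
  fm <- f_matrix_from_values(data.frame(
    age = c("newborn", "15y", "1y", "newborn", "newborn"),
    modality = c("photon", "photon", "photon", "proton", "photon"),
    position = "P4",
    organ = c("brain", "spine", "spine", "spine", "left_lung"),
    F = c(0.656, 0.387, 0.700, 0.162, 1)))
  rep <- chart_doses(fm, prescription = 54, position = "P4")
  expect_identical(rep$fractions, 36L)
  expect_identical(rep$fractions_per_day, 3L)
  expect_identical(rep$duration_days, 12L)
  d <- rep$doses
  expect_equal(d$dose_Gy[d$age == "newborn" & d$organ == "brain"], 54 * 0.656)
  expect_equal(d$dose_Gy[d$age == "1y" & d$organ == "spine" &
    d$modality == "photon"], 37.8)
  # cell-wise: chart equals prescription x F exactly
  expect_identical(d$dose_Gy, 54 * d$F)
  # zero coefficient gives zero dose
  fm0 <- f_matrix_from_values(data.frame(age = "5y", modality = "photon",
    position = "P4", organ = "brain", F = 0))
  expect_identical(chart_doses(fm0)$doses$dose_Gy, 0)
  expect_error(chart_doses(fm, prescription = -1), "positive")
  expect_error(chart_doses(fm, position = "P2"), "absent")
  expect_error(f_matrix_from_values(data.frame(age = "5y",
    modality = "photon", position = "P4", organ = "left_lung", F = 0.5)),
    "F = 1")
})

test_that("paired t-test matches the closed-form statistic", {
  set.seed(21)
  photon <- runif(28, 0.05, 0.6)
  proton <- photon - (0.08 + rnorm(28, 0, 0.02))
  out <- paired_t_test(photon, proton)
  d <- photon - proton
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- pt(t_manual, df = length(d) - 1, lower.tail = FALSE)
  expect_equal(out$t, t_manual, tolerance = 1e-9)
  expect_equal(out$p_value, p_manual, tolerance = 1e-9)
  expect_identical(out$df, 27)
  expect_identical(out$n, 28L)
  expect_error(paired_t_test(photon, photon), "degenerate")
  expect_error(paired_t_test(photon, proton[-1]), "matched")
  expect_error(paired_t_test(1, 2), "at least two")
  two <- paired_t_test(photon, proton, alternative = "two.sided")
  expect_equal(two$p_value, 2 * min(p_manual, 1 - p_manual), tolerance = 1e-9)
})

test_that("F matrix exports round-trip through CSV", {
  fm <- build_F_matrix(fake_grid("10y"))
  base <- tempfile()
  write_F_matrix(fm, base)
  back <- f_matrix_from_values(read.csv(paste0(base, ".csv")))
  expect_equal(back$F, fm$F)
  expect_identical(back$targeted, fm$targeted)
})
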