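# Tally accumulation, batch statistics, finalization, merging.

test_that("track-length scores are linear and zero for empty segments", {
  acc <- tally_accumulator(c("a", "b"), c(100, 200))
  score_photon_tracklength(acc, "a", 0, 1.0, material = "water")
  expect_identical(unname(acc$hist["a"]), 0)
  score_photon_tracklength(acc, "a", 2, 1.0, weight = 1, material = "water")
  one <- unname(acc$hist["a"])
  score_photon_tracklength(acc, "a", 2, 1.0, weight = 3, material = "water")
  expect_equal(unname(acc$hist["a"]), one + 3 * one)
  acc2 <- tally_accumulator(c("a", "b"), c(100, 200))
  score_photon_tracklength(acc2, "a", 4, 1.0, material = "water")
  expect_equal(unname(acc2$hist["a"]), 2 * one)
  # the scored quantity is length * E * mu_tr
  mu_tr <- photon_muen_over_rho("water", 1.0) * pd_materials()$water$density
  expect_equal(one, 2 * 1.0 * mu_tr)
  expect_error(score_photon_tracklength(acc, "a", -1, 1), "non-negative")
  # unknown organ drops the score and counts the event
  score_photon_tracklength(acc, "nope", 1, 1, material = "water")
  expect_identical(acc$dropped, 1)
})

test_that("proton deposits are additive and reject negative energy", {
  acc <- tally_accumulator("organ", 50)
  score_proton_deposit(acc, "organ", 120)
  score_proton_deposit(acc, "organ", 120)
  tally_end_history(acc)
  acc2 <- tally_accumulator("organ", 50)
  score_proton_deposit(acc2, "organ", 240)
  tally_end_history(acc2)
  expect_equal(acc$sum, acc2$sum, tolerance = 1e-12)
  expect_error(score_proton_deposit(acc, "organ", -0.1), "bookkeeping")
  # stopping a 240 MeV proton in one organ deposits exactly 240 MeV
  expect_identical(unname(acc2$sum["organ"]), 240)
})

test_that("finalize converts MeV/g to Gy with batch statistics", {
  acc <- tally_accumulator(c("hit", "cold"), c(10, 10))
  set.seed(1)
  p <- 0.3; n <- 4000
  hits <- rbinom(n, 1, p)
  for (h in hits) {
    if (h) score_proton_deposit(acc, "hit", 1)
    tally_end_history(acc)
  }
  res <- finalize(acc)
  # dose = mean/mass * Gy conversion
  expect_equal(res$dose_Gy_per_primary[res$organ == "hit"],
    mean(hits) / 10 * 1.602176634e-10, tolerance = 1e-12)
  # Bernoulli relative error matches the closed form
  rel_closed <- sqrt((1 - p) / (n * p))
  expect_equal(res$rel_error[res$organ == "hit"], rel_closed,
    tolerance = 0.2)
  # never-scored organ: zero dose, undefined (NA) relative error
  expect_identical(res$dose_Gy_per_primary[res$organ == "cold"], 0)
  expect_true(is.na(res$rel_error[res$organ == "cold"]))
  expect_error(finalize(tally_accumulator("x", 1)), "zero histories")
  expect_error(tally_accumulator("x", 0), "positive mass")
})

test_that("finalize is scale-consistent in organ mass", {
  mk <- function(masses) {
    acc <- tally_accumulator(c("a", "b"), masses)
    set.seed(5)
    for (i in 1:50) {
      score_proton_deposit(acc, "a", runif(1, 0, 10))
      score_proton_deposit(acc, "b", runif(1, 0, 2))
      tally_end_history(acc)
    }
    finalize(acc)
  }
  r1 <- mk(c(10, 40))
  r2 <- mk(c(20, 80))
  expect_equal(r1$dose_Gy_per_primary, 2 * r2$dose_Gy_per_primary,
    tolerance = 1e-14)
  expect_equal(r1$rel_error, r2$rel_error, tolerance = 1e-14)
})

test_that("merging disjoint accumulators equals one accumulator", {
  fill <- function(acc, seed, n) {
    set.seed(seed)
    for (i in seq_len(n)) {
      score_proton_deposit(acc, "a", rexp(1))
      if (i %% 2 == 0) score_proton_deposit(acc, "b", rexp(1, 2))
      tally_end_history(acc)
    }
    acc
  }
  a <- fill(tally_accumulator(c("a", "b"), c(3, 7)), 1, 40)
  b <- fill(tally_accumulator(c("a", "b"), c(3, 7)), 2, 60)
  whole <- tally_accumulator(c("a", "b"), c(3, 7))
  set.seed(1)
  for (i in 1:40) {
    score_proton_deposit(whole, "a", rexp(1))
    if (i %% 2 == 0) score_proton_deposit(whole, "b", rexp(1, 2))
    tally_end_history(whole)
  }
  set.seed(2)
  for (i in 1:60) {
    score_proton_deposit(whole, "a", rexp(1))
    if (i %% 2 == 0) score_proton_deposit(whole, "b", rexp(1, 2))
    tally_end_history(whole)
  }
  m <- tally_merge(a, b)
  expect_equal(m$sum, whole$sum, tolerance = 1e-12)
  expect_equal(m$sumsq, whole$sumsq, tolerance = 1e-12)
  expect_identical(m$histories, whole$histories)
  expect_equal(as.data.frame(finalize(m)), as.data.frame(finalize(whole)),
    tolerance = 1e-12)
})

test_that("scored energy in a photoelectric absorber matches the kerma integral", {
  # brass at 30 keV: photoelectric dominates, so the track-length kerma of
  # the first flight is the whole story to ~0.1%
  t_cm <- 0.02
  ph <- water_slab(thickness = t_cm, material = "brass", half_width = 5)
  E <- 0.03
  beam <- pencil_photon(ph, E)
  n <- 20000
  res <- run_histories(n, beam, ph, seed = 6)
  mu <- photon_mu("brass", E, "total")
  mu_tr <- photon_muen_over_rho("brass", E) * pd_materials()$brass$density
  # analytic kerma: integral of exp(-mu x) mu_tr E dx over the slab
  e_exp <- E * mu_tr / mu * (1 - exp(-mu * t_cm))
  mass <- as.numeric(organ_mass(ph, "slab"))
  d <- res[res$organ == "slab", ]
  expect_equal(d$dose_Gy_per_primary,
    e_exp / mass * 1.602176634e-10,
    tolerance = max(3.5 * d$rel_error, 0.01))
})

test_that("dose results serialize losslessly to JSON/CSV", {
  ph <- test_phantom("1y")
  res <- run_histories(500, aim_at_target(ph, "colon", "photon"), ph, seed = 3)
  base <- tempfile()
  write_dose_result(res, base)
  back <- read_dose_result(base)
  expect_equal(back$dose_Gy_per_primary, res$dose_Gy_per_primary)
  expect_equal(back$rel_error, res$rel_error)
  expect_identical(attr(back, "metadata")$position,
    attr(res, "metadata")$position)
  expect_true(file.exists(paste0(base, ".csv")))
})
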