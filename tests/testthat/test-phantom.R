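# Stylized phantom construction, point location, ray tracing, masses.

test_that("phantoms contain the nine named organs and scale with age", {
  organs <- c("skeleton", "skin", "brain", "spine", "left_lung",
    "right_lung", "testes", "colon", "liver")
  heights <- numeric(0)
  masses <- list()
  for (age in pd_age_classes()) {
    ph <- test_phantom(age)
    expect_true(all(organs %in% ph$masses$organ), info = age)
    heights <- c(heights, phantom_height(ph))
    masses[[age]] <- stats::setNames(ph$masses$mass_g, ph$masses$organ)[organs]
  }
  # total height strictly increases with age class
  expect_true(all(diff(heights) > 0))
  # every organ mass strictly increases from newborn to 15y
  for (i in seq_len(length(pd_age_classes()) - 1)) {
    a <- pd_age_classes()[i]; b <- pd_age_classes()[i + 1]
    expect_true(all(masses[[b]] > masses[[a]]),
      info = paste(a, "vs", b))
  }
})

test_that("phantom construction is deterministic and rejects bad input", {
  a <- build_phantom("1y")
  b <- build_phantom("1y")
  expect_identical(a$masses, b$masses)
  expect_identical(a$geom, b$geom)
  expect_error(build_phantom("30y"), "age_class")
  expect_error(build_phantom("5y", list(trunk_a = -3)), "positive")
  expect_error(build_phantom("5y", list(nonsense = 2)), "override")
  # overrides that slam two organs together are caught by the volume check
  expect_error(
    build_phantom("5y", list(liver_center = c(0, 2.5, 12), liver_semi = c(7, 4.5, 6))),
    "overlapping")
})

test_that("point location resolves centroids, exterior and bad coordinates", {
  ph <- test_phantom("15y")
  for (org in c("brain", "liver", "colon", "testes", "left_lung",
    "right_lung", "spine")) {
    expect_identical(locate_region(ph, organ_centroid(ph, org)), org)
  }
  expect_identical(locate_region(ph, c(100, 0, 0)), "exterior")
  expect_error(locate_region(ph, c(NA, 0, 0)), "finite")
  expect_error(locate_region(ph, c(Inf, 0, 0)), "finite")
})

test_that("analytic organ volumes match independent rejection sampling", {
  ph <- test_phantom("5y")
  prm <- ph$regions[[which(vapply(ph$regions, `[[`, "", "name") == "brain")]]
  p <- prm$terms[[1]]$inside[[1]]
  v_analytic <- 4 / 3 * pi * prod(p$semi)
  # independent oracle: uniform points in the ellipsoid's bounding box,
  # classified with locate_region
  set.seed(42)
  n <- 100000L
  lo <- p$center - p$semi; hi <- p$center + p$semi
  pts <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
    runif(n, lo[3], hi[3]))
  hits <- sum(vapply(seq_len(n), function(i) {
    locate_region(ph, pts[i, ]) == "brain"
  }, logical(1)))
  vbox <- prod(hi - lo)
  v_mc <- hits / n * vbox
  se <- sqrt(hits / n * (1 - hits / n) / n) * vbox
  expect_lt(abs(v_mc - v_analytic), max(0.01 * v_analytic, 4 * se))
  expect_equal(unclass(organ_mass(ph, "brain")),
    v_analytic * pd_materials()$soft_tissue$density,
    tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(organ_mass(ph, "spleen"), "unknown organ")
})

test_that("region volume fractions from shared sampling match analytic values", {
  ph <- test_phantom("10y")
  counts <- pedidose:::cpp_region_fractions(ph$geom, 400000L, 2024L)
  vbox <- prod(ph$bbox[2, ] - ph$bbox[1, ])
  nms <- ph$geom$names
  n <- 400000L
  for (org in c("brain", "liver", "left_lung", "colon", "spine")) {
    i <- which(nms == org)
    frac <- counts[i] / n
    v_mc <- frac * vbox
    se <- sqrt(frac * (1 - frac) / n) * vbox
    v_true <- ph$masses$volume_cm3[ph$masses$organ == org]
    expect_lt(abs(v_mc - v_true), 3.5 * se + 1e-9,
      label = paste("volume of", org))
  }
})

test_that("interior region volumes sum to the analytic body volume", {
  ph <- test_phantom("1y")
  p <- ph$params
  sxy <- ph$sxy; sz <- ph$sz
  v_body <- (pi * p$trunk_a * p$trunk_b * p$trunk_h +
    4 / 3 * pi * prod(p$head_semi) +
    pi * p$legs_a * p$legs_b * p$legs_len) * sxy^2 * sz
  inside <- ph$masses$organ != "skin"
  expect_equal(sum(ph$masses$volume_cm3[inside]), v_body,
    tolerance = 0.005)
})

test_that("next_crossing returns analytic quadric roots and handles misses", {
  ph <- test_phantom("15y")
  c0 <- organ_centroid(ph, "brain")
  semi <- ph$regions[[which(vapply(ph$regions, `[[`, "", "name") == "brain")]]$terms[[1]]$inside[[1]]$semi
  nc <- next_crossing(ph, c0, c(1, 0, 0))
  expect_equal(nc$distance, semi[1], tolerance = 1e-9)
  expect_identical(nc$region, "skeleton")  # skull shell surrounds the brain
  # ray pointing away from everything
  far <- c(0, ph$bbox[2, 2] + 50, 0)
  nc2 <- next_crossing(ph, far, c(0, 1, 0))
  expect_identical(nc2$region, "exterior")
  expect_identical(nc2$distance, Inf)
  expect_error(next_crossing(ph, c0, c(0, 0, 0)), "norm")
})

test_that("chord lengths through a sphere match a ray-marching oracle", {
  sph <- phantom_from_regions(list(
    simple_region("ball", "water", 10, "ellipsoid",
      center = c(0, 0, 0), semi = c(3, 3, 3))
  ), bbox = rbind(c(-8, -8, -8), c(8, 8, 8)), n_volume = 20000L)
  set.seed(7)
  for (k in 1:5) {
    # random exterior ray through the ball
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    b <- rnorm(3); b <- b / sqrt(sum(b^2)) * runif(1, 0, 1.5)  # impact point
    start <- b - 5.5 * u
    entry <- next_crossing(sph, start, u)
    expect_identical(entry$region, "ball")
    p_in <- start + (entry$distance + 1e-6) * u
    chord <- next_crossing(sph, p_in, u)$distance
    # fixed-step marching oracle
    step <- 1e-3
    s <- 0
    repeat {
      s <- s + step
      if (locate_region(sph, p_in + s * u) != "ball") break
    }
    expect_lt(abs(chord - s), 1e-2)
  }
})

test_that("ray tracing and point location are mutually consistent", {
  ph <- test_phantom("5y")
  set.seed(11)
  n_rays <- 10000L
  lo <- ph$bbox[1, ]; hi <- ph$bbox[2, ]
  mismatches <- 0L
  for (k in seq_len(n_rays)) {
    p <- lo + runif(3) * (hi - lo)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    for (s in 1:4) {
      nc <- next_crossing(ph, p, u)
      if (!is.finite(nc$distance)) break
      p <- p + (nc$distance + 1e-6) * u
      if (locate_region(ph, p) != nc$region) mismatches <- mismatches + 1L
      if (any(p < lo) || any(p > hi)) break
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("geometry export and voxel preview produce consistent tables", {
  ph <- test_phantom("newborn")
  csv <- tempfile(fileext = ".csv")
  df <- export_phantom_csv(ph, csv)
  expect_true(file.exists(csv))
  expect_true(all(c("testes", "brain", "skin") %in% df$region))
  arr <- voxelize_phantom(ph, n = c(12, 8, 20))
  expect_identical(dim(arr), c(12L, 8L, 20L))
  # central voxels should be inside the body, corners outside
  expect_identical(arr[1, 1, 1], 0L)
  expect_gt(arr[6, 4, 10], 0L)
})
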