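# Shared fixtures. Phantom builds are cached per session; all geometries are
# generated in code (no stored data).

.fixture_env <- new.env(parent = emptyenv())

test_phantom <- function(age) {
  key <- paste0("ph_", age)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build_phantom(age)
  .fixture_env[[key]]
}

water_slab <- function(thickness = 10, material = "water", half_width = 30) {
  key <- paste("slab", thickness, material, half_width, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- pedidose:::.pd_water_slab_phantom(
      thickness = thickness, material = material, half_width = half_width)
  }
  .fixture_env[[key]]
}

pencil_photon <- function(phantom, E = 1.0) {
  pedidose:::.pd_pencil_photon_beam(phantom, E = E)
}

# monoenergetic proton pencil beam entering along -y from y = +5
pencil_proton <- function(E = 240, x = 0, z = 0, radius = 0) {
  structure(list(
    modality = "proton", aim = "P0", target = "slab",
    aim_point = c(x, 0, z), center = c(x, 5, z),
    aperture_semi = c(radius, radius), radius = radius,
    source_energy = E, shifter_cm = 0, energy_spread_MeV = 0,
    nozzle_transmission = 1, exit_energy = E, margin = 0
  ), class = "pd_beam")
}

# layered hand-computable phantom: slabs along -y, one per reported organ,
# liver (the P3 target) in the middle
layered_body <- function() {
  if (!is.null(.fixture_env$layered)) return(.fixture_env$layered)
  organs <- c("skin", "skeleton", "left_lung", "liver", "right_lung",
    "spine", "brain")
  mats <- c("skin", "bone", "lung", "soft_tissue", "lung", "bone",
    "soft_tissue")
  regions <- lapply(seq_along(organs), function(i) {
    y1 <- -2 * (i - 1); y0 <- -2 * i
    simple_region(organs[i], mats[i], 10 + i, "box",
      lo = c(-8, y0, -8), hi = c(8, y1, 8))
  })
  .fixture_env$layered <- phantom_from_regions(regions,
    bbox = rbind(c(-9, -15, -9), c(9, 6, 9)), n_volume = 20000L)
  .fixture_env$layered
}

# fake dose result for F-matrix plumbing tests
fake_dose_result <- function(doses, rel = 0.01, age = "5y",
                             modality = "photon", position = "P4") {
  out <- data.frame(
    organ = names(doses),
    dose_Gy_per_primary = unname(doses),
    rel_error = ifelse(unname(doses) > 0, rel, NA_real_),
    histories = 1000,
    stringsAsFactors = FALSE
  )
  attr(out, "metadata") <- list(age_class = age, modality = modality,
    position = position, masses_g = as.list(stats::setNames(
      rep(100, length(doses)), names(doses))))
  class(out) <- c("pd_dose_result", "data.frame")
  out
}

reported_set <- function() {
  c(skeleton = 2e-18, skin = 1e-18, brain = 5e-19, spine = 3e-18,
    left_lung = 4e-18, right_lung = 6e-19, testes = 1e-20, colon = 2e-19,
    liver = 8e-19)
}

# a full synthetic 1-age grid of fake results (target organ dose boosted)
fake_grid <- function(age = "5y") {
  runs <- list()
  for (mod in c("photon", "proton")) {
    for (i in seq_len(nrow(pd_positions()))) {
      pos <- pd_positions()$position[i]
      tgt <- pd_positions()$organ[i]
      d <- reported_set()
      if (mod == "proton") d <- d / 50
      d[tgt] <- 3e-16
      runs[[length(runs) + 1L]] <- list(age = age, modality = mod,
        position = pos, result = fake_dose_result(d, age = age,
          modality = mod, position = pos))
    }
  }
  runs
}
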