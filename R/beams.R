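# Simplified therapy beam models aimed at positions P1-P5.
#
# Photon mode: 6 MV point source at source-axis distance `sad` on the +y
# (anterior) side, energies drawn from a configurable spectrum histogram,
# directions uniform over the pyramid subtending a rectangular field that
# circumscribes the target organ. The accelerator head is replaced by an
# ideal-jaw surrogate: primaries are emitted isotropically into a forward
# cone (default half-angle 45 degrees) and those outside the field pyramid
# are absorbed by the jaws. Absorbed primaries deposit nothing, so only
# in-field photons are transported and the per-primary normalization is the
# analytic solid-angle ratio `head_transmission` (see methods vignette).
#
# Proton mode: 240 MeV source degraded by a PMMA range shifter chosen to
# place the Bragg peak at the target-organ centroid depth, emitted parallel
# to -y uniformly over an elliptical aperture circumscribing the organ's
# beam's-eye silhouette (the flat-field surrogate of a double-scattered
# beamline with a patient collimator shaped to the target).

.pd_positions <- data.frame(
  position = c("P1", "P2", "P3", "P4", "P5"),
  organ = c("testes", "colon", "liver", "left_lung", "brain"),
  stringsAsFactors = FALSE
)

#' Irradiation positions P1-P5
#'
#' @return data.frame mapping position labels to target organs.
#' @export
pd_positions <- function() .pd_positions

#' Default 6 MV photon spectrum
#'
#' Histogram surrogate for a 6 MV linac spectrum: endpoint 6 MeV, mode near
#' 0.7 MeV, bin probabilities proportional to the integral of E exp(-E/0.8)
#' over each bin.
#'
#' @param n_bins Number of energy bins.
#' @return list(edges, probs): bin edges (MeV) and normalized probabilities.
#' @export
default_photon_spectrum <- function(n_bins = 24) {
  edges <- seq(0.05, 6, length.out = n_bins + 1)
  b <- 0.8
  antider <- function(x) -b * (x + b) * exp(-x / b)  # integral of x exp(-x/b)
  probs <- antider(edges[-1]) - antider(edges[-length(edges)])
  list(edges = edges, probs = probs / sum(probs))
}

# solid angle of a rectangle (half-widths hx, hz) seen from distance d on axis
.pd_solid_angle_rect <- function(hx, hz, d) {
  4 * atan(hx * hz / (d * sqrt(hx^2 + hz^2 + d^2)))
}

# skin-entry y coordinate of the anterior body surface along -y at (x, z)
.pd_skin_entry_y <- function(phantom, x, z) {
  p <- c(x, phantom$bbox[2, 2] - 1e-3, z)
  dir <- c(0, -1, 0)
  for (i in 1:50) {
    if (locate_region(phantom, p) != "exterior") return(p[2])
    nc <- next_crossing(phantom, p, dir)
    if (!is.finite(nc$distance)) return(NA_real_)
    p <- p + (nc$distance + 1e-6) * dir
  }
  NA_real_
}

# material path segments from `start` along -y until past y_stop
.pd_beam_path <- function(phantom, start, y_stop) {
  segs <- list()
  p <- start
  dir <- c(0, -1, 0)
  mats_by_region <- vapply(phantom$regions, `[[`, "", "material")
  names(mats_by_region) <- vapply(phantom$regions, `[[`, "", "name")
  for (i in 1:200) {
    reg <- locate_region(phantom, p)
    nc <- next_crossing(phantom, p, dir)
    len <- if (is.finite(nc$distance)) nc$distance else (p[2] - phantom$bbox[1, 2])
    segs[[length(segs) + 1L]] <- list(region = reg,
      material = unname(mats_by_region[reg]), y0 = p[2], len = len)
    p <- p + (len + 1e-6) * dir
    if (p[2] < y_stop - 0.5 || !is.finite(nc$distance)) break
  }
  segs
}

# depth (cm along -y from `start_y`) at which a proton of energy E stops,
# walking the CSDA range through the material sequence
.pd_proton_stop_y <- function(segs, E) {
  for (s in segs) {
    r <- csda_range(s$material, E)
    if (r <= s$len) return(s$y0 - r)
    # residual energy after traversing the segment
    E <- csda_energy_from_range(s$material, r - s$len)
    if (is.na(E) || E <= 1) return(s$y0 - s$len)
  }
  segs[[length(segs)]]$y0 - segs[[length(segs)]]$len
}

#' Select the PMMA range-shifter thickness
#'
#' Returns the PMMA thickness that places the Bragg peak (the residual CSDA
#' range computed through the actual region sequence along the beam axis) at
#' the target organ's centroid depth.
#'
#' @param phantom A `pd_phantom`.
#' @param beam A proton `pd_beam` (shifter field ignored).
#' @return Thickness in cm.
#' @export
select_range_shifter <- function(phantom, beam) {
  stopifnot(inherits(beam, "pd_beam"), beam$modality == "proton")
  aim <- beam$aim_point
  start <- c(aim[1], phantom$bbox[2, 2] - 1e-3, aim[3])
  segs <- .pd_beam_path(phantom, start, phantom$bbox[1, 2])
  rmax <- csda_range("pmma", beam$source_energy)
  depth_for <- function(t) {
    E <- if (t <= 0) beam$source_energy else {
      csda_energy_from_range("pmma", rmax - t)
    }
    if (is.na(E)) return(start[2])  # fully stopped in the shifter
    .pd_proton_stop_y(segs, E)
  }
  if (depth_for(0) > aim[2]) {
    stop("target organ lies deeper than the ", beam$source_energy,
      " MeV proton range; cannot place the Bragg peak")
  }
  lo <- 0; hi <- rmax - 0.05
  if (depth_for(hi) > aim[2]) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (depth_for(mid) > aim[2]) hi <- mid else lo <- mid
    }
  } else hi <- hi  # target so shallow even the thickest shifter overshoots
  out <- (lo + hi) / 2
  if (depth_for(0) >= aim[2] - 1e-9 && out < 1e-3) 0 else out
}

#' Aim a beam at a target organ
#'
#' Builds the beam specification for one of the five irradiation positions:
#' the beam axis passes through the organ centroid along -y; the photon field
#' (or proton aperture) circumscribes the organ's lateral extent plus a
#' margin.
#'
#' @param phantom A `pd_phantom`.
#' @param organ One of testes, colon, liver, left_lung, brain.
#' @param modality `"photon"` or `"proton"`.
#' @param margin Field/aperture margin beyond the organ silhouette, cm.
#' @param sad Photon source-axis distance, cm.
#' @param cone_half_angle_deg Photon head-emission cone half-angle used for
#'   the per-primary normalization.
#' @param aperture_standoff Proton aperture-to-skin distance, cm.
#' @param shifter_cm Optional explicit PMMA range-shifter thickness; by
#'   default chosen with [select_range_shifter()].
#' @param spectrum Photon spectrum list(edges, probs); default
#'   [default_photon_spectrum()].
#' @param energy_spread_MeV Gaussian sigma of the proton nozzle-exit energy
#'   (0 = monoenergetic).
#' @return A `pd_beam` object.
#' @export
aim_at_target <- function(phantom, organ, modality = c("photon", "proton"),
                          margin = 0.5, sad = 100, cone_half_angle_deg = 45,
                          aperture_standoff = 20, shifter_cm = NULL,
                          spectrum = default_photon_spectrum(),
                          energy_spread_MeV = 0) {
  modality <- match.arg(modality)
  pos <- .pd_positions$position[match(organ, .pd_positions$organ)]
  if (is.na(pos)) {
    stop("organ must be one of ", paste(.pd_positions$organ, collapse = ", "))
  }
  names_all <- vapply(phantom$regions, `[[`, "", "name")
  if (!(organ %in% names_all)) stop("organ absent from phantom: ", organ)
  aim <- organ_centroid(phantom, organ)
  ri <- which(names_all == organ)
  prim <- phantom$regions[[ri]]$terms[[1]]$inside[[1]]
  if (prim$kind != "ellipsoid") stop("target organ must be an ellipsoid region")
  hx <- prim$semi[1] + margin
  hz <- prim$semi[3] + margin

  if (modality == "photon") {
    if (!length(spectrum$probs) || any(spectrum$probs < 0) ||
      sum(spectrum$probs) <= 0) {
      stop("photon spectrum is empty or invalid")
    }
    if (abs(sum(spectrum$probs) - 1) > 1e-9) {
      spectrum$probs <- spectrum$probs / sum(spectrum$probs)
    }
    if (max(spectrum$edges) > 6 + 1e-9) {
      stop("photon spectrum extends above the 6 MeV endpoint")
    }
    omega_f <- .pd_solid_angle_rect(hx, hz, sad)
    omega_c <- 2 * pi * (1 - cos(cone_half_angle_deg * pi / 180))
    structure(list(
      modality = "photon", aim = pos, target = organ, aim_point = aim,
      source = aim + c(0, sad, 0), sad = sad, hx = hx, hz = hz,
      spectrum = spectrum, cone_half_angle_deg = cone_half_angle_deg,
      head_transmission = omega_f / omega_c, margin = margin
    ), class = "pd_beam")
  } else {
    # elliptical aperture circumscribing the organ's beam's-eye silhouette
    # plus margin (the patient-collimator surrogate); a circle is the
    # special case of equal semi-axes
    aperture_semi <- c(prim$semi[1] + margin, prim$semi[3] + margin)
    y_skin <- .pd_skin_entry_y(phantom, aim[1], aim[3])
    if (!is.finite(y_skin)) stop("beam axis misses the phantom body")
    center <- c(aim[1], y_skin + aperture_standoff, aim[3])
    bm <- structure(list(
      modality = "proton", aim = pos, target = organ, aim_point = aim,
      center = center, aperture_semi = aperture_semi,
      radius = max(aperture_semi), source_energy = 240,
      shifter_cm = 0, energy_spread_MeV = energy_spread_MeV,
      nozzle_transmission = 1, margin = margin
    ), class = "pd_beam")
    bm$shifter_cm <- if (is.null(shifter_cm)) {
      select_range_shifter(phantom, bm)
    } else shifter_cm
    rmax <- csda_range("pmma", bm$source_energy)
    if (bm$shifter_cm >= rmax) {
      stop("range shifter (", signif(bm$shifter_cm, 4),
        " cm) exceeds the PMMA range of a ", bm$source_energy,
        " MeV proton (", signif(rmax, 4), " cm): beam fully stopped")
    }
    bm$exit_energy <- if (bm$shifter_cm <= 0) bm$source_energy else {
      csda_energy_from_range("pmma", rmax - bm$shifter_cm)
    }
    bm
  }
}

#' @export
print.pd_beam <- function(x, ...) {
  if (x$modality == "photon") {
    cat(sprintf(
      "<photon beam %s -> %s: field %.1f x %.1f cm at SAD %.0f cm, head transmission %.3g>\n",
      x$aim, x$target, 2 * x$hx, 2 * x$hz, x$sad, x$head_transmission))
  } else {
    cat(sprintf(
      "<proton beam %s -> %s: aperture %.1f x %.1f cm, shifter %.2f cm PMMA, exit %.1f MeV>\n",
      x$aim, x$target, 2 * x$aperture_semi[1], 2 * x$aperture_semi[2],
      x$shifter_cm, x$exit_energy))
  }
  invisible(x)
}

# C++ encoding of a beam
.pd_encode_beam <- function(beam) {
  if (beam$modality == "photon") {
    list(modality = 0L, src = beam$source, aim = beam$aim_point,
      hx = beam$hx, hz = beam$hz,
      edges = beam$spectrum$edges, probs = beam$spectrum$probs)
  } else {
    list(modality = 1L, center = beam$center,
      ax = beam$aperture_semi[1], az = beam$aperture_semi[2],
      E0 = beam$exit_energy, esigma = beam$energy_spread_MeV)
  }
}

#' Sample primary particles from a beam
#'
#' Draws `n` primaries using the same counter-based per-history substreams
#' the transport engine uses (history index = row index), so a stream is
#' reproducible for a fixed seed and independent of batching.
#'
#' @param beam A `pd_beam`.
#' @param n Number of primaries.
#' @param seed Integer seed.
#' @return data.frame: kind, x, y, z, ux, uy, uz, energy_MeV, weight.
#' @export
sample_primaries <- function(beam, n, seed = 1L) {
  m <- cpp_sample_primaries(.pd_encode_beam(beam), as.integer(n),
    as.integer(seed))
  data.frame(
    kind = beam$modality, x = m[, 1], y = m[, 2], z = m[, 3],
    ux = m[, 4], uy = m[, 5], uz = m[, 6], energy_MeV = m[, 7], weight = 1
  )
}

#' @rdname sample_primaries
#' @export
sample_photon_primary <- function(beam, n = 1L, seed = 1L) {
  stopifnot(beam$modality == "photon")
  sample_primaries(beam, n, seed)
}

#' @rdname sample_primaries
#' @export
sample_proton_primary <- function(beam, n = 1L, seed = 1L) {
  stopifnot(beam$modality == "proton")
  sample_primaries(beam, n, seed)
}
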