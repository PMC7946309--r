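# R-facing surface of the Monte Carlo engine.
#
# Photons: analog transport, boundary-to-boundary exponential free-path
# sampling (exact for piecewise-constant mu), Klein-Nishina Compton
# scattering, photoelectric absorption, pair production handled as
# annihilation-in-place (two 0.511 MeV photons, no positron transport).
# Energy transfer is scored with the track-length kerma estimator (F6-style
# tally semantics); electrons are not transported. A collision-site analog
# estimator is accumulated in parallel as a consistency check.
#
# Protons: condensed-history stepping (step capped by a maximum length, the
# distance to the next boundary and a maximum fractional energy loss),
# Bethe stopping, Highland small-angle multiple scattering, optional Bohr
# energy straggling, residual energy deposited at the CSDA stopping point.

#' Transport configuration
#'
#' @param photon_cutoff Photon cutoff energy, MeV.
#' @param proton_cutoff Proton cutoff energy, MeV (residual energy deposited
#'   locally below it).
#' @param max_step Maximum condensed-history proton step, cm.
#' @param max_floss Maximum fractional proton energy loss per step.
#' @param straggle Gaussian (Bohr) proton energy straggling on/off. Off by
#'   default for test determinism of the energy ledger.
#' @param scatter Highland multiple scattering on/off.
#' @param track_cap Maximum number of exported track segments.
#' @return list of class `pd_config`.
#' @export
transport_config <- function(photon_cutoff = 0.01, proton_cutoff = 1,
                             max_step = 0.1, max_floss = 0.02,
                             straggle = FALSE, scatter = TRUE,
                             track_cap = 20000L) {
  stopifnot(photon_cutoff >= 0.01, proton_cutoff >= 1, max_step > 0,
    max_floss > 0)
  structure(list(
    photon_cutoff = photon_cutoff, proton_cutoff = proton_cutoff,
    max_step = max_step, max_floss = max_floss,
    straggle = isTRUE(straggle), scatter = isTRUE(scatter),
    track_cap = as.integer(track_cap)
  ), class = "pd_config")
}

# engine material tables for a phantom's region list
.pd_engine_mats <- function(phantom) {
  mats_by_region <- vapply(phantom$regions, `[[`, "", "material")
  uniq <- unique(mats_by_region)
  all_mats <- pd_materials()
  ph <- photon_coefficients()
  pr <- proton_tables()
  tabs <- lapply(uniq, function(nm) {
    m <- all_mats[[nm]]
    sub <- ph[ph$material == nm, ]
    psub <- pr[pr$material == nm, ]
    list(
      rho = m$density, za = .pd_comp_sum(m, 1),
      X0 = .pd_radiation_length(m),
      logE = log(sub$energy_MeV),
      mu_c = sub$mu_compton, mu_pe = sub$mu_photoelectric,
      mu_pair = sub$mu_pair,
      mu_tr = sub$muen_over_rho * m$density,
      plogE = log(psub$energy_MeV), S = psub$S_MeV_per_cm,
      R = psub$csda_range_cm
    )
  })
  list(tabs = tabs, region_mat = match(mats_by_region, uniq) - 1L)
}

#' Sample the Klein-Nishina scattered-photon distribution
#'
#' @param E Incident photon energy, MeV (> 0).
#' @param n Number of samples.
#' @param seed Integer seed (per-sample substreams).
#' @return data.frame E_scattered (MeV), cos_theta.
#' @export
sample_klein_nishina <- function(E, n = 1L, seed = 1L) {
  stopifnot(E > 0)
  m <- cpp_sample_kn(E, as.integer(n), as.integer(seed))
  data.frame(E_scattered = m[, 1], cos_theta = m[, 2])
}

#' Run Monte Carlo histories
#'
#' Samples `n` primaries from the beam, transports each through the phantom
#' and finalizes the tally per primary particle. Results are reproducible
#' for a fixed seed and independent of any batch decomposition because every
#' history owns a counter-based RNG substream.
#'
#' For photon beams the finalized doses include the analytic head
#' transmission factor (primaries absorbed in the ideal jaws), so doses are
#' normalized per emitted primary, not per in-field photon.
#'
#' @param n Number of histories (>= 1).
#' @param beam A `pd_beam`.
#' @param phantom A `pd_phantom`.
#' @param config A [transport_config()].
#' @param seed Integer seed.
#' @param tracks If TRUE, attach exported track segments (capped at
#'   `config$track_cap`) as attribute `"tracks"`.
#' @param estimator `"tracklength"` (photon kerma default) or `"collision"`.
#' @return A `pd_dose_result`; attributes: `metadata` (run provenance),
#'   `ledger` (energy bookkeeping), optionally `tracks`.
#' @export
run_histories <- function(n, beam, phantom, config = transport_config(),
                          seed = 1L, tracks = FALSE,
                          estimator = c("tracklength", "collision")) {
  estimator <- match.arg(estimator)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive number of histories")
  }
  mats <- .pd_engine_mats(phantom)
  res <- cpp_run(phantom$geom, mats, .pd_encode_beam(beam),
    unclass(config), as.numeric(n), as.integer(seed), isTRUE(tracks))

  organs <- phantom$geom$names
  keep <- organs != "exterior"
  scale <- if (beam$modality == "photon") beam$head_transmission else
    beam$nozzle_transmission
  use_sum <- if (beam$modality == "photon" && estimator == "collision") {
    list(s = res$sum_coll, q = res$sumsq_coll)
  } else {
    list(s = res$sum_track, q = res$sumsq_track)
  }
  masses <- phantom$masses$mass_g[match(organs[keep], phantom$masses$organ)]
  acc <- .pd_tally_from_sums(organs[keep], masses,
    use_sum$s[keep] * scale, use_sum$q[keep] * scale^2, res$n)

  md <- list(
    modality = beam$modality, position = beam$aim, target = beam$target,
    age_class = phantom$age_class, seed = as.integer(seed),
    histories = res$n, estimator = estimator,
    head_transmission = scale,
    masses_g = stats::setNames(as.list(masses), organs[keep]),
    config = unclass(config), counters = res$counters
  )
  out <- finalize(acc, metadata = md)
  attr(out, "ledger") <- res$ledger
  if (isTRUE(tracks)) {
    tm <- res$tracks
    colnames(tm) <- c("history", "kind", "region", "x0", "y0", "z0",
      "x1", "y1", "z1", "energy_MeV", "event")
    td <- as.data.frame(tm)
    td$region <- organs[td$region + 1L]
    td$kind <- c("photon", "proton")[td$kind + 1L]
    td$event <- c("boundary", "collision", "escape", "absorbed", "stop")[td$event + 1L]
    attr(out, "tracks") <- td
  }
  out
}

#' Energy-ledger closure of a run
#'
#' Relative imbalance of emitted primary energy versus
#' (transferred + cutoff + deposited + escaped). At a pair-production event
#' the photon's energy splits into local transfer (E - 1.022 MeV) plus the
#' two annihilation photons, so the books close against the primary energy
#' alone (the `created` ledger entry is informational). Zero to floating
#' point for analog runs with straggling off.
#'
#' @param result A `pd_dose_result` from [run_histories()].
#' @return Relative imbalance (dimensionless).
#' @export
ledger_imbalance <- function(result) {
  l <- attr(result, "ledger")
  if (is.null(l)) stop("result carries no energy ledger")
  inflow <- l$primary
  outflow <- l$transferred + l$cutoff + l$deposited + l$escaped
  abs(inflow - outflow) / inflow
}

#' Fraction of deposited energy dispersed outside the target organ
#'
#' @param result A `pd_dose_result`.
#' @param target Target organ name (defaults to the run metadata).
#' @return Dimensionless fraction in [0, 1].
#' @export
dispersed_energy_fraction <- function(result, target = NULL) {
  md <- attr(result, "metadata")
  if (is.null(target)) target <- md$target
  if (is.null(md$masses_g)) stop("result metadata carries no organ masses")
  masses <- unlist(md$masses_g)[result$organ]
  energy <- result$dose_Gy_per_primary * masses
  tot <- sum(energy)
  if (tot <= 0) return(0)
  sum(energy[result$organ != target]) / tot
}

#' Write exported track segments to CSV
#'
#' One row per segment (history id, particle kind, region, start/end
#' coordinates, energy, terminating event).
#'
#' @param result A `pd_dose_result` from `run_histories(..., tracks = TRUE)`.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
write_tracks_csv <- function(result, path) {
  td <- attr(result, "tracks")
  if (is.null(td)) stop("run was made without tracks = TRUE")
  write.csv(td, path, row.names = FALSE)
  invisible(td)
}
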