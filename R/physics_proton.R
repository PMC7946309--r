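# Proton stopping powers, CSDA ranges and multiple-scattering angles.
#
# Stopping power: Bethe formula for protons (z = 1) with Bragg-additivity
# mean excitation energies; no shell or density-effect corrections (valid at
# the 1-250 MeV energies used here at the percent level). Nuclear
# interactions are ignored throughout (documented fluence bias).

.pd_mpc2 <- 938.27208816  # proton rest energy, MeV
.pd_K <- 0.307075         # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol

# Bethe mass stopping power, MeV cm^2/g (vectorized in E).
.pd_bethe_mass_stopping <- function(mat, E) {
  gamma <- 1 + E / .pd_mpc2
  beta2 <- 1 - 1 / gamma^2
  I <- .pd_mean_excitation(mat) * 1e-6  # MeV
  za <- .pd_comp_sum(mat, 1)            # sum w Z/A
  arg <- 2 * .pd_mec2 * beta2 * gamma^2 / I
  .pd_K * za / beta2 * (log(arg) - beta2)
}

# Fine-grid CSDA range table by trapezoid quadrature of 1/S from 1 MeV.
.pd_proton_table_analytic <- function(mat) {
  grid <- .pd_proton_grid()
  fine <- exp(seq(log(1), log(250), length.out = 4000))
  S_fine <- .pd_bethe_mass_stopping(mat, fine) * mat$density  # MeV/cm
  inv <- 1 / S_fine
  R_fine <- c(0, cumsum(diff(fine) * (inv[-1] + inv[-length(inv)]) / 2))
  data.frame(
    energy_MeV = grid,
    S_MeV_per_cm = .pd_bethe_mass_stopping(mat, grid) * mat$density,
    csda_range_cm = stats::approx(fine, R_fine, xout = grid)$y
  )
}

#' Proton stopping and range tables
#'
#' @param regenerate Recompute from the Bethe parameterization instead of
#'   reading the bundled CSV.
#' @return data.frame with columns material, energy_MeV, S_MeV_per_cm,
#'   csda_range_cm.
#' @export
proton_tables <- function(regenerate = FALSE) {
  key <- if (regenerate) "proton_regen" else "proton"
  if (!is.null(.pd_cache[[key]])) return(.pd_cache[[key]])
  tab <- if (regenerate) {
    mats <- pd_materials()
    do.call(rbind, lapply(names(mats), function(nm) {
      cbind(material = nm, .pd_proton_table_analytic(mats[[nm]]))
    }))
  } else {
    ok <- physics_table_checksums_ok()
    if (!ok[["proton_stopping.csv"]]) {
      stop("bundled table proton_stopping.csv failed its checksum; ",
        "regenerate with generate_physics_tables()")
    }
    read.csv(.pd_extdata("proton_stopping.csv"), stringsAsFactors = FALSE)
  }
  .pd_cache[[key]] <- tab
  tab
}

.pd_proton_sub <- function(mat) {
  tab <- proton_tables()
  sub <- tab[tab$material == mat, ]
  if (!nrow(sub)) stop("unknown material: ", mat)
  sub
}

#' Proton stopping power
#'
#' Log-log interpolation of the bundled Bethe table. Queries below 1 MeV are
#' rejected: in transport a proton dropping below that energy is considered
#' stopped and its residual energy is deposited locally by the caller.
#'
#' @param mat Material name.
#' @param E Proton kinetic energy in MeV, within [1, 250].
#' @return Linear stopping power, MeV/cm.
#' @export
proton_stopping_power <- function(mat, E) {
  sub <- .pd_proton_sub(mat)
  if (any(!is.finite(E)) || any(E < 1 - 1e-9) || any(E > 250 + 1e-9)) {
    stop("proton energy outside the stopping-power grid [1, 250] MeV")
  }
  exp(stats::approx(log(sub$energy_MeV), log(sub$S_MeV_per_cm),
    xout = log(pmin(pmax(E, 1), 250)), rule = 2)$y)
}

#' CSDA range
#'
#' Continuous-slowing-down range (cm), measured from 1 MeV (the transport
#' cutoff; the residual sub-MeV range of a few tens of micrometers is
#' deposited locally).
#'
#' @inheritParams proton_stopping_power
#' @return Range in cm.
#' @export
csda_range <- function(mat, E) {
  sub <- .pd_proton_sub(mat)
  if (any(!is.finite(E)) || any(E < 1 - 1e-9) || any(E > 250 + 1e-9)) {
    stop("proton energy outside the range grid [1, 250] MeV")
  }
  stats::approx(sub$energy_MeV, sub$csda_range_cm, xout = E, rule = 2)$y
}

#' Invert the CSDA range table
#'
#' Energy whose CSDA range equals `range_cm` in material `mat`.
#'
#' @param mat Material name.
#' @param range_cm Residual range in cm.
#' @return Kinetic energy in MeV (NA when the range is below the 1 MeV grid).
#' @export
csda_energy_from_range <- function(mat, range_cm) {
  sub <- .pd_proton_sub(mat)
  out <- stats::approx(sub$csda_range_cm, sub$energy_MeV, xout = range_cm,
    rule = 1)$y
  out
}

#' Highland multiple-scattering angle
#'
#' theta0 = (13.6 MeV / (beta c p)) sqrt(step / X0) (1 + 0.038 ln(step / X0)),
#' the standard Gaussian-core width for a condensed-history step. Returns 0
#' in the step -> 0 limit (the logarithmic correction is floored at zero so
#' very thin steps do not produce a negative width).
#'
#' @param E Proton kinetic energy, MeV (>= 1).
#' @param step Step length, cm (> 0, or 0 for the limit).
#' @param mat Material name.
#' @return Scattering angle theta0 in radians.
#' @export
highland_theta0 <- function(E, step, mat) {
  if (any(step < 0)) stop("step must be non-negative")
  if (any(E < 1)) stop("proton energy below the 1 MeV cutoff")
  m <- pd_materials()[[mat]]
  if (is.null(m)) stop("unknown material: ", mat)
  X0 <- .pd_radiation_length(m)
  gamma <- 1 + E / .pd_mpc2
  beta2 <- 1 - 1 / gamma^2
  pc <- sqrt((E + .pd_mpc2)^2 - .pd_mpc2^2)  # momentum * c, MeV
  betapc <- sqrt(beta2) * pc
  t <- step / X0
  out <- 13.6 / betapc * sqrt(t) * pmax(0, 1 + 0.038 * log(t))
  out[step == 0] <- 0
  out
}
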