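#' @useDynLib pedidose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate pt qt rnorm runif sd t.test chisq.test ks.test
#' @importFrom utils read.csv write.csv
NULL

# Element constants used by the analytic photon / proton parameterizations.
# I = mean excitation energy (eV), per standard tabulations.
.pd_elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Ar", "P", "Ca", "Cu", "Zn"),
  Z = c(1, 6, 7, 8, 18, 15, 20, 29, 30),
  A = c(1.008, 12.011, 14.007, 15.999, 39.948, 30.974, 40.078, 63.546, 65.38),
  I_eV = c(19.2, 78, 82, 95, 188, 173, 191, 322, 330),
  stringsAsFactors = FALSE
)

#' Define a material
#'
#' A material is a density plus an elemental composition by mass fraction.
#' Mass fractions must sum to one (tolerance 1e-6) and every element must be
#' one of the supported set (H, C, N, O, Ar, P, Ca, Cu, Zn).
#'
#' @param name Material label.
#' @param density Mass density in g/cm^3 (> 0).
#' @param composition Named numeric vector of element mass fractions.
#' @return An object of class `pd_material`.
#' @export
#' @examples
#' material("water", 0.998, c(H = 0.1119, O = 0.8881))
material <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("material density must be a single positive number")
  }
  if (is.null(names(composition)) || any(names(composition) == "")) {
    stop("composition must be a named numeric vector of mass fractions")
  }
  unknown <- setdiff(names(composition), .pd_elements$symbol)
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", signif(sum(composition), 8), ")")
  }
  structure(
    list(name = name, density = density, composition = composition),
    class = "pd_material"
  )
}

#' @export
print.pd_material <- function(x, ...) {
  cat(sprintf(
    "<material %s: rho = %.4g g/cm^3; %s>\n", x$name, x$density,
    paste(sprintf("%s %.4f", names(x$composition), x$composition), collapse = ", ")
  ))
  invisible(x)
}

#' Built-in material set
#'
#' The frozen material set used by the phantoms and the simplified nozzle:
#' soft tissue, bone, lung, skin, air, water, PMMA, brass and polyethylene.
#' Tissue compositions are four-component (H, C, N, O) ICRU-like mixtures
#' (plus P/Ca for bone); the exact phantom elemental make-up is a documented
#' assumption since organ-level compositions are not part of the study inputs.
#'
#' @return Named list of [material()] objects.
#' @export
pd_materials <- function() {
  list(
    soft_tissue = material("soft_tissue", 1.04,
      c(H = 0.101, C = 0.111, N = 0.026, O = 0.762)),
    bone = material("bone", 1.40,
      c(H = 0.0704, C = 0.2279, N = 0.0387, O = 0.4856, P = 0.0694, Ca = 0.1080)),
    lung = material("lung", 0.296,
      c(H = 0.101, C = 0.111, N = 0.026, O = 0.762)),
    skin = material("skin", 1.09,
      c(H = 0.100, C = 0.204, N = 0.042, O = 0.654)),
    air = material("air", 0.001205,
      c(N = 0.755, O = 0.232, Ar = 0.013)),
    water = material("water", 0.998,
      c(H = 0.1119, O = 0.8881)),
    pmma = material("pmma", 1.19,
      c(H = 0.0805, C = 0.5998, O = 0.3197)),
    brass = material("brass", 8.52,
      c(Cu = 0.70, Zn = 0.30)),
    polyethylene = material("polyethylene", 0.94,
      c(H = 0.1437, C = 0.8563))
  )
}

# Electrons per gram for a material (1/g).
.pd_electrons_per_gram <- function(mat) {
  el <- .pd_elements
  idx <- match(names(mat$composition), el$symbol)
  6.02214076e23 * sum(mat$composition * el$Z[idx] / el$A[idx])
}

# <Z^p/A> style composition sums used by the photoelectric / pair terms.
.pd_comp_sum <- function(mat, power) {
  el <- .pd_elements
  idx <- match(names(mat$composition), el$symbol)
  sum(mat$composition * el$Z[idx]^power / el$A[idx])
}

# Bragg-additivity mean excitation energy (eV).
.pd_mean_excitation <- function(mat) {
  el <- .pd_elements
  idx <- match(names(mat$composition), el$symbol)
  za <- mat$composition * el$Z[idx] / el$A[idx]
  exp(sum(za * log(el$I_eV[idx])) / sum(za))
}

# Radiation length (cm) from the standard per-element approximation
# X0_i = 716.408 A / (Z (Z + 1) ln(287/sqrt(Z))) g/cm^2, mixed by mass fraction.
.pd_radiation_length <- function(mat) {
  el <- .pd_elements
  idx <- match(names(mat$composition), el$symbol)
  x0i <- 716.408 * el$A[idx] / (el$Z[idx] * (el$Z[idx] + 1) *
    log(287 / sqrt(el$Z[idx])))
  (1 / sum(mat$composition / x0i)) / mat$density
}
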