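# Per-organ energy accumulation with MCNP-style per-history batch statistics.
#
# Scores are collected into a per-history buffer and committed at end of
# history, so correlations within a history (multiple segments of the same
# photon, annihilation photons, proton steps) are handled correctly. The
# Gy conversion constant is fixed at 1.602176634e-10 Gy g / MeV so outputs
# are bit-comparable across platforms.

.pd_mev_per_g_to_gy <- 1.602176634e-10

#' Create a tally accumulator
#'
#' @param organs Character vector of organ/region names.
#' @param masses_g Numeric vector of organ masses in grams (> 0).
#' @return A `pd_tally` environment.
#' @export
tally_accumulator <- function(organs, masses_g) {
  stopifnot(length(organs) == length(masses_g))
  if (any(!is.finite(masses_g)) || any(masses_g <= 0)) {
    stop("every scored organ must have a positive mass")
  }
  acc <- new.env(parent = emptyenv())
  acc$organs <- organs
  acc$masses_g <- masses_g
  acc$sum <- stats::setNames(numeric(length(organs)), organs)
  acc$sumsq <- stats::setNames(numeric(length(organs)), organs)
  acc$hist <- stats::setNames(numeric(length(organs)), organs)
  acc$histories <- 0
  acc$dropped <- 0
  class(acc) <- "pd_tally"
  acc
}

#' Score a photon track segment (track-length kerma estimator)
#'
#' Adds weight x length x E x muen/rho x rho, i.e. the expected energy
#' transferred to charged particles along the segment (MeV), to the organ's
#' current-history buffer.
#'
#' @param acc A `pd_tally`.
#' @param organ Organ containing the segment.
#' @param segment_length Segment length, cm (>= 0).
#' @param E Photon energy, MeV, on the coefficient grid.
#' @param weight Statistical weight.
#' @param material Material name for the muen lookup.
#' @return Invisibly, the accumulator.
#' @export
score_photon_tracklength <- function(acc, organ, segment_length, E,
                                     weight = 1, material = "soft_tissue") {
  if (segment_length < 0) stop("segment length must be non-negative")
  if (!(organ %in% acc$organs)) {
    acc$dropped <- acc$dropped + 1  # diagnostic counter; score dropped
    return(invisible(acc))
  }
  rho <- pd_materials()[[material]]$density
  acc$hist[organ] <- acc$hist[organ] +
    weight * segment_length * E * photon_muen_over_rho(material, E) * rho
  invisible(acc)
}

#' Score a proton energy deposit
#'
#' @param acc A `pd_tally`.
#' @param organ Organ receiving the deposit.
#' @param deltaE Deposited energy, MeV (>= 0).
#' @param weight Statistical weight.
#' @return Invisibly, the accumulator.
#' @export
score_proton_deposit <- function(acc, organ, deltaE, weight = 1) {
  if (deltaE < 0) stop("negative energy deposit: bookkeeping bug upstream")
  if (!(organ %in% acc$organs)) {
    acc$dropped <- acc$dropped + 1
    return(invisible(acc))
  }
  acc$hist[organ] <- acc$hist[organ] + weight * deltaE
  invisible(acc)
}

#' Commit the current history
#'
#' @param acc A `pd_tally`.
#' @return Invisibly, the accumulator.
#' @export
tally_end_history <- function(acc) {
  acc$sum <- acc$sum + acc$hist
  acc$sumsq <- acc$sumsq + acc$hist^2
  acc$hist[] <- 0
  acc$histories <- acc$histories + 1
  invisible(acc)
}

#' Merge two accumulators over disjoint history ranges
#'
#' @param a,b `pd_tally` accumulators over the same organs and masses.
#' @return A new `pd_tally` equal to one accumulator over the union.
#' @export
tally_merge <- function(a, b) {
  stopifnot(identical(a$organs, b$organs), identical(a$masses_g, b$masses_g))
  out <- tally_accumulator(a$organs, a$masses_g)
  out$sum <- a$sum + b$sum
  out$sumsq <- a$sumsq + b$sumsq
  out$histories <- a$histories + b$histories
  out$dropped <- a$dropped + b$dropped
  out
}

# Build an accumulator directly from engine sums (already per-history batched).
.pd_tally_from_sums <- function(organs, masses_g, sum, sumsq, n) {
  acc <- tally_accumulator(organs, masses_g)
  acc$sum[] <- sum
  acc$sumsq[] <- sumsq
  acc$histories <- n
  acc
}

#' Finalize a tally into per-organ doses
#'
#' Dose = mean per-history energy per organ / organ mass, converted from
#' MeV/g to Gy. Relative error is the standard error of the per-history mean
#' divided by the mean; organs never scored report dose 0 with relative
#' error NA (undefined, MCNP convention).
#'
#' @param acc A `pd_tally`.
#' @param metadata Optional list stored on the result (beam, phantom, seed,
#'   config hash, ...).
#' @return A `pd_dose_result`: data.frame organ, dose_Gy_per_primary,
#'   rel_error, histories (+ metadata attribute).
#' @export
finalize <- function(acc, metadata = list()) {
  n <- acc$histories
  if (n < 1) stop("cannot finalize a tally with zero histories")
  m <- acc$sum / n
  vm <- if (n > 1) pmax(acc$sumsq / n - m^2, 0) / (n - 1) else rep(NA_real_, length(m))
  se <- sqrt(vm)
  dose <- m / acc$masses_g * .pd_mev_per_g_to_gy
  rel <- ifelse(m > 0, se / m, NA_real_)
  out <- data.frame(
    organ = acc$organs,
    dose_Gy_per_primary = unname(dose),
    rel_error = unname(rel),
    histories = n,
    stringsAsFactors = FALSE
  )
  attr(out, "metadata") <- metadata
  class(out) <- c("pd_dose_result", "data.frame")
  out
}

#' @export
print.pd_dose_result <- function(x, ...) {
  md <- attr(x, "metadata")
  hdr <- if (!is.null(md$age_class)) {
    sprintf(" (%s %s at %s, %g histories)", md$modality, md$age_class,
      md$position, x$histories[1])
  } else sprintf(" (%g histories)", x$histories[1])
  cat("Per-organ dose, Gy per primary particle", hdr, "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Dose of one organ from a dose result
#'
#' @param result A `pd_dose_result`.
#' @param organ Organ name.
#' @return list(dose, se): Gy per primary and its absolute standard error.
#' @export
organ_dose <- function(result, organ) {
  i <- match(organ, result$organ)
  if (is.na(i)) stop("organ not present in dose result: ", organ)
  d <- result$dose_Gy_per_primary[i]
  r <- result$rel_error[i]
  list(dose = d, se = if (is.na(r)) 0 else d * r)
}

#' Serialize a dose result
#'
#' Writes both CSV (organ table) and JSON (table + metadata) forms.
#'
#' @param result A `pd_dose_result`.
#' @param path Base path; `.csv` and `.json` are appended.
#' @return Invisibly, the paths written.
#' @export
write_dose_result <- function(result, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  write.csv(as.data.frame(result), csv, row.names = FALSE)
  jsonlite::write_json(
    list(table = as.data.frame(result), metadata = attr(result, "metadata")),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, json))
}

#' Read a serialized dose result
#'
#' @param path Base path used in [write_dose_result()].
#' @return A `pd_dose_result`.
#' @export
read_dose_result <- function(path) {
  obj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- obj$table
  attr(out, "metadata") <- obj$metadata
  class(out) <- c("pd_dose_result", "data.frame")
  out
}
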