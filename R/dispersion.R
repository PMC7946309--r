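# Dispersed-dose conversion coefficients F = Dd/Dt, the F matrix over
# age x modality x position x organ, the CHART case study, and the paired
# photon-vs-proton comparison.

# the six non-targeted organs reported in the F matrix
.pd_reported_organs <- c("skeleton", "skin", "brain", "spine",
  "left_lung", "right_lung")

utils::globalVariables(c("position", "F_se", "age"))

#' Reported organ set of the F matrix
#' @return Character vector of the six reported organs.
#' @export
pd_reported_organs <- function() .pd_reported_organs

#' Dispersed-dose conversion coefficient
#'
#' F = Dd / Dt with first-order error propagation assuming independent
#' numerator and denominator uncertainties:
#' se_F = F sqrt((se_d/Dd)^2 + (se_t/Dt)^2) (se flagged NA when Dd = 0).
#'
#' @param Dd Dispersed (non-targeted organ) dose, Gy per primary.
#' @param Dt Targeted organ dose, Gy per primary (> 0).
#' @param se_d,se_t Absolute standard errors of Dd and Dt.
#' @return list(F, se).
#' @export
conversion_coefficient <- function(Dd, Dt, se_d = 0, se_t = 0) {
  if (!is.finite(Dt) || Dt <= 0) {
    stop("targeted organ dose must be positive (got Dt = ", Dt, ")")
  }
  if (Dd < 0) stop("dispersed dose cannot be negative")
  f <- Dd / Dt
  se <- if (Dd == 0) NA_real_ else f * sqrt((se_d / Dd)^2 + (se_t / Dt)^2)
  list(F = f, se = se)
}

#' Assemble the F matrix from a grid of dose results
#'
#' Input is a list of runs, each `list(age, modality, position, result)`
#' with `result` a `pd_dose_result` containing the targeted organ and the
#' six reported organs. Cells where the reported organ is the targeted organ
#' are fixed at F = 1 exactly (se 0); for each (age, modality) with all five
#' positions present this leaves 28 non-trivial cells.
#'
#' @param runs List of run entries (order irrelevant).
#' @return Long-format data.frame: age, modality, position, organ, F, F_se,
#'   targeted; class `pd_fmatrix`.
#' @export
build_F_matrix <- function(runs) {
  if (!length(runs)) stop("no dose results supplied")
  key <- vapply(runs, function(r) paste(r$age, r$modality, r$position), "")
  if (anyDuplicated(key)) stop("duplicate (age, modality, position) runs")
  full <- expand.grid(
    age = unique(vapply(runs, `[[`, "", "age")),
    modality = unique(vapply(runs, `[[`, "", "modality")),
    position = unique(vapply(runs, `[[`, "", "position")),
    stringsAsFactors = FALSE)
  missing <- setdiff(paste(full$age, full$modality, full$position), key)
  if (length(missing)) {
    stop("missing dose result(s) for: ", paste(missing, collapse = "; "))
  }
  rows <- lapply(runs, function(r) {
    pos <- r$position
    tgt <- .pd_positions$organ[match(pos, .pd_positions$position)]
    if (is.na(tgt)) stop("unknown position: ", pos)
    dt <- organ_dose(r$result, tgt)
    if (dt$dose <= 0) {
      stop("targeted organ dose is zero for ", paste(r$age, r$modality, pos))
    }
    do.call(rbind, lapply(.pd_reported_organs, function(org) {
      if (org == tgt) {
        f <- list(F = 1, se = 0)
      } else {
        dd <- organ_dose(r$result, org)
        f <- conversion_coefficient(dd$dose, dt$dose, dd$se, dt$se)
      }
      data.frame(age = r$age, modality = r$modality, position = pos,
        organ = org, F = f$F, F_se = f$se, targeted = org == tgt,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$age, out$modality, out$position,
    match(out$organ, .pd_reported_organs)), ]
  rownames(out) <- NULL
  class(out) <- c("pd_fmatrix", "data.frame")
  out
}

#' Build an F matrix from explicit coefficient values
#'
#' Constructor for conversion-coefficient tables given directly (for example
#' published coefficients used as inputs to the CHART case study) rather
#' than derived from simulated dose results.
#'
#' @param df data.frame with columns age, modality, position, organ, F and
#'   optionally F_se.
#' @return A `pd_fmatrix`.
#' @export
f_matrix_from_values <- function(df) {
  need <- c("age", "modality", "position", "organ", "F")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  if (any(df$F < 0)) stop("F values must be non-negative")
  if (!all(df$position %in% .pd_positions$position)) {
    stop("positions must be among ", paste(.pd_positions$position, collapse = ", "))
  }
  if (is.null(df$F_se)) df$F_se <- NA_real_
  tgt <- .pd_positions$organ[match(df$position, .pd_positions$position)]
  df$targeted <- df$organ == tgt
  if (any(df$targeted & df$F != 1)) {
    stop("the targeted organ at its own position must have F = 1")
  }
  out <- df[, c("age", "modality", "position", "organ", "F", "F_se", "targeted")]
  class(out) <- c("pd_fmatrix", "data.frame")
  out
}

#' Extract the 28 non-trivial F values for one (age, modality)
#'
#' Ordered by (position, organ) so photon and proton vectors are matched
#' pairwise.
#'
#' @param fm A `pd_fmatrix`.
#' @param age Age class.
#' @param modality `"photon"` or `"proton"`.
#' @return Numeric vector (length 28 for a complete grid), named
#'   "position:organ".
#' @export
f_vector <- function(fm, age, modality) {
  sub <- fm[fm$age == age & fm$modality == modality & !fm$targeted, ]
  sub <- sub[order(sub$position, match(sub$organ, .pd_reported_organs)), ]
  stats::setNames(sub$F, paste(sub$position, sub$organ, sep = ":"))
}

#' CHART case-study doses
#'
#' Scales the F column of the matrix by the prescription dose: dispersed
#' dose per organ = prescription x F(organ | position), per age and
#' modality. The hyper-fractionated schedule is fixed at 36 fractions,
#' 3 per day over 12 days.
#'
#' @param fm A `pd_fmatrix`.
#' @param prescription Prescribed target dose, Gy (> 0); default 54.
#' @param position Irradiation position of the case study; default `"P4"`
#'   (left lung).
#' @return A `pd_chart_report`: list(prescription_Gy, fractions,
#'   fractions_per_day, duration_days, doses) where `doses` has columns age,
#'   modality, organ, F, dose_Gy.
#' @export
chart_doses <- function(fm, prescription = 54, position = "P4") {
  if (!is.finite(prescription) || prescription <= 0) {
    stop("prescription dose must be positive")
  }
  if (!position %in% fm$position) {
    stop("position ", position, " absent from the F matrix")
  }
  sub <- fm[fm$position == position, ]
  doses <- data.frame(age = sub$age, modality = sub$modality,
    organ = sub$organ, F = sub$F, dose_Gy = prescription * sub$F,
    stringsAsFactors = FALSE)
  fractions <- 36L; per_day <- 3L
  out <- list(prescription_Gy = prescription, fractions = fractions,
    fractions_per_day = per_day, duration_days = fractions %/% per_day,
    position = position, doses = doses)
  stopifnot(out$duration_days * per_day == fractions)
  class(out) <- "pd_chart_report"
  out
}

#' @export
print.pd_chart_report <- function(x, ...) {
  cat(sprintf(
    "CHART case study: %.0f Gy to %s in %d fractions (%d/day over %d days)\n",
    x$prescription_Gy, x$position, x$fractions, x$fractions_per_day,
    x$duration_days))
  print(x$doses, digits = 4)
  invisible(x)
}

#' Paired photon-versus-proton test on matched F values
#'
#' One-sided paired Student t-test of mean(photon - proton) > 0 over the
#' matched (position, organ) cells, computed with [stats::t.test()].
#'
#' @param photon_F,proton_F Equal-length (>= 2) numeric vectors matched by
#'   (position, organ).
#' @param alternative `"greater"` (default, photon larger) or `"two.sided"`.
#' @return A `pd_paired_test`: list(n, mean_difference, t, df, p_value,
#'   alternative).
#' @export
paired_t_test <- function(photon_F, proton_F,
                          alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(photon_F) != length(proton_F)) {
    stop("photon and proton F vectors must be matched (equal length)")
  }
  if (length(photon_F) < 2) stop("need at least two matched pairs")
  d <- photon_F - proton_F
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences: degenerate test")
  }
  tt <- stats::t.test(photon_F, proton_F, paired = TRUE,
    alternative = alternative)
  out <- list(
    n = length(d),
    mean_difference = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    alternative = alternative
  )
  class(out) <- "pd_paired_test"
  out
}

#' @export
print.pd_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test (photon vs proton F, %s): n = %d, mean diff = %.4g, t = %.3f, df = %d, p = %.3g\n",
    x$alternative, x$n, x$mean_difference, x$t, x$df, x$p_value))
  invisible(x)
}

#' Export the F matrix
#'
#' @param fm A `pd_fmatrix`.
#' @param path Base path; `.csv` and `.json` are appended.
#' @return Invisibly, the paths written.
#' @export
write_F_matrix <- function(fm, path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  write.csv(as.data.frame(fm), csv, row.names = FALSE)
  jsonlite::write_json(as.data.frame(fm), json, auto_unbox = TRUE,
    digits = NA)
  invisible(c(csv, json))
}

#' Bar-panel figure of F values (one panel per modality)
#'
#' Mirrors the study's per-organ bar layout: F value versus irradiation
#' position, bars grouped by age class. Requires ggplot2.
#'
#' @param fm A `pd_fmatrix`.
#' @param organ Organ to plot.
#' @param log_y Log-scale the F axis (useful for proton panels).
#' @return A ggplot object.
#' @export
plot_F_values <- function(fm, organ, log_y = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_F_values requires the ggplot2 package")
  }
  sub <- fm[fm$organ == organ & !fm$targeted, ]
  sub$age <- factor(sub$age, levels = pd_age_classes())
  gg <- ggplot2::ggplot(sub,
    ggplot2::aes(x = position, y = F, fill = age)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = F - F_se, ymax = F + F_se),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = "irradiation position", y = "F = Dd / Dt",
      title = paste("Dispersed-dose conversion coefficients:", organ))
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}
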