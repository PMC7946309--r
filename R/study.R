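# Orchestration of the full age x modality x position study grid, with
# reproducible seeding, a provenance manifest and resumable runs.

#' Study run configuration
#'
#' @param ages Age classes to simulate.
#' @param modalities `"photon"`, `"proton"` or both.
#' @param positions Irradiation positions P1-P5.
#' @param n_photon,n_proton Transported histories per photon / proton run.
#' @param seed Base integer seed; each grid cell derives its own seed from
#'   it deterministically.
#' @param transport A [transport_config()].
#' @param margin Field/aperture margin, cm.
#' @param outdir Output directory (NULL = nothing written).
#' @return list of class `pd_run_config`.
#' @export
run_config <- function(ages = pd_age_classes(),
                       modalities = c("photon", "proton"),
                       positions = pd_positions()$position,
                       n_photon = 40000, n_proton = 20000, seed = 1L,
                       transport = transport_config(), margin = 0.5,
                       outdir = NULL) {
  stopifnot(all(ages %in% pd_age_classes()),
    all(modalities %in% c("photon", "proton")),
    all(positions %in% .pd_positions$position),
    n_photon >= 1, n_proton >= 1)
  structure(list(
    ages = ages, modalities = modalities, positions = positions,
    n_photon = n_photon, n_proton = n_proton, seed = as.integer(seed),
    transport = transport, margin = margin, outdir = outdir
  ), class = "pd_run_config")
}

#' Write / read a run configuration (YAML)
#'
#' The configuration round-trips losslessly through its file form.
#'
#' @param config A `pd_run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: invisibly, the path. `read_run_config`: the
#'   configuration.
#' @export
write_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$transport <- unclass(obj$transport)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  tr <- do.call(transport_config, obj$transport)
  run_config(ages = obj$ages, modalities = obj$modalities,
    positions = obj$positions, n_photon = obj$n_photon,
    n_proton = obj$n_proton, seed = obj$seed, transport = tr,
    margin = obj$margin, outdir = obj$outdir)
}

# deterministic md5 hash of a configuration (base tools only)
.pd_config_hash <- function(config) {
  obj <- unclass(config)
  obj$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

# per-cell seed derived from the base seed, kept below 2^31
.pd_cell_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483647L)
}

#' Run the full study grid
#'
#' Executes every (age, modality, position) cell, builds the F matrix, the
#' CHART case-study report and the per-age paired photon-vs-proton tests.
#' When `config$outdir` is set, per-run dose results, the F matrix, the
#' CHART table, the test results and a provenance manifest (config hash,
#' seeds) are written there; completed runs found in the manifest with a
#' matching config hash are skipped on re-run.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-run progress lines.
#' @return list(F = `pd_fmatrix`, chart = `pd_chart_report`,
#'   tests = per-age `pd_paired_test` list, runs = dose results,
#'   config_hash).
#' @export
run_study <- function(config = run_config(), quiet = FALSE) {
  hash <- .pd_config_hash(config)
  outdir <- config$outdir
  manifest <- list(config_hash = hash, runs = list())
  manifest_path <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest_path <- file.path(outdir, "manifest.json")
    if (file.exists(manifest_path)) {
      old <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
      if (identical(old$config_hash, hash)) manifest <- old
    }
    write_run_config(config, file.path(outdir, "config.yaml"))
  }

  grid <- expand.grid(age = config$ages, modality = config$modalities,
    position = config$positions, stringsAsFactors = FALSE)
  phantoms <- stats::setNames(
    lapply(unique(grid$age), build_phantom), unique(grid$age))

  runs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tag <- paste(g$age, g$modality, g$position, sep = "_")
    base <- if (!is.null(outdir)) file.path(outdir, paste0("dose_", tag))
    if (!is.null(outdir) && !is.null(manifest$runs[[tag]]) &&
      file.exists(paste0(base, ".json"))) {
      result <- read_dose_result(base)
    } else {
      ph <- phantoms[[g$age]]
      organ <- .pd_positions$organ[match(g$position, .pd_positions$position)]
      beam <- aim_at_target(ph, organ, g$modality, margin = config$margin)
      n <- if (g$modality == "photon") config$n_photon else config$n_proton
      cell_seed <- .pd_cell_seed(config$seed, i)
      result <- run_histories(n, beam, ph, config$transport, seed = cell_seed)
      if (!is.null(outdir)) {
        write_dose_result(result, base)
        # use the serialized form from here on so resumed and fresh runs
        # produce byte-identical downstream artifacts
        result <- read_dose_result(base)
        manifest$runs[[tag]] <- list(seed = cell_seed, histories = n)
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
          digits = NA)
      }
      if (!quiet) {
        tgt <- organ_dose(result, organ)
        message(sprintf("[%d/%d] %s: Dt = %.3g Gy/primary (rel err %.3f)",
          i, nrow(grid), tag, tgt$dose,
          result$rel_error[match(organ, result$organ)]))
      }
    }
    runs[[i]] <- list(age = g$age, modality = g$modality,
      position = g$position, result = result)
  }

  fm <- build_F_matrix(runs)
  chart <- if ("P4" %in% config$positions) chart_doses(fm) else NULL
  tests <- NULL
  if (all(c("photon", "proton") %in% config$modalities)) {
    tests <- lapply(stats::setNames(config$ages, config$ages), function(a) {
      fp <- f_vector(fm, a, "photon")
      fq <- f_vector(fm, a, "proton")
      if (length(fp) >= 2) paired_t_test(fp, fq[names(fp)]) else NULL
    })
  }

  if (!is.null(outdir)) {
    write_F_matrix(fm, file.path(outdir, "f_matrix"))
    if (!is.null(chart)) {
      write.csv(chart$doses, file.path(outdir, "chart_doses.csv"),
        row.names = FALSE)
    }
    if (!is.null(tests)) {
      jsonlite::write_json(lapply(tests, unclass),
        file.path(outdir, "paired_tests.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
    }
  }
  list(F = fm, chart = chart, tests = tests, runs = runs, config_hash = hash)
}

#' Built-in physics validation suite
#'
#' Re-derives core transport behaviour against independent closed forms:
#' exponential attenuation of a broad beam in water, Klein-Nishina sampling
#' against the analytic differential cross section, the CSDA range against
#' direct quadrature of 1/S, per-history energy-ledger closure, agreement of
#' the track-length and collision estimators on a two-region toy phantom,
#' and the bundled-table checksums.
#'
#' @param n_histories Histories for the Monte Carlo checks.
#' @param seed Integer seed.
#' @param tolerance_scale Multiplies every tolerance (diagnostic use).
#' @return data.frame check, value, tolerance, pass; attribute `"ok"` TRUE
#'   when all checks pass.
#' @export
validate_physics <- function(n_histories = 30000, seed = 7L,
                             tolerance_scale = 1) {
  checks <- list()
  add <- function(name, value, tol) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, value = value, tolerance = tol,
      pass = is.finite(value) & value <= tol, stringsAsFactors = FALSE)
  }

  ok <- physics_table_checksums_ok()
  add("bundled_table_checksums", as.numeric(!all(ok)), 0.5)

  # attenuation: uncollided fraction through a water slab vs exp(-mu t)
  t_cm <- 10
  ph <- .pd_water_slab_phantom(thickness = t_cm)
  beam <- .pd_pencil_photon_beam(ph, E = 1.0)
  res <- run_histories(n_histories, beam, ph,
    transport_config(track_cap = 500000L), seed = seed, tracks = TRUE)
  frac <- .pd_uncollided_fraction(res, y_top = 0, y_bottom = -t_cm)
  mu <- photon_mu("water", 1.0, "total")
  expect <- exp(-mu * t_cm)
  se <- sqrt(expect * (1 - expect) / n_histories)
  add("water_slab_attenuation_sigma", abs(frac - expect) / se,
    3 * tolerance_scale)

  # Klein-Nishina sampling vs analytic differential cross section
  p <- .pd_kn_chisq_p(E = 1.0, n = min(n_histories, 50000), seed = seed)
  add("klein_nishina_chisq_inv_p", 1 / p, 1 / (0.01 / tolerance_scale))

  # CSDA range vs dense trapezoid quadrature of 1/S
  r_tab <- csda_range("water", 240)
  r_quad <- .pd_trapz_inv_stopping("water", 1, 240)
  add("csda_range_vs_quadrature_rel", abs(r_tab - r_quad) / r_quad,
    0.001 * tolerance_scale)

  # ledger closure on a small phantom run
  ph5 <- build_phantom("5y")
  bm5 <- aim_at_target(ph5, "liver", "photon")
  r5 <- run_histories(2000, bm5, ph5, seed = seed)
  add("energy_ledger_imbalance", ledger_imbalance(r5), 1e-6)

  # estimator agreement on a two-region toy phantom
  est <- .pd_estimator_agreement(n = n_histories, seed = seed)
  add("estimator_agreement_sigma", est, 3 * tolerance_scale)

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}

# --- internal fixtures shared by validate_physics and the test suite -------

# trapezoid quadrature of 1/S on a dense log grid; the adaptive integrator
# struggles with the piecewise-interpolated stopping power
.pd_trapz_inv_stopping <- function(mat, E0, E1, n = 20000L) {
  e <- exp(seq(log(E0), log(E1), length.out = n))
  y <- 1 / proton_stopping_power(mat, e)
  sum(diff(e) * (y[-1] + y[-n]) / 2)
}

# water slab: 60x60 cm slab from y = 0 down to y = -thickness
.pd_water_slab_phantom <- function(thickness = 10, material = "water",
                                   half_width = 30) {
  phantom_from_regions(list(
    simple_region("slab", material, 10, "box",
      lo = c(-half_width, -thickness, -half_width),
      hi = c(half_width, 0, half_width))
  ), bbox = rbind(c(-half_width - 1, -thickness - 5, -half_width - 1),
    c(half_width + 1, 5, half_width + 1)),
  n_volume = 50000L)
}

# monoenergetic pencil photon beam entering the slab along -y at the origin
.pd_pencil_photon_beam <- function(phantom, E = 1.0, sad = 100) {
  structure(list(
    modality = "photon", aim = "P0", target = "slab",
    aim_point = c(0, 0, 0), source = c(0, sad, 0), sad = sad,
    hx = 1e-9, hz = 1e-9,
    spectrum = list(edges = c(E - 1e-6, E + 1e-6), probs = 1),
    cone_half_angle_deg = NA, head_transmission = 1, margin = 0
  ), class = "pd_beam")
}

# fraction of histories with no collision between y_top and y_bottom
.pd_uncollided_fraction <- function(result, y_top, y_bottom) {
  td <- attr(result, "tracks")
  n <- attr(result, "metadata")$histories
  coll <- td[td$event == "collision" & td$y1 <= y_top & td$y1 >= y_bottom, ]
  1 - length(unique(coll$history)) / n
}

# chi-square goodness-of-fit p-value of sampled KN scattered energies
.pd_kn_chisq_p <- function(E, n = 50000, seed = 1, bins = 25) {
  k <- E / 0.51099895
  eps0 <- 1 / (1 + 2 * k)
  smp <- sample_klein_nishina(E, n, seed)$E_scattered / E
  edges <- seq(eps0, 1, length.out = bins + 1)
  obs <- tabulate(findInterval(smp, edges, rightmost.closed = TRUE), bins)
  probs <- vapply(seq_len(bins), function(i) {
    stats::integrate(klein_nishina_diff, edges[i], edges[i + 1], E = E,
      rel.tol = 1e-9)$value
  }, numeric(1))
  probs <- probs / sum(probs)
  suppressWarnings(stats::chisq.test(obs, p = probs)$p.value)
}

# z-score between track-length and collision estimators on a toy phantom
.pd_estimator_agreement <- function(n = 30000, seed = 1) {
  ph <- .pd_two_region_phantom()
  beam <- .pd_pencil_photon_beam(ph, E = 1.0)
  beam$target <- "core"
  r_trk <- run_histories(n, beam, ph, seed = seed, estimator = "tracklength")
  r_col <- run_histories(n, beam, ph, seed = seed, estimator = "collision")
  a <- organ_dose(r_trk, "core"); b <- organ_dose(r_col, "core")
  abs(a$dose - b$dose) / sqrt(a$se^2 + b$se^2)
}

# two nested regions: soft-tissue shell with a bone core, beam along -y
.pd_two_region_phantom <- function() {
  phantom_from_regions(list(
    simple_region("core", "bone", 20, "box",
      lo = c(-5, -12, -5), hi = c(5, -6, 5)),
    simple_region("shell", "soft_tissue", 10, "box",
      lo = c(-10, -20, -10), hi = c(10, 0, 10))
  ), bbox = rbind(c(-11, -22, -11), c(11, 3, 11)), n_volume = 50000L)
}
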