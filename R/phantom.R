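# Age-parameterized stylized pediatric phantoms.
#
# Bodies are built from quadric primitives (ellipsoids, elliptical cylinders,
# axis-aligned boxes) combined into priority-ordered regions: a point belongs
# to the highest-priority region whose boolean expression contains it.
# Coordinates are right-handed with z the body axis (feet -> head), y the
# posterior -> anterior axis and the origin at the trunk-base midline; beams
# travel along -y (anterior-posterior entry).
#
# Organ dimensions are a versioned default table: a 15-year master anatomy
# scaled per age class, laterally by s_xy and axially by s_z, chosen so total
# heights and body masses follow the standard stylized-phantom series and the
# aim points are anatomically ordered (testes < colon < liver < lungs < brain
# along z). Absolute fidelity to any specific reference phantom equation set
# is not claimed.

#' Supported phantom age classes
#'
#' @return Character vector of the five age classes, youngest first.
#' @export
pd_age_classes <- function() c("newborn", "1y", "5y", "10y", "15y")

.pd_age_table <- data.frame(
  age_class = c("newborn", "1y", "5y", "10y", "15y"),
  height_cm = c(51, 75, 109, 138, 168),
  mass_kg = c(3.6, 9.7, 19.8, 33.2, 56.8),
  stringsAsFactors = FALSE
)

# Master (15-year) anatomy in cm. All entries overridable via build_phantom().
.pd_master_params <- function() {
  list(
    trunk_a = 16, trunk_b = 9, trunk_h = 62,
    head_semi = c(7.5, 9.5, 11),
    legs_a = 12, legs_b = 8, legs_len = 84,
    skin_t = 0.2,
    brain_semi = c(6.2, 7.4, 8.0), skull_scale = 1.12,
    spine_r = 1.8, spine_y = -5, spine_z = c(8, 60),
    left_lung_center = c(6.5, 0.5, 46), left_lung_semi = c(4.5, 5.5, 10.5),
    right_lung_center = c(-6.5, 0.5, 46), right_lung_semi = c(4.8, 5.5, 10.5),
    liver_center = c(-4.5, 2, 28), liver_semi = c(8, 6, 5.5),
    colon_center = c(0, 2.5, 12), colon_semi = c(7, 4.5, 6),
    testes_center = c(0, 5.5, -4), testes_semi = c(2.0, 2.0, 2.5),
    pelvis_center = c(0, -4.5, 5), pelvis_semi = c(7, 3.5, 5),
    rib_outer = c(15, 8), rib_inner = c(13.5, 6.5), rib_z = c(33, 59),
    legbone_r = 2.8, legbone_x = 7, legbone_z = c(-80, -2)
  )
}

# Primitive constructors ------------------------------------------------------

.pd_ellipsoid <- function(center, semi) {
  list(kind = "ellipsoid", center = center, semi = semi)
}
.pd_ecyl <- function(center_xy, semi_xy, zlim) {
  list(kind = "ecyl", center = center_xy, semi = semi_xy, zlim = zlim)
}
.pd_box <- function(lo, hi) list(kind = "box", lo = lo, hi = hi)

.pd_prim_row <- function(p) {
  switch(p$kind,
    ellipsoid = c(1, p$center, p$semi, 0, 0),
    ecyl = c(2, p$center, p$semi, p$zlim, 0, 0),
    box = c(3, p$lo, p$hi, 0, 0),
    stop("unknown primitive kind: ", p$kind)
  )
}

# Non-uniform age scaling: x,y by s_xy and z by s_z.
.pd_scale_prim <- function(p, sxy, sz) {
  switch(p$kind,
    ellipsoid = .pd_ellipsoid(p$center * c(sxy, sxy, sz), p$semi * c(sxy, sxy, sz)),
    ecyl = .pd_ecyl(p$center * sxy, p$semi * sxy, p$zlim * sz),
    box = .pd_box(p$lo * c(sxy, sxy, sz), p$hi * c(sxy, sxy, sz))
  )
}

.pd_prim_volume <- function(p) {
  switch(p$kind,
    ellipsoid = 4 / 3 * pi * prod(p$semi),
    ecyl = pi * prod(p$semi) * diff(p$zlim),
    box = prod(p$hi - p$lo)
  )
}

# Region assembly -------------------------------------------------------------

# A region is a list of terms; each term is list(inside = <prims>,
# outside = <prims>). A point is in the region when some term has the point
# inside all of its `inside` primitives and outside all of its `outside` ones.
.pd_region <- function(name, mat, priority, terms, analytic_volume = NA_real_) {
  list(name = name, material = mat, priority = priority, terms = terms,
    analytic_volume = analytic_volume)
}

.pd_master_regions <- function(p) {
  t1 <- function(inside, outside = list()) list(list(inside = inside, outside = outside))

  trunk <- .pd_ecyl(c(0, 0), c(p$trunk_a, p$trunk_b), c(0, p$trunk_h))
  head_c <- c(0, 0, p$trunk_h + p$head_semi[3])
  head <- .pd_ellipsoid(head_c, p$head_semi)
  legs <- .pd_ecyl(c(0, 0), c(p$legs_a, p$legs_b), c(-p$legs_len, 0))

  ts <- p$skin_t
  trunk_s <- .pd_ecyl(c(0, 0), c(p$trunk_a + ts, p$trunk_b + ts),
    c(-ts, p$trunk_h + ts))
  head_s <- .pd_ellipsoid(head_c, p$head_semi + ts)
  legs_s <- .pd_ecyl(c(0, 0), c(p$legs_a + ts, p$legs_b + ts),
    c(-p$legs_len - ts, 0))

  brain <- .pd_ellipsoid(head_c, p$brain_semi)
  skull <- .pd_ellipsoid(head_c, p$brain_semi * p$skull_scale)
  spine <- .pd_ecyl(c(0, p$spine_y), c(p$spine_r, p$spine_r), p$spine_z)
  llung <- .pd_ellipsoid(p$left_lung_center, p$left_lung_semi)
  rlung <- .pd_ellipsoid(p$right_lung_center, p$right_lung_semi)
  liver <- .pd_ellipsoid(p$liver_center, p$liver_semi)
  colon <- .pd_ellipsoid(p$colon_center, p$colon_semi)
  testes <- .pd_ellipsoid(p$testes_center, p$testes_semi)
  pelvis <- .pd_ellipsoid(p$pelvis_center, p$pelvis_semi)
  rib_o <- .pd_ecyl(c(0, 0), p$rib_outer, p$rib_z)
  rib_i <- .pd_ecyl(c(0, 0), p$rib_inner, p$rib_z)
  lb_l <- .pd_ecyl(c(p$legbone_x, 0), c(p$legbone_r, p$legbone_r), p$legbone_z)
  lb_r <- .pd_ecyl(c(-p$legbone_x, 0), c(p$legbone_r, p$legbone_r), p$legbone_z)

  list(
    .pd_region("testes", "soft_tissue", 100, t1(list(testes)),
      .pd_prim_volume(testes)),
    .pd_region("brain", "soft_tissue", 95, t1(list(brain)),
      .pd_prim_volume(brain)),
    .pd_region("left_lung", "lung", 90, t1(list(llung)),
      .pd_prim_volume(llung)),
    .pd_region("right_lung", "lung", 85, t1(list(rlung)),
      .pd_prim_volume(rlung)),
    .pd_region("spine", "bone", 80, t1(list(spine)),
      .pd_prim_volume(spine)),
    .pd_region("liver", "soft_tissue", 75, t1(list(liver)),
      .pd_prim_volume(liver)),
    .pd_region("colon", "soft_tissue", 70, t1(list(colon)),
      .pd_prim_volume(colon)),
    .pd_region("skeleton", "bone", 60, list(
      list(inside = list(skull), outside = list(brain)),
      list(inside = list(rib_o), outside = list(rib_i)),
      list(inside = list(pelvis), outside = list()),
      list(inside = list(lb_l), outside = list()),
      list(inside = list(lb_r), outside = list())
    )),
    .pd_region("soft_tissue", "soft_tissue", 50, list(
      list(inside = list(trunk), outside = list()),
      list(inside = list(head), outside = list()),
      list(inside = list(legs), outside = list())
    )),
    .pd_region("skin", "skin", 40, list(
      list(inside = list(trunk_s), outside = list()),
      list(inside = list(head_s), outside = list()),
      list(inside = list(legs_s), outside = list())
    )),
    .pd_region("exterior", "air", 0, list())
  )
}

# Flatten regions to the numeric encoding the C++ kernels take.
.pd_encode_geometry <- function(regions, bbox) {
  prims <- list()
  add_prim <- function(p) {
    prims[[length(prims) + 1L]] <<- .pd_prim_row(p)
    length(prims)
  }
  enc_regions <- lapply(regions, function(r) {
    lapply(r$terms, function(term) {
      c(
        vapply(term$inside, add_prim, 0L),
        -vapply(term$outside, add_prim, 0L)
      )
    })
  })
  pm <- if (length(prims)) do.call(rbind, prims) else matrix(0, 0, 7)
  list(
    prims = pm,
    regions = enc_regions,
    bbox_lo = bbox[1, ], bbox_hi = bbox[2, ],
    names = vapply(regions, `[[`, "", "name"),
    materials = vapply(regions, `[[`, "", "material")
  )
}

#' Build an age-parameterized stylized pediatric phantom
#'
#' @param age_class One of `"newborn"`, `"1y"`, `"5y"`, `"10y"`, `"15y"`.
#' @param parameter_overrides Optional named list replacing entries of the
#'   master (15-year scale) anatomy table before age scaling; all dimensions
#'   must stay positive. See the methods vignette for the schema.
#' @param validate If TRUE (default), rejection-sample the geometry and fail
#'   when an analytic organ volume disagrees with its sampled volume, which
#'   signals overlapping organs from bad overrides.
#' @return A `pd_phantom` object with regions, organ masses (g), centroids
#'   and bounding box.
#' @export
build_phantom <- function(age_class, parameter_overrides = NULL, validate = TRUE) {
  if (!is.character(age_class) || length(age_class) != 1L ||
    !(age_class %in% pd_age_classes())) {
    stop("unknown age_class: ", paste(age_class, collapse = ", "),
      " (expected one of ", paste(pd_age_classes(), collapse = ", "), ")")
  }
  params <- .pd_master_params()
  if (!is.null(parameter_overrides)) {
    bad <- setdiff(names(parameter_overrides), names(params))
    if (length(bad)) stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    params <- utils::modifyList(params, parameter_overrides)
    dims <- c(params$trunk_a, params$trunk_b, params$trunk_h, params$head_semi,
      params$legs_a, params$legs_b, params$legs_len, params$skin_t,
      params$brain_semi, params$skull_scale, params$spine_r,
      params$left_lung_semi, params$right_lung_semi, params$liver_semi,
      params$colon_semi, params$testes_semi, params$pelvis_semi,
      params$rib_outer, params$rib_inner, params$legbone_r)
    if (any(!is.finite(dims)) || any(dims <= 0)) {
      stop("parameter overrides must keep all dimensions positive")
    }
  }

  row <- .pd_age_table[.pd_age_table$age_class == age_class, ]
  sz <- row$height_cm / .pd_age_table$height_cm[.pd_age_table$age_class == "15y"]
  m15 <- .pd_age_table$mass_kg[.pd_age_table$age_class == "15y"]
  sxy <- sqrt((row$mass_kg / m15) / sz)

  master <- .pd_master_regions(params)
  regions <- lapply(master, function(r) {
    r$terms <- lapply(r$terms, function(term) {
      list(
        inside = lapply(term$inside, .pd_scale_prim, sxy = sxy, sz = sz),
        outside = lapply(term$outside, .pd_scale_prim, sxy = sxy, sz = sz)
      )
    })
    if (!is.na(r$analytic_volume)) r$analytic_volume <- r$analytic_volume * sxy^2 * sz
    r
  })

  ts <- params$skin_t * sxy
  xext <- (max(params$trunk_a, params$legs_a, params$head_semi[1]) * sxy) + ts + 1
  yext <- (max(params$trunk_b, params$legs_b, params$head_semi[2],
    abs(params$testes_center[2]) + params$testes_semi[2]) * sxy) + ts + 1
  zlo <- -params$legs_len * sz - ts - 1
  zhi <- (params$trunk_h + 2 * params$head_semi[3]) * sz + ts + 1
  bbox <- rbind(c(-xext, -yext, zlo), c(xext, yext, zhi))

  geom <- .pd_encode_geometry(regions, bbox)

  # centroids of the aimable organs (+ spine)
  prm <- params
  cent <- list(
    testes = prm$testes_center, colon = prm$colon_center,
    liver = prm$liver_center, left_lung = prm$left_lung_center,
    right_lung = prm$right_lung_center,
    brain = c(0, 0, prm$trunk_h + prm$head_semi[3]),
    spine = c(0, prm$spine_y, mean(prm$spine_z))
  )
  cent <- lapply(cent, function(v) v * c(sxy, sxy, sz))

  ph <- structure(list(
    age_class = age_class, params = params, sxy = sxy, sz = sz,
    regions = regions, geom = geom, bbox = bbox, centroids = cent,
    height_cm = (zhi - 1) - (zlo + 1)
  ), class = "pd_phantom")

  ph$masses <- .pd_phantom_masses(ph, validate = validate)
  ph
}

# Rejection-sampled region volumes (shared point cloud, fixed internal seed so
# phantom construction is deterministic); analytic organs keep closed forms.
.pd_phantom_masses <- function(ph, n = 800000L, seed = 987654L, validate = TRUE) {
  counts <- cpp_region_fractions(ph$geom, n, seed)
  vbox <- prod(ph$bbox[2, ] - ph$bbox[1, ])
  frac <- counts / n
  v_mc <- frac * vbox
  se_mc <- sqrt(pmax(frac * (1 - frac), 0) / n) * vbox
  mats <- pd_materials()
  out <- do.call(rbind, lapply(seq_along(ph$regions), function(i) {
    r <- ph$regions[[i]]
    analytic <- !is.na(r$analytic_volume)
    vol <- if (analytic) r$analytic_volume else v_mc[i]
    se <- if (analytic) 0 else se_mc[i]
    data.frame(
      organ = r$name, material = r$material,
      volume_cm3 = vol, volume_se_cm3 = se,
      mass_g = vol * mats[[r$material]]$density,
      mass_se_g = se * mats[[r$material]]$density,
      method = if (analytic) "analytic" else "rejection",
      stringsAsFactors = FALSE
    )
  }))
  out <- out[out$organ != "exterior", ]
  rownames(out) <- NULL
  if (validate) {
    for (i in seq_along(ph$regions)) {
      r <- ph$regions[[i]]
      if (is.na(r$analytic_volume)) next
      tol <- 4 * se_mc[i] + 0.015 * r$analytic_volume
      if (abs(v_mc[i] - r$analytic_volume) > tol) {
        stop("phantom validation failure: region '", r$name,
          "' sampled volume ", signif(v_mc[i], 5), " cm^3 disagrees with its ",
          "closed form ", signif(r$analytic_volume, 5),
          " cm^3; overrides likely created overlapping regions")
      }
    }
  }
  out
}

#' @export
print.pd_phantom <- function(x, ...) {
  cat(sprintf("<pd_phantom %s: height %.1f cm, %d regions, body mass %.2f kg>\n",
    x$age_class, x$height_cm, length(x$regions) - 1L,
    sum(x$masses$mass_g[x$masses$organ != "exterior"]) / 1000))
  invisible(x)
}

#' Phantom standing height
#'
#' @param phantom A `pd_phantom`.
#' @return Height in cm, skin included.
#' @export
phantom_height <- function(phantom) phantom$height_cm

#' Locate the region containing a point
#'
#' Returns the unique highest-priority region whose expression contains the
#' point; points outside the body (or outside the bounding box) return
#' `"exterior"`.
#'
#' @param phantom A `pd_phantom`.
#' @param point Numeric 3-vector (cm), finite.
#' @return Region name.
#' @export
locate_region <- function(phantom, point) {
  if (!is.numeric(point) || length(point) != 3L || any(!is.finite(point))) {
    stop("point must be a finite numeric 3-vector (cm)")
  }
  idx <- cpp_locate(phantom$geom, point)
  phantom$geom$names[idx + 1L]
}

#' Distance to the next region boundary along a ray
#'
#' @param phantom A `pd_phantom`.
#' @param point Ray origin, cm.
#' @param direction Unit 3-vector.
#' @return list(distance, region): smallest positive distance to any bounding
#'   surface and the region entered just beyond it (after a 1e-6 cm nudge);
#'   `distance = Inf` with region `"exterior"` when no surface lies ahead.
#' @export
next_crossing <- function(phantom, point, direction) {
  if (!is.numeric(point) || length(point) != 3L || any(!is.finite(point))) {
    stop("point must be a finite numeric 3-vector (cm)")
  }
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("direction must have non-zero norm")
  direction <- direction / nrm
  res <- cpp_next_crossing(phantom$geom, point, direction)
  if (!is.finite(res$distance)) {
    return(list(distance = Inf, region = "exterior"))
  }
  list(distance = res$distance,
    region = phantom$geom$names[res$region + 1L])
}

#' Organ mass
#'
#' Mass = density x volume; closed-form volume for quadric organs, otherwise
#' rejection-sampled with a reported standard error.
#'
#' @param phantom A `pd_phantom`.
#' @param organ Organ/region name.
#' @return Mass in grams, with attributes `se_g` and `method`.
#' @export
organ_mass <- function(phantom, organ) {
  i <- match(organ, phantom$masses$organ)
  if (is.na(i)) stop("unknown organ: ", organ)
  structure(phantom$masses$mass_g[i],
    se_g = phantom$masses$mass_se_g[i],
    method = phantom$masses$method[i])
}

#' Centroid of an aimable organ
#'
#' @param phantom A `pd_phantom`.
#' @param organ One of testes, colon, liver, left_lung, right_lung, brain,
#'   spine.
#' @return Numeric 3-vector, cm.
#' @export
organ_centroid <- function(phantom, organ) {
  v <- phantom$centroids[[organ]]
  if (is.null(v)) stop("no centroid available for organ: ", organ)
  v
}

#' Assemble a phantom from explicit regions
#'
#' Low-level constructor used for toy geometries (slabs, two-region test
#' bodies). Regions are checked against unique names and materials from
#' [pd_materials()]. Region volumes are rejection-sampled unless supplied.
#'
#' @param regions List of regions built with [simple_region()].
#' @param bbox 2x3 matrix, rows = lower/upper corner, cm.
#' @param age_class Label stored on the object (default `"custom"`).
#' @param n_volume Points for the volume sampling pass.
#' @return A `pd_phantom`.
#' @export
phantom_from_regions <- function(regions, bbox, age_class = "custom",
                                 n_volume = 400000L) {
  nms <- vapply(regions, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("region names must be unique")
  mats <- pd_materials()
  for (r in regions) {
    if (is.null(mats[[r$material]])) stop("unknown material: ", r$material)
  }
  if (!"exterior" %in% nms) {
    regions <- c(regions, list(.pd_region("exterior", "air", 0, list())))
  }
  ord <- order(vapply(regions, `[[`, 0, "priority"), decreasing = TRUE)
  regions <- regions[ord]
  geom <- .pd_encode_geometry(regions, bbox)
  ph <- structure(list(
    age_class = age_class, params = NULL, sxy = 1, sz = 1,
    regions = regions, geom = geom, bbox = bbox,
    centroids = lapply(regions, function(r) {
      p <- if (length(r$terms)) r$terms[[1]]$inside[[1]] else NULL
      if (is.null(p)) return(NULL)
      switch(p$kind,
        ellipsoid = p$center,
        ecyl = c(p$center, mean(p$zlim)),
        box = (p$lo + p$hi) / 2)
    }),
    height_cm = bbox[2, 3] - bbox[1, 3]
  ), class = "pd_phantom")
  names(ph$centroids) <- vapply(regions, `[[`, "", "name")
  ph$masses <- .pd_phantom_masses(ph, n = n_volume, validate = FALSE)
  ph
}

#' Define a single-primitive region for toy phantoms
#'
#' @param name Region name.
#' @param material Material name.
#' @param priority Integer; higher wins where regions overlap.
#' @param kind `"ellipsoid"`, `"ecyl"` or `"box"`.
#' @param ... Primitive parameters: `center`/`semi` (ellipsoid),
#'   `center`/`semi`/`zlim` (elliptical cylinder along z), `lo`/`hi` (box).
#' @param analytic_volume Optional closed-form volume (cm^3).
#' @export
simple_region <- function(name, material, priority, kind, ...,
                          analytic_volume = NA_real_) {
  args <- list(...)
  p <- switch(kind,
    ellipsoid = .pd_ellipsoid(args$center, args$semi),
    ecyl = .pd_ecyl(args$center, args$semi, args$zlim),
    box = .pd_box(args$lo, args$hi),
    stop("unknown primitive kind: ", kind))
  if (is.na(analytic_volume)) analytic_volume <- .pd_prim_volume(p)
  .pd_region(name, material, priority,
    list(list(inside = list(p), outside = list())), analytic_volume)
}

#' Export the phantom region table as CSV
#'
#' One row per primitive per term: region, material, priority, term index,
#' role (inside/outside), primitive kind and parameters.
#'
#' @param phantom A `pd_phantom`.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
export_phantom_csv <- function(phantom, path) {
  rows <- list()
  for (r in phantom$regions) {
    for (ti in seq_along(r$terms)) {
      term <- r$terms[[ti]]
      for (role in c("inside", "outside")) {
        for (p in term[[role]]) {
          enc <- .pd_prim_row(p)
          rows[[length(rows) + 1L]] <- data.frame(
            region = r$name, material = r$material, priority = r$priority,
            term = ti, role = role, kind = p$kind,
            p1 = enc[2], p2 = enc[3], p3 = enc[4], p4 = enc[5],
            p5 = enc[6], p6 = enc[7], stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Voxelized preview grid
#'
#' Rasterizes the phantom onto a regular grid of region indices (0 =
#' exterior) for visualization; optionally writes a plain-text array
#' (one z-slice per block) readable by any array tool.
#'
#' @param phantom A `pd_phantom`.
#' @param n Grid dimensions c(nx, ny, nz).
#' @param path Optional output text file.
#' @return Integer array nx x ny x nz of region indices (1-based into
#'   `phantom$geom$names`; 0 outside).
#' @export
voxelize_phantom <- function(phantom, n = c(40, 24, 80), path = NULL) {
  lo <- phantom$bbox[1, ]; hi <- phantom$bbox[2, ]
  xs <- seq(lo[1], hi[1], length.out = n[1])
  ys <- seq(lo[2], hi[2], length.out = n[2])
  zs <- seq(lo[3], hi[3], length.out = n[3])
  arr <- cpp_voxelize(phantom$geom, xs, ys, zs)
  arr <- array(arr, dim = n)
  ext <- which(phantom$geom$names == "exterior")
  arr[arr == ext] <- 0L
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# pedidose voxel preview %d %d %d", n[1], n[2], n[3]), con)
    for (k in seq_len(n[3])) {
      write.table(arr[, , k], con, row.names = FALSE, col.names = FALSE)
      writeLines("", con)
    }
  }
  invisible(arr)
}
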