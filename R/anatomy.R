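# Parametric synthetic anatomy for a T11-L1 segment: three vertebral bodies
# (elliptical cylinders with a 1.5 mm cortical shell and 0.5 mm endplates),
# two discs (annulus matrix around a nucleus), simplified posterior elements
# (pedicle bars, lamina, spinous/transverse processes, articular processes
# articulating through a facet contact layer) and seven ligament groups.
# Coordinate frame:
# +x anterior, +y subject-left, +z superior, origin at the centroid of the
# L1 inferior surface.  The construction is exactly mirror-symmetric about
# y = 0 until unilateral cement is placed.

#' Vertebra parameters
#'
#' @param level one of "T11", "T12", "L1".
#' @param body_width_ap anterior-posterior body width (mm).
#' @param body_width_lat lateral body width (mm).
#' @param body_height body height (mm).
#' @param cortical_thickness cortical shell thickness (mm).
#' @param endplate_thickness endplate thickness (mm).
#' @param posterior_element include posterior elements.
#' @return a `vertebra_params` list.
#' @export
vertebra_params <- function(level, body_width_ap = 30, body_width_lat = 42,
                            body_height = 24, cortical_thickness = 1.5,
                            endplate_thickness = 0.5,
                            posterior_element = TRUE) {
  level <- match.arg(level, c("T11", "T12", "L1"))
  dims <- c(body_width_ap, body_width_lat, body_height,
            cortical_thickness, endplate_thickness)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("invalid vertebra parameters: all dimensions must be positive")
  if (cortical_thickness >= min(body_width_ap, body_width_lat) / 4)
    stop("invalid vertebra parameters: cortical thickness too large for body widths")
  if (endplate_thickness >= body_height / 4)
    stop("invalid vertebra parameters: endplate thickness too large for body height")
  structure(list(level = level, body_width_ap = body_width_ap,
                 body_width_lat = body_width_lat, body_height = body_height,
                 cortical_thickness = cortical_thickness,
                 endplate_thickness = endplate_thickness,
                 posterior_element = isTRUE(posterior_element)),
            class = "vertebra_params")
}

#' Intervertebral disc parameters
#'
#' @param height disc height (mm).
#' @param nucleus_area_fraction fraction of the disc cross-section occupied
#'   by the nucleus pulposus, in (0, 1).
#' @param nucleus_center_offset posterior offset of the nucleus centroid (mm).
#' @return a `disc_params` list.
#' @export
disc_params <- function(height = 10.3, nucleus_area_fraction = 0.4,
                        nucleus_center_offset = 1.5) {
  if (!is.finite(height) || height <= 0)
    stop("invalid disc parameters: height must be positive")
  if (!is.finite(nucleus_area_fraction) ||
      nucleus_area_fraction <= 0 || nucleus_area_fraction >= 1)
    stop("invalid disc parameters: nucleus_area_fraction must be in (0,1)")
  structure(list(height = height,
                 nucleus_area_fraction = nucleus_area_fraction,
                 nucleus_center_offset = nucleus_center_offset),
            class = "disc_params")
}

#' Posterior-element geometry parameters
#'
#' Dimensions of the simplified posterior elements: pedicle bars from the
#' posterolateral body wall to a lamina block, spinous and transverse
#' processes as prisms, and superior/inferior articular processes joined by
#' a bonded cartilage slab.  Values are calibration targets frozen by the
#' range-of-motion validation (see the methods vignette).
#'
#' @param pedicle_angle target attachment angle on the body wall (degrees
#'   from anterior; 180 = posterior midline).
#' @param pedicle_sectors number of body-wall sectors each pedicle spans
#'   (wider base = stiffer attachment).
#' @param pedicle_length radial length of the pedicle bars (mm).
#' @param block_depth anterior-posterior depth of the lamina block (mm).
#' @param process_thickness lateral thickness of the articular processes (mm).
#' @param cartilage_gap thickness of the facet cartilage slab (mm).
#' @param facet_overhang how far the articular processes reach past the
#'   adjacent body surface (mm); sets the cartilage slab height.
#' @param lamina_halfheight half-height of the lamina/pedicle band (mm).
#' @param spinous_length spinous process length behind the lamina (mm).
#' @param spinous_halfwidth spinous process half-width (mm).
#' @param tp_extent transverse process tip distance past the articular
#'   processes (mm).
#' @param interspinous_stop_area effective contact area (mm^2) of the
#'   compression-only interspinous stop that arrests extension (sliding
#'   mode only).
#' @param facet_curvature_ratio transverse-curvature restraint of the
#'   sliding facet layer: stiffness in x as a fraction of the normal (y)
#'   stiffness (0 = planar sagittal facets, 1 = fully interlocking).
#' @param facet_mode `"sliding"` (facet surfaces exchange only normal forces
#'   through a linearised cartilage spring layer; the calibrated default) or
#'   `"bonded"` (cartilage slab meshed and tied to both processes).
#' @return a `posterior_params` list.
#' @export
posterior_params <- function(pedicle_angle = 157.5, pedicle_sectors = 3L,
                             pedicle_length = 6,
                             block_depth = 6, process_thickness = 7,
                             cartilage_gap = 0.21, facet_overhang = 3,
                             lamina_halfheight = 5.25, spinous_length = 8.5,
                             spinous_halfwidth = 1.5, tp_extent = 7,
                             facet_curvature_ratio = 0.40,
                             interspinous_stop_area = 140,
                             facet_mode = c("sliding", "bonded")) {
  facet_mode <- match.arg(facet_mode)
  out <- as.list(environment())
  out$pedicle_sectors <- as.integer(pedicle_sectors)
  structure(out, class = "posterior_params")
}

#' Ligament specifications (the seven spinal ligament groups)
#'
#' Young's modulus (MPa) and total cross-sectional area (mm^2) per ligament
#' group; every group is modelled tension-only.
#'
#' @return data frame with one row per ligament group.
#' @export
default_ligaments <- function() {
  lg <- material_table()$ligaments
  lg$tension_only <- TRUE
  lg
}

#' Assemble the parametric T11-L1 segment geometry
#'
#' Builds the tagged solid-region description of the segment: three
#' vertebrae, two discs, endplates on every disc-facing surface, posterior
#' elements with facet cartilage, and the seven ligament groups.  The three
#' vertebrae must share body widths and cortical thickness (the column is
#' meshed as one prismatic template); heights and endplate thicknesses are
#' free.
#'
#' @param t11,t12,l1 `vertebra_params` for the three levels.
#' @param disc_t11t12,disc_t12l1 `disc_params` for the two discs.
#' @param ligaments ligament table (see [default_ligaments]).
#' @param posterior `posterior_params`.
#' @return a `segment_geometry` object.
#' @export
build_segment <- function(t11 = vertebra_params("T11"),
                          t12 = vertebra_params("T12"),
                          l1 = vertebra_params("L1"),
                          disc_t11t12 = disc_params(),
                          disc_t12l1 = disc_params(),
                          ligaments = default_ligaments(),
                          posterior = posterior_params()) {
  vs <- list(T11 = t11, T12 = t12, L1 = l1)
  for (nm in names(vs)) {
    if (!inherits(vs[[nm]], "vertebra_params"))
      stop("invalid vertebra parameters for ", nm)
    if (vs[[nm]]$level != nm) stop("level label mismatch for ", nm)
  }
  for (d in list(disc_t11t12, disc_t12l1))
    if (!inherits(d, "disc_params")) stop("invalid disc parameters")
  eq <- function(f) length(unique(vapply(vs, `[[`, numeric(1), f))) == 1L
  if (!eq("body_width_ap") || !eq("body_width_lat") || !eq("cortical_thickness"))
    stop("dimension conflict: vertebral bodies T11/T12/L1 must share widths ",
         "and cortical thickness (prismatic column)")

  ## z-layout, bottom to top: L1, disc T12L1, T12, disc T11T12, T11
  z <- 0
  lay <- list()
  add_v <- function(lay, v, z0, cap_bot, cap_top) {
    z1 <- z0 + v$body_height
    lay[[v$level]] <- list(kind = "vertebra", level = v$level, z0 = z0, z1 = z1,
                           zmid = (z0 + z1) / 2, cap_bot = cap_bot,
                           cap_top = cap_top, params = v)
    lay
  }
  lay <- add_v(lay, l1, 0,
               c(l1$cortical_thickness, "cortical"),
               c(l1$endplate_thickness, "endplate"))
  z <- l1$body_height
  lay$discT12L1 <- list(kind = "disc", name = "T12L1", lower = "L1",
                        upper = "T12", z0 = z, z1 = z + disc_t12l1$height,
                        params = disc_t12l1)
  z <- z + disc_t12l1$height
  lay <- add_v(lay, t12, z,
               c(t12$endplate_thickness, "endplate"),
               c(t12$endplate_thickness, "endplate"))
  z <- z + t12$body_height
  lay$discT11T12 <- list(kind = "disc", name = "T11T12", lower = "T12",
                         upper = "T11", z0 = z, z1 = z + disc_t11t12$height,
                         params = disc_t11t12)
  z <- z + disc_t11t12$height
  lay <- add_v(lay, t11, z,
               c(t11$endplate_thickness, "endplate"),
               c(t11$cortical_thickness, "cortical"))
  z_total <- z + t11$body_height

  has_post <- all(vapply(vs, `[[`, logical(1), "posterior_element"))
  if (has_post) {
    hl <- posterior$lamina_halfheight
    fa <- posterior$facet_overhang
    for (v in c("T11", "T12", "L1")) {
      lv <- lay[[v]]
      if (hl >= lv$params$body_height / 2)
        stop("dimension conflict: lamina band of ", v,
             " exceeds its vertebral body")
    }
    for (d in c("discT12L1", "discT11T12")) {
      dd <- lay[[d]]
      lo <- lay[[dd$lower]]; up <- lay[[dd$upper]]
      if (dd$z0 - fa <= lo$zmid + hl || dd$z1 + fa >= up$zmid - hl)
        stop("dimension conflict: facet cartilage band of disc ", dd$name,
             " overlaps the lamina of ", dd$lower, " or ", dd$upper)
    }
  }

  geom <- structure(list(
    vertebrae = vs, discs = list(T11T12 = disc_t11t12, T12L1 = disc_t12l1),
    ligaments = ligaments, posterior = posterior,
    has_posterior = has_post, layout = lay, z_total = z_total,
    semi_ap = l1$body_width_ap / 2, semi_lat = l1$body_width_lat / 2,
    cortical_thickness = l1$cortical_thickness,
    cement = NULL
  ), class = "segment_geometry")
  geom
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat("T11-L1 segment geometry\n")
  cat(sprintf("  body: %.1f (ap) x %.1f (lat) mm, cortical %.2f mm\n",
              2 * x$semi_ap, 2 * x$semi_lat, x$cortical_thickness))
  cat(sprintf("  stack height: %.1f mm; posterior elements: %s\n",
              x$z_total, if (x$has_posterior) "yes" else "no"))
  if (is.null(x$cement)) cat("  cement: none\n")
  else {
    cat(sprintf("  cement group %s: %d cylinder(s)\n",
                x$cement$plan$group_label, nrow(x$cement$cylinders)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cement planning

#' Cement placement plan for an experimental group
#'
#' The four study groups place about 6 mL of cement in each of T11 and L1
#' (never in the sandwich vertebra T12): B-B bilateral/bilateral, L-B left
#' unilateral in T11 + bilateral in L1, L-R crossed unilateral (T11 left,
#' L1 right), L-L ipsilateral unilateral (both left).  Custom per-vertebra
#' placements are allowed with `group_label = "custom"` (used e.g. for
#' mirror-image checks).
#'
#' @param group_label "B-B", "L-B", "L-R", "L-L" or "custom".
#' @param placements named list `list(T11 = ..., L1 = ...)` with values in
#'   `c("bilateral", "left", "right")`; ignored unless `group_label` is
#'   "custom".
#' @param unilateral_dims printed bounding box (ap, lat, height) of the
#'   unilateral cement cylinder (mm).
#' @param bilateral_dims printed bounding box of each bilateral cylinder (mm).
#' @param target_total_volume target cement volume per augmented vertebra (mL).
#' @return a `cement_plan`.
#' @export
cement_plan <- function(group_label,
                        placements = NULL,
                        unilateral_dims = c(10.5, 10.5, 18),
                        bilateral_dims = c(12, 12, 14),
                        target_total_volume = 6.0) {
  groups <- list(
    "B-B" = list(T11 = "bilateral", L1 = "bilateral"),
    "L-B" = list(T11 = "left", L1 = "bilateral"),
    "L-R" = list(T11 = "left", L1 = "right"),
    "L-L" = list(T11 = "left", L1 = "left")
  )
  if (group_label %in% names(groups)) {
    if (!is.null(placements) && !identical(placements, groups[[group_label]]))
      stop("invalid cement plan: placements inconsistent with group label ",
           group_label)
    placements <- groups[[group_label]]
  } else if (identical(group_label, "custom")) {
    if (is.null(placements)) stop("custom cement plan needs placements")
  } else stop("unknown cement group label: ", group_label)
  if (!setequal(names(placements), c("T11", "L1")))
    stop("invalid cement plan: cement may only be placed in T11 and L1 ",
         "(the sandwich vertebra T12 is never augmented)")
  ok <- vapply(placements, function(p) p %in% c("bilateral", "left", "right"),
               logical(1))
  if (!all(ok)) stop("invalid cement plan: unknown placement")
  if (target_total_volume <= 0) stop("invalid cement plan: volume <= 0")
  structure(list(group_label = group_label, placements = placements,
                 unilateral_dims = unilateral_dims,
                 bilateral_dims = bilateral_dims,
                 target_total_volume = target_total_volume),
            class = "cement_plan")
}

## point-to-ellipse minimum distance (dense parametric sampling; the
## sampling error is far below the tolerances it is used against)
ellipse_min_distance <- function(px, py, ax, ay, nsamp = 4096L) {
  th <- seq(0, 2 * pi, length.out = nsamp + 1L)[-1L]
  ex <- ax * cos(th); ey <- ay * sin(th)
  dx <- outer(px, ex, "-"); dy <- outer(py, ey, "-")
  sqrt(apply(dx * dx + dy * dy, 1L, min))
}

#' Place cement inclusions according to a plan
#'
#' Adds vertical elliptical-cylinder cement regions inside the cancellous
#' bone of T11 and L1.  The printed bounding boxes are scaled isotropically
#' so that each augmented vertebra receives exactly
#' `target_total_volume` of cement; if the isotropically scaled cylinder
#' would be taller than the cancellous cavity, its height is capped (an
#' axial margin is kept to the endplates) and the cross-section alone is
#' rescaled to preserve the target volume.  Bilateral cylinders sit at
#' +/-45% of the cancellous lateral semi-axis; unilateral cylinders at 25%
#' (left = +y).
#'
#' @param geometry a cement-free `segment_geometry`.
#' @param plan a `cement_plan`.
#' @param axial_margin clearance kept between cement and the endplate /
#'   cortical caps (mm).
#' @return the geometry with a `cement` component (plan + cylinder table).
#' @export
place_cement <- function(geometry, plan, axial_margin = 1.75) {
  stopifnot(inherits(geometry, "segment_geometry"), inherits(plan, "cement_plan"))
  if (!is.null(geometry$cement))
    stop("geometry already contains cement regions")
  V_target <- plan$target_total_volume * 1000   # mm^3
  t <- geometry$cortical_thickness
  ax_c <- geometry$semi_ap - t                  # cancellous semi-axes (at the
  ay_c <- geometry$semi_lat - t                 # axes; inner offset boundary)
  cyl <- list()
  for (v in names(plan$placements)) {
    lv <- geometry$layout[[v]]
    zc0 <- lv$z0 + as.numeric(lv$cap_bot[1])
    zc1 <- lv$z1 - as.numeric(lv$cap_top[1])
    h_avail <- (zc1 - zc0) - 2 * axial_margin
    if (h_avail <= 0)
      stop("invalid cement plan: no cancellous cavity available in ", v)
    pl <- plan$placements[[v]]
    if (pl == "bilateral") {
      dims <- plan$bilateral_dims
      n_cyl <- 2L
      offs <- c(+0.45, -0.45) * ay_c
      sides <- c("left", "right")
    } else {
      dims <- plan$unilateral_dims
      n_cyl <- 1L
      offs <- if (pl == "left") +0.25 * ay_c else -0.25 * ay_c
      sides <- pl
    }
    v_cyl <- V_target / n_cyl
    v0 <- pi * (dims[1] / 2) * (dims[2] / 2) * dims[3]
    s <- (v_cyl / v0)^(1 / 3)
    sx <- s * dims[1] / 2; sy <- s * dims[2] / 2; h <- s * dims[3]
    if (h > h_avail) {
      h <- h_avail
      s2 <- sqrt(v_cyl / (pi * (dims[1] / 2) * (dims[2] / 2) * h))
      sx <- s2 * dims[1] / 2; sy <- s2 * dims[2] / 2
    }
    zmid <- (zc0 + zc1) / 2
    for (k in seq_len(n_cyl)) {
      cy <- offs[k]
      ## containment: cylinder boundary at least cortical_thickness from the
      ## outer body wall, i.e. inside the cancellous boundary
      phi <- seq(0, 2 * pi, length.out = 257L)[-257L]
      bx <- 0 + sx * cos(phi); by <- cy + sy * sin(phi)
      inside <- (bx / ax_c)^2 + (by / ay_c)^2 < 1
      dmin <- min(ellipse_min_distance(bx, by, geometry$semi_ap,
                                       geometry$semi_lat))
      if (!all(inside) || dmin < t - 1e-9)
        stop("invalid cement plan: cement cylinder in ", v,
             " would intersect the cortical shell")
      cyl[[length(cyl) + 1L]] <- data.frame(
        vertebra = v, side = sides[k], cx = 0, cy = cy,
        semi_ap = sx, semi_lat = sy,
        z0 = zmid - h / 2, z1 = zmid + h / 2,
        volume = pi * sx * sy * h, stringsAsFactors = FALSE)
    }
  }
  cylinders <- do.call(rbind, cyl)
  ## bilateral pairs must not interpenetrate
  for (v in unique(cylinders$vertebra)) {
    cc <- cylinders[cylinders$vertebra == v, ]
    if (nrow(cc) == 2L && abs(cc$cy[1] - cc$cy[2]) <= cc$semi_lat[1] + cc$semi_lat[2])
      stop("invalid cement plan: bilateral cylinders in ", v, " overlap")
  }
  geometry$cement <- list(plan = plan, cylinders = cylinders)
  geometry
}

#' Per-vertebra cement volume report
#'
#' @param geometry a `segment_geometry` with cement.
#' @return named numeric vector of cement volume per augmented vertebra (mL).
#' @export
cement_volumes <- function(geometry) {
  if (is.null(geometry$cement)) return(numeric(0))
  cc <- geometry$cement$cylinders
  out <- tapply(cc$volume, cc$vertebra, sum) / 1000
  res <- as.numeric(out); names(res) <- names(out)
  res
}

#' Mirror a segment geometry about the mid-sagittal plane (y = 0)
#'
#' The cement-free construction is exactly mirror-symmetric, so only cement
#' placements change: lateral centroids flip sign and left/right labels swap.
#'
#' @param geometry a `segment_geometry`.
#' @return the mirrored geometry.
#' @export
mirror_geometry <- function(geometry) {
  if (!is.null(geometry$cement)) {
    cc <- geometry$cement$cylinders
    cc$cy <- -cc$cy
    cc$side <- c(left = "right", right = "left")[cc$side]
    geometry$cement$cylinders <- cc
    pl <- geometry$cement$plan
    pl$placements <- lapply(pl$placements, function(p)
      switch(p, left = "right", right = "left", bilateral = "bilateral"))
    pl$group_label <- "custom"
    geometry$cement$plan <- pl
  }
  geometry
}

#' Analytic region volumes of the geometry (mm^3)
#'
#' Cross-section areas are exact for the elliptical regions (the cortical
#' band uses the inward-offset boundary, area `A - P t + pi t^2`); cement
#' cylinders are exact.  Posterior-element volumes are reported from their
#' prismatic 2D patches at mesh time, not here.
#'
#' @param geometry a `segment_geometry`.
#' @return named list of volumes.
#' @export
geometry_volumes <- function(geometry) {
  ax <- geometry$semi_ap; ay <- geometry$semi_lat
  t <- geometry$cortical_thickness
  A_out <- pi * ax * ay
  th <- seq(0, 2 * pi, length.out = 20001L)
  P <- sum(sqrt((ax * diff(cos(th)))^2 + (ay * diff(sin(th)))^2))
  A_in <- A_out - P * t + pi * t^2        # inward offset area
  out <- list()
  for (v in c("T11", "T12", "L1")) {
    lv <- geometry$layout[[v]]
    hcore <- lv$z1 - lv$z0
    cb <- as.numeric(lv$cap_bot[1]); ct <- as.numeric(lv$cap_top[1])
    out[[paste0("cancellous_", v)]] <- A_in * (hcore - cb - ct)
    ## the cortical ring runs the full body height (the endplate is bounded
    ## laterally by the ring apophysis); cortical caps fill the inner area
    out[[paste0("cortical_", v)]] <- (A_out - A_in) * hcore +
      A_in * ((lv$cap_bot[2] == "cortical") * cb +
              (lv$cap_top[2] == "cortical") * ct)
    out[[paste0("endplate_", v)]] <- A_in *
      ((lv$cap_bot[2] == "endplate") * cb + (lv$cap_top[2] == "endplate") * ct)
  }
  for (d in c("T12L1", "T11T12")) {
    dd <- geometry$layout[[paste0("disc", d)]]
    h <- dd$z1 - dd$z0
    fr <- dd$params$nucleus_area_fraction
    out[[paste0("nucleus_", d)]] <- A_out * fr * h
    out[[paste0("annulus_", d)]] <- A_out * (1 - fr) * h
  }
  if (!is.null(geometry$cement)) {
    cv <- cement_volumes(geometry) * 1000
    for (v in names(cv)) out[[paste0("cement_", v)]] <- cv[[v]]
  }
  out
}
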