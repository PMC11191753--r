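# Template-based structured meshing of the parametric segment: one global 2D
# cross-section (elliptical body rings + posterior block) swept along one
# global z-grid.  Region interfaces share nodes ("fully bound"); ligaments
# become vertical truss elements between existing mesh nodes.

#' Mesh density settings
#'
#' @param target_edge_solid target element edge for bone, discs and cement
#'   (mm).  The published model used 2 mm; the desk-scale default is 5 mm
#'   (see the convergence study in [refine_study]).
#' @param target_edge_cartilage target in-plane edge for facet cartilage
#'   (mm; published 0.5, desk default 1.5).
#' @param element_order 1 (TET4) or 2 (TET10, default, as in the published
#'   model).
#' @return a `mesh_settings` list.
#' @export
mesh_settings <- function(target_edge_solid = 5, target_edge_cartilage = 1.5,
                          element_order = 2L) {
  if (target_edge_solid <= 0 || target_edge_cartilage <= 0)
    stop("mesh edge targets must be positive")
  if (!element_order %in% c(1L, 2L)) stop("element_order must be 1 or 2")
  structure(list(target_edge_solid = target_edge_solid,
                 target_edge_cartilage = target_edge_cartilage,
                 element_order = as.integer(element_order)),
            class = "mesh_settings")
}

ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))   # Ramanujan
}

## Build the shared 2D cross-section.  Returns nodes2d, tris2d, tri_patch,
## and bookkeeping (ring ids, posterior feature nodes, ellipse node ids).
segment_cross_section <- function(geom, settings) {
  ax <- geom$semi_ap; ay <- geom$semi_lat; t <- geom$cortical_thickness
  d1 <- geom$discs$T11T12; d2 <- geom$discs$T12L1
  if (abs(d1$nucleus_area_fraction - d2$nucleus_area_fraction) > 1e-12 ||
      abs(d1$nucleus_center_offset - d2$nucleus_center_offset) > 1e-12)
    stop("dimension conflict: the two discs must share nucleus geometry ",
         "(prismatic template)")
  rho_n <- sqrt(d1$nucleus_area_fraction)
  off <- d1$nucleus_center_offset

  n <- 2L * max(6L, round(ellipse_perimeter(ax, ay) /
                            (2 * settings$target_edge_solid)))
  m <- n %/% 2L
  th_up <- pi * (0:m) / m
  cu <- cos(th_up); su <- sin(th_up)
  su[1] <- 0; su[m + 1] <- 0; cu[m + 1] <- -1
  ## full ring index i = 0..n-1 ; i <= m upper half, others mirrored
  full_xy <- function(pxu, pyu) {
    i <- 0:(n - 1L)
    up <- i <= m
    x <- numeric(n); y <- numeric(n)
    x[up] <- pxu[i[up] + 1L];  y[up] <- pyu[i[up] + 1L]
    x[!up] <- pxu[n - i[!up] + 1L]; y[!up] <- -pyu[n - i[!up] + 1L]
    cbind(x, y)
  }
  ## outer ellipse and its inward normal offset (cortical inner boundary)
  r1u <- cbind(ax * cu, ay * su)
  nrm <- cbind(cu / ax, su / ay)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  r2u <- r1u - t * nrm
  r4u <- cbind(rho_n * ax * cu - off, rho_n * ay * su)
  r3u <- (r2u + r4u) / 2
  r5u <- cbind(0.5 * rho_n * ax * cu - off, 0.5 * rho_n * ay * su)
  rings <- lapply(list(r1u, r2u, r3u, r4u, r5u), function(r)
    full_xy(r[, 1], r[, 2]))

  nodes <- do.call(rbind, rings)
  center_id <- nrow(nodes) + 1L
  nodes <- rbind(nodes, c(-off, 0))
  rid <- function(r, i) (r - 1L) * n + (i %% n) + 1L   # i is 0-based

  quads <- list(); qpatch <- character(0)
  tris <- list(); tpatch <- character(0)
  band_names <- c("cx", "c3", "c2", "c1")               # ring1-2, 2-3, 3-4, 4-5
  for (b in 1:4) {
    i <- 0:(n - 1L)
    quads[[length(quads) + 1L]] <- cbind(rid(b, i), rid(b, i + 1L),
                                         rid(b + 1L, i + 1L), rid(b + 1L, i))
    qpatch <- c(qpatch, rep(band_names[b], n))
  }
  i <- 0:(n - 1L)
  tris[[1]] <- cbind(rep(center_id, n), rid(5L, i), rid(5L, i + 1L))
  tpatch <- c(tpatch, rep("c0", n))

  feat <- list(n_sectors = n, center_id = center_id,
               ring_ids = lapply(1:5, function(r) rid(r, 0:(n - 1L))),
               theta = 2 * pi * (0:(n - 1L)) / n)

  post <- NULL
  if (geom$has_posterior) {
    pp <- geom$posterior
    th_full <- feat$theta
    ## pedicle attachment: consecutive upper-half ring-1 nodes around the
    ## target angle, strictly inside (90, 180) degrees
    tgt <- pp$pedicle_angle * pi / 180
    nsp <- pp$pedicle_sectors
    cand <- which(th_up > pi / 2 + 1e-9 & th_up < pi - 1e-9)
    if (length(cand) < nsp + 1L)
      stop("unmeshable region: pedicle (too few sectors)")
    starts <- seq_len(length(cand) - nsp)
    mids <- (th_up[cand[starts]] + th_up[cand[starts + nsp]]) / 2
    k <- starts[which.min(abs(mids - tgt))]
    iA <- cand[k + 0:nsp] - 1L                 # 0-based ring indices, theta up
    yA <- ay * su[iA + 1L]                     # decreasing, all > 0
    yP1 <- yA[1L]; yP2 <- yA[nsp + 1L]
    wsp <- pp$spinous_halfwidth
    yF1 <- yP1 + pp$process_thickness
    yF2 <- yF1 + pp$cartilage_gap
    yF3 <- yF2 + pp$process_thickness
    tp_tip <- yF3 + pp$tp_extent
    tp_y <- seq(yF3, tp_tip, length.out = 4L)[-1L]
    lad_up <- c(0, wsp, rev(yA), yF1, yF2, yF3, tp_y)
    if (any(diff(lad_up) <= 1e-9))
      stop("dimension conflict: posterior-element widths collide ",
           "(spinous/pedicle/facet ladder not increasing)")
    lad <- c(-rev(lad_up[-1L]), lad_up)               # sorted, exact mirror
    xA <- -(ax + pp$pedicle_length)
    xB <- xA - pp$block_depth
    nxc <- max(1L, ceiling(pp$block_depth / settings$target_edge_cartilage))
    xcols <- seq(xA, xB, length.out = nxc + 1L)
    nlad <- length(lad)
    b0 <- nrow(nodes)
    nodes <- rbind(nodes, cbind(rep(xcols, each = nlad), rep(lad, nxc + 1L)))
    bid <- function(k, j) b0 + (k - 1L) * nlad + j    # col k, ladder row j
    jof <- function(y) match(TRUE, abs(lad - y) < 1e-9)

    ## lamina / facet / transverse-process block
    for (k in seq_len(nxc)) {
      j <- seq_len(nlad - 1L)
      quads[[length(quads) + 1L]] <-
        cbind(bid(k, j), bid(k + 1L, j), bid(k + 1L, j + 1L), bid(k, j + 1L))
      ym <- (lad[j] + lad[j + 1L]) / 2
      cls <- ifelse(abs(ym) < yP1, "lam",
              ifelse(abs(ym) < yF1, "s1",
               ifelse(abs(ym) < yF2, "s2",
                ifelse(abs(ym) < yF3, "s3", "tp"))))
      side <- ifelse(ym > 0, "L", "R")
      cls <- ifelse(cls == "lam", "lam", paste(cls, side, sep = "_"))
      qpatch <- c(qpatch, cls)
    }
    ## pedicles: body-wall chords -> column xA
    for (sgn in c(1L, -1L)) {
      for (s in seq_len(nsp)) {
        ia <- iA[s]; ib <- iA[s + 1L]
        if (sgn == 1L) { e1 <- rid(1L, ia); e2 <- rid(1L, ib) }
        else           { e1 <- rid(1L, n - ia); e2 <- rid(1L, n - ib) }
        q <- cbind(e1, e2, bid(1L, jof(sgn * yA[s + 1L])),
                   bid(1L, jof(sgn * yA[s])))
        quads[[length(quads) + 1L]] <- q
        qpatch <- c(qpatch, if (sgn == 1L) "ped_L" else "ped_R")
      }
    }
    ## spinous process columns behind the block
    nsx <- 3L
    xs <- seq(xB, xB - pp$spinous_length, length.out = nsx + 1L)[-1L]
    s0 <- nrow(nodes)
    spy <- c(-wsp, 0, wsp)
    nodes <- rbind(nodes, cbind(rep(xs, each = 3L), rep(spy, nsx)))
    sid <- function(k, j) s0 + (k - 1L) * 3L + j      # col k (1..nsx), row j
    prevcol <- c(bid(nxc + 1L, jof(-wsp)), bid(nxc + 1L, jof(0)),
                 bid(nxc + 1L, jof(wsp)))
    for (k in seq_len(nsx)) {
      cur <- c(sid(k, 1L), sid(k, 2L), sid(k, 3L))
      quads[[length(quads) + 1L]] <- cbind(prevcol[1:2], cur[1:2], cur[2:3],
                                           prevcol[2:3])
      qpatch <- c(qpatch, rep("spin", 2L))
      prevcol <- cur
    }
    cmid <- (nxc %/% 2L) + 1L
    post <- list(
      yP1 = yP1, yP2 = yP2, yF1 = yF1, yF2 = yF2, yF3 = yF3,
      iA = iA, nxc = nxc, xcols = xcols,
      facet_col_ids = lapply(c(-1, 1), function(sgn)
        list(f1 = vapply(seq_len(nxc + 1L), function(k)
               bid(k, jof(sgn * yF1)), 1L),
             f2 = vapply(seq_len(nxc + 1L), function(k)
               bid(k, jof(sgn * yF2)), 1L),
             f3 = vapply(seq_len(nxc + 1L), function(k)
               bid(k, jof(sgn * yF3)), 1L))),
      lf_nodes = c(bid(cmid, jof(-yP2)), bid(cmid, jof(-wsp)),
                   bid(cmid, jof(wsp)), bid(cmid, jof(yP2))),
      spin_ids = as.vector(outer(1:3, seq_len(nsx), function(j, k) s0 + (k - 1L) * 3L + j)),
      isl_nodes = c(sid(1L, 2L), sid(2L, 2L)),
      ssl_nodes = c(sid(nsx, 1L), sid(nsx, 2L), sid(nsx, 3L)),
      itl_nodes = c(bid(cmid, jof(-tp_tip)), bid(cmid, jof(tp_tip))),
      cl_f1 = c(bid(1L, jof(-yF1)), bid(1L, jof(yF1)),
                bid(nxc + 1L, jof(-yF1)), bid(nxc + 1L, jof(yF1))),
      cl_f2 = c(bid(1L, jof(-yF2)), bid(1L, jof(yF2)),
                bid(nxc + 1L, jof(-yF2)), bid(nxc + 1L, jof(yF2)))
    )
  }

  rank <- node2d_rank(nodes)
  qall <- do.call(rbind, quads)
  tq <- split_quads(qall, rank)
  tris2d <- rbind(do.call(rbind, tris), tq)
  tri_patch <- c(tpatch, rep(qpatch, 2L))
  n_ell <- 5L * n + 1L
  list(nodes2d = nodes, tris2d = tris2d, tri_patch = tri_patch,
       feat = feat, post = post, ellipse_ids = seq_len(n_ell))
}

## region activity spans: data.frame(patch, z0, z1, tag)
segment_spans <- function(geom) {
  lay <- geom$layout
  pp <- geom$posterior
  sp <- list()
  add <- function(patch, z0, z1, tag)
    sp[[length(sp) + 1L]] <<- data.frame(patch = patch, z0 = z0, z1 = z1,
                                         tag = tag, stringsAsFactors = FALSE)
  core_bands <- c("c0", "c1", "c2", "c3")
  for (v in c("T11", "T12", "L1")) {
    lv <- lay[[v]]
    cb <- as.numeric(lv$cap_bot[1]); ct <- as.numeric(lv$cap_top[1])
    for (b in core_bands) {
      add(b, lv$z0, lv$z0 + cb, paste0(lv$cap_bot[2], "_", v))
      add(b, lv$z0 + cb, lv$z1 - ct, paste0("cancellous_", v))
      add(b, lv$z1 - ct, lv$z1, paste0(lv$cap_top[2], "_", v))
    }
    add("cx", lv$z0, lv$z1, paste0("cortical_", v))
  }
  for (dn in c("discT12L1", "discT11T12")) {
    dd <- lay[[dn]]
    for (b in c("c0", "c1")) add(b, dd$z0, dd$z1, paste0("nucleus_", dd$name))
    for (b in c("c2", "c3", "cx")) add(b, dd$z0, dd$z1,
                                       paste0("annulus_", dd$name))
  }
  if (geom$has_posterior) {
    hl <- pp$lamina_halfheight; fa <- pp$facet_overhang
    joints <- list(T11 = "discT11T12", T12 = "discT12L1", L1 = NULL)   # above
    below <- list(T11 = "discT11T12", T12 = "discT12L1")               # keyed by upper
    for (v in c("T11", "T12", "L1")) {
      lv <- lay[[v]]
      band <- c(lv$zmid - hl, lv$zmid + hl)
      tag <- paste0("posterior_", v)
      for (p in c("ped_L", "ped_R", "lam", "spin", "tp_L", "tp_R"))
        add(p, band[1], band[2], tag)
      ## articular-process strips: the superior process (s1) reaches up past
      ## the disc above, the inferior process (s3) down past the disc below,
      ## and between the joint bands all three strips are filled as a
      ## continuous pars-interarticularis block (clearance `gap` keeps the
      ## processes of adjacent vertebrae from sharing nodes).
      gap <- 2
      up_disc <- switch(v, L1 = "discT12L1", T12 = "discT11T12", T11 = NULL)
      dn_disc <- switch(v, T11 = "discT11T12", T12 = "discT12L1", L1 = NULL)
      root_lo <- if (is.null(dn_disc)) band[1] else lay[[dn_disc]]$z1 + fa + gap
      root_hi <- if (is.null(up_disc)) band[2] else lay[[up_disc]]$z0 - fa - gap
      s1_top <- if (is.null(up_disc)) band[2] else lay[[up_disc]]$z1 + fa
      s3_bot <- if (is.null(dn_disc)) band[1] else lay[[dn_disc]]$z0 - fa
      for (p in c("s1_L", "s1_R")) add(p, root_lo, s1_top, tag)
      for (p in c("s3_L", "s3_R")) add(p, s3_bot, root_hi, tag)
      for (p in c("s2_L", "s2_R")) add(p, root_lo, root_hi, tag)
    }
    if (pp$facet_mode == "bonded") {
      for (dn in c("discT12L1", "discT11T12")) {
        dd <- lay[[dn]]
        for (p in c("s2_L", "s2_R"))
          add(p, dd$z0 - fa, dd$z1 + fa, paste0("cartilage_", dd$name))
      }
    }
  }
  do.call(rbind, sp)
}

## ligament truss schedule: data.frame(i2, zlo, zhi, ligament, level)
segment_truss_schedule <- function(geom, cs) {
  lay <- geom$layout
  feat <- cs$feat; post <- cs$post
  th <- feat$theta
  r1 <- feat$ring_ids[[1]]
  all_ids <- r1[cos(th) >= cos(35 * pi / 180) - 1e-12]
  pll_ids <- r1[cos(th) <= -cos(20 * pi / 180) + 1e-12]
  out <- list()
  add <- function(i2, zlo, zhi, lig, level)
    out[[length(out) + 1L]] <<- data.frame(i2 = i2, zlo = zlo, zhi = zhi,
                                           ligament = lig, level = level,
                                           stringsAsFactors = FALSE)
  pp <- geom$posterior
  for (dn in c("discT12L1", "discT11T12")) {
    dd <- lay[[dn]]
    lo <- lay[[dd$lower]]; up <- lay[[dd$upper]]
    add(all_ids, dd$z0, dd$z1, "ALL", dd$name)
    add(pll_ids, dd$z0, dd$z1, "PLL", dd$name)
    if (geom$has_posterior) {
      hl <- pp$lamina_halfheight; fa <- pp$facet_overhang
      zl <- lo$zmid + hl; zu <- up$zmid - hl
      add(post$lf_nodes, zl, zu, "LF", dd$name)
      add(post$isl_nodes, zl, zu, "ISL", dd$name)
      add(post$ssl_nodes, zl, zu, "SSL", dd$name)
      add(post$itl_nodes, zl, zu, "ITL", dd$name)
      add(post$cl_f1, dd$z0 - fa, zu, "CL", dd$name)
      add(post$cl_f2, zl, dd$z0 - fa, "CL", dd$name)
    }
  }
  do.call(rbind, out)
}

#' Generate the tetrahedral mesh of a segment geometry
#'
#' Structured template meshing: deterministic, conforming (all region
#' interfaces share nodes) and exactly mirror-symmetric about y = 0 for a
#' symmetric geometry.  Cement regions are applied by re-tagging cancellous
#' elements whose centroid falls inside a cement cylinder.
#'
#' @param geom a `segment_geometry`.
#' @param settings a `mesh_settings`.
#' @return an `fe_mesh` with region tags, named surface groups
#'   (`T11_superior`, `L1_inferior`, per-level superior surfaces,
#'   `facet_surfaces`) and the ligament truss table (`$trusses`).
#' @export
generate_mesh <- function(geom, settings = mesh_settings()) {
  stopifnot(inherits(geom, "segment_geometry"))
  cs <- segment_cross_section(geom, settings)
  spans <- segment_spans(geom)
  bad <- spans$z1 - spans$z0 <= 1e-9
  if (any(bad))
    stop("unmeshable region: ", paste(unique(spans$tag[bad]), collapse = ", "))

  brk <- sort(unique(round(c(spans$z0, spans$z1), 9)))
  zgrid <- numeric(0)
  for (k in seq_len(length(brk) - 1L)) {
    len <- brk[k + 1L] - brk[k]
    nsub <- max(1L, ceiling(len / settings$target_edge_solid - 1e-9))
    zgrid <- c(zgrid, seq(brk[k], brk[k + 1L], length.out = nsub + 1L)[-(nsub + 1L)])
  }
  zgrid <- c(zgrid, brk[length(brk)])

  tag_names <- unique(spans$tag)
  if (!is.null(geom$cement))
    tag_names <- c(tag_names,
                   paste0("cement_", unique(geom$cement$cylinders$vertebra)))
  nl <- length(zgrid) - 1L
  zmid <- (zgrid[-1L] + zgrid[-length(zgrid)]) / 2
  ntri <- nrow(cs$tris2d)
  layer_tag <- matrix(0L, ntri, nl)
  for (s in seq_len(nrow(spans))) {
    rows <- which(cs$tri_patch == spans$patch[s])
    cols <- which(zmid > spans$z0[s] & zmid < spans$z1[s])
    if (any(layer_tag[rows, cols] != 0L))
      stop("overlapping regions in span table: ", spans$tag[s])
    layer_tag[rows, cols] <- match(spans$tag[s], tag_names)
  }

  mesh <- extrude_mesh(cs$nodes2d, cs$tris2d, zgrid, layer_tag, tag_names)
  mesh$geom <- geom
  mesh$settings <- settings
  mesh$cross_section <- cs[c("feat", "post", "ellipse_ids")]

  ## surface groups (on the linear mesh node grid)
  izof <- function(z) {
    iz <- which(abs(zgrid - z) < 1e-8)
    if (length(iz) != 1L) stop("internal: z level not on grid")
    iz
  }
  grp_nodes <- function(iz, ids2d = NULL) {
    g <- mesh$node_grid[, iz]
    if (!is.null(ids2d)) g <- g[ids2d]
    g[g > 0L]
  }
  top_facets <- function(iz, top = TRUE) {
    lt <- if (top) layer_tag[, iz - 1L] else layer_tag[, iz]
    act <- which(lt > 0L)
    f <- matrix(mesh$node_grid[cbind(as.vector(cs$tris2d[act, ]),
                                     iz)], ncol = 3L)
    f
  }
  izmax <- length(zgrid)
  lay <- geom$layout
  groups <- list(
    T11_superior = list(nodes = grp_nodes(izmax),
                        facets = top_facets(izmax, TRUE)),
    L1_inferior = list(nodes = grp_nodes(1L),
                       facets = top_facets(1L, FALSE)),
    T12_superior = list(nodes = grp_nodes(izof(lay$T12$z1), cs$ellipse_ids)),
    L1_superior = list(nodes = grp_nodes(izof(lay$L1$z1), cs$ellipse_ids)),
    T11_superior_plate = list(nodes = grp_nodes(izmax))
  )
  cart <- grep("^cartilage_", mesh$tag_names)
  if (length(cart))
    groups$facet_surfaces <- list(
      nodes = sort(unique(as.vector(mesh$tets[mesh$tag %in% cart, 1:4]))))
  mesh$groups <- groups

  ## ligament trusses
  sched <- segment_truss_schedule(geom, cs)
  ligtab <- geom$ligaments
  gi <- mesh$node_grid[cbind(sched$i2, vapply(sched$zlo, izof, 1L))]
  gj <- mesh$node_grid[cbind(sched$i2, vapply(sched$zhi, izof, 1L))]
  if (any(gi == 0L) || any(gj == 0L))
    stop("internal: ligament attachment node missing from mesh")
  row <- match(sched$ligament, ligtab$name)
  cnt <- stats::ave(seq_len(nrow(sched)), sched$ligament, sched$level,
                    FUN = length)
  trusses <- data.frame(
    i = gi, j = gj, ligament = sched$ligament, level = sched$level,
    E = ligtab$young_modulus[row], area = ligtab$total_area[row] / cnt,
    sense = 1, stringsAsFactors = FALSE)
  mesh$trusses <- trusses

  ## sliding facets: a bilateral spring layer across the cartilage gap.
  ## The articulating surfaces are curved in the transverse plane, so the
  ## linearised contact layer restrains both transverse directions (joint
  ## normal y and, through the surface curvature, x) while leaving the
  ## cranio-caudal glide (z) free.
  mesh$facet_springs <- NULL
  if (geom$has_posterior && geom$posterior$facet_mode == "sliding") {
    pp <- geom$posterior
    fa <- pp$facet_overhang
    E_cart <- material_table()$solids
    E_cart <- E_cart$young_modulus[E_cart$name == "cartilage"]
    sp <- list()
    for (dn in c("discT12L1", "discT11T12")) {
      dd <- geom$layout[[dn]]
      izs <- which(zgrid >= dd$z0 - fa - 1e-8 & zgrid <= dd$z1 + fa + 1e-8)
      A_slab <- pp$block_depth * (dd$z1 - dd$z0 + 2 * fa)
      for (side in 1:2) {
        cols <- cs$post$facet_col_ids[[side]]
        G1 <- mesh$node_grid[cols$f1, izs, drop = FALSE]
        G2 <- mesh$node_grid[cols$f2, izs, drop = FALSE]
        gi <- as.vector(G1); gj <- as.vector(G2)
        ok <- gi > 0L & gj > 0L
        gi <- gi[ok]; gj <- gj[ok]
        kn <- E_cart * (A_slab / length(gi)) / pp$cartilage_gap
        dnorm <- mesh$nodes[gj, , drop = FALSE] - mesh$nodes[gi, , drop = FALSE]
        dnorm <- dnorm / sqrt(rowSums(dnorm^2))
        sp[[length(sp) + 1L]] <- data.frame(
          i = gi, j = gj, ax = dnorm[, 1], ay = dnorm[, 2], az = dnorm[, 3],
          k = kn, level = dd$name, stringsAsFactors = FALSE)
        ## transverse-curvature restraint: crossed diagonal springs between
        ## neighbouring columns of the two articulating faces (axes along
        ## the connecting lines, so each spring is exactly self-equilibrated
        ## -- the linearisation of an arcuate joint surface)
        cr <- if (is.null(pp$facet_curvature_ratio)) 1 else pp$facet_curvature_ratio
        if (cr > 0 && nrow(G1) > 1L) {
          nxp <- nrow(G1) - 1L
          di <- c(G1[1:nxp, ], G1[2:(nxp + 1L), ])
          dj <- c(G2[2:(nxp + 1L), ], G2[1:nxp, ])
          okd <- di > 0L & dj > 0L
          di <- di[okd]; dj <- dj[okd]
          dd2 <- mesh$nodes[dj, , drop = FALSE] - mesh$nodes[di, , drop = FALSE]
          L2 <- sqrt(rowSums(dd2^2))
          dd2 <- dd2 / L2
          cx2 <- dd2[, 1]^2
          ## total x-stiffness per joint side = cr * total normal stiffness
          kd <- cr * (kn * length(gi)) / sum(2 * cx2) * 2
          sp[[length(sp) + 1L]] <- data.frame(
            i = di, j = dj, ax = dd2[, 1], ay = dd2[, 2], az = dd2[, 3],
            k = kd, level = dd$name, stringsAsFactors = FALSE)
        }
      }
    }
    mesh$facet_springs <- do.call(rbind, sp)
    mesh$groups$facet_surfaces <- list(
      nodes = sort(unique(c(mesh$facet_springs$i, mesh$facet_springs$j))))
    ## compression-only interspinous stop: in extension the posterior
    ## elements approximate until the spinous processes abut through the
    ## interposed soft tissue; modelled as cartilage-stiffness struts in
    ## parallel with the (tension-only) interspinous ligament.  Midline
    ## position means no engagement in bending or rotation.
    st <- list()
    hl <- pp$lamina_halfheight
    A_stop <- pp$interspinous_stop_area
    if (is.null(A_stop)) A_stop <- 140
    for (dn in c("discT12L1", "discT11T12")) {
      dd <- geom$layout[[dn]]
      lo <- geom$layout[[dd$lower]]; up <- geom$layout[[dd$upper]]
      iz_lo <- which(abs(zgrid - (lo$zmid + hl)) < 1e-8)
      iz_hi <- which(abs(zgrid - (up$zmid - hl)) < 1e-8)
      ids2 <- cs$post$spin_ids
      gi <- mesh$node_grid[ids2, iz_lo]
      gj <- mesh$node_grid[ids2, iz_hi]
      ok <- gi > 0L & gj > 0L
      st[[length(st) + 1L]] <- data.frame(
        i = gi[ok], j = gj[ok], ligament = "interspinous_stop",
        level = dd$name, E = E_cart, area = A_stop / sum(ok), sense = -1,
        stringsAsFactors = FALSE)
    }
    mesh$trusses <- rbind(mesh$trusses, do.call(rbind, st))
  }

  if (settings$element_order == 2L) mesh <- to_tet10(mesh)
  if (!is.null(geom$cement)) mesh <- tag_cement(mesh, geom)
  mesh
}

#' Re-tag cancellous elements lying inside cement cylinders
#'
#' @param mesh an `fe_mesh` from [generate_mesh].
#' @param geom the matching `segment_geometry` carrying cement.
#' @return the mesh with `cement_*` region tags applied.
#' @export
tag_cement <- function(mesh, geom) {
  if (is.null(geom$cement)) return(mesh)
  cc <- geom$cement$cylinders
  cx <- (mesh$nodes[mesh$tets[, 1], 1] + mesh$nodes[mesh$tets[, 2], 1] +
         mesh$nodes[mesh$tets[, 3], 1] + mesh$nodes[mesh$tets[, 4], 1]) / 4
  cy <- (mesh$nodes[mesh$tets[, 1], 2] + mesh$nodes[mesh$tets[, 2], 2] +
         mesh$nodes[mesh$tets[, 3], 2] + mesh$nodes[mesh$tets[, 4], 2]) / 4
  cz <- (mesh$nodes[mesh$tets[, 1], 3] + mesh$nodes[mesh$tets[, 2], 3] +
         mesh$nodes[mesh$tets[, 3], 3] + mesh$nodes[mesh$tets[, 4], 3]) / 4
  for (k in seq_len(nrow(cc))) {
    v <- cc$vertebra[k]
    tagname <- paste0("cement_", v)
    if (!tagname %in% mesh$tag_names) mesh$tag_names <- c(mesh$tag_names, tagname)
    src <- match(paste0("cancellous_", v), mesh$tag_names)
    dst <- match(tagname, mesh$tag_names)
    sel <- mesh$tag == src &
      ((cx - cc$cx[k]) / cc$semi_ap[k])^2 +
      ((cy - cc$cy[k]) / cc$semi_lat[k])^2 <= 1 &
      cz >= cc$z0[k] & cz <= cc$z1[k]
    mesh$tag[sel] <- dst
  }
  mesh
}

#' Cortical shell thickness sampled on a transverse plane of the mesh
#'
#' Measures, at the mesh z-level closest to the T12 mid-height, the distance
#' between each outer-boundary node and its cortical-inner counterpart.
#'
#' @param mesh an `fe_mesh` from [generate_mesh].
#' @return numeric vector of thickness samples (mm), one per sector.
#' @export
measure_cortical_thickness <- function(mesh) {
  feat <- mesh$cross_section$feat
  zm <- mesh$geom$layout$T12$zmid
  iz <- which.min(abs(mesh$zgrid - zm))
  outer <- mesh$node_grid[feat$ring_ids[[1]], iz]
  inner <- mesh$node_grid[feat$ring_ids[[2]], iz]
  stopifnot(all(outer > 0L), all(inner > 0L))
  sqrt(rowSums((mesh$nodes[outer, 1:2] - mesh$nodes[inner, 1:2])^2))
}

#' Element ids belonging to one vertebra or disc
#'
#' @param mesh an `fe_mesh`.
#' @param region e.g. "T12" (vertebra, incl. posterior elements and any
#'   cement), "T12_body" (vertebral body only), "disc_T11T12",
#'   "disc_T12L1".
#' @return integer element ids.
#' @export
region_elements <- function(mesh, region) {
  tn <- mesh$tag_names
  if (region %in% c("T11", "T12", "L1")) {
    pick <- tn %in% paste0(c("cortical_", "cancellous_", "endplate_",
                             "posterior_", "cement_"), region)
  } else if (grepl("_body$", region)) {
    v <- sub("_body$", "", region)
    pick <- tn %in% paste0(c("cortical_", "cancellous_", "endplate_",
                             "cement_"), v)
  } else if (grepl("^disc_", region)) {
    d <- sub("^disc_", "", region)
    pick <- tn %in% paste0(c("annulus_", "nucleus_"), d)
  } else pick <- tn == region
  if (!any(pick)) stop("unknown region: ", region)
  which(mesh$tag %in% which(pick))
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("fe_mesh: %d nodes, %d TET%d elements, %d regions\n",
              nrow(x$nodes), nrow(x$tets), if (x$order == 2L) 10 else 4,
              length(unique(x$tag))))
  if (!is.null(x$trusses))
    cat(sprintf("  %d ligament trusses (%s)\n", nrow(x$trusses),
                paste(unique(x$trusses$ligament), collapse = ", ")))
  invisible(x)
}
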