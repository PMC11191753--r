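# Synthetic anatomy: parameter validation, shell thickness, mirror
# symmetry, cement placement contracts.

test_that("parameter invariants are enforced", {
  expect_error(vertebra_params("T12", body_height = -1), "positive")
  expect_error(vertebra_params("T12", cortical_thickness = 10), "cortical")
  expect_error(vertebra_params("T12", endplate_thickness = 7), "endplate")
  expect_error(disc_params(0), "positive")
  expect_error(disc_params(8, nucleus_area_fraction = 1.2), "nucleus")
  expect_error(build_segment(t11 = vertebra_params("T11", body_width_ap = 40)),
               "dimension conflict")
  expect_error(
    build_segment(posterior = posterior_params(lamina_halfheight = 15)),
    "dimension conflict")
})

test_that("generated cortical shell is 1.5 mm thick everywhere on the mid-plane", {
  geom <- build_segment()
  mesh <- cached("geom_mesh_default", generate_mesh(geom))
  th <- measure_cortical_thickness(mesh)
  expect_equal(length(th), mesh$cross_section$feat$n_sectors)
  expect_true(all(abs(th - 1.5) < 1e-9))
})

test_that("endplates are 0.5 mm thick as measured on the mesh", {
  geom <- build_segment()
  mesh <- cached("geom_mesh_default", generate_mesh(geom))
  ## prismatic column: thickness = region volume / cross-section area.
  ## The endplate is bounded laterally by the cortical rim (ring apophysis),
  ## so its footprint is the polygon inside the cortical inner boundary.
  v <- region_volumes(mesh)
  feat <- mesh$cross_section$feat
  poly <- mesh$nodes2d[feat$ring_ids[[2]], ]
  A_poly <- abs(sum(poly[, 1] * poly[c(2:nrow(poly), 1), 2] -
                    poly[c(2:nrow(poly), 1), 1] * poly[, 2]) / 2)
  ## T12 has endplates top and bottom
  expect_equal(unname(v["endplate_T12"] / A_poly / 2), 0.5, tolerance = 1e-9)
  ## L1 and T11 have one endplate each (disc-facing surface only)
  expect_equal(unname(v["endplate_L1"] / A_poly), 0.5, tolerance = 1e-9)
  expect_equal(unname(v["endplate_T11"] / A_poly), 0.5, tolerance = 1e-9)
})

test_that("cement-free geometry meshes mirror-symmetrically about y = 0", {
  geom <- build_segment()
  mesh <- cached("geom_mesh_default", generate_mesh(geom))
  P <- mesh$nodes
  key <- paste(round(P[, 1], 9), round(P[, 2], 9), round(P[, 3], 9))
  keym <- paste(round(P[, 1], 9), round(-P[, 2], 9), round(P[, 3], 9))
  expect_true(all(keym %in% key))
})

test_that("cement plans enforce the group definitions and never touch T12", {
  p <- cement_plan("B-B")
  expect_equal(p$placements, list(T11 = "bilateral", L1 = "bilateral"))
  expect_equal(cement_plan("L-B")$placements, list(T11 = "left", L1 = "bilateral"))
  expect_equal(cement_plan("L-R")$placements, list(T11 = "left", L1 = "right"))
  expect_equal(cement_plan("L-L")$placements, list(T11 = "left", L1 = "left"))
  expect_error(cement_plan("B-B", placements = list(T11 = "left", L1 = "left")),
               "inconsistent")
  expect_error(cement_plan("custom",
                           placements = list(T12 = "left", L1 = "left")),
               "T12")
  expect_error(cement_plan("X-X"), "unknown")
})

test_that("each augmented vertebra receives 6.0 mL of cement within 2%", {
  geom <- build_segment()
  for (g in c("B-B", "L-B", "L-R", "L-L")) {
    cv <- cement_volumes(place_cement(geom, cement_plan(g)))
    expect_equal(sort(names(cv)), c("L1", "T11"))
    expect_true(all(cv >= 5.88 & cv <= 6.12), info = g)
  }
})

test_that("bilateral cement cylinders are mirror images about y = 0", {
  gg <- place_cement(build_segment(), cement_plan("B-B"))
  cc <- gg$cement$cylinders
  for (v in c("T11", "L1")) {
    cv <- cc[cc$vertebra == v, ]
    expect_equal(nrow(cv), 2L)
    expect_lt(abs(cv$cy[1] + cv$cy[2]), 1e-9)
    expect_equal(cv$semi_ap[1], cv$semi_ap[2])
    expect_equal(cv$z0[1], cv$z0[2])
  }
})

test_that("mirroring the L-L geometry equals building the right-right plan", {
  geom <- build_segment()
  gm <- mirror_geometry(place_cement(geom, cement_plan("L-L")))
  g2 <- place_cement(geom, cement_plan("custom",
                                       placements = list(T11 = "right",
                                                         L1 = "right")))
  a <- gm$cement$cylinders[, c("vertebra", "cx", "cy", "semi_ap", "semi_lat",
                               "z0", "z1", "volume")]
  b <- g2$cement$cylinders[, c("vertebra", "cx", "cy", "semi_ap", "semi_lat",
                               "z0", "z1", "volume")]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("cement must stay clear of the cortical shell", {
  geom <- build_segment()
  big <- cement_plan("L-L", target_total_volume = 16)
  expect_error(place_cement(geom, big), "invalid cement plan")
  expect_error(place_cement(place_cement(geom, cement_plan("L-L")),
                            cement_plan("B-B")),
               "already contains cement")
})

test_that("cement containment: cylinder boundary at least one shell thickness inside", {
  gg <- place_cement(build_segment(), cement_plan("L-R"))
  cc <- gg$cement$cylinders
  phi <- seq(0, 2 * pi, length.out = 181L)
  for (k in seq_len(nrow(cc))) {
    bx <- cc$cx[k] + cc$semi_ap[k] * cos(phi)
    by <- cc$cy[k] + cc$semi_lat[k] * sin(phi)
    d <- svfem:::ellipse_min_distance(bx, by, gg$semi_ap, gg$semi_lat)
    expect_gte(min(d), gg$cortical_thickness - 1e-6)
  }
})

test_that("identical parameters give bit-identical geometry and cement", {
  g1 <- place_cement(build_segment(), cement_plan("L-B"))
  g2 <- place_cement(build_segment(), cement_plan("L-B"))
  expect_identical(g1$cement$cylinders, g2$cement$cylinders)
  expect_identical(g1$layout, g2$layout)
})
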