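# Post-processing: region maxima, rigid-fit range of motion, the ordering
# report on published summary values, CSV round trip.

test_that("region_max agrees with an exhaustive scan and breaks ties low", {
  mesh <- box_mesh(2, 2, 2, 3L, 3L, 3L, tag_name = "blk")
  set.seed(7)
  field <- runif(nrow(mesh$tets))
  rm <- region_max(mesh, field, "blk")
  ## independent linear scan
  best <- 1L
  for (e in seq_len(nrow(mesh$tets))) if (field[e] > field[best]) best <- e
  expect_equal(rm$element, best)
  expect_equal(rm$value, field[best])
  expect_equal(rm$location,
               colMeans(mesh$nodes[mesh$tets[best, 1:4], ]),
               ignore_attr = TRUE)
  ## constant field: first element wins
  rm2 <- region_max(mesh, rep(3, nrow(mesh$tets)), "blk")
  expect_equal(rm2$element, 1L)
  ## single spike
  f3 <- rep(0, nrow(mesh$tets)); f3[57] <- 9
  expect_equal(region_max(mesh, f3, "blk")$element, 57L)
  expect_error(region_max(mesh, field, "nope"), "unknown region")
})

test_that("region_max honours node exclusions", {
  mesh <- box_mesh(2, 2, 2, 2L, 2L, 2L, tag_name = "blk")
  field <- seq_len(nrow(mesh$tets))
  worst <- mesh$tets[which.max(field), 1:4]
  rm <- region_max(mesh, field, "blk", exclude_nodes = worst[1])
  expect_lt(rm$value, max(field))
})

test_that("rigid-fit ROM reproduces imposed rotations exactly", {
  mesh <- cached("geom_mesh_default", generate_mesh(build_segment()))
  u0 <- rep(0, 3 * nrow(mesh$nodes))
  expect_equal(compute_rom(mesh, u0, "T11", "L1", c(0, 1, 0)), 0)
  rot_u <- function(deg, axis, nodes_sel) {
    th <- deg * pi / 180
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    u <- matrix(0, nrow(mesh$nodes), 3)
    ctr <- c(0, 0, 50)
    u[nodes_sel, ] <- sweep(mesh$nodes[nodes_sel, ], 2, ctr) %*% t(R) -
      sweep(mesh$nodes[nodes_sel, ], 2, ctr)
    as.vector(t(u))
  }
  lay <- mesh$geom$layout
  t11_nodes <- which(mesh$nodes[, 3] > lay$T11$z0 - 1e-9)
  ## rigid 3 degree rotation of T11 about y, L1 fixed
  u <- rot_u(3, c(0, 1, 0), t11_nodes)
  expect_equal(compute_rom(mesh, u, "T11", "L1", c(0, 1, 0)), 3,
               tolerance = 1e-6)
  ## composition: 2 degrees on T11 relative to T12 plus 1 degree of the
  ## whole T12+T11 block about the same axis gives 3 degrees total
  t12_up <- which(mesh$nodes[, 3] > lay$T12$z0 - 1e-9)
  u2 <- rot_u(1, c(0, 0, 1), t12_up)
  m2 <- matrix(u2, ncol = 3, byrow = TRUE)
  th <- 2 * pi / 180
  Kz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  R2 <- diag(3) + sin(th) * Kz + (1 - cos(th)) * Kz %*% Kz
  X <- mesh$nodes
  Xmoved <- X + m2
  ctr <- c(0, 0, 50)
  Xfinal <- Xmoved
  Xfinal[t11_nodes, ] <- sweep(sweep(Xmoved[t11_nodes, ], 2, ctr) %*% t(R2),
                               2, ctr, `+`)
  u3 <- as.vector(t(Xfinal - X))
  expect_equal(compute_rom(mesh, u3, "T11", "T12", c(0, 0, 1)), 2,
               tolerance = 1e-4)
  expect_equal(compute_rom(mesh, u3, "T12", "L1", c(0, 0, 1)), 1,
               tolerance = 1e-6)
  expect_equal(compute_rom(mesh, u3, "T11", "L1", c(0, 0, 1)), 3,
               tolerance = 1e-4)
})

## published summary values used as synthetic report inputs
published_results <- function() {
  cases <- load_case_labels()
  vals <- list(
    "B-B" = list(vms = c(19.13, 18.86, 25.17, 25.01, 19.24, 20.08),
                 disp = c(0.67, 1.57, 1.34, 1.14, 1.1, 1.02),
                 d1 = c(1.09, 1.86, 1.86, 1.35, 1.32, 0.92),
                 d2 = c(0.87, 1.91, 2.32, 3.33, 1.33, 1.55)),
    "L-B" = list(vms = c(19.54, 19.58, 27.30, 25.23, 20.50, 20.3),
                 disp = c(0.68, 1.64, 1.54, 1.16, 1.23, 1.09),
                 d1 = c(1.15, 2.06, 2.12, 1.35, 1.33, 0.84),
                 d2 = rep(NA_real_, 6)),
    "L-R" = list(vms = c(20.71, 21.31, 28.25, 28.58, 19.18, 23.64),
                 disp = c(0.82, 1.74, 1.65, 1.28, 1.29, 1.1),
                 d1 = c(1.23, 2.14, 2.17, 1.51, 1.47, 0.87),
                 d2 = c(0.96, 2.65, 2.40, 3.68, 1.28, 2.05)),
    "L-L" = list(vms = c(21.55, 21.54, 30.17, 28.33, 19.88, 25.27),
                 disp = c(0.84, 1.83, 1.63, 1.31, 1.27, 1.81),
                 d1 = c(1.23, 2.11, 2.22, 1.61, 1.48, 1.43),
                 d2 = c(0.96, 2.75, 2.56, 3.72, 1.36, 2.31))
  )
  do.call(rbind, lapply(names(vals), function(g)
    data.frame(group = g, case = cases, max_vms_T12 = vals[[g]]$vms,
               max_disp_T12 = vals[[g]]$disp,
               max_vms_disc_T11T12 = vals[[g]]$d1,
               max_vms_disc_T12L1 = vals[[g]]$d2,
               stringsAsFactors = FALSE)))
}

test_that("ordering report reproduces the published comparative pattern", {
  rep <- build_ordering_report(published_results())
  ## full ordering holds in flexion but not in left rotation, where the
  ## published L-R value (19.18) undercuts B-B (19.24)
  expect_true(rep$full_order_by_case[["flexion"]])
  expect_false(rep$full_order_by_case[["left_rotation"]])
  expect_false(rep$bb_smallest_all_cases)
  expect_true(rep$ll_largest_overall)
  expect_true(rep$disc_T12L1_LL_gt_BB)
  expect_equal(rep$rankings$left_rotation, c("L-R", "B-B", "L-L", "L-B"))
  expect_equal(rep$rankings$flexion, c("B-B", "L-B", "L-R", "L-L"))
})

test_that("identical groups give tie-broken rankings and false strict flags", {
  tab <- published_results()
  for (col in c("max_vms_T12", "max_disp_T12", "max_vms_disc_T11T12",
                "max_vms_disc_T12L1"))
    tab[[col]] <- 1
  rep <- build_ordering_report(tab)
  expect_false(any(rep$full_order_by_case))
  expect_false(rep$bb_smallest_all_cases)
  expect_false(rep$ll_largest_overall)
  expect_false(rep$disc_T12L1_LL_gt_BB)
  expect_equal(rep$rankings$flexion, c("B-B", "L-B", "L-R", "L-L"))
})

test_that("a missing group is reported as an error", {
  tab <- published_results()
  expect_error(build_ordering_report(tab[tab$group != "L-R", ]),
               "missing group")
})

test_that("summary CSV round-trips the in-memory table", {
  tab <- published_results()
  tab <- tab[!is.na(tab$max_vms_disc_T12L1), ]
  dir <- withr::local_tempdir()
  export_summary(tab, build_ordering_report(published_results()),
                 dir = file.path(dir, "new", "nested"))
  expect_true(file.exists(file.path(dir, "new", "nested", "report.md")))
  back <- utils::read.csv(file.path(dir, "new", "nested", "summary.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  expect_equal(back, tab, ignore_attr = TRUE)
})
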