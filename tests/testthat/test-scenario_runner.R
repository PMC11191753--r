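# Scenario orchestration at a coarse density: determinism, mirror
# equivariance of the full pipeline, disc-stiffness monotonicity,
# zero-moment behaviour, convergence bookkeeping.

test_that("a single (group, case) run is deterministic to the bit", {
  cfg <- coarse_config(groups = "B-B", cases = "flexion")
  r1 <- run_matrix(cfg)
  r2 <- run_matrix(cfg)
  expect_equal(length(r1), 1L)
  s1 <- r1[[1]]$summary; s2 <- r2[[1]]$summary
  expect_identical(s1$max_vms_T12, s2$max_vms_T12)
  expect_identical(s1$max_disp_T12, s2$max_disp_T12)
  expect_identical(s1$rom, s2$rom)
  expect_true(all(c("config_hash", "n_nodes", "solver_iterations") %in%
                    names(r1[[1]]$provenance)))
})

test_that("mirrored cement under mirrored load gives identical summaries", {
  ## reflection equivariance of the whole pipeline: L-L under left rotation
  ## must match the mirror-image plan (right-right) under right rotation,
  ## and the crossed plans swap the same way
  model <- cached("coarse_model", prepare_model(coarse_config()))
  cfg <- coarse_config()
  run_custom <- function(placements, cases) {
    geom_g <- place_cement(model$geom, cement_plan("custom",
                                                   placements = placements))
    mesh_g <- tag_cement(model$mesh, geom_g)
    mats <- mesh_materials(mesh_g)
    K <- assemble_stiffness(mesh_g, mats$E, mats$nu)
    model_g <- model; model_g$mesh <- mesh_g
    cfg2 <- cfg; cfg2$cases <- cases
    out <- svfem:::solve_cases(model_g, K, mats, cfg2)
    rm(K); gc(FALSE)
    out
  }
  ll <- run_custom(list(T11 = "left", L1 = "left"), "left_rotation")
  rr <- run_custom(list(T11 = "right", L1 = "right"), "right_rotation")
  sl <- ll$left_rotation$summary; sr <- rr$right_rotation$summary
  expect_equal(sl$max_vms_T12, sr$max_vms_T12, tolerance = 1e-9)
  expect_equal(sl$max_disp_T12, sr$max_disp_T12, tolerance = 1e-9)
  expect_equal(sl$max_vms_disc_T12L1, sr$max_vms_disc_T12L1, tolerance = 1e-9)
  expect_equal(unname(sl$rom), unname(sr$rom), tolerance = 1e-9)
  ## the maximum location mirrors in y
  expect_equal(sl$max_vms_T12_loc$location[c(1, 3)],
               sr$max_vms_T12_loc$location[c(1, 3)], tolerance = 1e-6)
  expect_equal(sl$max_vms_T12_loc$location[2],
               -sr$max_vms_T12_loc$location[2], tolerance = 1e-6)
})

test_that("a symmetric model under flexion has a mirror-symmetric T12 stress field", {
  model <- cached("coarse_model", prepare_model(coarse_config()))
  mesh <- model$mesh
  mats <- mesh_materials(mesh)
  K <- cached("coarse_K", assemble_stiffness(mesh, mats$E, mats$nu))
  ctx <- cached("coarse_ctx",
                fe_context(K, model$fixed, trusses = mesh$trusses,
                           nodes = mesh$nodes,
                           springs = mesh$facet_springs))
  lc <- load_case("flexion")
  sol <- fe_solve_ctx(ctx, model$f_pre +
                        apply_moment(mesh, "T11_superior", lc$moment_vec))
  st <- recover_stress(mesh, sol$u, mats$E, mats$nu)
  ids <- region_elements(mesh, "T12")
  cen <- (mesh$nodes[mesh$tets[ids, 1], 1:3] + mesh$nodes[mesh$tets[ids, 2], 1:3] +
          mesh$nodes[mesh$tets[ids, 3], 1:3] + mesh$nodes[mesh$tets[ids, 4], 1:3]) / 4
  key <- paste(round(cen[, 1], 6), round(cen[, 2], 6), round(cen[, 3], 6))
  keym <- paste(round(cen[, 1], 6), round(-cen[, 2], 6), round(cen[, 3], 6))
  match_m <- match(keym, key)
  expect_false(anyNA(match_m))
  v <- st$vms[ids]
  expect_lt(max(abs(v - v[match_m])) / max(v), 1e-6)
})

test_that("preload alone produces no out-of-plane rotation", {
  model <- cached("coarse_model", prepare_model(coarse_config()))
  mesh <- model$mesh
  mats <- mesh_materials(mesh)
  K <- cached("coarse_K", assemble_stiffness(mesh, mats$E, mats$nu))
  ctx <- cached("coarse_ctx",
                fe_context(K, model$fixed, trusses = mesh$trusses,
                           nodes = mesh$nodes,
                           springs = mesh$facet_springs))
  sol <- fe_solve_ctx(ctx, model$f_pre)   # 500 N preload only
  ## lateral bending and axial rotation vanish by mirror symmetry; the
  ## sagittal tilt under pure compression (stiffness centroid posterior of
  ## the load centroid) is real but stays well below the moment-driven ROM
  expect_lt(compute_rom(mesh, sol$u, "T11", "L1", c(1, 0, 0)), 1e-6)
  expect_lt(compute_rom(mesh, sol$u, "T11", "L1", c(0, 0, 1)), 1e-6)
  expect_lt(compute_rom(mesh, sol$u, "T11", "L1", c(0, 1, 0)), 2)
})

test_that("stiffening the discs strictly reduces every ROM", {
  model <- cached("coarse_model", prepare_model(coarse_config()))
  mesh <- model$mesh
  mats <- mesh_materials(mesh)
  disc_el <- mesh$tag_names[mesh$tag] %in%
    c("annulus_T11T12", "annulus_T12L1", "nucleus_T11T12", "nucleus_T12L1")
  mats2 <- mats
  mats2$E[disc_el] <- 2 * mats2$E[disc_el]
  solve_all <- function(mm) {
    K <- assemble_stiffness(mesh, mm$E, mm$nu)
    ctx <- fe_context(K, model$fixed, trusses = mesh$trusses,
                      nodes = mesh$nodes,
                      springs = mesh$facet_springs)
    out <- numeric(0)
    for (cs in c("flexion", "left_bending", "left_rotation")) {
      lc <- load_case(cs)
      sol <- fe_solve_ctx(ctx, model$f_pre +
                            apply_moment(mesh, "T11_superior", lc$moment_vec))
      out[cs] <- compute_rom(mesh, sol$u, "T11", "L1", lc$axis)
    }
    out
  }
  rom1 <- solve_all(mats)
  rom2 <- solve_all(mats2)
  expect_true(all(rom2 < rom1))
})

test_that("refine_study returns one converging row per density", {
  cfg <- coarse_config()
  tab <- refine_study(cfg, edges = c(8, 6.5))
  expect_equal(nrow(tab), 2L)
  expect_true(all(diff(tab$n_elements) > 0))
  expect_true(all(is.finite(tab$max_vms_T12)))
  ## identical settings give identical rows
  tab2 <- refine_study(cfg, edges = c(8, 6.5))
  expect_identical(tab, tab2)
  expect_error(refine_study(cfg, edges = c(5, 5)), "decreasing")
})

test_that("configuration validation rejects empty studies", {
  expect_error(run_config(groups = character(0)), "at least one")
  expect_error(run_config(cases = "sideways"), "arg")
})
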