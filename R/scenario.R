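# Orchestration: four cement groups x six load cases, plus the cement-free
# validation model and its range-of-motion corridor check.  Everything is
# deterministic given the configuration; the mesh is built once and reused
# across groups (cement only re-tags elements), and one stiffness
# factorisation per group serves all six load cases.

#' Run configuration
#'
#' Geometry, mesh, material and load settings for a full study.  The
#' defaults are the calibrated study conditions (see the methods vignette
#' for the calibration of disc height and facet geometry against the
#' published range-of-motion corridor).
#'
#' @param body_width_ap,body_width_lat,body_height vertebral body dimensions
#'   (mm).
#' @param cortical_thickness,endplate_thickness shell thicknesses (mm).
#' @param disc_height disc height (mm).
#' @param nucleus_fraction nucleus area fraction of the disc cross-section.
#' @param nucleus_offset posterior nucleus centroid offset (mm).
#' @param posterior `posterior_params()`.
#' @param mesh_edge,cartilage_edge,element_order mesh density settings.
#' @param osteoporotic model an osteoporotic patient (the study default).
#' @param cancellous_alt use the 88.4 MPa alternative osteoporotic
#'   cancellous modulus.
#' @param facet_mode facet treatment: `"sliding"` (normal-contact spring
#'   layer, the calibrated default) or `"bonded"` (tied cartilage slab).
#' @param groups cement groups to run.
#' @param cases load cases to run.
#' @param preload,moment load magnitudes (N, N*m).
#' @param out_dir optional output directory for CSV/report export.
#' @return a `run_config`.
#' @export
run_config <- function(body_width_ap = 30, body_width_lat = 42,
                       body_height = 24, cortical_thickness = 1.5,
                       endplate_thickness = 0.5,
                       disc_height = 10.3, nucleus_fraction = 0.4,
                       nucleus_offset = 1.5,
                       posterior = posterior_params(),
                       mesh_edge = 5, cartilage_edge = 1.5,
                       element_order = 2L,
                       osteoporotic = TRUE, cancellous_alt = FALSE,
                       facet_mode = c("sliding", "bonded"),
                       groups = c("B-B", "L-B", "L-R", "L-L"),
                       cases = load_case_labels(),
                       preload = 500, moment = 7.5, out_dir = NULL) {
  facet_mode <- match.arg(facet_mode)
  if (length(groups) < 1L || length(cases) < 1L)
    stop("at least one group and one case must be requested")
  cases <- vapply(cases, match.arg, "", choices = load_case_labels())
  structure(list(
    body_width_ap = body_width_ap, body_width_lat = body_width_lat,
    body_height = body_height, cortical_thickness = cortical_thickness,
    endplate_thickness = endplate_thickness, disc_height = disc_height,
    nucleus_fraction = nucleus_fraction, nucleus_offset = nucleus_offset,
    posterior = posterior, mesh_edge = mesh_edge,
    cartilage_edge = cartilage_edge, element_order = as.integer(element_order),
    osteoporotic = osteoporotic, cancellous_alt = cancellous_alt,
    facet_mode = facet_mode, groups = groups, cases = unname(cases),
    preload = preload, moment = moment, out_dir = out_dir
  ), class = "run_config")
}

#' Build the segment geometry described by a configuration
#' @param config a `run_config`.
#' @return a `segment_geometry`.
#' @export
config_geometry <- function(config) {
  vp <- function(level) vertebra_params(
    level, body_width_ap = config$body_width_ap,
    body_width_lat = config$body_width_lat,
    body_height = config$body_height,
    cortical_thickness = config$cortical_thickness,
    endplate_thickness = config$endplate_thickness)
  dp <- disc_params(config$disc_height, config$nucleus_fraction,
                    config$nucleus_offset)
  post <- config$posterior
  post$facet_mode <- config$facet_mode
  build_segment(vp("T11"), vp("T12"), vp("L1"), dp, dp, posterior = post)
}

## polynomial rolling hash of a serialised object (provenance fingerprints)
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Prepare the shared cement-free model for a configuration
#'
#' Builds the geometry and mesh once, with the fixed-base constraint set
#' and the uniform preload vector.  Loads are force-controlled: the preload
#' is a uniform traction and the moments are self-equilibrated nodal
#' couples on the free T11 superior surface, so an asymmetric structure is
#' free to tilt under them.  The returned model can be shared between
#' [run_matrix] and [run_validation].
#'
#' @param config a `run_config`.
#' @return list with `geom`, `mesh`, `fixed` (constrained dofs), `f_pre`
#'   (preload vector) and `exclude` (nodes skipped by stress maxima).
#' @export
prepare_model <- function(config) {
  geom <- config_geometry(config)
  mesh <- generate_mesh(geom, mesh_settings(config$mesh_edge,
                                            config$cartilage_edge,
                                            config$element_order))
  fixed <- fix_base(mesh, "L1_inferior")
  loaded <- coupling_nodes(mesh, "T11_superior")
  f_pre <- distribute_pressure(mesh, "T11_superior", config$preload)
  exclude <- sort(unique(c(mesh$groups$L1_inferior$nodes, loaded)))
  list(geom = geom, mesh = mesh, fixed = fixed,
       f_pre = f_pre, exclude = exclude)
}

## solve the requested cases on one assembled model; returns summaries
solve_cases <- function(model, K, mats, config) {
  mesh <- model$mesh
  ctx <- fe_context(K, model$fixed, trusses = mesh$trusses,
                    nodes = mesh$nodes, springs = mesh$facet_springs)
  out <- list()
  active <- NULL
  for (cs in config$cases) {
    lc <- load_case(cs, preload = config$preload, moment = config$moment)
    f <- model$f_pre + apply_moment(mesh, "T11_superior", lc$moment_vec)
    sol <- fe_solve_ctx(ctx, f, active_init = active)
    active <- sol$active
    out[[cs]] <- list(case = lc, sol = sol,
                      summary = solution_summary(mesh, sol, mats, lc,
                                                 model$exclude))
  }
  rm(ctx); gc(FALSE)
  out
}

#' Run the full cement-group x load-case matrix
#'
#' Builds the segment once, then for every requested cement group re-tags
#' the mesh, assembles and factorises the stiffness, and solves every
#' requested load case (uniform 500 N preload + 7.5 N*m nodal couple on
#' the T11 superior surface; L1 inferior surface fixed).
#'
#' @param config a `run_config`.
#' @param model optional prepared model (from an earlier call), to share
#'   the mesh between the matrix and the validation run.
#' @return list of run results, one per (group, case), each with `group`,
#'   `case`, `summary` and a `provenance` block; attribute `"table"` holds
#'   the flattened data frame.
#' @export
run_matrix <- function(config, model = NULL) {
  if (is.null(model)) model <- prepare_model(config)
  mesh0 <- model$mesh
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  mats0 <- mesh_materials(mesh0, config$osteoporotic, config$cancellous_alt)
  K_base <- assemble_stiffness(mesh0, mats0$E, mats0$nu)
  results <- list()
  for (g in config$groups) {
    geom_g <- place_cement(model$geom, cement_plan(g))
    mesh_g <- tag_cement(mesh0, geom_g)
    mats <- mesh_materials(mesh_g, config$osteoporotic, config$cancellous_alt)
    ## incremental assembly: cement only re-tags cancellous elements, so
    ## K differs from the cement-free matrix by those elements alone
    cem <- which(grepl("^cement_", mesh_g$tag_names[mesh_g$tag]))
    K <- K_base +
      assemble_stiffness(mesh_g, mats$E, mats$nu, elements = cem) -
      assemble_stiffness(mesh0, mats0$E, mats0$nu, elements = cem)
    model_g <- model; model_g$mesh <- mesh_g
    runs <- solve_cases(model_g, K, mats, config)
    rm(K); gc(FALSE)
    if (!is.null(config$out_dir)) {
      if (!dir.exists(config$out_dir))
        dir.create(config$out_dir, recursive = TRUE)
      for (cs in names(runs)) {
        st <- recover_stress(mesh_g, runs[[cs]]$sol$u, mats$E, mats$nu)
        write_vtu(mesh_g,
                  file.path(config$out_dir,
                            sprintf("%s_%s.vtu", gsub("-", "", g), cs)),
                  point_data = list(displacement = matrix(runs[[cs]]$sol$u,
                                                          ncol = 3,
                                                          byrow = TRUE)),
                  cell_data = list(vms = st$vms))
      }
    }
    for (cs in names(runs)) {
      results[[paste(g, cs, sep = ":")]] <- list(
        group = g, case = cs, summary = runs[[cs]]$summary,
        provenance = list(config_hash = hash,
                          n_nodes = nrow(mesh_g$nodes),
                          n_elements = nrow(mesh_g$tets),
                          solver_iterations = runs[[cs]]$sol$iterations,
                          active_ligaments = sum(runs[[cs]]$sol$active)))
    }
  }
  attr(results, "table") <- results_table(results)
  if (!is.null(config$out_dir)) {
    rep <- tryCatch(build_ordering_report(attr(results, "table")),
                    error = function(e) NULL)
    export_summary(results, rep, config$out_dir)
  }
  results
}

#' Published range-of-motion reference values (degrees)
#'
#' The validation corridor: segmental ROM of T11-T12, T12-L1 and T11-L1
#' under 7.5 N*m in six directions, as reported by the study this model is
#' validated against and the two literature models cited there.
#'
#' @return data frame with columns `case`, `level`, `present`, `dai`, `liao`.
#' @export
rom_reference_table <- function() {
  lev <- rep(c("T11T12", "T12L1", "T11L1"), each = 6L)
  cs <- rep(load_case_labels(), 3L)
  present <- c(3.24, 2.86, 3.54, 3.68, 1.82, 1.88,
               3.12, 3.30, 3.28, 3.34, 1.24, 1.29,
               6.31, 6.12, 6.87, 6.82, 3.23, 3.27)
  dai <- c(3.38, 2.84, 3.60, 3.72, 1.76, 1.75,
           3.38, 3.74, 3.92, 3.73, 1.41, 1.45,
           6.26, 6.18, 6.92, 6.85, 3.17, 3.18)
  liao <- c(3.00, 3.10, 3.30, 3.80, 2.20, 2.00,
            3.30, 3.70, 4.00, 3.60, 1.30, 1.40,
            6.60, 6.80, 7.30, 6.90, 3.50, 3.40)
  data.frame(case = cs, level = lev, present = present, dai = dai,
             liao = liao, stringsAsFactors = FALSE)
}

#' Range-of-motion validation of the cement-free model
#'
#' Solves the six load cases on the cement-free model and tabulates the
#' segmental ROM against the published values: `ratio` is model/reference,
#' `in_corridor` flags values inside the min-max corridor of the two
#' literature models.
#'
#' @param config a `run_config`.
#' @param model optional prepared model to reuse.
#' @param preload preload used for the validation runs (N).  The default is
#'   a pure-moment protocol (0 N), the convention of the segment-validation
#'   studies the reference values come from; pass `config$preload` to apply
#'   the full compressive preload instead.  The value used is recorded in
#'   the `"preload"` attribute.
#' @return data frame (18 rows) with the computed and reference ROM;
#'   attribute `"preload"` records the preload used.
#' @export
run_validation <- function(config, model = NULL, preload = 0) {
  cfg <- config
  cfg$preload <- preload
  cfg$cases <- load_case_labels()
  if (is.null(model)) {
    model <- prepare_model(cfg)
  } else {
    model$f_pre <- distribute_pressure(model$mesh, "T11_superior", preload)
  }
  mats <- mesh_materials(model$mesh, cfg$osteoporotic, cfg$cancellous_alt)
  K <- assemble_stiffness(model$mesh, mats$E, mats$nu)
  runs <- solve_cases(model, K, mats, cfg)
  rm(K); gc(FALSE)
  ref <- rom_reference_table()
  ref$rom <- NA_real_
  for (cs in names(runs)) {
    rom <- runs[[cs]]$summary$rom
    for (lv in names(rom))
      ref$rom[ref$case == cs & ref$level == lv] <- rom[[lv]]
  }
  ref$ratio <- ref$rom / ref$present
  ref$in_corridor <- ref$rom >= pmin(ref$dai, ref$liao) &
    ref$rom <= pmax(ref$dai, ref$liao)
  attr(ref, "preload") <- preload
  ref[, c("case", "level", "rom", "present", "dai", "liao", "ratio",
          "in_corridor")]
}

#' Mesh-convergence study
#'
#' Re-meshes the cement-free model at a sequence of decreasing edge lengths
#' and reports the maximum T12 von Mises stress and the T11-L1 flexion ROM
#' per density; used to document the discretisation error of the desk-scale
#' default density.
#'
#' @param config a `run_config`.
#' @param edges decreasing solid edge lengths (mm).
#' @return data frame with one row per density.
#' @export
refine_study <- function(config, edges = c(8, 6, 4)) {
  if (length(edges) >= 2L && any(diff(edges) >= 0))
    stop("edges must be strictly decreasing")
  out <- list()
  for (e in edges) {
    cfg <- config
    cfg$mesh_edge <- e
    cfg$cases <- "flexion"
    model <- prepare_model(cfg)
    mats <- mesh_materials(model$mesh, cfg$osteoporotic, cfg$cancellous_alt)
    K <- assemble_stiffness(model$mesh, mats$E, mats$nu)
    runs <- solve_cases(model, K, mats, cfg)
    s <- runs$flexion$summary
    out[[length(out) + 1L]] <- data.frame(
      edge = e, n_nodes = nrow(model$mesh$nodes),
      n_elements = nrow(model$mesh$tets),
      max_vms_T12 = s$max_vms_T12, rom_T11L1_flexion = s$rom[["T11L1"]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Grid-search calibration of the range of motion
#'
#' Evaluates the squared relative ROM error (18 entries against the
#' published reference) over a parameter grid; used once to freeze the
#' shipped defaults.
#'
#' @param config base `run_config`.
#' @param grid data frame whose columns name `run_config` fields
#'   (e.g. `disc_height`) or posterior fields prefixed `posterior.`
#'   (e.g. `posterior.cartilage_gap`).
#' @return the grid with error columns, sorted best first.
#' @export
calibrate_rom <- function(config, grid) {
  res <- list()
  for (r in seq_len(nrow(grid))) {
    cfg <- config
    for (nm in names(grid)) {
      if (startsWith(nm, "posterior.")) {
        cfg$posterior[[sub("^posterior\\.", "", nm)]] <- grid[[nm]][r]
      } else cfg[[nm]] <- grid[[nm]][r]
    }
    val <- tryCatch(run_validation(cfg), error = function(e) NULL)
    if (is.null(val)) {
      err <- NA_real_; flex <- NA_real_; n_corr <- NA_integer_
    } else {
      err <- sum(((val$rom - val$present) / val$present)^2)
      flex <- val$rom[val$case == "flexion" & val$level == "T11L1"]
      n_corr <- sum(abs(val$ratio - 1) <= 0.3)
    }
    res[[r]] <- cbind(grid[r, , drop = FALSE],
                      data.frame(sq_rel_error = err, flexion_T11L1 = flex,
                                 n_within_30pct = n_corr))
  }
  out <- do.call(rbind, res)
  out[order(out$sq_rel_error), ]
}
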