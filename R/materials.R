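# Linear-elastic material catalogue for the T11-L1 segment model.
# Young's moduli in MPa; with the mm/N/MPa unit system used throughout,
# forces are N, moments N*mm, stresses MPa.

#' Material property catalogue
#'
#' Isotropic linear-elastic constants for every region of the segment model,
#' plus the seven ligament groups (Young's modulus, Poisson ratio and total
#' cross-sectional area in mm^2).  Osteoporotic bone and endplate moduli are
#' 67% of the normal values, except that the published osteoporotic
#' cancellous modulus is 34 MPa; the arithmetic 67% value (88.4 MPa) is
#' kept available as `cancellous_osteoporotic_alt` so either convention can
#' be selected in a run configuration.
#'
#' @return a list with data frames `solids` and `ligaments`.
#' @export
material_table <- function() {
  solids <- data.frame(
    name = c("cortical", "cortical_osteoporotic",
             "cancellous", "cancellous_osteoporotic",
             "cancellous_osteoporotic_alt",
             "endplate", "endplate_osteoporotic",
             "cartilage", "annulus", "nucleus", "cement"),
    young_modulus = c(12000, 8040, 132, 34, 88.4, 1000, 670,
                      10, 4.2, 1, 3000),
    poisson_ratio = c(0.3, 0.3, 0.2, 0.2, 0.2, 0.4, 0.4,
                      0.4, 0.45, 0.499, 0.4),
    stringsAsFactors = FALSE
  )
  ligaments <- data.frame(
    name = c("ALL", "PLL", "LF", "SSL", "ISL", "ITL", "CL"),
    long_name = c("anterior longitudinal", "posterior longitudinal",
                  "ligamentum flavum", "supraspinous", "interspinous",
                  "intertransverse", "capsular"),
    young_modulus = c(20, 20, 19.5, 15, 12, 59, 7.5),
    poisson_ratio = rep(0.3, 7),
    total_area = c(65, 20, 40, 30, 40, 1.8, 30),
    stringsAsFactors = FALSE
  )
  list(solids = solids, ligaments = ligaments)
}

#' Material for a mesh region tag
#'
#' Maps a region tag such as `"cancellous_T12"` or `"annulus_T11T12"` to its
#' material constants.  When `osteoporotic` is `TRUE` (the default: the
#' study population is osteoporotic) cortical bone, cancellous bone,
#' posterior elements and endplates take the reduced moduli; cement, discs
#' and cartilage are unaffected.  Posterior elements carry cortical
#' properties.
#'
#' @param tag region tag (character).
#' @param osteoporotic logical flag.
#' @param cancellous_alt use 88.4 MPa (the literal 67% value) instead of the
#'   published 34 MPa for osteoporotic cancellous bone.
#' @return a `material_spec` list with `name`, `young_modulus`,
#'   `poisson_ratio`, `osteoporotic_flag`.
#' @export
material_for <- function(tag, osteoporotic = TRUE, cancellous_alt = FALSE) {
  base <- sub("_.*$", "", tag)
  if (base == "posterior") base <- "cortical"
  tab <- material_table()$solids
  key <- base
  if (osteoporotic && base %in% c("cortical", "cancellous", "endplate")) {
    key <- paste0(base, "_osteoporotic")
    if (base == "cancellous" && cancellous_alt) key <- paste0(key, "_alt")
  }
  row <- tab[tab$name == key, ]
  if (nrow(row) != 1L)
    stop("unknown region tag: ", tag)
  structure(list(name = key, young_modulus = row$young_modulus,
                 poisson_ratio = row$poisson_ratio,
                 osteoporotic_flag = osteoporotic),
            class = "material_spec")
}

#' Per-element material vectors for a mesh
#'
#' @param mesh an `fe_mesh` with region tags.
#' @param osteoporotic,cancellous_alt see [material_for].
#' @return list with numeric vectors `E` and `nu`, one entry per element.
#' @export
mesh_materials <- function(mesh, osteoporotic = TRUE, cancellous_alt = FALSE) {
  specs <- lapply(mesh$tag_names, material_for,
                  osteoporotic = osteoporotic, cancellous_alt = cancellous_alt)
  Ev <- vapply(specs, `[[`, numeric(1), "young_modulus")
  nuv <- vapply(specs, `[[`, numeric(1), "poisson_ratio")
  list(E = Ev[mesh$tag], nu = nuv[mesh$tag])
}
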