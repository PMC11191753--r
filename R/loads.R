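# The six physiological load cases: a uniformly distributed 500 N
# compressive preload on the superior surface of T11 plus a 7.5 N*m moment,
# with all nodes of the L1 inferior surface fully constrained.
#
# Sign conventions (right-handed frame, +x anterior, +y subject-left,
# +z superior):
#   flexion        +7.5 N*m about +y      extension      -y
#   right bending  +7.5 N*m about +x      left bending   -x
#   left rotation  +7.5 N*m about +z      right rotation -z

#' The six standard load-case labels
#' @export
load_case_labels <- function() c("flexion", "extension", "left_bending",
                                 "right_bending", "left_rotation",
                                 "right_rotation")

#' Build one physiological load case
#'
#' @param label one of [load_case_labels()].
#' @param preload compressive preload magnitude (N, applied in -z).
#' @param moment moment magnitude (N*m).
#' @return a `load_case` with the moment axis vector (N*mm scale).
#' @export
load_case <- function(label, preload = 500, moment = 7.5) {
  label <- match.arg(label, load_case_labels())
  axis <- switch(label,
    flexion = c(0, 1, 0), extension = c(0, -1, 0),
    right_bending = c(1, 0, 0), left_bending = c(-1, 0, 0),
    left_rotation = c(0, 0, 1), right_rotation = c(0, 0, -1))
  structure(list(label = label, preload = preload, moment = moment,
                 moment_vec = axis * moment * 1000,
                 axis = axis,
                 application = "T11_superior", constraint = "L1_inferior"),
            class = "load_case")
}

#' Load-case sign-convention table
#'
#' @return data frame echoed into run reports.
#' @export
load_case_table <- function() {
  do.call(rbind, lapply(load_case_labels(), function(l) {
    lc <- load_case(l)
    data.frame(case = l, preload_N = lc$preload, moment_Nm = lc$moment,
               axis_x = lc$axis[1], axis_y = lc$axis[2], axis_z = lc$axis[3],
               stringsAsFactors = FALSE)
  }))
}

facet_areas_normals <- function(mesh, facets) {
  p1 <- mesh$nodes[facets[, 1], , drop = FALSE]
  p2 <- mesh$nodes[facets[, 2], , drop = FALSE]
  p3 <- mesh$nodes[facets[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(area = sqrt(rowSums(cr^2)) / 2)
}

#' Consistent nodal forces for a uniform downward surface load
#'
#' Distributes a total force of magnitude `total` in -z as a uniform
#' traction over the named surface group; the resultant equals
#' `(0, 0, -total)` exactly.  On quadratic facets the consistent load for a
#' constant traction puts 1/3 of the facet force on each mid-side node and
#' nothing on the corners.
#'
#' @param mesh an `fe_mesh` from [generate_mesh].
#' @param group surface group name (default `"T11_superior"`).
#' @param total total force magnitude (N).
#' @return full-length nodal force vector.
#' @export
distribute_pressure <- function(mesh, group = "T11_superior", total = 500) {
  g <- mesh$groups[[group]]
  if (is.null(g) || is.null(g$facets) || nrow(g$facets) == 0L)
    stop("unknown or facet-less surface group: ", group)
  fac <- g$facets
  ar <- facet_areas_normals(mesh, fac)$area
  A <- sum(ar)
  if (A <= 1e-12) stop("zero-area surface group: ", group)
  f <- numeric(3L * nrow(mesh$nodes))
  if (total == 0) return(f)
  p <- total / A
  if (mesh$order == 2L) {
    m1 <- midside_lookup(mesh, fac[, 1], fac[, 2])
    m2 <- midside_lookup(mesh, fac[, 2], fac[, 3])
    m3 <- midside_lookup(mesh, fac[, 3], fac[, 1])
    if (anyNA(c(m1, m2, m3))) stop("internal: surface mid-side nodes missing")
    ids <- cbind(m1, m2, m3)
  } else {
    ids <- fac
  }
  w <- rep(ar / 3, 3L) * p
  dz <- 3L * (as.vector(ids) - 1L) + 3L
  acc <- tapply(w, dz, sum)
  f[as.integer(names(acc))] <- -as.numeric(acc)
  f
}

#' Equivalent nodal force couple for a pure moment on a surface
#'
#' Builds a self-equilibrated nodal force system `f_i = m x r_i` over the
#' corner nodes of the group (with `m` solved from a 3x3 system) whose net
#' force is zero and whose net moment about the surface centroid equals the
#' requested vector.  The scenario runner applies moments through the rigid
#' coupling instead; this nodal form is the coupling-free equivalent.
#'
#' @param mesh an `fe_mesh`.
#' @param group surface group name.
#' @param moment_vec length-3 moment vector (N*mm).
#' @return full-length nodal force vector.
#' @export
apply_moment <- function(mesh, group = "T11_superior", moment_vec) {
  g <- mesh$groups[[group]]
  if (is.null(g) || length(g$nodes) < 3L)
    stop("surface group needs at least 3 nodes: ", group)
  X <- mesh$nodes[g$nodes, , drop = FALSE]
  ctr <- colMeans(X)
  r <- sweep(X, 2, ctr)
  if (sum(svd(r, nu = 0, nv = 0)$d > 1e-9) < 2L)
    stop("surface group nodes are collinear: ", group)
  f <- numeric(3L * nrow(mesh$nodes))
  if (all(moment_vec == 0)) return(f)
  A <- sum(rowSums(r * r)) * diag(3) - crossprod(r)
  m <- solve(A, moment_vec)
  fi <- cbind(m[2] * r[, 3] - m[3] * r[, 2],
              m[3] * r[, 1] - m[1] * r[, 3],
              m[1] * r[, 2] - m[2] * r[, 1])
  f[3L * (g$nodes - 1L) + 1L] <- fi[, 1]
  f[3L * (g$nodes - 1L) + 2L] <- fi[, 2]
  f[3L * (g$nodes - 1L) + 3L] <- fi[, 3]
  f
}

#' Fully constrain a surface group
#'
#' @param mesh an `fe_mesh`.
#' @param group surface group name (default the L1 inferior surface).
#' @return integer vector of constrained dof ids (all three components of
#'   every node in the group, including mid-side nodes on those facets).
#' @export
fix_base <- function(mesh, group = "L1_inferior") {
  g <- mesh$groups[[group]]
  if (is.null(g) || length(g$nodes) == 0L)
    stop("empty surface group: ", group)
  nodes <- g$nodes
  if (mesh$order == 2L && !is.null(g$facets) && nrow(g$facets) > 0L) {
    fac <- g$facets
    nodes <- c(nodes,
               midside_lookup(mesh, fac[, 1], fac[, 2]),
               midside_lookup(mesh, fac[, 2], fac[, 3]),
               midside_lookup(mesh, fac[, 3], fac[, 1]))
    nodes <- sort(unique(nodes[!is.na(nodes)]))
  }
  as.vector(t(outer(3L * (nodes - 1L), 1:3, `+`)))
}

#' Nodes rigidly coupled for moment application (incl. mid-side nodes)
#' @param mesh an `fe_mesh`.
#' @param group surface group name.
#' @return integer node ids.
#' @keywords internal
coupling_nodes <- function(mesh, group = "T11_superior") {
  g <- mesh$groups[[group]]
  nodes <- g$nodes
  if (mesh$order == 2L && !is.null(g$facets) && nrow(g$facets) > 0L) {
    fac <- g$facets
    nodes <- c(nodes,
               midside_lookup(mesh, fac[, 1], fac[, 2]),
               midside_lookup(mesh, fac[, 2], fac[, 3]),
               midside_lookup(mesh, fac[, 3], fac[, 1]))
    nodes <- sort(unique(nodes[!is.na(nodes)]))
  }
  nodes
}
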