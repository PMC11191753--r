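# Structured extrusion meshing: a 2D triangulation is swept along a global
# z-grid; every active (triangle, layer) prism is cut into three tetrahedra.
# All cutting rules depend only on node coordinates through the key
# (x, |y|, y), so a model that is geometrically mirror-symmetric about y = 0
# produces a mesh that is exactly mirror-symmetric, element by element.

#' Total order on 2D nodes used for diagonal/prism-splitting rules
#'
#' Ranks nodes by (x, |y|, y).  The first two components are invariant under
#' reflection about y = 0, which makes every splitting decision
#' mirror-equivariant as long as no edge connects a node to its own mirror
#' image (guaranteed here because nodes on the symmetry plane have y = 0).
#'
#' @param nodes2d numeric matrix with columns x, y.
#' @return integer rank per node (1 = smallest).
#' @keywords internal
node2d_rank <- function(nodes2d) {
  ord <- order(nodes2d[, 1], abs(nodes2d[, 2]), nodes2d[, 2])
  rk <- integer(nrow(nodes2d))
  rk[ord] <- seq_len(nrow(nodes2d))
  rk
}

#' Split a list of quadrilaterals into triangles
#'
#' The diagonal passing through the corner with the smallest node rank is
#' chosen, so the triangulation is deterministic and mirror-equivariant.
#'
#' @param quads integer matrix (n x 4), corners in cyclic order.
#' @param rank integer rank per 2D node (from [node2d_rank]).
#' @return integer matrix (2n x 3).
#' @keywords internal
split_quads <- function(quads, rank) {
  if (nrow(quads) == 0L) return(matrix(integer(0), 0L, 3L))
  r <- matrix(rank[quads], ncol = 4L)
  use13 <- pmin(r[, 1], r[, 3]) < pmin(r[, 2], r[, 4])
  t1 <- ifelse(use13, quads[, 1], quads[, 2])
  t2 <- ifelse(use13, quads[, 2], quads[, 3])
  t3 <- ifelse(use13, quads[, 3], quads[, 4])
  s1 <- ifelse(use13, quads[, 1], quads[, 2])
  s2 <- ifelse(use13, quads[, 3], quads[, 4])
  s3 <- ifelse(use13, quads[, 4], quads[, 1])
  rbind(cbind(t1, t2, t3), cbind(s1, s2, s3))
}

#' Build a tetrahedral mesh by extruding a tagged 2D triangulation
#'
#' @param nodes2d numeric matrix (n2 x 2) of cross-section coordinates (mm).
#' @param tris2d integer matrix (m x 3) of 2D triangles.
#' @param zgrid strictly increasing numeric vector of layer boundaries (mm).
#' @param layer_tag integer matrix (m x (length(zgrid) - 1)); entry (t, l) is
#'   the region id of the prism over triangle t in layer l, 0 = void.
#' @param tag_names character vector naming the region ids.
#' @return an object of class `fe_mesh` (linear TET4) with fields `nodes`,
#'   `tets`, `tag`, `tag_names`, `node_grid` (lookup (2D node, z index) ->
#'   3D node id, 0 if absent), `node2d`, `nodeiz`, `nodes2d`, `zgrid`.
#' @keywords internal
extrude_mesh <- function(nodes2d, tris2d, zgrid, layer_tag, tag_names) {
  stopifnot(ncol(nodes2d) == 2L, ncol(tris2d) == 3L)
  if (any(diff(zgrid) <= 0)) stop("zgrid must be strictly increasing")
  n2 <- nrow(nodes2d)
  nl <- length(zgrid) - 1L
  stopifnot(nrow(layer_tag) == nrow(tris2d), ncol(layer_tag) == nl)

  rank <- node2d_rank(nodes2d)
  ## sort each triangle's vertices by rank (v1 < v2 < v3)
  rt <- matrix(rank[tris2d], ncol = 3L)
  o1 <- max.col(-rt)                      # index of min
  o3 <- max.col(rt)                       # index of max
  if (any(o1 == o3)) stop("degenerate 2D triangle (duplicate node)")
  o2 <- 6L - o1 - o3
  idx <- cbind(seq_len(nrow(tris2d)), o1)
  v1 <- tris2d[idx]
  v2 <- tris2d[cbind(seq_len(nrow(tris2d)), o2)]
  v3 <- tris2d[cbind(seq_len(nrow(tris2d)), o3)]

  act <- which(layer_tag > 0L, arr.ind = TRUE)
  if (nrow(act) == 0L) stop("no active prisms")
  t_id <- act[, 1]; l_id <- act[, 2]
  tagv <- layer_tag[act]

  base_b <- (l_id - 1L) * n2
  base_t <- l_id * n2
  b1 <- base_b + v1[t_id]; b2 <- base_b + v2[t_id]; b3 <- base_b + v3[t_id]
  t1 <- base_t + v1[t_id]; t2 <- base_t + v2[t_id]; t3 <- base_t + v3[t_id]

  ## prism -> 3 tets with face diagonals "bottom of lower rank -> top of
  ## higher rank": globally conforming by construction.
  tets <- rbind(
    cbind(b1, b2, b3, t3),
    cbind(b1, b2, t3, t2),
    cbind(b1, t2, t3, t1)
  )
  tag <- rep.int(tagv, 3L)

  ## renumber to the used nodes only
  used <- sort(unique(as.vector(tets)))
  remap <- integer(n2 * (nl + 1L))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  i2 <- ((used - 1L) %% n2) + 1L
  iz <- ((used - 1L) %/% n2) + 1L
  nodes <- cbind(nodes2d[i2, 1], nodes2d[i2, 2], zgrid[iz])
  colnames(nodes) <- c("x", "y", "z")

  node_grid <- matrix(0L, n2, nl + 1L)
  node_grid[cbind(i2, iz)] <- seq_along(used)

  mesh <- structure(list(
    nodes = nodes, tets = tets, tag = tag, tag_names = tag_names,
    node_grid = node_grid, node2d = i2, nodeiz = iz,
    nodes2d = nodes2d, zgrid = zgrid, order = 1L
  ), class = "fe_mesh")

  ## orient all elements positively (reflection-produced prisms come out
  ## negative; swapping two vertices fixes the sign without touching faces)
  v <- tet_volumes(mesh)
  neg <- v < 0
  if (any(neg)) {
    tmp <- mesh$tets[neg, 3L]
    mesh$tets[neg, 3L] <- mesh$tets[neg, 4L]
    mesh$tets[neg, 4L] <- tmp
  }
  if (any(abs(tet_volumes(mesh)) < 1e-12))
    stop("degenerate (zero-volume) element produced by extrusion")
  mesh
}

#' Signed volumes of the tetrahedra of a mesh
#'
#' Uses the four corner nodes; exact for straight-sided TET10 as well.
#'
#' @param mesh an `fe_mesh`.
#' @return numeric vector of signed volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  X <- mesh$nodes; T4 <- mesh$tets[, 1:4, drop = FALSE]
  a <- X[T4[, 2], , drop = FALSE] - X[T4[, 1], , drop = FALSE]
  b <- X[T4[, 3], , drop = FALSE] - X[T4[, 1], , drop = FALSE]
  c <- X[T4[, 4], , drop = FALSE] - X[T4[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
   a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
   a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Promote a linear TET4 mesh to quadratic TET10
#'
#' Mid-side nodes are inserted at edge midpoints (straight-sided elements).
#' Edge ordering follows the VTK convention: (1,2), (2,3), (3,1), (1,4),
#' (2,4), (3,4).
#'
#' @param mesh an `fe_mesh` with `order == 1`.
#' @return the quadratic `fe_mesh` (`order == 2`), with `edge_key`/`edge_mid`
#'   lookup tables for mid-side retrieval.
#' @export
to_tet10 <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"), mesh$order == 1L)
  T4 <- mesh$tets
  n <- nrow(mesh$nodes)
  ep <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  A <- cbind(T4[, ep[, 1]])
  B <- cbind(T4[, ep[, 2]])
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- as.numeric(lo) * (n + 1) + as.numeric(hi)
  ukey <- sort(unique(key))
  mid_id <- n + match(key, ukey)
  ulo <- floor((ukey - 1e-9) / (n + 1)); uhi <- ukey - ulo * (n + 1)
  midnodes <- (mesh$nodes[ulo, , drop = FALSE] +
               mesh$nodes[uhi, , drop = FALSE]) / 2
  mesh$nodes <- rbind(mesh$nodes, midnodes)
  mesh$tets <- cbind(T4, matrix(mid_id, ncol = 6L))
  mesh$node2d <- c(mesh$node2d, rep(NA_integer_, length(ukey)))
  mesh$nodeiz <- c(mesh$nodeiz, rep(NA_integer_, length(ukey)))
  mesh$edge_key <- ukey
  mesh$edge_mid <- n + seq_along(ukey)
  mesh$n_corner <- n
  mesh$order <- 2L
  mesh
}

#' Look up mid-side node ids for pairs of corner nodes
#'
#' @param mesh a TET10 `fe_mesh`.
#' @param i,j corner node id vectors.
#' @return integer vector of mid-side node ids (NA when the edge is absent).
#' @keywords internal
midside_lookup <- function(mesh, i, j) {
  stopifnot(mesh$order == 2L)
  n <- mesh$n_corner
  key <- as.numeric(pmin(i, j)) * (n + 1) + as.numeric(pmax(i, j))
  mesh$edge_mid[match(key, mesh$edge_key)]
}

#' Boundary and interface facets of a tetrahedral mesh
#'
#' @param mesh an `fe_mesh`.
#' @return list with `facets` (f x 3 corner node ids), `elem` (owning element
#'   of each facet; boundary facets have one owner), `count` (1 = boundary,
#'   2 = interior).
#' @keywords internal
mesh_facets <- function(mesh) {
  T4 <- mesh$tets[, 1:4, drop = FALSE]
  f <- rbind(T4[, c(1, 2, 3)], T4[, c(1, 2, 4)], T4[, c(1, 3, 4)], T4[, c(2, 3, 4)])
  fs <- t(apply(f, 1L, sort.int))
  n <- nrow(mesh$nodes)
  key <- (as.numeric(fs[, 1]) * (n + 1) + fs[, 2]) * (n + 1) + fs[, 3]
  elem <- rep.int(seq_len(nrow(T4)), 4L)
  ord <- order(key)
  key <- key[ord]; f <- f[ord, , drop = FALSE]; elem <- elem[ord]
  first <- !duplicated(key)
  cnt <- tabulate(cumsum(first), sum(first))
  list(facets = f[first, , drop = FALSE], elem = elem[first],
       count = cnt, key = key[first], all_key = key, all_elem = elem)
}

#' Mesh quality and sanity summary
#'
#' Reports element volumes and the minimum dihedral angle over the mesh;
#' used by the meshing tests to enforce a quality floor and the absence of
#' inverted elements.
#'
#' @param mesh an `fe_mesh`.
#' @return list with `n_nodes`, `n_elements`, `min_volume`, `total_volume`,
#'   `min_dihedral_deg`.
#' @export
mesh_quality <- function(mesh) {
  X <- mesh$nodes; T4 <- mesh$tets[, 1:4, drop = FALSE]
  v <- tet_volumes(mesh)
  ## face normals: faces opposite each vertex
  p1 <- X[T4[, 1], , drop = FALSE]; p2 <- X[T4[, 2], , drop = FALSE]
  p3 <- X[T4[, 3], , drop = FALSE]; p4 <- X[T4[, 4], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- function(m) m / sqrt(rowSums(m * m))
  ## outward-ish normals of the 4 faces (sign irrelevant for dihedrals)
  n1 <- nrm(cr(p3 - p2, p4 - p2))  # face (2,3,4)
  n2 <- nrm(cr(p3 - p1, p4 - p1))  # face (1,3,4)
  n3 <- nrm(cr(p2 - p1, p4 - p1))  # face (1,2,4)
  n4 <- nrm(cr(p2 - p1, p3 - p1))  # face (1,2,3)
  ang <- function(a, b) {
    d <- pmin(1, pmax(-1, rowSums(a * b)))
    acos(abs(d)) * 180 / pi        # angle between face planes, in (0, 90]
  }
  dih <- pmin(ang(n1, n2), ang(n1, n3), ang(n1, n4),
              ang(n2, n3), ang(n2, n4), ang(n3, n4))
  list(n_nodes = nrow(X), n_elements = nrow(T4),
       min_volume = min(v), total_volume = sum(v),
       min_dihedral_deg = min(dih))
}

#' Volume of each tagged region of a mesh
#'
#' @param mesh an `fe_mesh`.
#' @return named numeric vector (mm^3), one entry per region present.
#' @export
region_volumes <- function(mesh) {
  v <- tet_volumes(mesh)
  out <- tapply(v, mesh$tag_names[mesh$tag], sum)
  out2 <- as.numeric(out); names(out2) <- names(out)
  out2
}

#' Structured box mesh (testing and verification workhorse)
#'
#' Meshes the box `[0, lx] x [0, ly] x [0, lz]` with `nx x ny x nz` cells,
#' using the same extrusion machinery as the anatomical mesher.
#'
#' @param lx,ly,lz box edge lengths (mm).
#' @param nx,ny,nz cell counts.
#' @param order 1 (TET4) or 2 (TET10).
#' @param tag_name region name for all elements.
#' @return an `fe_mesh`.
#' @export
box_mesh <- function(lx = 1, ly = 1, lz = 1, nx = 2L, ny = 2L, nz = 2L,
                     order = 1L, tag_name = "box") {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  nodes2d <- cbind(rep(xs, times = ny + 1L), rep(ys, each = nx + 1L))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
  quads <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  tris <- split_quads(quads, node2d_rank(nodes2d))
  zg <- seq(0, lz, length.out = nz + 1L)
  lt <- matrix(1L, nrow(tris), nz)
  m <- extrude_mesh(nodes2d, tris, zg, lt, tag_name)
  if (order == 2L) m <- to_tet10(m) else m
}
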