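# Small-strain isotropic elasticity on TET4/TET10 meshes with tension-only
# truss (ligament) elements.  Assembly is fully vectorised over elements;
# the factorisation of the all-ligaments-active stiffness is reused across
# active-set iterations through rank-one Woodbury downdates (each truss
# contributes a rank-one term (EA/L) a a^T).

lame_constants <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

## barycentric derivative table of the 10 quadratic shape functions
## at barycentric point L (length 4); rows: 4 corners then mid-sides
## (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)
tet10_dNdL <- function(L) {
  D <- matrix(0, 10, 4)
  for (i in 1:4) D[i, i] <- 4 * L[i] - 1
  ep <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) {
    i <- ep[e, 1]; j <- ep[e, 2]
    D[4 + e, i] <- 4 * L[j]
    D[4 + e, j] <- 4 * L[i]
  }
  D
}

## 4-point Gauss rule on the tetrahedron (degree-2 exact)
tet_gauss4 <- function() {
  a <- (5 + 3 * sqrt(5)) / 20
  b <- (5 - sqrt(5)) / 20
  pts <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(points = pts, weights = rep(1 / 4, 4))
}

## constant barycentric gradients (grad L_k) and volumes for all elements;
## returns list(g = list of four n x 3 matrices, vol = signed volumes)
corner_gradients <- function(nodes, tets) {
  x1 <- nodes[tets[, 1], , drop = FALSE]
  e2 <- nodes[tets[, 2], , drop = FALSE] - x1
  e3 <- nodes[tets[, 3], , drop = FALSE] - x1
  e4 <- nodes[tets[, 4], , drop = FALSE] - x1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c34 <- cr(e3, e4); c42 <- cr(e4, e2); c23 <- cr(e2, e3)
  V6 <- rowSums(e2 * c34)
  if (any(V6 <= 0)) stop("inverted element encountered during assembly")
  g2 <- c34 / V6; g3 <- c42 / V6; g4 <- c23 / V6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = V6 / 6)
}

#' Stiffness matrix of a single tetrahedral element
#'
#' Isotropic linear elasticity; `coords` is 4 x 3 (TET4) or 10 x 3 (TET10,
#' VTK node ordering, straight-sided).  The result is symmetric positive
#' semi-definite with exactly six rigid-body modes.
#'
#' @param coords node coordinate matrix.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return 12 x 12 or 30 x 30 stiffness matrix (N/mm).
#' @export
element_stiffness <- function(coords, E, nu) {
  nn <- nrow(coords)
  if (!nn %in% c(4L, 10L)) stop("coords must have 4 or 10 rows")
  cg <- corner_gradients(coords[1:4, , drop = FALSE], matrix(1:4, 1))
  if (cg$vol <= 0) stop("inverted element")
  lc <- lame_constants(E, nu)
  gmat <- do.call(rbind, lapply(cg$g, as.numeric))   # 4 x 3
  K <- matrix(0, 3 * nn, 3 * nn)
  if (nn == 4L) {
    gp_dNdL <- list(diag(4)); w <- cg$vol
  } else {
    gq <- tet_gauss4()
    gp_dNdL <- lapply(seq_len(4), function(k) tet10_dNdL(gq$points[k, ]))
    w <- gq$weights * cg$vol
  }
  for (k in seq_along(gp_dNdL)) {
    G <- gp_dNdL[[k]] %*% gmat                       # nn x 3 gradients
    for (a in seq_len(nn)) for (b in seq_len(nn)) {
      ga <- G[a, ]; gb <- G[b, ]
      blk <- lc$lambda * outer(ga, gb) + lc$mu * outer(gb, ga) +
        lc$mu * sum(ga * gb) * diag(3)
      ia <- 3 * (a - 1) + 1:3; ib <- 3 * (b - 1) + 1:3
      K[ia, ib] <- K[ia, ib] + w[k] * blk
    }
  }
  (K + t(K)) / 2
}

#' Assemble the global stiffness matrix of a mesh
#'
#' Vectorised over elements; returns a symmetric sparse matrix over the
#' 3 N displacement degrees of freedom (dof `3 (i - 1) + c` is component c
#' of node i).
#'
#' @param mesh an `fe_mesh`.
#' @param E,nu per-element material vectors (recycled if scalar).
#' @param elements optional element ids to assemble (a partial matrix of
#'   full dimension; used for incremental material changes).
#' @return a `dsCMatrix` stiffness matrix.
#' @export
assemble_stiffness <- function(mesh, E, nu, elements = NULL) {
  tets <- mesh$tets
  E <- rep_len(E, nrow(tets)); nu <- rep_len(nu, nrow(tets))
  if (!is.null(elements)) {
    tets <- tets[elements, , drop = FALSE]
    E <- E[elements]; nu <- nu[elements]
  }
  ne <- nrow(tets); nn <- ncol(tets)
  ## assemble big TET10 meshes in chunks to bound the triplet-array peak
  chunk <- max(1L, floor(8e6 / (3L * nn)^2))
  if (ne > chunk) {
    starts <- seq(1L, ne, by = chunk)
    K <- NULL
    for (s in starts) {
      ids <- s:min(s + chunk - 1L, ne)
      Kc <- assemble_stiffness_block(mesh$nodes, tets[ids, , drop = FALSE],
                                     E[ids], nu[ids])
      K <- if (is.null(K)) Kc else K + Kc
    }
    return(Matrix::forceSymmetric(K, uplo = "U"))
  }
  Matrix::forceSymmetric(assemble_stiffness_block(mesh$nodes, tets, E, nu),
                         uplo = "U")
}

## triplet assembly of one block of elements (symmetric matrix, full pattern)
assemble_stiffness_block <- function(nodes, tets, E, nu) {
  ne <- nrow(tets); nn <- ncol(tets)
  lc <- lame_constants(E, nu)
  cg <- corner_gradients(nodes, tets)
  vol <- cg$vol
  if (nn == 4L) {
    gps <- list(list(dNdL = diag(4), w = 1))
  } else {
    gq <- tet_gauss4()
    gps <- lapply(1:4, function(k)
      list(dNdL = tet10_dNdL(gq$points[k, ]), w = gq$weights[k]))
  }
  nd <- 3L * nn
  VAL <- matrix(0, ne, nd * nd)
  ## entry index for block (a,b), components (i,j):
  ## column ((3(b-1)+j) - 1) * nd + (3(a-1)+i)
  for (gp in gps) {
    dNdL <- gp$dNdL; w <- gp$w
    ## gradients of all shape functions: G[[a]] is ne x 3
    G <- vector("list", nn)
    for (a in seq_len(nn)) {
      Ga <- matrix(0, ne, 3)
      for (k in 1:4) if (dNdL[a, k] != 0)
        Ga <- Ga + dNdL[a, k] * cg$g[[k]]
      G[[a]] <- Ga
    }
    for (a in seq_len(nn)) for (b in seq_len(nn)) {
      S <- rowSums(G[[a]] * G[[b]])
      for (i in 1:3) for (j in 1:3) {
        v <- lc$lambda * G[[a]][, i] * G[[b]][, j] +
             lc$mu * G[[a]][, j] * G[[b]][, i]
        if (i == j) v <- v + lc$mu * S
        col <- (3L * (b - 1L) + j - 1L) * nd + 3L * (a - 1L) + i
        VAL[, col] <- VAL[, col] + (w * vol) * v
      }
    }
  }
  dof <- matrix(0L, ne, nd)
  for (a in seq_len(nn)) for (i in 1:3)
    dof[, 3L * (a - 1L) + i] <- 3L * (tets[, a] - 1L) + i
  ii <- dof[, rep(seq_len(nd), times = nd)]
  jj <- dof[, rep(seq_len(nd), each = nd)]
  ndof <- 3L * nrow(nodes)
  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(VAL), dims = c(ndof, ndof))
  (K + Matrix::t(K)) / 2
}

#' Stiffness matrix of a single truss (tension-only ligament) element
#'
#' Axial stiffness `E A / L` along the element axis when active, the zero
#' matrix when inactive.
#'
#' @param x1,x2 end-point coordinates (length-3).
#' @param E Young's modulus (MPa).
#' @param area cross-sectional area (mm^2).
#' @param active logical.
#' @return 6 x 6 stiffness matrix (dofs: node 1 xyz, node 2 xyz).
#' @export
truss_stiffness <- function(x1, x2, E, area, active = TRUE) {
  d <- x2 - x1
  L <- sqrt(sum(d * d))
  if (L < 1e-12) stop("coincident truss end points")
  if (!active) return(matrix(0, 6, 6))
  n <- d / L
  k <- E * area / L
  nn <- k * outer(n, n)
  rbind(cbind(nn, -nn), cbind(-nn, nn))
}

## axial direction vectors, lengths and stiffnesses for a truss table
truss_geometry <- function(nodes, trusses) {
  d <- nodes[trusses$j, , drop = FALSE] - nodes[trusses$i, , drop = FALSE]
  L <- sqrt(rowSums(d * d))
  if (any(L < 1e-12)) stop("coincident truss end points")
  list(n = d / L, L = L, k = trusses$E * trusses$area / L)
}

## sparse (ndof x ntruss) matrix whose column t satisfies
## elongation_t = a_t' u ; stiffness contribution of truss t = k_t a_t a_t'
truss_axial_matrix <- function(nodes, trusses, tg) {
  nt <- nrow(trusses)
  ii <- c(3 * (trusses$i - 1) + 1, 3 * (trusses$i - 1) + 2, 3 * (trusses$i - 1) + 3,
          3 * (trusses$j - 1) + 1, 3 * (trusses$j - 1) + 2, 3 * (trusses$j - 1) + 3)
  jj <- rep(seq_len(nt), 6)
  xx <- c(-tg$n[, 1], -tg$n[, 2], -tg$n[, 3], tg$n[, 1], tg$n[, 2], tg$n[, 3])
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(3 * nrow(nodes), nt))
}

#' Rigid coupling of a node set to a reference point
#'
#' Builds the multi-point-constraint transformation that ties every node of
#' `node_ids` rigidly to a six-dof reference at `ref_point` (small-rotation
#' kinematics, `u_s = u_ref + theta x r_s`).  Used to apply pure moments to
#' the superior surface through a rigid platen.
#'
#' @param mesh an `fe_mesh`.
#' @param node_ids nodes to couple (corner and/or mid-side).
#' @param ref_point length-3 reference location; defaults to the centroid of
#'   the coupled nodes.
#' @return list with sparse transformation `T` (full dofs x reduced dofs),
#'   `full2red` (NA for slave dofs), `master` (the six reference dof columns)
#'   and `ref_point`.
#' @export
build_rigid_coupling <- function(mesh, node_ids, ref_point = NULL) {
  node_ids <- sort(unique(node_ids))
  if (length(node_ids) < 3L) stop("rigid coupling needs at least 3 nodes")
  X <- mesh$nodes[node_ids, , drop = FALSE]
  if (is.null(ref_point)) ref_point <- colMeans(X)
  ## collinearity check
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(svd(Xc, nu = 0, nv = 0)$d > 1e-9) < 2L)
    stop("coupled surface nodes are collinear")
  ndof <- 3L * nrow(mesh$nodes)
  slave <- as.vector(t(outer(3L * (node_ids - 1L), 1:3, `+`)))
  keep <- setdiff(seq_len(ndof), slave)
  nred <- length(keep) + 6L
  full2red <- rep(NA_integer_, ndof)
  full2red[keep] <- seq_along(keep)
  master <- length(keep) + 1:6
  r <- sweep(X, 2, ref_point)
  ## u_s = u_ref + theta x r :
  ## ux = uX + thY rz - thZ ry ; uy = uY + thZ rx - thX rz ; uz = uZ + thX ry - thY rx
  ns <- length(node_ids)
  rowx <- 3L * (node_ids - 1L) + 1L
  rowy <- 3L * (node_ids - 1L) + 2L
  rowz <- 3L * (node_ids - 1L) + 3L
  ii <- c(keep,
          rowx, rowx, rowx,
          rowy, rowy, rowy,
          rowz, rowz, rowz)
  jj <- c(seq_along(keep),
          rep(master[1], ns), rep(master[5], ns), rep(master[6], ns),
          rep(master[2], ns), rep(master[6], ns), rep(master[4], ns),
          rep(master[3], ns), rep(master[4], ns), rep(master[5], ns))
  xx <- c(rep(1, length(keep)),
          rep(1, ns),  r[, 3], -r[, 2],
          rep(1, ns),  r[, 1], -r[, 3],
          rep(1, ns),  r[, 2], -r[, 1])
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, nred))
  list(T = T, full2red = full2red, master = master, ref_point = ref_point,
       node_ids = node_ids)
}

#' Prepare a reusable solver context
#'
#' Applies the rigid coupling and fixed constraints to the stiffness matrix,
#' adds all truss elements at full stiffness, and computes one sparse
#' Cholesky factorisation.  The context can then solve many load cases; the
#' tension-only active-set iteration never refactorises because deactivating
#' a truss is a rank-one Woodbury downdate of the factored operator.
#'
#' @param K sparse symmetric solid stiffness (from [assemble_stiffness]).
#' @param fixed_dofs integer dof ids constrained to zero.
#' @param trusses optional data frame with columns `i`, `j`, `E`, `area`
#'   (tension-only elements).
#' @param nodes node coordinates (needed when `trusses` or `springs` is
#'   given).
#' @param coupling optional result of [build_rigid_coupling].
#' @param springs optional data frame like `trusses` describing bilateral
#'   axial springs (always active; e.g. the facet normal-contact layer).
#' @return an `fe_context`.
#' @export
fe_context <- function(K, fixed_dofs, trusses = NULL, nodes = NULL,
                       coupling = NULL, springs = NULL) {
  if (!is.null(springs) && nrow(springs) > 0L) {
    if (is.null(nodes)) stop("nodes required with springs")
    if (all(c("ax", "ay", "az", "k") %in% names(springs))) {
      ## directional springs: explicit axis and stiffness
      d <- as.matrix(springs[, c("ax", "ay", "az")])
      d <- d / sqrt(rowSums(d * d))
      ns <- nrow(springs)
      ii <- c(3 * (springs$i - 1) + 1, 3 * (springs$i - 1) + 2,
              3 * (springs$i - 1) + 3,
              3 * (springs$j - 1) + 1, 3 * (springs$j - 1) + 2,
              3 * (springs$j - 1) + 3)
      jj <- rep(seq_len(ns), 6)
      xx <- c(-d[, 1], -d[, 2], -d[, 3], d[, 1], d[, 2], d[, 3])
      As <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(3 * nrow(nodes), ns))
      K <- K + As %*% Matrix::Diagonal(x = springs$k) %*% Matrix::t(As)
    } else {
      sg <- truss_geometry(nodes, springs)
      As <- truss_axial_matrix(nodes, springs, sg)
      K <- K + As %*% Matrix::Diagonal(x = sg$k) %*% Matrix::t(As)
    }
  }
  has_trusses <- !is.null(trusses) && nrow(trusses) > 0L
  if (has_trusses) {
    if (is.null(nodes)) stop("nodes required with trusses")
    tg <- truss_geometry(nodes, trusses)
    ## sense: +1 = tension-only (ligaments), -1 = compression-only (bony stops)
    tg$sense <- if ("sense" %in% names(trusses)) trusses$sense else rep(1, nrow(trusses))
    A <- truss_axial_matrix(nodes, trusses, tg)
    K0 <- K + A %*% Matrix::Diagonal(x = tg$k) %*% Matrix::t(A)
  } else {
    tg <- NULL; A <- NULL; K0 <- K
  }
  if (!is.null(coupling)) {
    T <- coupling$T
    if (anyNA(coupling$full2red[fixed_dofs]))
      stop("cannot fix a dof that is slaved to the rigid coupling")
    Kr <- Matrix::forceSymmetric(Matrix::t(T) %*% K0 %*% T)
    fixed_red <- coupling$full2red[fixed_dofs]
  } else {
    T <- NULL
    Kr <- Matrix::forceSymmetric(K0)
    fixed_red <- fixed_dofs
  }
  nred <- nrow(Kr)
  free <- setdiff(seq_len(nred), fixed_red)
  if (length(free) == 0L) stop("no free degrees of freedom")
  Kff <- Kr[free, free, drop = FALSE]
  Ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("stiffness matrix is singular after constraints ",
                        "(insufficient supports?): ", conditionMessage(e)))
  Af <- NULL; W <- NULL; G <- NULL; U <- NULL
  if (has_trusses) {
    Ar <- if (is.null(T)) A else Matrix::t(T) %*% A
    Af <- Ar[free, , drop = FALSE]
    ## precompute the Woodbury columns once: deactivating truss t is a
    ## rank-one downdate by U[, t]; W = K0^-1 U and G = U' W are reused by
    ## every load case and every active-set iteration
    U <- Af %*% Matrix::Diagonal(x = sqrt(tg$k))
    W <- as.matrix(Matrix::solve(Ch, as.matrix(U), system = "A"))
    G <- as.matrix(Matrix::t(U) %*% W)
    gc(FALSE)
  }
  structure(list(K0 = K0, T = T, coupling = coupling, free = free,
                 fixed_red = fixed_red, nred = nred, Ch = Ch,
                 A = A, Af = Af, U = U, W = W, G = G, tg = tg,
                 trusses = trusses, has_trusses = has_trusses),
            class = "fe_context")
}

#' Solve one load case on a prepared context
#'
#' @param ctx an [fe_context].
#' @param f full-length nodal force vector.
#' @param master_load optional length-6 load (Fx,Fy,Fz,Mx,My,Mz) at the
#'   rigid-coupling reference point.
#' @param active_init warm-start active set for the tension-only iteration.
#' @param max_iter active-set iteration cap.
#' @return an `fe_solution` (see [fe_solve]).
#' @export
fe_solve_ctx <- function(ctx, f, master_load = NULL, active_init = NULL,
                         max_iter = 50L) {
  T <- ctx$T
  if (!is.null(T)) {
    fr <- as.numeric(Matrix::t(T) %*% f)
    if (!is.null(master_load))
      fr[ctx$coupling$master] <- fr[ctx$coupling$master] + master_load
  } else {
    if (!is.null(master_load)) stop("master_load requires a coupling")
    fr <- f
  }
  free <- ctx$free
  rhs <- fr[free]
  solve0 <- function(b) as.matrix(Matrix::solve(ctx$Ch, b, system = "A"))
  ured <- numeric(ctx$nred)
  if (!ctx$has_trusses) {
    ured[free] <- solve0(cbind(rhs))[, 1]
    ufull <- if (is.null(T)) ured else as.numeric(T %*% ured)
    active <- logical(0); tforce <- numeric(0); iter <- 1L
    Keff <- ctx$K0
  } else {
    nt <- nrow(ctx$trusses)
    active <- if (is.null(active_init)) rep(TRUE, nt) else active_init
    seen <- character(0)
    iter <- 0L
    x0 <- solve0(cbind(rhs))[, 1]
    ux0 <- as.numeric(Matrix::t(ctx$U) %*% x0)
    repeat {
      iter <- iter + 1L
      inact <- which(!active)
      if (length(inact) == 0L) {
        uf <- x0
      } else {
        M <- diag(length(inact)) - ctx$G[inact, inact, drop = FALSE]
        y <- solve(M, ux0[inact])
        uf <- x0 + as.numeric(ctx$W[, inact, drop = FALSE] %*% y)
      }
      ured[free] <- uf
      ufull <- if (is.null(T)) ured else as.numeric(T %*% ured)
      elong <- as.numeric(Matrix::t(ctx$A) %*% ufull)
      new_active <- ctx$tg$sense * elong > 0
      if (identical(new_active, active)) break
      sig <- paste(as.integer(new_active), collapse = "")
      if (iter >= max_iter || sig %in% seen) {
        osc <- which(new_active != active)
        stop("tension-only iteration did not converge; oscillating trusses: ",
             paste(osc, collapse = ", "))
      }
      seen <- c(seen, sig)
      active <- new_active
    }
    tforce <- ifelse(active, ctx$tg$k * elong, 0)
    Keff <- ctx$K0
    if (any(!active)) {
      inact <- which(!active)
      Ai <- ctx$A[, inact, drop = FALSE]
      Keff <- ctx$K0 - Ai %*% Matrix::Diagonal(x = ctx$tg$k[inact]) %*%
        Matrix::t(Ai)
    }
  }
  reactions <- as.numeric(Keff %*% ufull) - f
  structure(list(u = ufull, truss_force = tforce, active = active,
                 iterations = iter, reactions = reactions),
            class = "fe_solution")
}

#' Solve the constrained linear-elastic system
#'
#' One-shot interface over [fe_context]/[fe_solve_ctx].  With tension-only
#' trusses present, a fixed-point active-set iteration is run: all trusses
#' start active; after each solve, compressed trusses are deactivated and
#' stretched ones reactivated, until the active set is stable.  Non-zero
#' prescribed displacements are supported for truss-free systems (patch
#' tests and the like).
#'
#' @param K sparse symmetric solid stiffness (from [assemble_stiffness]).
#' @param f full-length nodal force vector.
#' @param fixed_dofs integer dof ids with prescribed displacement.
#' @param fixed_values prescribed values (recycled; tension-only iteration
#'   requires all zero).
#' @param trusses optional data frame with columns `i`, `j`, `E`, `area`.
#' @param nodes node coordinates (needed when `trusses` is given).
#' @param coupling optional result of [build_rigid_coupling].
#' @param master_load length-6 load (Fx,Fy,Fz,Mx,My,Mz) applied at the
#'   coupling reference point.
#' @param max_iter active-set iteration cap.
#' @return an `fe_solution` list: `u` (full displacement vector),
#'   `truss_force` (axial forces, N), `active` (logical per truss),
#'   `iterations`, `reactions` (K u - f over all dofs, nonzero at
#'   constraints).
#' @export
fe_solve <- function(K, f, fixed_dofs, fixed_values = 0, trusses = NULL,
                     nodes = NULL, coupling = NULL, master_load = NULL,
                     max_iter = 50L) {
  fixed_values <- rep_len(fixed_values, length(fixed_dofs))
  if (any(fixed_values != 0)) {
    if (!is.null(trusses) && nrow(trusses) > 0L)
      stop("tension-only iteration requires homogeneous constraints")
    if (!is.null(coupling)) stop("prescribed values not supported with coupling")
    free <- setdiff(seq_len(nrow(K)), fixed_dofs)
    Kff <- K[free, free, drop = FALSE]
    rhs <- f[free] - as.numeric(K[free, fixed_dofs, drop = FALSE] %*% fixed_values)
    Ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                                    super = TRUE),
                   error = function(e)
                     stop("stiffness matrix is singular after constraints ",
                          "(insufficient supports?): ", conditionMessage(e)))
    u <- numeric(nrow(K))
    u[fixed_dofs] <- fixed_values
    u[free] <- as.matrix(Matrix::solve(Ch, cbind(rhs), system = "A"))[, 1]
    return(structure(list(u = u, truss_force = numeric(0), active = logical(0),
                          iterations = 1L,
                          reactions = as.numeric(K %*% u) - f),
                     class = "fe_solution"))
  }
  ctx <- fe_context(K, fixed_dofs, trusses = trusses, nodes = nodes,
                    coupling = coupling)
  fe_solve_ctx(ctx, f, master_load = master_load, max_iter = max_iter)
}

#' Recover element stresses and von Mises values
#'
#' Stress is evaluated at the element centroid (for TET10 this equals the
#' average over the four Gauss points of a straight-sided element), which
#' keeps the reported maxima well-defined.
#'
#' @param mesh an `fe_mesh`.
#' @param u full displacement vector.
#' @param E,nu per-element material vectors.
#' @return list with `stress` (n x 6 matrix, order xx,yy,zz,xy,yz,zx) and
#'   `vms` (von Mises stress per element, MPa).
#' @export
recover_stress <- function(mesh, u, E, nu) {
  tets <- mesh$tets
  ne <- nrow(tets); nn <- ncol(tets)
  E <- rep_len(E, ne); nu <- rep_len(nu, ne)
  lc <- lame_constants(E, nu)
  cg <- corner_gradients(mesh$nodes, tets)
  if (nn == 4L) dNdL <- diag(4) else dNdL <- tet10_dNdL(rep(1 / 4, 4))
  ux <- matrix(u[3 * (tets - 1) + 1], ne, nn)
  uy <- matrix(u[3 * (tets - 1) + 2], ne, nn)
  uz <- matrix(u[3 * (tets - 1) + 3], ne, nn)
  exx <- eyy <- ezz <- gxy <- gyz <- gzx <- numeric(ne)
  for (a in seq_len(nn)) {
    Ga <- matrix(0, ne, 3)
    for (k in 1:4) if (dNdL[a, k] != 0) Ga <- Ga + dNdL[a, k] * cg$g[[k]]
    exx <- exx + Ga[, 1] * ux[, a]
    eyy <- eyy + Ga[, 2] * uy[, a]
    ezz <- ezz + Ga[, 3] * uz[, a]
    gxy <- gxy + Ga[, 2] * ux[, a] + Ga[, 1] * uy[, a]
    gyz <- gyz + Ga[, 3] * uy[, a] + Ga[, 2] * uz[, a]
    gzx <- gzx + Ga[, 1] * uz[, a] + Ga[, 3] * ux[, a]
  }
  tr <- exx + eyy + ezz
  sxx <- lc$lambda * tr + 2 * lc$mu * exx
  syy <- lc$lambda * tr + 2 * lc$mu * eyy
  szz <- lc$lambda * tr + 2 * lc$mu * ezz
  sxy <- lc$mu * gxy; syz <- lc$mu * gyz; szx <- lc$mu * gzx
  stress <- cbind(xx = sxx, yy = syy, zz = szz, xy = sxy, yz = syz, zx = szx)
  list(stress = stress, vms = von_mises(stress))
}

#' von Mises equivalent stress
#'
#' `sqrt(((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2)/2 + 3 (s12^2+s23^2+s31^2))`.
#'
#' @param stress either a symmetric 3 x 3 tensor, a length-6 vector, or an
#'   n x 6 matrix in the order (xx, yy, zz, xy, yz, zx).
#' @return nonnegative scalar or vector (MPa).
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && nrow(stress) == 3L && ncol(stress) == 3L) {
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      stop("stress tensor must be symmetric")
    stress <- matrix(c(stress[1, 1], stress[2, 2], stress[3, 3],
                       stress[1, 2], stress[2, 3], stress[3, 1]), 1)
  } else if (!is.matrix(stress)) {
    stress <- matrix(stress, ncol = 6L)
  }
  s <- stress
  out <- sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
                     (s[, 3] - s[, 1])^2) +
              3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
  if (length(out) == 1L) as.numeric(out) else out
}
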