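# Elasticity core: element matrices, patch tests, von Mises closed forms,
# truss elements, tension-only active set vs brute force, equilibrium.

test_that("von Mises closed-form cases", {
  expect_equal(von_mises(c(10, 0, 0, 0, 0, 0)), 10, tolerance = 1e-12)
  expect_equal(von_mises(diag(3) * 7.3), 0, tolerance = 1e-12)
  expect_equal(von_mises(c(0, 0, 0, 5, 0, 0)), 5 * sqrt(3), tolerance = 1e-12)
  ## matrix input, vectorised
  S <- rbind(c(10, 0, 0, 0, 0, 0), c(3, 3, 3, 0, 0, 0), c(0, 0, 0, 0, 2, 0))
  expect_equal(von_mises(S), c(10, 0, 2 * sqrt(3)), tolerance = 1e-12)
  expect_error(von_mises(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)), "symmetric")
})

test_that("element stiffness is symmetric with exactly six rigid-body modes", {
  set.seed(42)
  for (order in c(4L, 10L)) {
    X4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) +
      matrix(rnorm(12, 0, 0.05), 4)
    X <- if (order == 4L) X4 else {
      ep <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
      rbind(X4, (X4[ep[, 1], ] + X4[ep[, 2], ]) / 2)
    }
    K <- element_stiffness(X, 1200, 0.3)
    expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
    ## rigid translation produces no force
    u <- rep(c(1, -2, 3), order)
    expect_lt(max(abs(K %*% u)), 1e-10 * max(abs(K)))
  }
})

test_that("constant-strain patch test recovers the analytic stress field", {
  A <- rbind(c(1e-3, 2e-4, 0), c(2e-4, -5e-4, 1e-4), c(0, 1e-4, 3e-4))
  eps <- (A + t(A)) / 2
  E <- 180; nu <- 0.33
  lc <- svfem:::lame_constants(E, nu)
  sex <- lc$lambda * sum(diag(eps)) * diag(3) + 2 * lc$mu * eps
  sexv <- c(sex[1, 1], sex[2, 2], sex[3, 3], sex[1, 2], sex[2, 3], sex[3, 1])
  for (ord in c(1L, 2L)) {
    m <- box_mesh(1, 1, 1, 2L, 2L, 2L, order = ord)
    K <- assemble_stiffness(m, E, nu)
    uex <- as.vector(t(m$nodes %*% t(A)))
    bnd <- which(apply(m$nodes, 1, function(p)
      any(abs(p) < 1e-12 | abs(p - 1) < 1e-12)))
    fd <- as.vector(t(outer(3 * (bnd - 1), 1:3, `+`)))
    sol <- fe_solve(K, rep(0, nrow(K)), fd, uex[fd])
    expect_lt(max(abs(sol$u - uex)), 1e-12)
    st <- recover_stress(m, sol$u, E, nu)
    err <- max(abs(sweep(st$stress, 2, sexv))) / max(abs(sexv))
    expect_lt(err, 1e-8)
  }
})

test_that("slender cantilever tip deflection matches beam theory within 2%", {
  E <- 1000; P <- 1
  m <- box_mesh(10, 10, 100, 4L, 4L, 40L, order = 2L)
  K <- assemble_stiffness(m, E, 0.0)
  base <- which(abs(m$nodes[, 3]) < 1e-9)
  tip <- which(abs(m$nodes[, 3] - 100) < 1e-9)
  fd <- as.vector(t(outer(3 * (base - 1), 1:3, `+`)))
  f <- rep(0, nrow(K)); f[3 * (tip - 1) + 1] <- P / length(tip)
  sol <- fe_solve(K, f, fd)
  delta <- mean(sol$u[3 * (tip - 1) + 1])
  I <- 10 * 10^3 / 12
  expect_equal(delta, P * 100^3 / (3 * E * I), tolerance = 0.02)
  ## global equilibrium: reactions balance the applied load
  expect_lt(abs(sum(sol$reactions[fd[seq(1, length(fd), 3)]]) + P), 1e-8 * P)
})

test_that("truss stiffness is EA/L along the axis, zero when inactive", {
  K <- truss_stiffness(c(0, 0, 0), c(0, 0, 10), E = 20, area = 65)
  expect_equal(K[3, 3], 130)                  # published ALL properties
  expect_equal(K[3, 9 - 3], -130)
  expect_equal(K[1, 1], 0)                    # only z-z block nonzero
  expect_equal(K[2, 2], 0)
  expect_equal(truss_stiffness(c(0, 0, 0), c(1, 1, 1), 20, 65, active = FALSE),
               matrix(0, 6, 6))
  expect_error(truss_stiffness(c(1, 2, 3), c(1, 2, 3), 20, 65), "coincident")
})

test_that("a truss above a compressed block deactivates with zero force", {
  m <- box_mesh(10, 10, 10, 2L, 2L, 2L, order = 1L)
  K <- assemble_stiffness(m, 100, 0.3)
  base <- which(abs(m$nodes[, 3]) < 1e-9)
  top <- which(abs(m$nodes[, 3] - 10) < 1e-9)
  pick <- function(set) set[which.min(rowSums(sweep(m$nodes[set, , drop = FALSE],
                                                    2, c(5, 5, 0))^2))]
  tr <- data.frame(i = pick(base), j = pick(top), E = 20, area = 65)
  fd <- as.vector(t(outer(3 * (base - 1), 1:3, `+`)))
  f <- rep(0, nrow(K)); f[3 * (top - 1) + 3] <- -100 / length(top)
  sol <- fe_solve(K, f, fd, trusses = tr, nodes = m$nodes)
  expect_false(sol$active)
  expect_equal(sol$truss_force, 0)
  ## pulled up instead: the truss is active and the solution matches a plain
  ## linear solve with the truss permanently in the stiffness
  sol2 <- fe_solve(K, -f, fd, trusses = tr, nodes = m$nodes)
  expect_true(sol2$active)
  dof <- c(3 * (tr$i - 1) + 1:3, 3 * (tr$j - 1) + 1:3)
  Kt <- K
  Kt[dof, dof] <- Kt[dof, dof] +
    truss_stiffness(m$nodes[tr$i, ], m$nodes[tr$j, ], tr$E, tr$area)
  ref <- fe_solve(Kt, -f, fd)
  expect_lt(max(abs(sol2$u - ref$u)), 1e-12 * max(abs(ref$u)))
})

test_that("tension-only active set matches brute-force enumeration", {
  sys <- toy_truss_system(nt = 4L)
  loads <- list(c(60, 0, -30), c(-40, 25, 10), c(0, -50, 40), c(15, 15, 25))
  for (ld in loads) {
    f <- rep(0, nrow(sys$K))
    f[3 * (sys$top - 1) + 1] <- ld[1] / length(sys$top)
    f[3 * (sys$top - 1) + 2] <- ld[2] / length(sys$top)
    f[3 * (sys$top - 1) + 3] <- ld[3] / length(sys$top)
    sol <- fe_solve(sys$K, f, sys$fixed, trusses = sys$trusses,
                    nodes = sys$mesh$nodes)
    oracle <- brute_force_active_set(sys, f)
    expect_identical(unname(sol$active), unname(oracle$active))
    expect_lt(max(abs(sol$u - oracle$u)), 1e-9 * max(abs(oracle$u), 1e-12))
  }
})

test_that("compression-only elements engage under closing gaps only", {
  m <- box_mesh(10, 10, 10, 2L, 2L, 2L, order = 1L)
  K <- assemble_stiffness(m, 100, 0.3)
  base <- which(abs(m$nodes[, 3]) < 1e-9)
  top <- which(abs(m$nodes[, 3] - 10) < 1e-9)
  pick <- function(set) set[which.min(rowSums(sweep(m$nodes[set, , drop = FALSE],
                                                    2, c(5, 5, 0))^2))]
  tr <- data.frame(i = pick(base), j = pick(top), E = 20, area = 65, sense = -1)
  fd <- as.vector(t(outer(3 * (base - 1), 1:3, `+`)))
  f <- rep(0, nrow(K)); f[3 * (top - 1) + 3] <- -100 / length(top)
  sol <- fe_solve(K, f, fd, trusses = tr, nodes = m$nodes)
  expect_true(sol$active)                     # compression engages the stop
  expect_lt(sol$truss_force, 0)
  sol2 <- fe_solve(K, -f, fd, trusses = tr, nodes = m$nodes)
  expect_false(sol2$active)                   # tension releases it
})

test_that("an unconstrained system reports a singular matrix", {
  m <- box_mesh(1, 1, 1, 1L, 1L, 1L)
  K <- assemble_stiffness(m, 10, 0.3)
  expect_error(fe_solve(K, rep(0, nrow(K)), integer(0)), "singular")
})

test_that("stiffened elements store more energy under the same imposed displacement", {
  m <- box_mesh(10, 10, 10, 2L, 2L, 2L, order = 1L)
  bot <- which(abs(m$nodes[, 3]) < 1e-9)
  top <- which(abs(m$nodes[, 3] - 10) < 1e-9)
  fd <- c(as.vector(t(outer(3 * (bot - 1), 1:3, `+`))), 3 * (top - 1) + 3)
  fv <- c(rep(0, 3 * length(bot)), rep(-0.1, length(top)))
  energy <- function(E_core) {
    cz <- (m$nodes[m$tets[, 1], 3] + m$nodes[m$tets[, 2], 3] +
           m$nodes[m$tets[, 3], 3] + m$nodes[m$tets[, 4], 3]) / 4
    Ev <- ifelse(cz > 2.5 & cz < 7.5, E_core, 100)
    K <- assemble_stiffness(m, Ev, 0.3)
    sol <- fe_solve(K, rep(0, nrow(K)), fd, fv)
    0.5 * sum(sol$u * as.numeric(K %*% sol$u))
  }
  e_soft <- energy(34)      # cancellous-like core
  e_stiff <- energy(3000)   # cement-like core
  ## stiffening raises the energy needed to impose the same displacement,
  ## i.e. compliance decreases monotonically
  expect_gt(e_stiff, e_soft)
})

test_that("rigid coupling applies a pure moment through a platen", {
  m <- box_mesh(10, 10, 20, 2L, 2L, 4L, order = 1L)
  K <- assemble_stiffness(m, 500, 0.3)
  base <- which(abs(m$nodes[, 3]) < 1e-9)
  top <- which(abs(m$nodes[, 3] - 20) < 1e-9)
  fd <- as.vector(t(outer(3 * (base - 1), 1:3, `+`)))
  cpl <- build_rigid_coupling(m, top)
  sol <- fe_solve(K, rep(0, nrow(K)), fd, coupling = cpl,
                  master_load = c(0, 0, 0, 0, 1000, 0))
  ## coupled surface moves as one linearised rigid body: u = u0 + theta x r
  ## must fit the slave displacements exactly
  ids <- top
  X <- m$nodes[ids, ]
  U <- cbind(sol$u[3 * (ids - 1) + 1], sol$u[3 * (ids - 1) + 2],
             sol$u[3 * (ids - 1) + 3])
  r <- sweep(X, 2, colMeans(X))
  ns <- nrow(X)
  A <- matrix(0, 3 * ns, 6)
  for (k in seq_len(ns)) {
    A[3 * k - 2, ] <- c(1, 0, 0, 0, r[k, 3], -r[k, 2])
    A[3 * k - 1, ] <- c(0, 1, 0, -r[k, 3], 0, r[k, 1])
    A[3 * k, ]     <- c(0, 0, 1, r[k, 2], -r[k, 1], 0)
  }
  fit <- qr.solve(A, as.vector(t(U)))
  resid <- max(abs(A %*% fit - as.vector(t(U))))
  expect_lt(resid, 1e-10)
  ## reactions balance the applied couple
  react <- matrix(sol$reactions, ncol = 3, byrow = TRUE)
  mom_y <- sum(react[base, 3] * m$nodes[base, 1] * (-1) +
               react[base, 1] * m$nodes[base, 3])
  expect_equal(-mom_y, 1000, tolerance = 1e-6)
  expect_error(build_rigid_coupling(m, top[1:2]), "at least 3")
})
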