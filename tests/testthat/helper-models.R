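# Shared fixtures: small meshes, toy tension-only systems and independent
# oracles.  Everything is built in code; heavyweight models are cached per
# session so several test files can share them.

## coarse study configuration for fast structural tests (not the calibrated
## density; used only where absolute accuracy is irrelevant)
coarse_config <- function(...) {
  run_config(mesh_edge = 8, cartilage_edge = 3,
             posterior = posterior_params(pedicle_sectors = 2), ...)
}

## session cache for expensive models
.svfem_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .svfem_cache)) {
    assign(key, force(expr), envir = .svfem_cache)
  }
  get(key, envir = .svfem_cache)
}

## small elastic block with nt attachable trusses on top, used by the
## tension-only brute-force comparisons
toy_truss_system <- function(nt = 4L, E_block = 100, seed_load = c(1, 0, 0)) {
  m <- box_mesh(10, 10, 10, 2L, 2L, 2L, order = 1L)
  K <- assemble_stiffness(m, E_block, 0.3)
  top <- which(abs(m$nodes[, 3] - 10) < 1e-9)
  base <- which(abs(m$nodes[, 3]) < 1e-9)
  ## trusses from distinct top nodes down to distinct base nodes (diagonal
  ## axes so several load directions produce mixed tension/compression)
  it <- top[seq_len(nt)]
  jb <- base[nt + seq_len(nt)]
  tr <- data.frame(i = jb, j = it, E = 50, area = 2 + seq_len(nt))
  fixed <- as.vector(t(outer(3 * (base - 1), 1:3, `+`)))
  list(mesh = m, K = K, trusses = tr, fixed = fixed, top = top)
}

## independent oracle: enumerate all active subsets, solve each, return the
## subset satisfying both sign conditions (tension in active, no stretch in
## inactive)
brute_force_active_set <- function(sys, f, tol = 1e-9) {
  nt <- nrow(sys$trusses)
  nodes <- sys$mesh$nodes
  dirs <- (nodes[sys$trusses$j, ] - nodes[sys$trusses$i, ])
  L <- sqrt(rowSums(dirs^2)); dirs <- dirs / L
  kt <- sys$trusses$E * sys$trusses$area / L
  elong <- function(u) {
    du <- cbind(u[3 * (sys$trusses$j - 1) + 1] - u[3 * (sys$trusses$i - 1) + 1],
                u[3 * (sys$trusses$j - 1) + 2] - u[3 * (sys$trusses$i - 1) + 2],
                u[3 * (sys$trusses$j - 1) + 3] - u[3 * (sys$trusses$i - 1) + 3])
    rowSums(du * dirs)
  }
  for (code in 0:(2^nt - 1L)) {
    S <- as.logical(bitwAnd(code, 2^(seq_len(nt) - 1L)))
    Kt <- sys$K
    for (t in which(S)) {
      dof <- c(3 * (sys$trusses$i[t] - 1) + 1:3, 3 * (sys$trusses$j[t] - 1) + 1:3)
      a <- c(-dirs[t, ], dirs[t, ])
      Kt[dof, dof] <- Kt[dof, dof] + kt[t] * outer(a, a)
    }
    sol <- tryCatch(fe_solve(Kt, f, sys$fixed), error = function(e) NULL)
    if (is.null(sol)) next
    e <- elong(sol$u)
    scale <- max(abs(e), 1e-12)
    if (all(e[S] >= -tol * scale) && all(e[!S] <= tol * scale))
      return(list(active = S, u = sol$u, elong = e))
  }
  stop("no admissible active set found by enumeration")
}

## shared default-density models for the acceptance suite
acceptance_model <- function() {
  cached("acc_model", prepare_model(run_config()))
}
acceptance_matrix <- function() {
  cached("acc_matrix", {
    model <- acceptance_model()
    run_matrix(run_config(), model = model)
  })
}
acceptance_validation <- function() {
  cached("acc_validation", {
    model <- acceptance_model()
    run_validation(run_config(), model = model, preload = 0)
  })
}
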