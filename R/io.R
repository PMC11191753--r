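# Mesh, field and configuration IO: ASCII VTU (VTK unstructured grid),
# Gmsh MSH 4.1, per-region ASCII STL, and YAML run configurations.

#' Write a mesh (and optional fields) as an ASCII VTU file
#'
#' @param mesh an `fe_mesh`.
#' @param file output path (conventionally `.vtu`).
#' @param point_data named list of per-node vectors (length N) or matrices
#'   (N x 3, e.g. displacement).
#' @param cell_data named list of per-element vectors (e.g. von Mises
#'   stress); the region tag is always written.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(mesh, file, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  nn <- ncol(mesh$tets)
  ctype <- if (nn == 10L) 24L else 10L
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w("          ", num(t(mesh$nodes)))
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  w("          ", paste(t(mesh$tets) - 1L, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  w("          ", paste(seq_len(ne) * nn, collapse = " "))
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  w("          ", paste(rep(ctype, ne), collapse = " "))
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(point_data)) {
    d <- point_data[[nm]]
    nc <- if (is.matrix(d)) ncol(d) else 1L
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              nm, nc))
    w("          ", num(if (is.matrix(d)) t(d) else d))
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('      <CellData>')
  cell_data$region <- mesh$tag
  for (nm in names(cell_data)) {
    w(sprintf('        <DataArray type="Float64" Name="%s" NumberOfComponents="1" format="ascii">',
              nm))
    w("          ", num(cell_data[[nm]]))
    w('        </DataArray>')
  }
  w('      </CellData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Write a mesh in Gmsh MSH 4.1 ASCII format
#'
#' One entity per region; region tags become physical groups.
#'
#' @param mesh an `fe_mesh`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_msh <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  n <- nrow(mesh$nodes)
  etype <- if (ncol(mesh$tets) == 10L) 11L else 4L
  regions <- sort(unique(mesh$tag))
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w(length(regions))
  for (r in regions) w(sprintf('3 %d "%s"', r, mesh$tag_names[r]))
  w("$EndPhysicalNames")
  w("$Entities")
  w(sprintf("0 0 0 %d", length(regions)))
  for (r in regions) w(sprintf("%d 0 0 0 1 1 1 1 %d", r, r))
  w("$EndEntities")
  w("$Nodes")
  w(sprintf("1 %d 1 %d", n, n))
  w(sprintf("3 %d 0 %d", regions[1], n))
  w(paste(seq_len(n)))
  w(sprintf("%.10g %.10g %.10g", mesh$nodes[, 1], mesh$nodes[, 2],
            mesh$nodes[, 3]))
  w("$EndNodes")
  w("$Elements")
  w(sprintf("%d %d 1 %d", length(regions), nrow(mesh$tets), nrow(mesh$tets)))
  eid <- 0L
  for (r in regions) {
    ids <- which(mesh$tag == r)
    w(sprintf("3 %d %d %d", r, etype, length(ids)))
    conn <- mesh$tets[ids, , drop = FALSE]
    w(paste(eid + seq_along(ids),
            apply(conn, 1L, paste, collapse = " ")))
    eid <- eid + length(ids)
  }
  w("$EndElements")
  invisible(file)
}

#' Read a Gmsh MSH 4.1 file written by [write_msh]
#'
#' Minimal reader for round-tripping this package's own exports.
#'
#' @param file path to the `.msh` file.
#' @return an `fe_mesh` (nodes, tets, tag, tag_names only).
#' @export
read_msh <- function(file) {
  ln <- readLines(file)
  sect <- function(name) {
    a <- which(ln == paste0("$", name)) + 1L
    b <- which(ln == paste0("$End", name)) - 1L
    ln[a:b]
  }
  pn <- sect("PhysicalNames")
  nreg <- as.integer(pn[1])
  tag_names <- character(nreg); tag_ids <- integer(nreg)
  for (k in seq_len(nreg)) {
    parts <- strsplit(pn[1 + k], " ")[[1]]
    tag_ids[k] <- as.integer(parts[2])
    tag_names[k] <- gsub('"', "", paste(parts[-(1:2)], collapse = " "))
  }
  nd <- sect("Nodes")
  nn <- as.integer(strsplit(nd[1], " ")[[1]][2])
  coords <- do.call(rbind, lapply(nd[2 + nn + seq_len(nn)], function(s)
    as.numeric(strsplit(s, " ")[[1]])))
  el <- sect("Elements")
  hdr <- as.integer(strsplit(el[1], " ")[[1]])
  nblk <- hdr[1]
  pos <- 2L
  tets <- list(); tags <- list()
  for (b in seq_len(nblk)) {
    bh <- as.integer(strsplit(el[pos], " ")[[1]])
    reg <- bh[2]; nel <- bh[4]
    rows <- do.call(rbind, lapply(el[pos + seq_len(nel)], function(s)
      as.integer(strsplit(s, " ")[[1]])))
    tets[[b]] <- rows[, -1, drop = FALSE]
    tags[[b]] <- rep(reg, nel)
    pos <- pos + nel + 1L
  }
  names(tag_names) <- NULL
  order_names <- character(max(tag_ids))
  order_names[tag_ids] <- tag_names
  structure(list(nodes = coords, tets = do.call(rbind, tets),
                 tag = unlist(tags), tag_names = order_names,
                 order = if (ncol(tets[[1]]) == 10L) 2L else 1L),
            class = "fe_mesh")
}

#' Export region boundary surfaces as ASCII STL
#'
#' Writes one STL file per region (facets of that region not shared with
#' another element of the same region), for visual inspection of the
#' generated anatomy.
#'
#' @param mesh an `fe_mesh`.
#' @param dir output directory (created on demand).
#' @param regions region names to export (default all).
#' @return character vector of file paths, invisibly.
#' @export
write_stl_regions <- function(mesh, dir, regions = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(regions)) regions <- mesh$tag_names[sort(unique(mesh$tag))]
  T4 <- mesh$tets[, 1:4, drop = FALSE]
  paths <- character(0)
  for (rg in regions) {
    ids <- which(mesh$tag_names[mesh$tag] == rg)
    if (!length(ids)) next
    f <- rbind(T4[ids, c(1, 3, 2)], T4[ids, c(1, 2, 4)],
               T4[ids, c(1, 4, 3)], T4[ids, c(2, 3, 4)])
    fs <- t(apply(f, 1L, sort.int))
    key <- paste(fs[, 1], fs[, 2], fs[, 3])
    bnd <- f[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    p1 <- mesh$nodes[bnd[, 1], , drop = FALSE]
    p2 <- mesh$nodes[bnd[, 2], , drop = FALSE]
    p3 <- mesh$nodes[bnd[, 3], , drop = FALSE]
    e1 <- p2 - p1; e2 <- p3 - p1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-30)
    path <- file.path(dir, paste0(rg, ".stl"))
    con <- file(path, "w")
    writeLines(paste0("solid ", rg), con)
    txt <- sprintf(paste0(
      "facet normal %.6e %.6e %.6e\n outer loop\n",
      "  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n",
      "  vertex %.6e %.6e %.6e\n endloop\nendfacet"),
      nrm[, 1], nrm[, 2], nrm[, 3],
      p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3],
      p3[, 1], p3[, 2], p3[, 3])
    writeLines(txt, con)
    writeLines(paste0("endsolid ", rg), con)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write a run configuration to a YAML file
#'
#' @param config a `run_config`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  x$posterior <- unclass(x$posterior)
  yaml::write_yaml(x, file)
  invisible(file)
}

#' Read a run configuration from a YAML file
#'
#' @param file path to a YAML file written by [write_config] (or edited by
#'   hand; missing fields take the calibrated defaults).
#' @return a `run_config`.
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  if (!is.null(x$posterior)) x$posterior <- do.call(posterior_params, x$posterior)
  do.call(run_config, x)
}
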