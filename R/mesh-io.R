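# Gmsh (v2.2 ASCII) mesh input/output and VTU (ASCII XML) state output.
# Indices are 0-based in VTU and 1-based in Gmsh files; internal storage is
# 1-based.  Coordinates are written at full double precision so that a
# write/read round trip is bit-exact.

fmtg <- function(x) sprintf("%.17g", x)

#' Write a mesh in Gmsh 2.2 ASCII format
#'
#' Boundary edges are emitted as 2-node line elements carrying a physical
#' group per tag; triangles as 3-node elements.  Node order is preserved.
#'
#' @param mesh an `eulerian_mesh` or `lagrangian_mesh`.
#' @param path output file path (conventionally `.msh`).
#' @export
write_mesh <- function(mesh, path) {
  if (inherits(mesh, "eulerian_mesh")) {
    nodes <- mesh$nodes
    be <- mesh$boundary_edges
  } else {
    nodes <- mesh$ref
    loops <- mesh$loops %||% list(mesh$boundary)
    be <- do.call(rbind, lapply(loops, function(loop) {
      j <- c(seq_along(loop)[-1], 1L)
      data.frame(n1 = loop, n2 = loop[j], tag = "boundary",
                 stringsAsFactors = FALSE)
    }))
  }
  tri <- mesh$tri
  tags <- unique(be$tag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(tags)), con)
  for (i in seq_along(tags))
    writeLines(sprintf("1 %d \"%s\"", i, tags[i]), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(nodes)), con)
  writeLines(sprintf("%d %s %s 0", seq_len(nrow(nodes)),
                     fmtg(nodes[, 1]), fmtg(nodes[, 2])), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  writeLines(as.character(nrow(be) + nrow(tri)), con)
  ptag <- match(be$tag, tags)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(be)),
                     ptag, ptag, be$n1, be$n2), con)
  writeLines(sprintf("%d 2 2 0 0 %d %d %d",
                     nrow(be) + seq_len(nrow(tri)),
                     tri[, 1], tri[, 2], tri[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh 2.2 ASCII mesh
#'
#' Reads nodes, triangles and tagged boundary line elements.  Returns an
#' [eulerian_mesh()] by default or, with `lagrangian = TRUE`, a
#' [lagrangian_mesh()] (reference coordinates set to the file coordinates).
#'
#' @param path `.msh` file path.
#' @param lagrangian return a solid mesh instead of a fluid mesh.
#' @export
read_mesh <- function(path, lagrangian = FALSE) {
  lines <- readLines(path)
  sect <- function(name) {
    i1 <- match(paste0("$", name), lines)
    i2 <- match(paste0("$End", name), lines)
    if (is.na(i1) || is.na(i2)) return(NULL)
    lines[(i1 + 1L):(i2 - 1L)]
  }
  phys <- sect("PhysicalNames")
  tagnames <- character(0)
  if (!is.null(phys) && length(phys) > 1L) {
    for (ln in phys[-1L]) {
      p <- strsplit(trimws(ln), "\\s+")[[1]]
      tagnames[as.integer(p[2])] <- gsub("\"", "", paste(p[-(1:2)],
                                                         collapse = " "))
    }
  }
  nl <- sect("Nodes")
  nn <- as.integer(nl[1])
  nod <- read.table(text = nl[-1L], colClasses = "numeric")
  nodes <- as.matrix(nod[order(nod[[1]]), 2:3])
  dimnames(nodes) <- NULL
  el <- sect("Elements")
  tri <- matrix(0L, 0L, 3L)
  be <- data.frame(n1 = integer(), n2 = integer(), tag = character(),
                   stringsAsFactors = FALSE)
  for (ln in el[-1L]) {
    p <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    type <- p[2]; ntag <- p[3]
    conn <- p[(4 + ntag):length(p)]
    if (type == 2) {
      tri <- rbind(tri, as.integer(conn))
    } else if (type == 1) {
      tg <- if (ntag >= 1 && p[4] >= 1 && p[4] <= length(tagnames))
        tagnames[p[4]] else "untagged"
      be <- rbind(be, data.frame(n1 = as.integer(conn[1]),
                                 n2 = as.integer(conn[2]), tag = tg,
                                 stringsAsFactors = FALSE))
    }
  }
  if (nrow(nodes) != nn) stop("corrupt mesh file: node count mismatch")
  if (lagrangian) {
    lagrangian_mesh(nodes, tri)
  } else {
    eulerian_mesh(nodes, tri, if (nrow(be)) be else NULL)
  }
}

vtu_darray <- function(name, x, ncomp = 1L) {
  c(sprintf(
    '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
    name, ncomp),
    paste(fmtg(t(x)), collapse = " "),
    "</DataArray>")
}

#' Write a mesh with nodal/element fields as an ASCII VTU file
#'
#' @param path output file (`.vtu`).
#' @param nodes n x 2 coordinates; written with z = 0.
#' @param tri m x 3 connectivity (1-based).
#' @param point_data named list of nodal fields (vectors of length n or
#'   n x k matrices, written with k components).
#' @param cell_data named list of element fields.
#' @export
write_vtu <- function(path, nodes, tri, point_data = list(),
                      cell_data = list()) {
  n <- nrow(nodes); m <- nrow(tri)
  out <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    "<UnstructuredGrid>",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    "<Points>",
    vtu_darray("Points", cbind(nodes, 0), 3L),
    "</Points>",
    "<Cells>",
    '<DataArray type="Int32" Name="connectivity" format="ascii">',
    paste(t(tri) - 1L, collapse = " "),
    "</DataArray>",
    '<DataArray type="Int32" Name="offsets" format="ascii">',
    paste(seq_len(m) * 3L, collapse = " "),
    "</DataArray>",
    '<DataArray type="UInt8" Name="types" format="ascii">',
    paste(rep(5L, m), collapse = " "),
    "</DataArray>",
    "</Cells>")
  if (length(point_data)) {
    out <- c(out, "<PointData>")
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      nc <- if (is.matrix(x)) ncol(x) else 1L
      if (nc == 2L) x <- cbind(x, 0)  # pad vectors to 3 components
      out <- c(out, vtu_darray(nm, x, if (nc == 2L) 3L else nc))
    }
    out <- c(out, "</PointData>")
  }
  if (length(cell_data)) {
    out <- c(out, "<CellData>")
    for (nm in names(cell_data)) {
      x <- cell_data[[nm]]
      nc <- if (is.matrix(x)) ncol(x) else 1L
      out <- c(out, vtu_darray(nm, x, nc))
    }
    out <- c(out, "</CellData>")
  }
  out <- c(out, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(out, path)
  invisible(path)
}

#' Write the simulation state of a time step as VTU files
#'
#' Writes `fluid_<step>.vtu` (velocity, pressure, indicator and distributed
#' interaction force on the Eulerian mesh) and `solid_<step>.vtu`
#' (displacement, velocity and element stress on the Lagrangian mesh, in the
#' current configuration) into `dir`.
#'
#' @param dir output directory (created if missing).
#' @param step integer step number used in the file names.
#' @param sim an `ifem_sim` simulation object.
#' @return paths of the written files, invisibly.
#' @export
write_state <- function(dir, step, sim) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- file.path(dir, sprintf("fluid_%05d.vtu", step))
  pd <- list(velocity = sim$fluid$v, pressure = sim$fluid$p)
  if (!is.null(sim$indicator)) pd$indicator <- sim$indicator
  if (!is.null(sim$f_fsi_f)) pd$f_fsi <- sim$f_fsi_f
  write_vtu(fp, sim$em$nodes, sim$em$tri, point_data = pd)
  sp <- file.path(dir, sprintf("solid_%05d.vtu", step))
  cd <- list()
  if (!is.null(sim$solid$sigma)) cd$stress <- sim$solid$sigma
  write_vtu(sp, sim$lm$cur, sim$lm$tri,
            point_data = list(displacement = sim$solid$u,
                              velocity = sim$solid$v),
            cell_data = cd)
  invisible(c(fp, sp))
}
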