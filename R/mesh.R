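#' Hexahedral mesh container
#'
#' Regular-grid 8-node hexahedral mesh: `nodes` (N x 3, mm), `elems`
#' (m x 8 connectivity, VTK node order), `edges` (element edge lengths, mm),
#' `materials` (list of `material` objects), `elem_material` (index per
#' element), `elem_volume` (mm^3) and optionally `elem_rho` (relative density
#' per element, homogenized meshes only).
#'
#' @name hex_mesh
NULL

# Build a hex mesh from a logical keep-mask on a regular cell grid.
grid_mesh <- function(keep, spacing, origin = c(0, 0, 0)) {
  d <- dim(keep)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  cells <- which(keep)
  if (!length(cells)) stop("empty mesh: no cells selected")
  ijk <- arrayInd(cells, d)
  nx1 <- d[1] + 1L; ny1 <- d[2] + 1L
  nid <- function(i, j, k) i + (j - 1L) * nx1 + (k - 1L) * nx1 * ny1
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  conn <- cbind(nid(i,     j,     k),
                nid(i + 1L, j,     k),
                nid(i + 1L, j + 1L, k),
                nid(i,     j + 1L, k),
                nid(i,     j,     k + 1L),
                nid(i + 1L, j,     k + 1L),
                nid(i + 1L, j + 1L, k + 1L),
                nid(i,     j + 1L, k + 1L))
  used <- sort(unique(as.vector(conn)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  conn <- matrix(remap[conn], ncol = 8L)
  gi <- (used - 1L) %% nx1
  gj <- ((used - 1L) %/% nx1) %% ny1
  gk <- (used - 1L) %/% (nx1 * ny1)
  nodes <- cbind(origin[1] + gi * spacing[1],
                 origin[2] + gj * spacing[2],
                 origin[3] + gk * spacing[3])
  structure(list(nodes = nodes, elems = conn, edges = spacing,
                 materials = list(), elem_material = rep(1L, nrow(conn)),
                 elem_volume = rep(prod(spacing), nrow(conn)),
                 elem_rho = NULL,
                 grid = list(dim = d, spacing = spacing, origin = origin,
                             cells = cells)),
            class = "hex_mesh")
}

#' Convert a voxel image to a micro-FE hexahedral mesh
#'
#' One 8-node element per bone voxel (direct voxel-to-element conversion);
#' adjacent elements share nodes; element volume = spacing^3.
#'
#' @param image a binary `voxel_image` (nonzero voxels become elements).
#' @param material a `material` assigned to every element (micro-FE tissue
#'   material, e.g. `material_isotropic(12000, 0.3)`).
#' @return a `hex_mesh`.
#' @export
image_to_mesh <- function(image, material = material_isotropic(12000, 0.3)) {
  stopifnot(inherits(image, "voxel_image"))
  keep <- image$values > 0
  if (!any(keep)) stop("empty mesh: image contains no bone voxels")
  mesh <- grid_mesh(keep, image$spacing, image$origin)
  mesh$materials <- list(material)
  mesh
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("hex_mesh: %d elements, %d nodes, edges %s mm\n",
              nrow(x$elems), nrow(x$nodes),
              paste(signif(x$edges, 4), collapse = "x")))
  invisible(x)
}

# Node indices lying on a coordinate plane (axis = 1..3, side = "min"/"max").
node_plane <- function(mesh, axis = 3, side = c("max", "min"), tol = NULL) {
  side <- match.arg(side)
  z <- mesh$nodes[, axis]
  if (is.null(tol)) tol <- mesh$edges[axis] * 1e-6
  ref <- if (side == "max") max(z) else min(z)
  which(abs(z - ref) <= tol)
}

element_centroids <- function(mesh) {
  n1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
  sweep(n1, 2, mesh$edges / 2, `+`)
}

#' Export a mesh (with optional element fields) as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with hexahedral cells; per-element
#' fields are written as CELL_DATA scalars.
#'
#' @param mesh a `hex_mesh`.
#' @param path output `.vtk` path.
#' @param cell_data named list of per-element numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "boneibr mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(format(mesh$nodes, scientific = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  utils::write.table(cbind(8L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_data[[nm]], scientific = TRUE, digits = 9), con)
    }
  }
  invisible(path)
}

#' Export a mesh in an Abaqus INP dialect
#'
#' Nodes and C3D8 elements, 1-based ids; one solid section per material
#' bucket (elements grouped by their material index).
#'
#' @param mesh a `hex_mesh`.
#' @param path output `.inp` path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines("*ELEMENT, TYPE=C3D8", con)
  e <- mesh$elems
  writeLines(sprintf("%d, %d, %d, %d, %d, %d, %d, %d, %d",
                     seq_len(nrow(e)), e[, 1], e[, 2], e[, 3], e[, 4],
                     e[, 5], e[, 6], e[, 7], e[, 8]), con)
  for (mi in sort(unique(mesh$elem_material))) {
    ids <- which(mesh$elem_material == mi)
    writeLines(sprintf("*ELSET, ELSET=MAT%d", mi), con)
    writeLines(paste(ids, collapse = ", "), con)
    mat <- mesh$materials[[mi]]
    writeLines(sprintf("*SOLID SECTION, ELSET=MAT%d, MATERIAL=MAT%d", mi, mi),
               con)
    writeLines(sprintf("*MATERIAL, NAME=MAT%d", mi), con)
    if (identical(mat$kind, "isotropic")) {
      writeLines(c("*ELASTIC", sprintf("%.9g, %.9g", mat$E, mat$nu)), con)
    } else {
      # engineering constants: E1,E2,E3,nu12,nu13,nu23,G12,G13,G23
      writeLines(c("*ELASTIC, TYPE=ENGINEERING CONSTANTS",
                   sprintf("%.9g, %.9g, %.9g, %.9g, %.9g, %.9g, %.9g, %.9g",
                           mat$E[1], mat$E[2], mat$E[3], mat$nu[1],
                           mat$nu[2], mat$nu[3], mat$G[3], mat$G[2]),
                   sprintf("%.9g", mat$G[1])), con)
    }
  }
  invisible(path)
}
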