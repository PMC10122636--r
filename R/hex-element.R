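# 8-node trilinear hexahedron on a rectangular box, 2x2x2 Gauss integration.
# Node order (VTK hexahedron): (0,0,0),(1,0,0),(1,1,0),(0,1,0) then the +z
# copies. DOF order per element: (u1x,u1y,u1z,u2x,...), 24 total.

hex_signs <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1), ncol = 3, byrow = TRUE)

# Strain-displacement matrix (6x24) at natural coordinates xi for a box with
# edge lengths `edges` (mm). Rows in Voigt order (11,22,33,23,13,12) with
# engineering shear.
hex_bmat <- function(edges, xi) {
  s <- hex_signs
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    dN[a, 1] <- 0.125 * s[a, 1] * (1 + s[a, 2] * xi[2]) * (1 + s[a, 3] * xi[3])
    dN[a, 2] <- 0.125 * s[a, 2] * (1 + s[a, 1] * xi[1]) * (1 + s[a, 3] * xi[3])
    dN[a, 3] <- 0.125 * s[a, 3] * (1 + s[a, 1] * xi[1]) * (1 + s[a, 2] * xi[2])
  }
  dN <- sweep(dN, 2, 2 / edges, `*`)  # d/dx = d/dxi * 2/edge
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 2] <- dN[a, 3]; B[4, c0 + 3] <- dN[a, 2]  # gamma_yz
    B[5, c0 + 1] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 1]  # gamma_xz
    B[6, c0 + 1] <- dN[a, 2]; B[6, c0 + 2] <- dN[a, 1]  # gamma_xy
  }
  B
}

#' Element stiffness matrix of a rectangular 8-node hexahedron
#'
#' 2x2x2 Gauss integration of B'CB over a box element; exact for the
#' trilinear element on a rectangular geometry.
#'
#' @param material a `material` object (or bare 6x6 Voigt stiffness, MPa).
#' @param edges element edge lengths in mm (scalar or length-3).
#' @return symmetric 24x24 stiffness (N/mm) with 6 rigid-body zero-energy
#'   modes.
#' @export
hex_stiffness <- function(material, edges) {
  C <- if (inherits(material, "material")) material$C else material
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("material stiffness must be symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("material stiffness must be positive definite")
  if (length(edges) == 1L) edges <- rep(edges, 3L)
  if (any(edges <= 0)) stop("edges must be positive")
  g <- 1 / sqrt(3)
  detJ <- prod(edges) / 8
  K <- matrix(0, 24, 24)
  for (i in c(-g, g)) for (j in c(-g, g)) for (k in c(-g, g)) {
    B <- hex_bmat(edges, c(i, j, k))
    K <- K + crossprod(B, C %*% B) * detJ
  }
  (K + t(K)) / 2
}

# Centroid strain-displacement matrix (element report point).
hex_bmat_centroid <- function(edges) {
  if (length(edges) == 1L) edges <- rep(edges, 3L)
  hex_bmat(edges, c(0, 0, 0))
}
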