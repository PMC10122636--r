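#' Sample relative density with spheres
#'
#' Bone volume fraction of the image inside a sphere of the given diameter
#' centered at each element centroid, clipped to the image domain.
#'
#' @param image a binary (or density) `voxel_image`.
#' @param mesh a `hex_mesh` whose element centroids are the sampling points
#'   (typically the coarse homogenized grid).
#' @param sphere_diameter sampling sphere diameter, mm; must exceed the
#'   element edge of the image grid.
#' @return per-element relative density in \[0, 1\].
#' @export
sample_density <- function(image, mesh, sphere_diameter = 5) {
  if (sphere_diameter <= max(image$spacing))
    stop("sphere_diameter must exceed the voxel edge")
  centers <- element_centroids(mesh)
  rho <- sphere_density_cpp(as.vector(image$values), dim(image$values),
                            image$spacing, image$origin, centers,
                            sphere_diameter / 2)
  if (anyNA(rho)) stop("sampling sphere entirely outside the image domain")
  pmin(pmax(rho, 0), 1)
}

#' Density-only isotropic bone material
#'
#' Power law E = E0 * rho^k, G = mu0 * rho^k; the implied (density-
#' independent) Poisson ratio is nu = E0 / (2 mu0) - 1.
#'
#' @param rho relative density in (0, 1].
#' @param constants a [bone_constants()] preset without fabric exponent
#'   (density-only rows).
#' @return an isotropic `material`.
#' @export
density_material <- function(rho, constants = bone_constants("trabecular-density")) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  nu <- constants$E0 / (2 * constants$mu0) - 1
  material_isotropic(constants$E0 * rho^constants$k, nu)
}

#' Density- and fabric-based orthotropic bone material (Zysset-Curnier type)
#'
#' Standard compliance-form power law in the fabric eigenbasis:
#' E_i = E0 rho^k m_i^(2l), G_ij = mu0 rho^k (m_i m_j)^l,
#' nu_ij = nu0 (m_i / m_j)^l, with material axes equal to the fabric
#' eigenvectors. Fabric eigenvalues are assumed normalized to det = 1.
#'
#' @param rho relative density in (0, 1].
#' @param fabric a `fabric_tensor` (see [mil_fabric()]) or list with
#'   `values` (3 eigenvalues) and `vectors` (3x3 eigenvector matrix).
#' @param constants a [bone_constants()] preset with fabric exponent
#'   (default "trabecular-fabric").
#' @return an orthotropic `material`; errors if the stiffness is not SPD.
#' @export
zysset_curnier_material <- function(rho, fabric,
                                    constants = bone_constants("trabecular-fabric")) {
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (is.na(constants$l)) stop("constants lack a fabric exponent l")
  m <- fabric$values
  if (any(m <= 0)) stop("fabric eigenvalues must be positive")
  l <- constants$l
  rk <- rho^constants$k
  E <- constants$E0 * rk * m^(2 * l)
  G <- constants$mu0 * rk * c((m[2] * m[3])^l, (m[1] * m[3])^l,
                              (m[1] * m[2])^l)
  nu <- constants$nu0 * c((m[1] / m[2])^l, (m[1] / m[3])^l, (m[2] / m[3])^l)
  material_orthotropic(E, G, nu, axes = fabric$vectors)
}

# Quasi-uniform antipodally-symmetric direction set (Fibonacci hemisphere).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n  # upper hemisphere
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Mean-intercept-length fabric tensor of a binary image
#'
#' MIL is measured by line probing along a quasi-uniform set of directions;
#' an ellipsoid n' H n = 1/MIL(n)^2 is fitted by least squares and the
#' fabric tensor is H^(-1/2) with eigenvalues normalized to product one
#' (determinant-one convention).
#'
#' @param image a binary `voxel_image` containing both phases.
#' @param n_directions number of probing directions (>= 9; default 60).
#' @return a `fabric_tensor`: `values` (eigenvalues m1 >= m2 >= m3,
#'   normalized so m1*m2*m3 = 1), `vectors` (matching eigenvector columns),
#'   `tensor` (3x3), `mil` (raw MIL per direction).
#' @export
mil_fabric <- function(image, n_directions = 60) {
  if (n_directions < 9) stop("need at least 9 directions")
  v <- image$values
  if (all(v > 0) || all(v == 0)) stop("fabric undefined: single-phase region")
  dirs <- fibonacci_directions(n_directions)
  mil <- mil_cpp(as.integer(v > 0), dim(v), image$spacing, dirs)
  y <- 1 / mil^2
  X <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  h <- qr.coef(qr(X), y)
  H <- matrix(c(h[1], h[4], h[5],
                h[4], h[2], h[6],
                h[5], h[6], h[3]), 3, 3)
  eh <- eigen(H, symmetric = TRUE)
  if (any(eh$values <= 0)) stop("MIL ellipsoid fit is not positive definite")
  m <- eh$values^(-1 / 2)
  m <- m / prod(m)^(1 / 3)
  ord <- order(m, decreasing = TRUE)
  m <- m[ord]
  V <- eh$vectors[, ord, drop = FALSE]
  structure(list(values = m, vectors = V,
                 tensor = V %*% diag(m) %*% t(V), mil = mil),
            class = "fabric_tensor")
}

isotropic_fabric <- function() {
  structure(list(values = c(1, 1, 1), vectors = diag(3), tensor = diag(3),
                 mil = NULL), class = "fabric_tensor")
}

#' Build a homogenized FE model from a microstructure image
#'
#' Coarse regular hexahedral grid covering the image; per-element relative
#' density by sphere sampling at the element centroid; elements below the
#' density threshold are dropped; per-element material from the density
#' power law (trabecular or, under `cortex_mask`, cortical constants) or
#' from density plus local MIL fabric (Zysset-Curnier). Fabric regions that
#' contain a single phase fall back to isotropic fabric.
#'
#' @param image binary `voxel_image` of the microstructure.
#' @param element_size edge length of the homogenized elements, mm.
#' @param mapping "density" or "density+fabric".
#' @param sphere_diameter sampling sphere diameter, mm (default 5).
#' @param rho_threshold drop elements with sampled density below this
#'   (default 0.01).
#' @param constants [bone_constants()] preset for trabecular elements.
#' @param cortex_mask optional logical voxel array marking cortical bone;
#'   elements whose sampled cortical fraction exceeds 0.5 get
#'   cortical-density material.
#' @param cortical_constants preset for cortical elements.
#' @return a `hex_mesh` with `elem_rho` and per-element materials.
#' @export
build_hfe_model <- function(image, element_size = 1,
                            mapping = c("density", "density+fabric"),
                            sphere_diameter = 5, rho_threshold = 0.01,
                            constants = NULL, cortex_mask = NULL,
                            cortical_constants = bone_constants("cortical-density")) {
  mapping <- match.arg(mapping)
  if (is.null(constants))
    constants <- bone_constants(if (mapping == "density") "trabecular-density"
                                else "trabecular-fabric")
  if (element_size <= max(image$spacing))
    stop("element_size must exceed the voxel spacing")
  d <- dim(image$values)
  extent <- d * image$spacing
  ncell <- pmax(1L, as.integer(round(extent / element_size)))
  h <- extent / ncell  # snap the grid to the image extent
  keep_all <- array(TRUE, dim = ncell)
  mesh <- grid_mesh(keep_all, h, image$origin)
  rho <- sample_density(image, mesh, sphere_diameter)
  keep <- rho >= rho_threshold
  if (!any(keep)) stop("all elements below the density threshold")
  keep_arr <- array(FALSE, dim = ncell)
  keep_arr[mesh$grid$cells[keep]] <- TRUE
  mesh <- grid_mesh(keep_arr, h, image$origin)
  rho <- rho[keep]

  cort <- rep(FALSE, length(rho))
  if (!is.null(cortex_mask)) {
    cimg <- voxel_image(array(as.numeric(cortex_mask), dim = d),
                        image$spacing, image$origin)
    cfrac <- sample_density(cimg, mesh, sphere_diameter)
    cort <- cfrac > 0.5
  }

  if (mapping == "density") {
    mats <- vector("list", length(rho))
    for (e in seq_along(rho)) {
      mats[[e]] <- density_material(rho[e],
                                    if (cort[e]) cortical_constants else constants)
    }
  } else {
    centers <- element_centroids(mesh)
    r_vox <- sphere_diameter / 2
    mats <- vector("list", length(rho))
    for (e in seq_along(rho)) {
      if (cort[e]) {
        mats[[e]] <- density_material(rho[e], cortical_constants)
        next
      }
      lo <- pmax(1L, as.integer(floor((centers[e, ] - image$origin - r_vox) /
                                        image$spacing)) + 1L)
      hi <- pmin(d, as.integer(ceiling((centers[e, ] - image$origin + r_vox) /
                                         image$spacing)))
      sub <- image$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      fab <- if (all(sub > 0) || all(sub == 0)) isotropic_fabric()
             else mil_fabric(voxel_image(sub, image$spacing), 40)
      mats[[e]] <- zysset_curnier_material(rho[e], fab, constants)
    }
  }
  mesh$materials <- mats
  mesh$elem_material <- seq_along(mats)
  mesh$elem_rho <- rho
  mesh
}
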