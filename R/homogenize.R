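#' Six canonical KUBC load cases on a cube
#'
#' Kinematic uniform boundary conditions: every bone-phase node on the
#' boundary of the cubic domain is prescribed the affine displacement
#' u = Ebar x. The six cases are three uniaxial compressions
#' (Ebar_kk = -d/L) and three pure shears (tensor shear
#' Ebar_kl = Ebar_lk = -d/(2L), i.e. face tangential displacement magnitude
#' d). `shear = "engineering"` switches the shear cases to Ebar_kl = -d/L.
#'
#' @param mesh a `hex_mesh` of a cubic domain.
#' @param displacement face normal/shear displacement d, mm (default -0.001).
#' @param shear shear convention, "tensor" (default) or "engineering".
#' @return list of six `load_case` objects (uniaxial 1..3, shear 23, 13, 12).
#' @export
kubc_loadcases <- function(mesh, displacement = -0.001,
                           shear = c("tensor", "engineering")) {
  shear <- match.arg(shear)
  # domain = full voxel grid the mesh was built on (bone need not span it)
  if (!is.null(mesh$grid)) {
    lo <- mesh$grid$origin
    hi <- mesh$grid$origin + mesh$grid$dim * mesh$grid$spacing
  } else {
    lo <- apply(mesh$nodes, 2, min)
    hi <- apply(mesh$nodes, 2, max)
  }
  L <- hi - lo
  if (diff(range(L)) > 1e-9 * max(L)) stop("domain is not cubic")
  L <- L[1]
  tol <- mesh$edges[1] * 1e-6
  on_boundary <- rowSums(abs(sweep(mesh$nodes, 2, lo)) <= tol |
                           abs(sweep(mesh$nodes, 2, hi)) <= tol) > 0
  bnodes <- which(on_boundary)
  X <- sweep(mesh$nodes[bnodes, , drop = FALSE], 2, lo)
  d <- displacement
  shear_val <- if (shear == "tensor") d / (2 * L) else d / L
  Ebars <- list()
  for (k in 1:3) {
    E <- matrix(0, 3, 3); E[k, k] <- d / L
    Ebars[[k]] <- E
  }
  pairs <- list(c(2, 3), c(1, 3), c(1, 2))
  for (p in 1:3) {
    E <- matrix(0, 3, 3)
    E[pairs[[p]][1], pairs[[p]][2]] <- shear_val
    E[pairs[[p]][2], pairs[[p]][1]] <- shear_val
    Ebars[[3 + p]] <- E
  }
  names <- c("uniaxial-11", "uniaxial-22", "uniaxial-33",
             "shear-23", "shear-13", "shear-12")
  lapply(seq_along(Ebars), function(i) {
    U <- X %*% t(Ebars[[i]])
    load_case(names[i],
              data.frame(node = rep(bnodes, 3L),
                         comp = rep(1:3, each = length(bnodes)),
                         value = as.vector(U)),
              Ebar = Ebars[[i]])
  })
}

voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[6], v[5],
           v[6], v[2], v[4],
           v[5], v[4], v[3]), 3, 3)
}

#' Apparent (homogenized) quantities from six KUBC solutions
#'
#' Volume-averaged microscopic stress per load case (pores contribute zero
#' stress; the average is over the total cube volume), the a-priori
#' macroscopic strain (exact under KUBC), relative density, and the
#' volume-weighted mean tissue SED.
#'
#' @param solutions list of `fe_solution` objects from [kubc_loadcases()].
#' @param mesh the `hex_mesh` they were solved on.
#' @param total_volume total cube volume V_total in mm^3.
#' @return list with `rho`, `sigma` (list of 3x3, MPa), `eps` (list of 3x3),
#'   `mean_sed` (per case, MPa), `sed` (m x n matrix of tissue SED),
#'   `volumes`.
#' @export
apparent_quantities <- function(solutions, mesh, total_volume) {
  if (total_volume <= 0) stop("total_volume must be positive")
  V <- mesh$elem_volume
  sig <- lapply(solutions, function(s)
    voigt_to_tensor(colSums(s$stress * V) / total_volume))
  eps <- lapply(solutions, function(s) {
    if (is.null(s$Ebar)) stop("solution lacks the applied macroscopic strain")
    s$Ebar
  })
  list(rho = sum(V) / total_volume,
       sigma = sig, eps = eps,
       mean_sed = vapply(solutions, function(s) sum(s$sed * V) / sum(V), 0),
       sed = vapply(solutions, function(s) s$sed, numeric(length(V))),
       volumes = V)
}

#' Apparent stiffness matrix from KUBC results
#'
#' Builds the 6x6 Voigt apparent stiffness from the six apparent stress
#' tensors, dividing each by the applied Voigt strain (engineering shear).
#'
#' @param aq result of [apparent_quantities()].
#' @return 6x6 apparent stiffness, MPa.
#' @export
apparent_stiffness <- function(aq) {
  tensor_to_voigt_strain <- function(E)
    c(E[1, 1], E[2, 2], E[3, 3], 2 * E[2, 3], 2 * E[1, 3], 2 * E[1, 2])
  tensor_to_voigt_stress <- function(S)
    c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[1, 3], S[1, 2])
  C <- matrix(0, 6, 6)
  for (i in 1:6) {
    ev <- tensor_to_voigt_strain(aq$eps[[i]])
    j <- which(abs(ev) > 0)
    if (length(j) != 1L) stop("load case ", i, " is not canonical")
    C[, j] <- tensor_to_voigt_stress(aq$sigma[[i]]) / ev[j]
  }
  C
}

#' Optimized continuum stimulus of a homogenized cube
#'
#' `<U_opt> = 0.5 * sum_i s_i <sigma_i> : <eps_i>`, the apparent strain
#' energy density of the optimally scaled load cases.
#'
#' @param s six non-negative SED scale factors.
#' @param sigma list of apparent stress tensors (3x3, MPa).
#' @param eps list of applied macroscopic strain tensors (3x3).
#' @return `<U_opt>` in MPa.
#' @export
optimized_continuum_stimulus <- function(s, sigma, eps) {
  if (length(s) != length(sigma) || length(s) != length(eps))
    stop("s, sigma and eps must have equal length")
  if (any(s < 0)) stop("scale factors must be non-negative")
  0.5 * sum(vapply(seq_along(s),
                   function(i) s[i] * sum(sigma[[i]] * eps[[i]]), 0))
}

#' Homogenize a trabecular cube and optimize its load scales
#'
#' Full per-cube workflow: voxel mesh, six KUBC solves, tissue-level IBR
#' against the target stimulus, apparent quantities and the optimized
#' continuum stimulus.
#'
#' @param image binary `voxel_image` of a (cubic) microstructure.
#' @param E,nu isotropic tissue material (MPa / -); defaults 12000, 0.3.
#' @param displacement KUBC displacement d, mm (default -0.001).
#' @param Ustar tissue target stimulus, MPa (default 0.02).
#' @param shear shear convention passed to [kubc_loadcases()].
#' @return list with `rho`, `sigma`, `eps`, `mean_sed`, `s`, `alpha`,
#'   `U_opt`, `cv_before`, `cv_after`, `apparent_stiffness`.
#' @export
homogenize_cube <- function(image, E = 12000, nu = 0.3,
                            displacement = -0.001, Ustar = 0.02,
                            shear = "tensor") {
  mesh <- image_to_mesh(image, material_isotropic(E, nu))
  lcs <- kubc_loadcases(mesh, displacement, shear)
  K <- assemble_stiffness(mesh)
  sols <- solve_fe_batch(mesh, lcs, K)
  d <- dim(image$values)
  V_total <- prod(d) * prod(image$spacing)
  aq <- apparent_quantities(sols, mesh, V_total)
  prob <- ibr_problem(aq$sed, aq$volumes, tissue_target(nrow(aq$sed), Ustar))
  res <- ibr_solve(prob)
  list(rho = aq$rho, sigma = aq$sigma, eps = aq$eps, mean_sed = aq$mean_sed,
       s = res$s, alpha = res$alpha,
       U_opt = optimized_continuum_stimulus(res$s, aq$sigma, aq$eps),
       cv_before = res$cv_before, cv_after = res$cv_after,
       apparent_stiffness = apparent_stiffness(aq))
}
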