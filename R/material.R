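# Voigt ordering used throughout: (11, 22, 33, 23, 13, 12), engineering shear
# strains (gamma = 2*eps), units mm-N-MPa.

#' Isotropic linear-elastic material
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio.
#' @return a `material` object holding the 6x6 Voigt stiffness (MPa).
#' @export
material_isotropic <- function(E, nu) {
  if (E <= 0 || nu <= -1 || nu >= 0.5) stop("material is not positive definite")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  structure(list(kind = "isotropic", E = E, nu = nu, C = C),
            class = "material")
}

#' Orthotropic linear-elastic material from engineering constants
#'
#' @param E length-3 Young's moduli (E1, E2, E3), MPa.
#' @param G length-3 shear moduli (G23, G13, G12), MPa (Voigt rows 4..6).
#' @param nu length-3 Poisson ratios (nu12, nu13, nu23).
#' @param axes 3x3 orthonormal matrix, columns = material axes in the global
#'   frame; default identity.
#' @return a `material` object; errors if the stiffness is not SPD.
#' @export
material_orthotropic <- function(E, G, nu, axes = diag(3)) {
  stopifnot(length(E) == 3, length(G) == 3, length(nu) == 3)
  S <- matrix(0, 6, 6)
  diag(S)[1:3] <- 1 / E
  S[1, 2] <- S[2, 1] <- -nu[1] / E[1]  # nu12
  S[1, 3] <- S[3, 1] <- -nu[2] / E[1]  # nu13
  S[2, 3] <- S[3, 2] <- -nu[3] / E[2]  # nu23
  diag(S)[4:6] <- 1 / G
  C <- solve(S)
  C <- (C + t(C)) / 2
  Cg <- rotate_stiffness(C, axes)
  ev <- eigen(Cg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("orthotropic material stiffness is not positive definite ",
         sprintf("(min eigenvalue %.3g); E=%s G=%s nu=%s", min(ev),
                 paste(signif(E, 5), collapse = ","),
                 paste(signif(G, 5), collapse = ","),
                 paste(signif(nu, 5), collapse = ",")))
  structure(list(kind = "orthotropic", E = E, G = G, nu = nu, axes = axes,
                 C = Cg),
            class = "material")
}

# Bond stress-transformation matrix for a rotation A (columns = material axes
# expressed in global coordinates), Voigt order (11,22,33,23,13,12).
bond_stress <- function(A) {
  a <- A
  M <- matrix(0, 6, 6)
  p <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (r in 1:6) {
    i <- p[[r]][1]; j <- p[[r]][2]
    for (cc in 1:6) {
      k <- p[[cc]][1]; l <- p[[cc]][2]
      M[r, cc] <- if (k == l) a[i, k] * a[j, k]
                  else a[i, k] * a[j, l] + a[i, l] * a[j, k]
    }
  }
  M
}

#' Rotate a Voigt stiffness matrix
#'
#' @param C 6x6 stiffness in the material frame.
#' @param A 3x3 orthonormal matrix, columns = material axes in global frame.
#' @return 6x6 stiffness in the global frame.
#' @export
rotate_stiffness <- function(C, A) {
  M <- bond_stress(A)
  M %*% C %*% t(M)
}

#' Elastic base constants for bone material mapping
#'
#' Power-law constants used to map relative density (and optionally fabric)
#' to continuum elastic properties: E = E0 * rho^k (and fabric factors
#' m_i^(2l) in the fabric model). Three presets are provided, matching the
#' trabecular density+fabric, trabecular density-only, and cortical
#' density-only calibrations used with KUBC-homogenized trabecular cubes.
#'
#' @param type one of "trabecular-fabric", "trabecular-density",
#'   "cortical-density".
#' @return list with `E0`, `mu0` (MPa), `nu0` (fabric preset only), `k`, and
#'   `l` (fabric preset only).
#' @export
bone_constants <- function(type = c("trabecular-fabric", "trabecular-density",
                                    "cortical-density")) {
  type <- match.arg(type)
  switch(type,
    "trabecular-fabric" = list(type = type, E0 = 10320.4, mu0 = 3470.7,
                               nu0 = 0.2278, k = 1.62, l = 1.1),
    "trabecular-density" = list(type = type, E0 = 8812.8, mu0 = 3536.0,
                                nu0 = NA_real_, k = 1.63, l = NA_real_),
    "cortical-density" = list(type = type, E0 = 12000.0, mu0 = 4615.4,
                              nu0 = NA_real_, k = 1.63, l = NA_real_)
  )
}
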