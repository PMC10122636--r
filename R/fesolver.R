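#' Displacement-controlled load case
#'
#' @param name load case label.
#' @param prescribed data.frame with columns `node`, `comp` (1..3) and
#'   `value` (mm); each (node, comp) pair may appear once.
#' @param sets named list of node-index vectors over which reaction forces
#'   are summed (e.g. `list(distal = ..., proximal = ...)`).
#' @param Ebar optional 3x3 macroscopic strain tensor (KUBC cases).
#' @return a `load_case` object.
#' @export
load_case <- function(name, prescribed, sets = list(), Ebar = NULL) {
  stopifnot(all(c("node", "comp", "value") %in% names(prescribed)))
  if (anyDuplicated(prescribed[, c("node", "comp")]))
    stop("a (node, component) pair is prescribed more than once")
  structure(list(name = name, prescribed = prescribed, sets = sets,
                 Ebar = Ebar), class = "load_case")
}

#' Canonical displacement load cases for a bone section
#'
#' Three load cases imitating physiological candidate loads on a cut bone
#' section: shear along axis 1, shear along axis 2, and axial compression
#' along axis 3, each applied as a 0.01 mm displacement of the distal
#' (max-3) plane; the proximal (min-3) plane is fully fixed. By default the
#' distal nodes are constrained only along the load direction (transverse
#' components free); `fix_transverse = TRUE` prescribes all three components.
#'
#' @param mesh a `hex_mesh` with identifiable distal/proximal planes.
#' @param magnitude prescribed displacement magnitude, mm (default 0.01).
#' @param fix_transverse prescribe zero transverse displacement on the distal
#'   plane as well.
#' @return list of three `load_case` objects (shear-1, shear-2,
#'   compression-3).
#' @export
canonical_section_loadcases <- function(mesh, magnitude = 0.01,
                                        fix_transverse = FALSE) {
  distal <- node_plane(mesh, 3, "max")
  proximal <- node_plane(mesh, 3, "min")
  if (!length(distal) || !length(proximal) ||
      length(intersect(distal, proximal)))
    stop("distal/proximal planes not found")
  sets <- list(distal = distal, proximal = proximal)
  fixed <- data.frame(node = rep(proximal, each = 3L),
                      comp = rep(1:3, length(proximal)),
                      value = 0)
  make <- function(name, comp, value) {
    if (fix_transverse) {
      pres <- data.frame(node = rep(distal, each = 3L),
                         comp = rep(1:3, length(distal)),
                         value = 0)
      pres$value[pres$comp == comp] <- value
    } else {
      pres <- data.frame(node = distal, comp = comp, value = value)
    }
    load_case(name, rbind(pres, fixed), sets = sets)
  }
  list(make("shear-1", 1L, magnitude),
       make("shear-2", 2L, magnitude),
       make("compression-3", 3L, -magnitude))
}

#' Assemble the global sparse stiffness matrix
#'
#' @param mesh a `hex_mesh`.
#' @return sparse symmetric stiffness (3N x 3N, `Matrix` dsCMatrix).
#' @export
assemble_stiffness <- function(mesh) {
  n_dof <- 3L * nrow(mesh$nodes)
  A <- rep(1:24, times = 24)
  B <- rep(1:24, each = 24)
  ii <- jj <- xx <- vector("list", length(mesh$materials))
  for (mi in seq_along(mesh$materials)) {
    el <- which(mesh$elem_material == mi)
    if (!length(el)) next
    Ke <- hex_stiffness(mesh$materials[[mi]], mesh$edges)
    conn <- mesh$elems[el, , drop = FALSE]
    # dof index matrix (m x 24): (n1x,n1y,n1z,n2x,...)
    idx <- matrix(0L, length(el), 24L)
    for (a in 1:8) {
      base <- 3L * (conn[, a] - 1L)
      idx[, 3L * a - 2L] <- base + 1L
      idx[, 3L * a - 1L] <- base + 2L
      idx[, 3L * a] <- base + 3L
    }
    ii[[mi]] <- as.vector(idx[, A])
    jj[[mi]] <- as.vector(idx[, B])
    xx[[mi]] <- rep(as.vector(Ke), each = length(el))
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_dof, n_dof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Solve a linear-elastic FE problem under displacement boundary conditions
#'
#' Direct sparse Cholesky factorization of the reduced system; per-element
#' strain/stress are evaluated at the element centroid, strain energy density
#' U = sigma:eps / 2 (MPa), and reaction forces are the assembled internal
#' forces on constrained nodes, summed per named node set.
#'
#' @param mesh a `hex_mesh`.
#' @param lc a `load_case`.
#' @param K optional pre-assembled stiffness (reused across load cases).
#' @return an `fe_solution`: `u` (N x 3 mm), `strain`/`stress` (m x 6 Voigt,
#'   engineering shear), `sed` (m, MPa), `reactions` (named list of
#'   3-vectors, N), `name`.
#' @export
solve_fe <- function(mesh, lc, K = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh)
  solve_fe_batch(mesh, list(lc), K)[[1]]
}

#' Solve several load cases, reusing factorizations
#'
#' Load cases sharing the same constrained degree-of-freedom set (e.g. the
#' six KUBC cases) are solved with a single sparse Cholesky factorization.
#'
#' @param mesh a `hex_mesh`.
#' @param lcs list of `load_case` objects.
#' @param K optional pre-assembled stiffness.
#' @return list of `fe_solution` objects, in input order.
#' @export
solve_fe_batch <- function(mesh, lcs, K = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh)
  n_dof <- 3L * nrow(mesh$nodes)
  keys <- vapply(lcs, function(lc) {
    pd <- sort(3L * (lc$prescribed$node - 1L) + lc$prescribed$comp)
    paste(pd, collapse = ",")
  }, "")
  out <- vector("list", length(lcs))
  for (key in unique(keys)) {
    members <- which(keys == key)
    lc1 <- lcs[[members[1]]]
    pres_dof <- 3L * (lc1$prescribed$node - 1L) + lc1$prescribed$comp
    free <- setdiff(seq_len(n_dof), pres_dof)
    ch <- NULL
    if (length(free)) {
      Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
      ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE), error = function(e)
        stop("singular system: a region of the mesh is disconnected from ",
             "the constrained nodes (", conditionMessage(e), ")"))
    }
    for (li in members) {
      lc <- lcs[[li]]
      pd <- 3L * (lc$prescribed$node - 1L) + lc$prescribed$comp
      u <- numeric(n_dof)
      u[pd] <- lc$prescribed$value
      if (length(free)) {
        rhs <- -(K[free, pd, drop = FALSE] %*% lc$prescribed$value)
        uf <- as.vector(Matrix::solve(ch, rhs))
        if (any(!is.finite(uf)))
          stop("solver produced non-finite displacements")
        u[free] <- uf
      }
      out[[li]] <- fe_postprocess(mesh, K, lc, u)
    }
  }
  out
}

fe_postprocess <- function(mesh, K, lc, u) {
  umat <- matrix(u, ncol = 3L, byrow = TRUE)

  # centroid strain per element: (m x 24) gather times t(B0)
  B0 <- hex_bmat_centroid(mesh$edges)
  m <- nrow(mesh$elems)
  uel <- matrix(0, m, 24L)
  for (a in 1:8) uel[, (3 * a - 2):(3 * a)] <- umat[mesh$elems[, a], , drop = FALSE]
  strain <- uel %*% t(B0)
  stress <- matrix(0, m, 6L)
  for (mi in seq_along(mesh$materials)) {
    el <- mesh$elem_material == mi
    if (any(el))
      stress[el, ] <- strain[el, , drop = FALSE] %*% mesh$materials[[mi]]$C
  }
  sed <- 0.5 * rowSums(stress * strain)
  sed[sed < 0 & sed > -1e-12 * max(abs(sed))] <- 0

  fint <- as.vector(K %*% u)
  fmat <- matrix(fint, ncol = 3L, byrow = TRUE)
  reactions <- lapply(lc$sets, function(ns) colSums(fmat[ns, , drop = FALSE]))

  structure(list(u = umat, strain = strain, stress = stress, sed = sed,
                 reactions = reactions, name = lc$name, Ebar = lc$Ebar),
            class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("fe_solution '%s': %d elements, mean SED %.4g MPa\n",
              x$name, length(x$sed), mean(x$sed)))
  for (nm in names(x$reactions))
    cat(sprintf("  reaction[%s] = (%.4g, %.4g, %.4g) N\n", nm,
                x$reactions[[nm]][1], x$reactions[[nm]][2],
                x$reactions[[nm]][3]))
  invisible(x)
}

#' Write a per-element solution table as CSV
#'
#' Columns: element id, relative density (if available), SED, stress and
#' strain Voigt components.
#'
#' @param solution an `fe_solution`.
#' @param mesh the `hex_mesh` it was computed on.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, mesh, path) {
  voigt <- c("11", "22", "33", "23", "13", "12")
  df <- data.frame(element = seq_along(solution$sed),
                   rho = if (is.null(mesh$elem_rho)) 1 else mesh$elem_rho,
                   sed = solution$sed)
  s <- as.data.frame(solution$stress)
  names(s) <- paste0("sigma", voigt)
  e <- as.data.frame(solution$strain)
  names(e) <- paste0("eps", voigt)
  utils::write.csv(cbind(df, s, e), path, row.names = FALSE)
  invisible(path)
}

#' Write a reaction-force summary as JSON
#'
#' @param solutions list of `fe_solution` objects.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_reaction_json <- function(solutions, path) {
  out <- lapply(solutions, function(s)
    list(name = s$name, reactions = s$reactions))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
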