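#' Study configuration
#'
#' Bundles every tunable of the two end-to-end workflows: micro-FE tissue
#' material, target stimulus, boundary condition magnitudes, the continuum
#' density exponent, and the homogenized-model discretization.
#'
#' @param E,nu micro-FE tissue material, MPa / - (defaults 12000, 0.3).
#' @param Ustar tissue target stimulus, MPa (default 0.02).
#' @param kubc_displacement KUBC face displacement, mm (default -0.001).
#' @param section_displacement section load case displacement, mm (default
#'   0.01).
#' @param d continuum stimulus density exponent (default 1.19; recalibrate
#'   with [run_cube_study()] for a different microstructure generator).
#' @param hfe_element_size homogenized element edge, mm (default 1).
#' @param sphere_diameter density sampling sphere diameter, mm (default 5;
#'   use ~2.5 on small desk-scale phantoms).
#' @param rho_threshold minimum sampled density to keep an hFE element.
#' @param hfe_mapping "density" (v-hFE style) or "density+fabric".
#' @param fix_transverse constrain transverse distal components in the
#'   section load cases (default FALSE: free-transverse variant).
#' @return a `study_config` list.
#' @export
study_config <- function(E = 12000, nu = 0.3, Ustar = 0.02,
                         kubc_displacement = -0.001,
                         section_displacement = 0.01, d = 1.19,
                         hfe_element_size = 1, sphere_diameter = 5,
                         rho_threshold = 0.01,
                         hfe_mapping = c("density", "density+fabric"),
                         fix_transverse = FALSE) {
  structure(list(E = E, nu = nu, Ustar = Ustar,
                 kubc_displacement = kubc_displacement,
                 section_displacement = section_displacement, d = d,
                 hfe_element_size = hfe_element_size,
                 sphere_diameter = sphere_diameter,
                 rho_threshold = rho_threshold,
                 hfe_mapping = match.arg(hfe_mapping),
                 fix_transverse = fix_transverse),
            class = "study_config")
}

#' Cube study: calibrate the continuum target stimulus exponent
#'
#' For each phantom spec: generate the cube, run the six KUBC load cases,
#' optimize the load scales against the tissue target stimulus, and compute
#' the optimized continuum stimulus. The density exponent d of
#' U_opt = Ustar * rho^d is then fitted over the cube set.
#'
#' @param specs list of [phantom_spec()] with at least two distinct
#'   densities.
#' @param config a [study_config()].
#' @return list with `table` (per-cube rho, U_opt, CV before/after, scales),
#'   `model` (fitted [stimulus_model()]), `d`, `r2` (fit, fraction).
#' @export
run_cube_study <- function(specs, config = study_config()) {
  rows <- lapply(specs, function(sp) {
    img <- generate_grf_cube(sp)
    h <- homogenize_cube(img, E = config$E, nu = config$nu,
                         displacement = config$kubc_displacement,
                         Ustar = config$Ustar)
    c(rho = h$rho, U_opt = h$U_opt, cv_before = h$cv_before,
      cv_after = h$cv_after, stats::setNames(h$s, paste0("s", 1:6)))
  })
  table <- as.data.frame(do.call(rbind, rows))
  fit <- calibrate_exponent(table$rho, table$U_opt, U0 = config$Ustar)
  list(table = table, model = fit$model, d = fit$d, r2 = fit$r2)
}

# micro-FE branch of the section workflow
mufe_section_ibr <- function(image, config) {
  mesh <- image_to_mesh(image, material_isotropic(config$E, config$nu))
  lcs <- canonical_section_loadcases(mesh, config$section_displacement,
                                     config$fix_transverse)
  K <- assemble_stiffness(mesh)
  sols <- solve_fe_batch(mesh, lcs, K)
  U <- vapply(sols, function(s) s$sed, numeric(length(sols[[1]]$sed)))
  forces <- t(vapply(sols, function(s) s$reactions$distal, numeric(3)))
  prob <- ibr_problem(U, mesh$elem_volume,
                      tissue_target(nrow(U), config$Ustar))
  res <- ibr_solve(prob, forces = forces)
  list(result = res, forces = forces, mesh = mesh)
}

# homogenized-FE branch of the section workflow
hfe_section_ibr <- function(image, config, cortex_mask = NULL) {
  mesh <- build_hfe_model(image, element_size = config$hfe_element_size,
                          mapping = config$hfe_mapping,
                          sphere_diameter = config$sphere_diameter,
                          rho_threshold = config$rho_threshold,
                          cortex_mask = cortex_mask)
  lcs <- canonical_section_loadcases(mesh, config$section_displacement,
                                     config$fix_transverse)
  K <- assemble_stiffness(mesh)
  sols <- solve_fe_batch(mesh, lcs, K)
  U <- vapply(sols, function(s) s$sed, numeric(length(sols[[1]]$sed)))
  forces <- t(vapply(sols, function(s) s$reactions$distal, numeric(3)))
  model <- stimulus_model(config$Ustar, config$d)
  rho <- pmin(mesh$elem_rho, 1)
  prob <- ibr_problem(U, mesh$elem_volume, continuum_target(rho, model))
  res <- ibr_solve(prob, forces = forces, normalizer = rho^config$d)
  list(result = res, forces = forces, mesh = mesh)
}

#' Section study: micro-FE vs homogenized-FE inverse (re)modeling
#'
#' Builds a micro-FE model (tissue target stimulus) and a voxel homogenized
#' model (density-mapped material, continuum target stimulus Ustar * rho^d)
#' of the same section phantom, runs the three canonical load cases on each,
#' optimizes load scales, and compares the predicted unit and optimized
#' reaction forces.
#'
#' @param spec a [phantom_spec()] for the section (set `cortex_thickness`
#'   for the full-model variant).
#' @param config a [study_config()].
#' @return list with `mufe` and `hfe` branches (each: `result`, `forces`,
#'   `F_unit`, `F_opt`, `theta`), and `scores` (S_a, S_m between the two
#'   optimized forces).
#' @export
run_section_study <- function(spec, config = study_config()) {
  image <- generate_section_phantom(spec)
  cortex_mask <- NULL
  mu <- mufe_section_ibr(image, config)
  hf <- hfe_section_ibr(image, config, cortex_mask)
  branch <- function(b) list(
    s = b$result$s, alpha = b$result$alpha, forces = b$forces,
    F_unit = b$result$F_unit, F_opt = b$result$F_opt,
    cv_before = b$result$cv_before, cv_after = b$result$cv_after,
    theta = off_axis_angle(b$result$F_opt))
  list(mufe = branch(mu), hfe = branch(hf),
       scores = list(S_a = angle_score(mu$result$F_opt, hf$result$F_opt),
                     S_m = magnitude_score(mu$result$F_opt, hf$result$F_opt)))
}

#' Section batch: force comparison across several phantoms
#'
#' Runs [run_section_study()] per spec and assembles per-component
#' regressions of the homogenized predictions on the micro-FE predictions
#' (unit and optimized forces).
#'
#' @param specs list of [phantom_spec()].
#' @param config a [study_config()].
#' @return list with `studies`, `unit` and `opt` (`force_comparison`
#'   objects).
#' @export
run_section_batch <- function(specs, config = study_config()) {
  studies <- lapply(specs, run_section_study, config = config)
  Fu_a <- t(vapply(studies, function(s) s$mufe$F_unit, numeric(3)))
  Fu_b <- t(vapply(studies, function(s) s$hfe$F_unit, numeric(3)))
  Fo_a <- t(vapply(studies, function(s) s$mufe$F_opt, numeric(3)))
  Fo_b <- t(vapply(studies, function(s) s$hfe$F_opt, numeric(3)))
  list(studies = studies,
       unit = compare_forces(Fu_a, Fu_b),
       opt = compare_forces(Fo_a, Fo_b))
}

#' Serialize a section study (or batch) to JSON
#'
#' @param x result of [run_section_study()] or [run_cube_study()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(x, path) {
  jsonlite::write_json(strip_heavy(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

strip_heavy <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, function(e) inherits(e, c("hex_mesh", "voxel_image")),
                   TRUE)]
    lapply(x, strip_heavy)
  } else x
}
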