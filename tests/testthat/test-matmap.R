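test_that("material presets match the calibrated base constants", {
  expect_equal(bone_constants("cortical-density")$E0, 12000.0)
  expect_equal(bone_constants("trabecular-density")$E0, 8812.8)
  expect_equal(bone_constants("trabecular-fabric")$E0, 10320.4)
  # implied cortical Poisson ratio is consistent with the tissue nu = 0.3
  nu <- density_material(1, bone_constants("cortical-density"))$nu
  expect_equal(round(nu, 3), 0.300)
  # power-law evaluation
  m <- density_material(0.5, bone_constants("trabecular-density"))
  expect_equal(m$E, 8812.8 * 0.5^1.63)
  expect_error(density_material(0), "rho")
  expect_error(density_material(1.5), "rho")
})

test_that("Zysset-Curnier material reduces correctly and orders with fabric", {
  iso <- list(values = c(1, 1, 1), vectors = diag(3))
  zc <- zysset_curnier_material(1, iso)
  expect_equal(zc$E, rep(10320.4, 3))
  expect_equal(zc$nu, rep(0.2278, 3))
  expect_equal(zc$G, rep(3470.7, 3))

  # matched constants: isotropic fabric degenerates to the density material
  cst <- bone_constants("trabecular-density")
  cst$nu0 <- cst$E0 / (2 * cst$mu0) - 1
  cst$l <- 1.1
  zc2 <- zysset_curnier_material(0.4, iso, cst)
  dm <- density_material(0.4, bone_constants("trabecular-density"))
  expect_equal(zc2$C, dm$C, tolerance = 1e-9)

  # stiffness ordering follows fabric eigenvalue ordering
  mvals <- c(1.2, 1.0, 1 / 1.2)
  mvals <- mvals / prod(mvals)^(1 / 3)
  zc3 <- zysset_curnier_material(0.3, list(values = mvals, vectors = diag(3)))
  expect_true(zc3$E[1] > zc3$E[2] && zc3$E[2] > zc3$E[3])
})

test_that("Zysset-Curnier stiffness is SPD over a parameter sweep", {
  set.seed(8)
  for (i in 1:50) {
    rho <- stats::runif(1, 0.02, 1)
    mv <- exp(stats::runif(3, -0.5, 0.5))
    mv <- mv / prod(mv)^(1 / 3)
    if (max(mv) / min(mv) > 3) next
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    mat <- zysset_curnier_material(rho, list(values = mv, vectors = R))
    ev <- eigen(mat$C, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("sphere density sampling is geometric and monotone", {
  solid <- solid_image(20, 0.1)
  grid <- boneibr:::grid_mesh(array(TRUE, c(2, 2, 2)), 1)
  expect_equal(sample_density(solid, grid, sphere_diameter = 0.8),
               rep(1, 8))
  void <- voxel_image(array(0, c(20, 20, 20)), 0.1)
  expect_equal(sample_density(void, grid, sphere_diameter = 0.8), rep(0, 8))

  # half space: sphere centered on the interface samples ~0.5
  a <- array(0, c(50, 50, 50))
  a[, , 1:25] <- 1
  half <- voxel_image(a, 0.1)
  centro <- boneibr:::grid_mesh(array(TRUE, c(1, 1, 1)), 2.5,
                                origin = c(1.25, 1.25, 1.25))
  rho <- sample_density(half, centro, sphere_diameter = 2.5)
  expect_lt(abs(rho - 0.5), 0.02)

  # monotone: adding bone never decreases any sampled density
  b <- a
  b[10:20, 10:20, 30:40] <- 1
  rho2 <- sample_density(voxel_image(b, 0.1), grid, sphere_diameter = 0.8)
  rho1 <- sample_density(voxel_image(a, 0.1), grid, sphere_diameter = 0.8)
  expect_true(all(rho2 >= rho1))

  far <- boneibr:::grid_mesh(array(TRUE, c(1, 1, 1)), 1, origin = c(50, 50, 50))
  expect_error(sample_density(half, far, sphere_diameter = 1),
               "outside")
})

test_that("MIL fabric identifies plates and respects axis permutation", {
  a <- array(0, c(30, 30, 30))
  a[, , seq(2, 30, by = 5)] <- 1  # plates normal to axis 3
  f <- mil_fabric(voxel_image(a, 0.1))
  expect_equal(abs(f$vectors[3, 3]), 1, tolerance = 0.05)
  expect_lt(f$values[3], f$values[1] / 2)
  expect_equal(prod(f$values), 1, tolerance = 1e-9)

  # permuting image axes permutes the fabric eigenvectors
  b <- aperm(a, c(3, 2, 1))  # plates now normal to axis 1
  fb <- mil_fabric(voxel_image(b, 0.1))
  expect_equal(abs(fb$vectors[1, 3]), 1, tolerance = 0.05)
  # eigenvalues agree approximately (the direction set is not itself
  # permutation-symmetric, so equivariance is approximate)
  expect_equal(fb$values, f$values, tolerance = 0.1)

  expect_error(mil_fabric(solid_image(10)), "single-phase")
  expect_error(mil_fabric(voxel_image(a, 0.1), n_directions = 5),
               "9 directions")
})

test_that("build_hfe_model maps a solid image to the full-density material", {
  img <- solid_image(30, 0.2)  # 6 mm cube
  mesh <- build_hfe_model(img, element_size = 2, sphere_diameter = 1.5)
  expect_identical(nrow(mesh$elems), 27L)
  expect_equal(mesh$elem_rho, rep(1, 27))
  expect_equal(mesh$materials[[1]]$E, 8812.8)

  # fully void elements are dropped
  a <- array(0, c(30, 30, 30))
  a[1:10, , ] <- 1
  mesh2 <- build_hfe_model(voxel_image(a, 0.2), element_size = 2,
                           sphere_diameter = 1.0, rho_threshold = 0.05)
  expect_lt(nrow(mesh2$elems), 27L)
  expect_error(build_hfe_model(voxel_image(array(0, c(30, 30, 30)), 0.2),
                               element_size = 2, sphere_diameter = 1),
               "below the density threshold")
})

test_that("cortex mask switches elements to the cortical constants", {
  a <- array(1, c(20, 20, 20))
  img <- voxel_image(a, 0.2)
  cm <- array(FALSE, c(20, 20, 20))
  cm[1:10, , ] <- TRUE
  mesh <- build_hfe_model(img, element_size = 2, sphere_diameter = 1.0,
                          cortex_mask = cm)
  Es <- vapply(mesh$materials, function(m) m$E, 0)
  expect_setequal(round(unique(Es), 1), c(8812.8, 12000.0))
})

test_that("fabric mapping produces orthotropic elements on anisotropic bone", {
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = 0.25,
                       target_density = 0.35, correlation_length = 0.5,
                       anisotropy = c(1, 1, 2), seed = 6)
  img <- generate_grf_cube(spec)
  mesh <- build_hfe_model(img, element_size = 2, mapping = "density+fabric",
                          sphere_diameter = 2.0)
  kinds <- vapply(mesh$materials, function(m) m$kind, "")
  expect_true(any(kinds == "orthotropic"))
  # fabric-mapped axial modulus should exceed transverse on average
  ortho <- mesh$materials[kinds == "orthotropic"]
  e3 <- vapply(ortho, function(m) {
    ax <- which.max(abs(m$axes[3, ]))
    m$E[ax]
  }, 0)
  e1 <- vapply(ortho, function(m) {
    ax <- which.max(abs(m$axes[1, ]))
    m$E[ax]
  }, 0)
  expect_gt(mean(e3), mean(e1))
})
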