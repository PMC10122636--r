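test_that("image_to_mesh counts nodes and elements correctly", {
  img2 <- voxel_image(array(c(1, 1), c(2, 1, 1)), 1)
  m2 <- image_to_mesh(img2)
  expect_identical(nrow(m2$elems), 2L)
  expect_identical(nrow(m2$nodes), 12L)
  expect_equal(m2$elem_volume, rep(1, 2))

  m1 <- image_to_mesh(voxel_image(array(1, c(1, 1, 1)), 0.5))
  expect_identical(nrow(m1$elems), 1L)
  expect_identical(nrow(m1$nodes), 8L)
  expect_equal(m1$elem_volume, 0.125)

  m27 <- image_to_mesh(solid_image(3))
  expect_identical(nrow(m27$elems), 27L)
  expect_identical(nrow(m27$nodes), 64L)

  expect_error(image_to_mesh(voxel_image(array(0, c(2, 2, 2)), 1)),
               "empty mesh")
})

test_that("hex stiffness is symmetric with 6 rigid-body modes", {
  K <- hex_stiffness(material_isotropic(12000, 0.3), c(0.5, 0.7, 1.1))
  expect_equal(max(abs(K - t(K))), 0)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-9 * max(ev)), 6L)
  # rigid translation is a zero-energy mode
  u <- rep(c(1, -2, 3), 8)
  expect_lt(max(abs(K %*% u)), 1e-9 * max(abs(K)))
  expect_error(hex_stiffness(material_isotropic(12000, 0.3), c(1, 0, 1)),
               "edges")
})

test_that("hex stiffness reproduces the constrained-modulus energy", {
  E <- 12000; nu <- 0.3; delta <- 1.887e-4
  K <- hex_stiffness(material_isotropic(E, nu), 1)
  corners <- boneibr:::hex_signs / 2 + 0.5
  u <- as.vector(t(cbind(0, 0, delta * corners[, 3])))
  C3333 <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  expect_rel_equal(0.5 * sum(u * (K %*% u)), 0.5 * C3333 * delta^2, 1e-12)
})

test_that("patch test: affine KUBC reproduces uniform strain and SED", {
  mesh <- image_to_mesh(solid_image(4, 5.3 / 4))
  lcs <- kubc_loadcases(mesh, -0.001)
  sol <- solve_fe(mesh, lcs[[3]])
  Ebar <- -0.001 / 5.3
  expect_lt(max(abs(sol$strain[, 3] - Ebar)), 1e-10)
  expect_lt(max(abs(sol$strain[, -3])), 1e-10)
  expect_lt(diff(range(sol$sed)), 1e-14)
  C <- material_isotropic(12000, 0.3)$C
  expect_rel_equal(sol$sed[1], 0.5 * C[3, 3] * Ebar^2, 1e-8)
})

test_that("linearity: scaling displacements scales reactions and SED", {
  img <- voxel_image(symmetric_lattice_image(10, 0.5)$values, 0.5)
  mesh <- image_to_mesh(img)
  lcs1 <- canonical_section_loadcases(mesh, 0.01)
  lcs2 <- canonical_section_loadcases(mesh, 0.02)
  K <- assemble_stiffness(mesh)
  s1 <- solve_fe(mesh, lcs1[[3]], K)
  s2 <- solve_fe(mesh, lcs2[[3]], K)
  expect_rel_equal(s2$reactions$distal, 2 * s1$reactions$distal, 1e-9)
  expect_rel_equal(s2$sed, 4 * s1$sed, 1e-9)
})

test_that("global equilibrium: distal and proximal reactions balance", {
  spec <- phantom_spec(shape = c(12, 12, 16), spacing = 0.3,
                       target_density = 0.35, correlation_length = 0.5,
                       seed = 5)
  mesh <- image_to_mesh(generate_section_phantom(spec))
  lcs <- canonical_section_loadcases(mesh, 0.01)
  sol <- solve_fe(mesh, lcs[[3]])
  Fd <- sol$reactions$distal
  Fp <- sol$reactions$proximal
  expect_lt(max(abs(Fd + Fp)), 1e-6 * max(abs(Fd)))
})

test_that("canonical load cases: prescriptions and axis-swap symmetry", {
  img <- symmetric_lattice_image(10, 0.5)
  mesh <- image_to_mesh(img)
  lcs <- canonical_section_loadcases(mesh, 0.01)
  expect_named(lcs[[3]]$sets, c("distal", "proximal"))
  lc3 <- lcs[[3]]$prescribed
  distal3 <- lc3[lc3$comp == 3 & lc3$value != 0, ]
  expect_true(all(distal3$value == -0.01))
  # magnitude 0 gives the zero solution
  z <- solve_fe(mesh, canonical_section_loadcases(mesh, 0)[[3]])
  expect_equal(max(abs(z$u)), 0)
  expect_equal(max(abs(z$reactions$distal)), 0)
  # 1<->2 symmetric lattice: LC1 and LC2 reactions swap components
  K <- assemble_stiffness(mesh)
  s1 <- solve_fe(mesh, lcs[[1]], K)
  s2 <- solve_fe(mesh, lcs[[2]], K)
  expect_rel_equal(s1$reactions$distal[c(1, 2, 3)],
                   s2$reactions$distal[c(2, 1, 3)], 1e-8)
})

test_that("sparse solve agrees with a dense direct solve", {
  spec <- phantom_spec(shape = c(8, 8, 10), spacing = 0.4,
                       target_density = 0.4, correlation_length = 0.5,
                       seed = 2)
  mesh <- image_to_mesh(generate_section_phantom(spec))
  expect_lte(nrow(mesh$elems), 500L)
  lc <- canonical_section_loadcases(mesh, 0.01)[[1]]
  u_dense <- dense_solve_oracle(mesh, lc)
  u_sparse <- solve_fe(mesh, lc)$u
  expect_rel_equal(u_sparse, u_dense, 1e-8)
})

test_that("solution is invariant under voxel-grid translation", {
  a <- array(0, c(8, 8, 8))
  a[2:5, 2:5, 2:7] <- 1
  b <- array(0, c(8, 8, 8))
  b[3:6, 4:7, 2:7] <- 1  # same block, shifted within the grid
  ma <- image_to_mesh(voxel_image(a, 0.5))
  mb <- image_to_mesh(voxel_image(b, 0.5))
  sa <- solve_fe(ma, canonical_section_loadcases(ma, 0.01)[[3]])
  sb <- solve_fe(mb, canonical_section_loadcases(mb, 0.01)[[3]])
  expect_rel_equal(sort(sa$sed), sort(sb$sed), 1e-9)
  expect_rel_equal(sa$reactions$distal[3], sb$reactions$distal[3], 1e-9)
})

test_that("singular systems are reported as disconnection", {
  a <- array(0, c(6, 6, 6))
  a[1:2, 1:2, 1:6] <- 1  # main column spanning both planes
  a[5:6, 5:6, 3:4] <- 1  # floating block touching neither plane
  mesh <- image_to_mesh(voxel_image(a, 0.5))
  lc <- canonical_section_loadcases(mesh, 0.01)[[3]]
  # CHOLMOD additionally warns before the factorization error surfaces
  suppressWarnings(
    expect_error(solve_fe(mesh, lc), "singular|disconnected|non-finite"))
})
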