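unit_cube_mesh <- function() {
  vol <- structure(list(labels = array(4L, c(1L, 1L, 1L)),
                        voxel_size_mm = 1000, origin_mm = rep(0, 3L)),
                   class = "labeled_volume")
  voxels_to_hex_mesh(vol, node_shift = 0)   # a single 1 m cube
}

test_that("unit-cube stiffness equals the exact symbolic matrix", {
  mesh <- unit_cube_mesh()
  K <- as.matrix(assemble_stiffness(mesh, c("4" = 1))$K)
  perm <- mesh$elements[1L, ]
  K <- K[perm, perm]
  # exact integrals of trilinear gradient products over the unit cube:
  # diagonal 1/3, edge-adjacent corners 0, all diagonals -1/12
  signs <- cbind(c(-1, 1, 1, -1, -1, 1, 1, -1),
                 c(-1, -1, 1, 1, -1, -1, 1, 1),
                 c(-1, -1, -1, -1, 1, 1, 1, 1))
  hops <- as.matrix(stats::dist(signs, method = "manhattan")) / 2
  expected <- matrix(-1 / 12, 8L, 8L)
  expected[hops == 1] <- 0
  diag(expected) <- 1 / 3
  expect_equal(K, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(rowSums(K))), 0, tolerance = 1e-15)
})

test_that("stiffness scales linearly in conductivity and validates labels", {
  small <- fix_small()
  K1 <- assemble_stiffness(small$mesh, small$profile)$K
  sig3 <- small$profile$sigma * 3
  K3 <- assemble_stiffness(small$mesh, sig3)$K
  expect_equal(K3@x, 3 * K1@x, tolerance = 1e-14)
  expect_error(assemble_stiffness(small$mesh, c("1" = 0.43)),
               "no conductivity")
  bad <- small$profile$sigma
  bad[] <- -bad
  expect_error(assemble_stiffness(small$mesh, bad), "strictly positive")
  # symmetry and zero row sums on a real mesh
  expect_lt(max(abs(K1 - Matrix::t(K1))), 1e-12 * max(abs(K1@x)))
  rs <- as.numeric(K1 %*% rep(1, nrow(small$mesh$nodes)))
  expect_lt(max(abs(rs)), 1e-10 * max(abs(K1@x)))
})

test_that("partial-integration load of a centered x-dipole is +-1/4 on faces", {
  mesh <- unit_cube_mesh()
  b <- dipole_load_vector(mesh, c(0, 0, 0), c(1, 0, 0))
  bn <- b[mesh$elements[1L, ]]
  xsign <- c(-1, 1, 1, -1, -1, 1, 1, -1)
  expect_equal(bn, xsign / 4, tolerance = 1e-12)
  expect_equal(sum(b), 0, tolerance = 1e-15)
  expect_equal(dipole_load_vector(mesh, c(100, -200, 0), c(0, 0, 0)),
               rep(0, nrow(mesh$nodes)))
})

test_that("load vectors sum to zero and reproduce moments", {
  small <- fix_small()
  pos <- c(4.3, -2.1, 7.7)
  mom <- c(2e-3, -1e-3, 5e-4)
  for (sm in c("partial", "venant")) {
    b <- source_load_vector(small$mesh, pos, mom, source_model = sm)
    expect_lt(abs(sum(b)), 1e-12 * max(abs(b)))
    # first moment about the source equals the dipole moment
    nz <- which(b != 0)
    dx <- sweep(small$mesh$nodes[nz, , drop = FALSE] * 1e-3, 2L, pos * 1e-3,
                "-")
    expect_equal(as.numeric(crossprod(dx, b[nz])), mom, tolerance = 1e-9)
  }
  expect_error(dipole_load_vector(small$mesh, c(100, 0, 0), c(1, 0, 0)),
               "outside the mesh")
})

test_that("solve_potential honors its contract", {
  small <- fix_small()
  sys <- assemble_stiffness(small$mesh, small$profile)
  n <- nrow(small$mesh$nodes)
  expect_equal(solve_potential(sys, numeric(n)), numeric(n))
  expect_error(solve_potential(sys, rep(1, n)), "sum to zero")
  b <- source_load_vector(small$mesh, c(4, 0, -3), c(3.5e-3, 0, 0))
  u <- solve_potential(sys, b, rel_tol = 1e-9)
  expect_equal(mean(u), 0, tolerance = 1e-15 * max(abs(u)))
  r <- as.numeric(sys$K %*% u) - b
  expect_lt(sqrt(sum(r^2)) / sqrt(sum(b^2)), 1e-9)
})

test_that("FEM surface potential matches the homogeneous closed form", {
  # homogeneous sphere, central radial dipole: V = 3 m cos(theta)/(4 pi s R^2)
  vol <- sphere_phantom(c(gray = 30), voxel_size_mm = 2)
  mesh <- voxels_to_hex_mesh(vol, 0.3)
  sys <- assemble_stiffness(mesh, conductivity_profile("4C"))
  m <- 3.5e-3
  b <- source_load_vector(mesh, c(0, 0, 0), c(0, 0, m))
  u <- solve_potential(sys, b, rel_tol = 1e-9)
  # evaluate just inside the surface along the axis and scale the closed form
  rr <- 28
  vfem <- interpolate_at_points(mesh, u, rbind(c(0, 0, rr), c(0, 0, -rr)))
  R <- 0.030
  rb <- rr * 1e-3
  sigma <- 0.33
  # interior closed form for a central dipole in a homogeneous sphere:
  # V(r, theta) = m cos(theta) (1/r^2 + 2 r / R^3) / (4 pi sigma)
  closed <- m * (1 / rb^2 + 2 * rb / R^3) / (4 * pi * sigma)
  expect_equal(vfem[1], closed, tolerance = 0.05)
  expect_equal(vfem[2], -closed, tolerance = 0.05)
})

test_that("direct and transfer potential tables agree by reciprocity", {
  small <- fix_small()
  mont <- montage_channels(small$electrodes)
  sys <- assemble_stiffness(small$mesh, small$profile)
  direct <- simulate_potential_table(small$mesh, small$profile,
                                     small$electrodes, small$plan,
                                     montage = mont, rel_tol = 1e-10,
                                     system = sys)
  transfer <- simulate_potential_table(small$mesh, small$profile,
                                       small$electrodes, small$plan,
                                       montage = mont, use_transfer = TRUE,
                                       rel_tol = 1e-10, system = sys)
  expect_lt(max(abs(direct - transfer)) / max(abs(direct)), 1e-6)
})

test_that("bipolar tables are gauge invariant and antisymmetric in the pair", {
  small <- fix_small()
  mesh <- small$mesh
  mont <- montage_channels(small$electrodes)
  sys <- assemble_stiffness(mesh, small$profile)
  pos <- contact_positions(small$electrodes)
  b <- source_load_vector(mesh, c(2, 1, -4), c(0, 3.5e-3, 0))
  u <- solve_potential(sys, b)
  va <- interpolate_at_points(mesh, u, pos[mont$contact_a, , drop = FALSE])
  vb <- interpolate_at_points(mesh, u, pos[mont$contact_b, , drop = FALSE])
  u2 <- u + 12.34   # constant gauge shift cancels in differences
  va2 <- interpolate_at_points(mesh, u2, pos[mont$contact_a, , drop = FALSE])
  vb2 <- interpolate_at_points(mesh, u2, pos[mont$contact_b, , drop = FALSE])
  expect_equal(va - vb, va2 - vb2, tolerance = 1e-9)

  plan <- small$plan
  swapped <- plan
  swapped$pairs$anode <- plan$pairs$cathode
  swapped$pairs$cathode <- plan$pairs$anode
  t1 <- simulate_potential_table(mesh, small$profile, small$electrodes, plan,
                                 montage = mont, rel_tol = 1e-10, system = sys)
  t2 <- simulate_potential_table(mesh, small$profile, small$electrodes,
                                 swapped, montage = mont, rel_tol = 1e-10,
                                 system = sys)
  expect_equal(unclass(t1), -unclass(t2), tolerance = 1e-6,
               ignore_attr = TRUE)
})
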