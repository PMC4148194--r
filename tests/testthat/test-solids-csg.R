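test_that("surveyor volume is exact on a hand-built cube mesh", {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, outward-oriented
  tri <- matrix(c(1,3,4, 1,4,2,   # z = 0 face (normal -z)
                  5,6,8, 5,8,7,   # z = 1
                  1,2,6, 1,6,5,   # y = 0
                  3,7,8, 3,8,4,   # y = 1
                  1,5,7, 1,7,3,   # x = 0
                  2,4,8, 2,8,6),  # x = 1
                ncol = 3, byrow = TRUE)
  mesh <- list(vertices = v, triangles = tri)
  expect_true(mesh_is_closed(mesh))
  expect_equal(mesh_volume(mesh), 1)
  open_mesh <- list(vertices = v, triangles = tri[-1, ])
  expect_false(mesh_is_closed(open_mesh))
  expect_error(mesh_volume(open_mesh), "not closed")
})

test_that("CSG identities hold exactly at occupancy level", {
  bp <- ball_pair(4, c(-2, 0, 0), 4, c(2, 0, 0))
  A <- bp$A; B <- bp$B
  expect_identical(csg_intersection(A, A)$occupancy, A$occupancy)
  expect_identical(csg_union(A, A)$occupancy, A$occupancy)
  expect_true(is_empty_solid(csg_difference(A, A)))
  E <- empty_solid(A$lattice)
  expect_identical(csg_union(A, E)$occupancy, A$occupancy)
  # no-op CSG keeps the boundary bit-identical (crossing inheritance)
  expect_identical(csg_intersection(A, A)$mesh$vertices, A$mesh$vertices)
  expect_equal(solid_volume(csg_union(A, E)), solid_volume(A))
})

test_that("disjoint and overlapping sphere pairs obey the analytic algebra", {
  far <- ball_pair(3, c(-5, 0, 0), 3, c(5, 0, 0))
  expect_true(is_empty_solid(csg_intersection(far$A, far$B)))
  expect_equal(solid_volume(csg_union(far$A, far$B)),
               solid_volume(far$A) + solid_volume(far$B),
               tolerance = 0.01)
  near <- ball_pair(4, c(-2, 0, 0), 4, c(2, 0, 0))
  expect_equal(solid_volume(csg_intersection(near$A, near$B)),
               sphere_lens_volume(4, 4), tolerance = 0.03)
})

test_that("inclusion-exclusion and the difference identity hold on random sphere pairs", {
  set.seed(101)
  for (i in 1:8) {
    r1 <- runif(1, 2.5, 4); r2 <- runif(1, 2.5, 4)
    off <- runif(3, -1, 1) * (r1 + r2) / 3
    bp <- ball_pair(r1, c(0, 0, 0), r2, off, spacing = 0.5)
    vU <- solid_volume(csg_union(bp$A, bp$B))
    vI <- solid_volume(csg_intersection(bp$A, bp$B))
    vA <- solid_volume(bp$A); vB <- solid_volume(bp$B)
    expect_lt(abs(vU - vA - vB + vI), 0.01 * vU)
    # difference identity, exact at occupancy level: (A - B) and (A ^ B)
    # partition A's occupancy
    D <- csg_difference(bp$A, bp$B); I <- csg_intersection(bp$A, bp$B)
    expect_identical(D$occupancy | I$occupancy, bp$A$occupancy)
    expect_false(any(D$occupancy & I$occupancy))
    expect_equal(voxel_volume(D) + voxel_volume(I), voxel_volume(bp$A))
  }
})

test_that("surveyor volume agrees with the voxel-count oracle on CSG outputs", {
  set.seed(202)
  for (i in 1:6) {
    r1 <- runif(1, 2.5, 4); r2 <- runif(1, 2.5, 4)
    bp <- ball_pair(r1, c(0, 0, 0), r2, runif(3, -2, 2), spacing = 0.5)
    for (S in list(csg_union(bp$A, bp$B), csg_intersection(bp$A, bp$B),
                   csg_difference(bp$A, bp$B))) {
      # the voxel oracle's half-cell surface bias needs volumes well above
      # one cell; sub-resolution slivers are excluded
      if (is_empty_solid(S) || voxel_volume(S) < 50) next
      expect_equal(solid_volume(S), voxel_volume(S), tolerance = 0.05)
    }
  }
})

test_that("jaccard distance identities", {
  bp <- ball_pair(4, c(-2, 0, 0), 4, c(2, 0, 0))
  expect_identical(jaccard_distance(bp$A, bp$A), 0)
  far <- ball_pair(3, c(-5, 0, 0), 3, c(5, 0, 0))
  expect_identical(jaccard_distance(far$A, far$B), 1)
  expect_equal(jaccard_distance(bp$A, bp$B), jaccard_distance(bp$B, bp$A))
  # nested solids: 1 - (r_small / r_large)^3
  nest <- ball_pair(3, c(0, 0, 0), 4, c(0, 0, 0), spacing = 0.25)
  expect_equal(jaccard_distance(nest$A, nest$B), 1 - (3 / 4)^3,
               tolerance = 0.02)
  E <- empty_solid(bp$A$lattice)
  expect_error(jaccard_distance(E, E), "empty")
})

test_that("CSG refuses non-congruent lattices, naming both", {
  A <- ball_solid(3, spacing = 0.5)
  B <- ball_solid(3, spacing = 0.4)
  expect_error(csg_intersection(A, B), "congruent lattices")
})

test_that("resample preserves occupancy on the same lattice and volume across lattices", {
  S <- ball_solid(3.7, ctr = c(0.13, 0.07, -0.11), spacing = 0.5)
  same <- resample_to(S, S$lattice)
  expect_identical(same$occupancy, S$occupancy)
  fine <- resample_to(S, lattice3d(S$lattice$origin, 0.25,
                                   S$lattice$dims * 2L - 1L))
  expect_equal(solid_volume(fine), solid_volume(S), tolerance = 0.02)
  shifted <- lattice3d(S$lattice$origin + c(0.21, -0.13, 0.17),
                       S$lattice$spacing, S$lattice$dims)
  tr <- resample_to(S, shifted)
  expect_equal(voxel_volume(tr), voxel_volume(S), tolerance = 0.02)
  expect_error(resample_to(S, lattice3d(S$lattice$origin, 1.5, c(10, 10, 10))),
               "twice")
})

test_that("OFF and PLY meshes round-trip, and an OFF cube voxelizes to its volume", {
  S <- ball_solid(3, spacing = 0.5)
  p1 <- tempfile(fileext = ".off"); p2 <- tempfile(fileext = ".ply")
  write_off(S, p1); write_ply(S, p2)
  m1 <- read_off(p1); m2 <- read_ply(p2)
  expect_equal(m1$vertices, S$mesh$vertices, tolerance = 1e-6)
  expect_identical(m1$triangles, S$mesh$triangles)
  expect_equal(m2$vertices, S$mesh$vertices, tolerance = 1e-6)
  expect_equal(mesh_volume(m1), solid_volume(S), tolerance = 1e-6)
  # 10 A cube as OFF input
  v <- as.matrix(expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10)))
  tri <- matrix(c(1,3,4, 1,4,2, 5,6,8, 5,8,7, 1,2,6, 1,6,5,
                  3,7,8, 3,8,4, 1,5,7, 1,7,3, 2,4,8, 2,8,6),
                ncol = 3, byrow = TRUE)
  p3 <- tempfile(fileext = ".off")
  write_off(list(vertices = v, triangles = tri), p3)
  lat <- lattice3d(c(-2, -2, -2), 0.5, c(29, 29, 29))
  cube <- cavity_solid(p3, lat)
  expect_equal(solid_volume(cube), 1000, tolerance = 0.02)
  unlink(c(p1, p2, p3))
})

test_that("occupancy run-length text round-trips", {
  S <- ball_solid(3, spacing = 0.5)
  p <- tempfile(fileext = ".rle")
  write_occupancy(S, p)
  S2 <- read_occupancy(p)
  expect_identical(S2$occupancy, S$occupancy)
  expect_true(lattice_congruent(S2$lattice, S$lattice))
  unlink(p)
})
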