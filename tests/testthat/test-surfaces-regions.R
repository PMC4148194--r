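test_that("union-of-balls solids match analytic sphere volumes", {
  lat <- lattice3d(c(-5, -5, -5), 0.25, c(41, 41, 41))
  s1 <- single_atom_structure(radius = 2)
  ub <- union_of_balls_solid(s1, lat)
  expect_equal(solid_volume(ub), ball_volume(2), tolerance = 0.03)
  # two far-apart atoms: volumes add
  s2 <- single_atom_structure(x = c(-4.5, 4.5), radius = 1.6, resnum = 1:2)
  lat2 <- lattice3d(c(-8, -8, -8), 0.25, c(65, 65, 65))
  expect_equal(solid_volume(union_of_balls_solid(s2, lat2)),
               2 * ball_volume(1.6), tolerance = 0.03)
  # inflation strictly grows the solid
  expect_gt(solid_volume(union_of_balls_solid(s1, lat, inflate = 1.4)),
            solid_volume(ub))
  expect_true(is_empty_solid(
    union_of_balls_solid(charged_structure(s1$atoms[0, ]), lat)))
})

test_that("the molecular surface is a closing: no-op on a ball, contains the union, seals pores", {
  lat <- lattice3d(c(-5, -5, -5), 0.25, c(41, 41, 41))
  s1 <- single_atom_structure(radius = 2)
  ses <- molecular_surface_solid(s1, lat)
  ub <- union_of_balls_solid(s1, lat)
  expect_equal(solid_volume(ses), ball_volume(2), tolerance = 0.03)
  expect_false(any(ub$occupancy & !ses$occupancy))   # SES >= union, always
  # two atoms 0.1 A short of probe passage: the reentrant neck appears in
  # the closed region (voxel oracle: strictly more occupancy than the union)
  s2 <- single_atom_structure(x = c(-3.35, 3.35), radius = 2, resnum = 1:2)
  lat2 <- lattice3d(c(-8, -8, -8), 0.25, c(65, 65, 65))
  ub2 <- union_of_balls_solid(s2, lat2)
  ses2 <- molecular_surface_solid(s2, lat2)
  expect_false(any(ub2$occupancy & !ses2$occupancy))
  expect_gt(sum(ses2$occupancy), sum(ub2$occupancy))
  # a ring pore narrower than the probe is sealed outright
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  s3 <- single_atom_structure(x = 3 * cos(ang), y = 3 * sin(ang), z = 0,
                              radius = 2, resnum = 1:6)
  ub3 <- union_of_balls_solid(s3, lat2)
  ses3 <- molecular_surface_solid(s3, lat2)
  expect_gt(solid_volume(ses3), 1.03 * solid_volume(ub3))
  expect_true(is_empty_solid(
    molecular_surface_solid(charged_structure(s1$atoms[0, ]), lat)))
})

test_that("interface residues follow the 5 A atom-atom rule symmetrically", {
  A <- single_atom_structure(x = 0)
  mk_at <- function(d) single_atom_structure(x = d, chain = "B")
  expect_equal(interface_residues(A, mk_at(4.9)),
               list(A = "A:1", B = "B:1"))
  expect_equal(interface_residues(A, mk_at(5.1)),
               list(A = character(0), B = character(0)))
  # 3-residue chain with only the middle within 5 A; brute-force check
  A3 <- single_atom_structure(x = c(-8, 0, 8), y = 0, resnum = 1:3)
  B1 <- single_atom_structure(x = 0, y = 4.5, chain = "B")
  ir <- interface_residues(A3, B1)
  expect_equal(ir$A, "A:2")
  expect_equal(ir$B, "B:1")
  brute <- sqrt(rowSums((atom_coords(A3) -
                         matrix(atom_coords(B1), 3, 3, byrow = TRUE))^2))
  expect_equal(which(brute <= 5), 2L)
  # swap symmetry
  ir2 <- interface_residues(B1, A3)
  expect_identical(ir2, list(A = ir$B, B = ir$A))
})

test_that("the interface region is the union of 5 A spheres over interfacial atoms", {
  A <- single_atom_structure(x = -2.5)
  B <- single_atom_structure(x = 2.5, chain = "B")
  lat <- lattice3d(c(-9, -9, -9), 0.3, c(61, 61, 61))
  reg <- interface_region(A, B, lat)
  r <- 5; d <- 5
  expect_equal(solid_volume(reg),
               2 * ball_volume(r) - sphere_lens_volume(r, d),
               tolerance = 0.03)
  # doubling the sphere radius grows the region
  reg2 <- suppressWarnings(interface_region(A, B, lat,
    region_params(interface_sphere_radius = 7)))
  expect_gt(solid_volume(reg2), solid_volume(reg))
  far <- single_atom_structure(x = 100, chain = "B")
  expect_warning(r0 <- interface_region(A, far, lat), "empty")
  expect_true(is_empty_solid(r0))
})

test_that("cavity solids build from sphere specs and reject empty or open input", {
  lat <- lattice3d(c(-6, -6, -6), 0.4, c(31, 31, 31))
  C <- cavity_solid(data.frame(x = 0, y = 0, z = 0, radius = 4), lat)
  expect_equal(solid_volume(C), ball_volume(4), tolerance = 0.03)
  expect_error(cavity_solid(data.frame(x = numeric(0), y = numeric(0),
                                       z = numeric(0),
                                       radius = numeric(0)), lat), "empty")
  # sphere spec file path
  p <- tempfile(fileext = ".txt")
  write_cavity_spec(data.frame(x = 0, y = 0, z = 0, radius = 3), p)
  expect_equal(solid_volume(cavity_solid(p, lat)), ball_volume(3),
               tolerance = 0.03)
  unlink(p)
  # open mesh input is refused
  S <- ball_solid(3, spacing = 0.5)
  open_mesh <- list(vertices = S$mesh$vertices,
                    triangles = S$mesh$triangles[-1, ])
  po <- tempfile(fileext = ".off")
  write_off(open_mesh, po)
  expect_error(cavity_solid(po, lat), "not closed")
  unlink(po)
})
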