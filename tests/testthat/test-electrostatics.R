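test_that("PQR parsing handles single atoms, chains and net charge", {
  p <- tempfile(fileext = ".pqr")
  writeLines("ATOM 1 NZ LYS A 1 0.000 0.000 0.000 1.0000 1.5000", p)
  s <- read_pqr(p)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(length(residue_ids(s)), 1)
  expect_equal(net_charge(s), 1)
  # two chains give distinct residue ids; chainless layout also parses
  writeLines(c("ATOM 1 CA GLY A 1 0 0 0 0.10 1.7",
               "ATOM 2 CA GLY B 1 3 0 0 -0.25 1.7",
               "ATOM 3 OD1 ASP B 2 5 0 0 -0.50 1.5",
               "ATOM 4 OD2 ASP B 2 6 0 0 -0.50 1.5",
               "ATOM 5 NZ LYS B 3 8 0 0 1.00 1.5"), p)
  s2 <- read_pqr(p)
  expect_equal(residue_ids(s2), c("A:1", "B:1", "B:2", "B:3"))
  expect_equal(net_charge(s2), 0.10 - 0.25 - 0.5 - 0.5 + 1)
  writeLines("ATOM 1 CA GLY 1 0 0 0 0.5 1.7", p)
  expect_equal(net_charge(read_pqr(p)), 0.5)
  writeLines("ATOM 1 CA GLY A 1 0 0 0 0.5", p)  # missing radius column
  expect_error(read_pqr(p), "line 1")
  unlink(p)
})

test_that("PQR writing round-trips a toy structure", {
  s <- toy_structure(list(seed = 5, residues = data.frame(
    charge = c(1, -0.5, 0), n_atoms = c(1, 2, 3))))
  p <- tempfile(fileext = ".pqr")
  write_pqr(s, p)
  s2 <- read_pqr(p)
  expect_equal(s2$atoms$charge, s$atoms$charge, tolerance = 1e-6)
  expect_equal(atom_coords(s2), atom_coords(s), tolerance = 1e-4)
  expect_equal(residue_ids(s2), residue_ids(s))
  unlink(p)
})

test_that("formal-charge fallback places the expected charges", {
  asp <- single_atom_structure(x = c(0, 1.2, 1.2), y = c(0, 1, -1), z = 0,
                               name = c("CB", "OD1", "OD2"), resname = "ASP",
                               resnum = 1)
  asp <- suppressMessages(assign_default_charges(asp))
  expect_equal(net_charge(asp), -1)
  gly <- single_atom_structure(x = 0:2, name = "CA", resname = "GLY",
                               resnum = 1:3)
  expect_equal(net_charge(suppressMessages(assign_default_charges(gly))), 0)
  expect_warning(suppressMessages(
    assign_default_charges(single_atom_structure(name = "X1",
                                                 resname = "UNK"))),
    "unknown residue")
  # Lys + Glu pair: net zero but a live dipole field
  pair <- single_atom_structure(x = c(0, 4), name = c("NZ", "OE1"),
                                resname = c("LYS", "GLU"), resnum = 1:2)
  pair <- suppressMessages(assign_default_charges(pair))
  expect_equal(net_charge(pair), 1 - 0.5)
  lat <- lattice3d(c(-6, -6, -6), 1, c(13, 13, 13))
  f <- compute_field(pair, lat)
  expect_gt(max(abs(f$values)), 0)
})

test_that("the screened-Coulomb field matches the closed form off-singularity", {
  m <- electrostatic_model()
  s <- single_atom_structure(charge = 1)
  lat <- lattice3d(c(-10.05, -10.05, -10.05), 0.5, c(41, 41, 41))
  f <- compute_field(s, lat, m)
  p <- lattice_points(lat)
  d <- sqrt(rowSums(p^2))
  sel <- d > 1
  expect_lt(max(abs(f$values[sel] - m$lvac / (80 * d[sel]))), 1e-6)
  # phi = 1 kT/e at d = lvac / eps exactly
  expect_equal(m$lvac * 1 / (80 * (m$lvac / 80)), 1)
  # screening: kappa > 0 attenuates by exp(-kappa d)
  mk <- electrostatic_model(kappa = 0.2)
  fk <- compute_field(s, lat, mk)
  expect_equal(fk$values[sel], f$values[sel] * exp(-0.2 * d[sel]),
               tolerance = 1e-12)
  empty_s <- charged_structure(single_atom_structure()$atoms[0, ])
  expect_error(compute_field(empty_s, lat, m), "no atoms")
})

test_that("fields superpose and nullification equals removing the residue's own field", {
  s <- single_atom_structure(x = c(-2, 3), charge = c(1, -0.7),
                             resnum = c(1, 2))
  lat <- lattice3d(c(-8.1, -8.1, -8.1), 0.6, c(28, 28, 28))
  f_all <- compute_field(s, lat)
  f1 <- compute_field(single_atom_structure(x = -2, charge = 1), lat)
  f2 <- compute_field(single_atom_structure(x = 3, charge = -0.7), lat)
  expect_equal(f_all$values, f1$values + f2$values, tolerance = 1e-12)
  nul <- nullify_residue(s, "A:2")
  expect_equal(nul$atoms$charge, c(1, 0))
  expect_equal(nrow(nul$atoms), 2)
  fn <- compute_field(nul, lat)
  expect_equal(f_all$values - fn$values, f2$values, tolerance = 1e-12)
  # nullifying an uncharged residue changes nothing, bit for bit
  s0 <- single_atom_structure(x = c(0, 4), charge = c(1, 0), resnum = 1:2)
  expect_identical(compute_field(nullify_residue(s0, "A:2"), lat)$values,
                   compute_field(s0, lat)$values)
  expect_error(nullify_residue(s, "A:9"), "valid ids")
})

test_that("the finite-difference LPB solver reduces to Coulomb and to the Born ion", {
  m <- electrostatic_model()
  s <- single_atom_structure(charge = 1)
  lat <- lattice3d(c(-10, -10, -10), 0.5, c(41, 41, 41))
  # uniform dielectric, no salt: discrete solution tracks 1/r beyond 2 cells
  mu <- electrostatic_model("fd_lpb", eps_solute = 80, kappa = 0)
  fu <- compute_field(s, lat, mu)
  p <- lattice_points(lat); d <- sqrt(rowSums(p^2))
  sel <- d > 2 * 0.5 & d <= 8
  coul <- m$lvac / (80 * d[sel])
  expect_lt(max(abs(fu$values[sel] - coul) / coul), 0.05)
  # charged sphere in salt: Debye-Hueckel closed form outside
  a <- 3; kap <- 0.1
  sb <- single_atom_structure(charge = 1, radius = a)
  latb <- lattice3d(c(-14, -14, -14), 0.5, c(57, 57, 57))
  mb <- electrostatic_model("fd_lpb", eps_solute = 4, kappa = kap)
  fb <- compute_field(sb, latb, mb)
  pb <- lattice_points(latb); db <- sqrt(rowSums(pb^2))
  exact <- mb$lvac * exp(-kap * (db - a)) / (80 * (1 + kap * a) * db)
  selb <- db >= 4 & db <= 9
  expect_lt(max(abs(fb$values[selb] - exact[selb]) / exact[selb]), 0.08)
  # nullification never touches the dielectric mask
  s2 <- single_atom_structure(x = c(0, 3), charge = c(1, -1), resnum = 1:2)
  expect_identical(dielectric_mask(nullify_residue(s2, "A:2"), lat),
                   dielectric_mask(s2, lat))
})

test_that("OpenDX grids round-trip and load as external fields", {
  lat <- lattice3d(c(-1.5, 0, 2), 0.75, c(5, 4, 3))
  f <- field_from_function(lat, function(p) p[, 1] - 2 * p[, 2] + 0.5 * p[, 3])
  p <- tempfile(fileext = ".dx")
  write_dx(f, p)
  f2 <- read_dx(p)
  expect_true(lattice_congruent(f2$lattice, lat, tol = 1e-6))
  expect_equal(f2$values, f$values, tolerance = 1e-9)
  # external_grid model: exact-match load and trilinear resample of a
  # linear field (trilinear interpolation is exact for linear fields)
  m <- electrostatic_model("external_grid", dx_path = p)
  g <- compute_field(NULL, lat, m)
  expect_equal(g$values, f$values, tolerance = 1e-9)
  lat2 <- lattice3d(c(-1.2, 0.3, 2.2), 0.5, c(4, 4, 2))
  g2 <- compute_field(NULL, lat2, m)
  expect_equal(as.vector(g2$values),
               lattice_points(lat2) %*% c(1, -2, 0.5) |> as.vector(),
               tolerance = 1e-9)
  unlink(p)
})
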