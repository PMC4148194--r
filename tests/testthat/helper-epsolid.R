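# shared builders for the test suite; everything is generated in code

single_atom_structure <- function(x = 0, y = 0, z = 0, charge = 0,
                                  radius = 1.5, name = "CA",
                                  resname = "GLY", chain = "A", resnum = 1) {
  charged_structure(data.frame(
    serial = seq_along(x), name = name, resname = resname, chain = chain,
    resnum = resnum, icode = "", x = x, y = y, z = z,
    radius = radius, charge = charge, stringsAsFactors = FALSE))
}

# solid ball of radius r centered at ctr, from an exact distance field
ball_solid <- function(r, ctr = c(0, 0, 0), spacing = 0.4, pad = 2) {
  lat <- lattice3d(ctr - r - pad, spacing,
                   rep(ceiling(2 * (r + pad) / spacing) + 1L, 3))
  f <- field_from_function(lat, function(p)
    sqrt(rowSums(sweep(p, 2, ctr)^2)))
  marching_cubes(f, threshold_spec(r, "below"))
}

# same-lattice pair of balls (for CSG tests)
ball_pair <- function(r1, c1, r2, c2, spacing = 0.4, pad = 2) {
  lo <- pmin(c1 - r1, c2 - r2) - pad
  hi <- pmax(c1 + r1, c2 + r2) + pad
  lat <- lattice3d(lo, spacing, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  mk <- function(r, ctr) marching_cubes(
    field_from_function(lat, function(p) sqrt(rowSums(sweep(p, 2, ctr)^2))),
    threshold_spec(r, "below"))
  list(A = mk(r1, c1), B = mk(r2, c2), lattice = lat)
}

sphere_lens_volume <- function(r, d) pi * (4 * r + d) * (2 * r - d)^2 / 12

ball_volume <- function(r) 4 / 3 * pi * r^3

# random smooth field: sum of gaussian bumps, with solids interior to the box
random_bump_field <- function(seed, n = 33, spacing = 0.5) {
  set.seed(seed)
  lat <- lattice3d(c(0, 0, 0), spacing, rep(n, 3))
  ext <- spacing * (n - 1)
  nb <- sample(2:4, 1)
  ctr <- matrix(runif(3 * nb, 0.3 * ext, 0.7 * ext), nb, 3)
  amp <- runif(nb, 1.5, 3)
  wid <- runif(nb, 4, 10)
  p <- lattice_points(lat)
  vals <- 0
  for (i in seq_len(nb))
    vals <- vals + amp[i] * exp(-rowSums(sweep(p, 2, ctr[i, ])^2) / wid[i])
  scalar_field(lat, vals)
}

# independent reference isosurfacer: scikit-image marching cubes through the
# system python; returns the enclosed mesh volume
skimage_volume <- function(field, level) {
  tmp <- tempfile(fileext = ".txt")
  lat <- field$lattice
  writeLines(c(paste(lat$dims, collapse = " "),
               sprintf("%.9g", lat$spacing),
               sprintf("%.9g", field$values)), tmp)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage import measure",
    "tok = open(sys.argv[1]).read().split()",
    "d = [int(x) for x in tok[:3]]; h = float(tok[3])",
    "v = np.array([float(x) for x in tok[4:]]).reshape(d, order='F')",
    "verts, faces, _, _ = measure.marching_cubes(v, level=float(sys.argv[2]), spacing=(h, h, h))",
    "a, b, c = verts[faces[:, 0]], verts[faces[:, 1]], verts[faces[:, 2]]",
    "print(abs(np.einsum('ij,ij->', a, np.cross(b, c)) / 6.0))"), py)
  out <- system2("python", c(py, tmp, format(level, digits = 12)),
                 stdout = TRUE, stderr = TRUE)
  on.exit(unlink(c(tmp, py)))
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (is.na(val)) stop("reference isosurfacer failed: ",
                       paste(out, collapse = "\n"))
  val
}

# every mesh vertex must lie on a lattice edge joining an inside point to an
# outside point (boundary-cap vertices sit on the clipped lattice face)
expect_vertices_on_crossing_edges <- function(S) {
  lat <- S$lattice
  occ <- S$occupancy
  v <- S$mesh$vertices
  rel <- sweep(v, 2, lat$origin) / lat$spacing
  near_int <- abs(rel - round(rel)) < 1e-7
  expect_true(all(rowSums(near_int) >= 2))
  d <- lat$dims
  occ_at <- function(i, j, k) {
    ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
    out <- rep(FALSE, length(i))
    out[ok] <- occ[cbind(i[ok] + 1L, j[ok] + 1L, k[ok] + 1L)]
    out
  }
  ax <- apply(near_int, 1, function(z) {
    w <- which(!z)
    if (length(w) == 1) w else 0L  # 0: vertex exactly on a lattice point
  })
  frac <- which(ax > 0)
  if (length(frac)) {
    lo <- round(rel[frac, , drop = FALSE]); hi <- lo
    for (u in seq_along(frac)) {
      a <- ax[frac[u]]
      lo[u, a] <- floor(rel[frac[u], a]); hi[u, a] <- ceiling(rel[frac[u], a])
    }
    o1 <- occ_at(lo[, 1], lo[, 2], lo[, 3])
    o2 <- occ_at(hi[, 1], hi[, 2], hi[, 3])
    expect_true(all(xor(o1, o2)))
  }
  invisible(TRUE)
}
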