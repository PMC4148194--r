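# Deterministic synthetic fixtures with planted ground truth.  These are the
# package's test bed: point-charge "toy proteins" whose fields, cavities and
# interfaces are known by construction, so every pipeline stage can be
# validated without external structures or a PB solver.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a toy charged structure from a residue table
#'
#' Pseudo-residues of 1-5 pseudo-atoms.  Each row of `residues` places one
#' residue: at (`x`, `y`, `z`) when given, otherwise uniformly at random in
#' the `[-extent, extent]` cube under the spec's seed.  `charge` is carried
#' by the residue's first atom; additional atoms (`n_atoms` > 1) are neutral
#' satellites jittered around the center.  The same spec and seed always
#' produce a bit-identical structure.
#'
#' @param spec list with `seed` (default 1), `residues` (data.frame with any
#'   of `x`, `y`, `z`, `charge`, `radius`, `n_atoms`, `resname`, `name`),
#'   and optional `extent` (default 15) and `chain` (default `"A"`).
#' @return a [charged_structure()].
#' @export
toy_structure <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$residues))
  seed <- if (is.null(spec$seed)) 1L else as.integer(spec$seed)
  extent <- if (is.null(spec$extent)) 15 else spec$extent
  chain <- if (is.null(spec$chain)) "A" else spec$chain
  res <- as.data.frame(spec$residues, stringsAsFactors = FALSE)
  n <- nrow(res)
  if (is.null(res$charge)) res$charge <- 0
  if (is.null(res$radius)) res$radius <- 1.8
  if (is.null(res$n_atoms)) res$n_atoms <- 1L
  if (is.null(res$resname)) res$resname <- "GLY"
  if (is.null(res$name)) res$name <- "CA"
  if (is.null(res$x)) res$x <- NA_real_
  if (is.null(res$y)) res$y <- NA_real_
  if (is.null(res$z)) res$z <- NA_real_
  stopifnot(all(res$n_atoms >= 1), all(res$n_atoms <= 5))
  atoms <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      ctr <- c(res$x[i], res$y[i], res$z[i])
      if (anyNA(ctr)) ctr <- stats::runif(3, -extent, extent)
      na <- res$n_atoms[i]
      pos <- matrix(rep(ctr, each = na), na, 3)
      if (na > 1) {
        off <- matrix(stats::rnorm(3 * (na - 1)), na - 1, 3)
        off <- off / sqrt(rowSums(off^2)) * 1.5
        pos[-1, ] <- pos[-1, ] + off
      }
      rows[[i]] <- data.frame(
        serial = 0L,
        name = c(res$name[i], paste0("X", seq_len(na))[-1])[seq_len(na)],
        resname = res$resname[i], chain = chain, resnum = i, icode = "",
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        radius = res$radius[i],
        charge = c(res$charge[i], rep(0, na - 1)),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  atoms$serial <- seq_len(nrow(atoms))
  if (nrow(atoms) > 1) {
    dmin <- min(stats::dist(atoms[, c("x", "y", "z")]))
    if (dmin < 0.1)
      warning(sprintf("toy structure has overlapping atoms (min separation %.3g A)",
                      dmin), call. = FALSE)
  }
  charged_structure(atoms)
}

#' Planted-charge cavity pair
#'
#' Emulates a trypsin-like specificity pocket: two structurally identical
#' pseudo-proteins share a spherical binding cavity (radius 4 A at the
#' origin, ringed by neutral residues), and the test protein additionally
#' carries a single -1 e residue just below the cavity base -- the analogue
#' of the buried aspartate that makes an S1 pocket electronegative.  Ten
#' decoy residues sit 20-28 A away; some carry modest partial charges
#' (+/- 0.5 e) so the scan has realistic long-range competition, but at that
#' distance no decoy can halve the cavity-field difference.  Ground truth:
#' nullifying the planted residue (and only it) collapses the difference
#' between the two cavity fields.
#'
#' @param seed integer seed; the same seed reproduces the fixture exactly.
#' @return list with `test` and `ref` structures, the analysis `lattice`
#'   (0.5 A spacing around the cavity), cavity solids `C_test` and `C_ref`,
#'   the `cavity_spec` table, and `planted`, the planted residue id.
#' @export
planted_cavity_pair <- function(seed) {
  geom <- with_seed(seed, {
    n_ring <- 8
    ang <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
    ring <- data.frame(
      x = 7.5 * cos(ang) + stats::runif(n_ring, -0.5, 0.5),
      y = 7.5 * sin(ang) + stats::runif(n_ring, -0.5, 0.5),
      z = stats::runif(n_ring, -1, 1),
      charge = 0, radius = 1.8, n_atoms = 1L,
      resname = "GLY", name = "CA", stringsAsFactors = FALSE)
    n_dec <- 10
    u <- matrix(stats::rnorm(3 * n_dec), n_dec, 3)
    u <- u / sqrt(rowSums(u^2))
    rad <- stats::runif(n_dec, 20, 28)
    qs <- sample(rep(c(-0.5, 0, 0.5), length.out = n_dec))
    decoys <- data.frame(
      x = u[, 1] * rad, y = u[, 2] * rad, z = u[, 3] * rad,
      charge = qs, radius = 1.8, n_atoms = 1L,
      resname = ifelse(qs == 0, "GLY", "SER"),
      name = ifelse(qs == 0, "CA", "OG"), stringsAsFactors = FALSE)
    list(ring = ring, decoys = decoys)
  })
  planted <- data.frame(x = 0, y = 0, z = -4.6, charge = -1, radius = 1.5,
                        n_atoms = 1L, resname = "ASP", name = "OD1",
                        stringsAsFactors = FALSE)
  shared <- rbind(geom$ring, geom$decoys)
  test <- toy_structure(list(seed = seed, residues = rbind(shared, planted)))
  ref <- toy_structure(list(seed = seed, residues = shared))
  planted_rid <- make_rid("A", nrow(shared) + 1L)
  cavity_spec <- data.frame(x = 0, y = 0, z = 0, radius = 4)
  lat <- lattice3d(c(-6.5, -6.5, -6.5), 0.5, c(27, 27, 27))
  C <- cavity_solid(cavity_spec, lat)
  list(test = test, ref = ref, lattice = lat, C_test = C, C_ref = C,
       cavity_spec = cavity_spec, planted = planted_rid)
}

#' Opposing-charge two-body complex
#'
#' Emulates a barnase/barstar-style electrostatic pairing: two pseudo-
#' proteins face each other across the x = 0 midplane.  Each side has a
#' neutral contact residue 2.2 A from the plane (so the 5 A interface rule
#' fires and the interface region covers the gap), one charged residue
#' slightly recessed behind it -- +1 e on side A opposing -1 e on side B,
#' 6-8 A apart -- and ten neutral decoy residues further back.  Ground
#' truth: the interface scan on either side labels exactly its charged
#' residue `contributes_complementarity`.
#'
#' @param seed integer seed.
#' @return list with structures `A` and `B`, the analysis `lattice`,
#'   `charged_A` and `charged_B` (residue ids of the planted pair), and the
#'   charge separation `gap`.
#' @export
opposing_complex <- function(seed) {
  half <- function(sgn, q, seedoff, resname, aname) {
    d <- with_seed(seed + seedoff, {
      xoff <- 3.0 + stats::runif(1, 0, 1)   # charge 3.0-4.0 A off-plane
      n_dec <- 10
      dec <- data.frame(
        x = sgn * stats::runif(n_dec, 6, 14),
        y = stats::runif(n_dec, -5, 5),
        z = stats::runif(n_dec, -5, 5),
        charge = 0, radius = 1.8, n_atoms = 1L,
        resname = "GLY", name = "CA", stringsAsFactors = FALSE)
      list(xoff = xoff, dec = dec)
    })
    contact <- data.frame(x = sgn * 2.2, y = 0, z = 0, charge = 0,
                          radius = 1.8, n_atoms = 1L, resname = "GLY",
                          name = "CB", stringsAsFactors = FALSE)
    charged <- data.frame(x = sgn * d$xoff, y = 0, z = 0, charge = q,
                          radius = 1.8, n_atoms = 1L, resname = resname,
                          name = aname, stringsAsFactors = FALSE)
    res <- rbind(contact, charged, d$dec)
    list(str = toy_structure(list(seed = seed + seedoff, residues = res,
                                  chain = if (sgn < 0) "A" else "B")),
         xoff = d$xoff)
  }
  a <- half(-1, +1, 0L, "LYS", "NZ")
  b <- half(+1, -1, 1000L, "ASP", "OD1")
  lat <- lattice3d(c(-8.5, -8.5, -8.5), 0.5, c(35, 35, 35))
  list(A = a$str, B = b$str, lattice = lat,
       charged_A = "A:2", charged_B = "B:2",
       gap = a$xoff + b$xoff)
}
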