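#' Electrostatic model configuration
#'
#' Linear-response stand-ins for a full nonlinear Poisson-Boltzmann solve.
#' Three models are available:
#'
#' * `"debye_huckel"` -- screened Coulomb superposition
#'   `phi(p) = sum_i lvac q_i exp(-kappa d_i) / (eps_solvent d_i)` in kT/e,
#'   with the distance clamped at half a lattice spacing so grids stay
#'   finite near atom centers.
#' * `"fd_lpb"` -- finite-difference linearized Poisson-Boltzmann:
#'   a 7-point-stencil successive-over-relaxation solve of
#'   `div(eps grad phi) - eps_solvent kappa^2 phi = -4 pi lvac rho` with the
#'   dielectric from the union-of-balls solute mask (`eps_solute` inside),
#'   trilinear charge spreading and Debye-Hueckel Dirichlet boundaries.
#' * `"external_grid"` -- a potential grid computed elsewhere (e.g. a
#'   nonlinear PB solver) and imported from an OpenDX file, matched exactly
#'   or resampled trilinearly onto the requested lattice.
#'
#' `lvac = e^2 / (4 pi eps0 kB T)` is the vacuum Coulomb length in Angstrom
#' (560.5 A at 298.15 K), derived from the model temperature so that
#' potentials are in thermal units kT/e throughout.
#'
#' @param model one of `"debye_huckel"`, `"fd_lpb"`, `"external_grid"`.
#' @param eps_solvent solvent dielectric constant (> 0, default 80).
#' @param eps_solute solute dielectric constant, `fd_lpb` only (default 4).
#' @param kappa inverse Debye screening length in 1/Angstrom (>= 0, default 0).
#' @param temperature temperature in Kelvin (default 298.15).
#' @param clamp_factor singularity clamp for `debye_huckel`, as a fraction of
#'   the lattice spacing (default 0.5).
#' @param dx_path path of the OpenDX grid for `external_grid`.
#' @param sor_tol,sor_maxit,sor_omega `fd_lpb` solver controls: convergence
#'   tolerance on the max Gauss-Seidel update (kT/e), iteration cap, and
#'   over-relaxation factor.
#' @return object of class `"ep_model"`.
#' @export
electrostatic_model <- function(model = c("debye_huckel", "fd_lpb",
                                          "external_grid"),
                                eps_solvent = 80, eps_solute = 4, kappa = 0,
                                temperature = 298.15, clamp_factor = 0.5,
                                dx_path = NULL, sor_tol = 1e-5,
                                sor_maxit = 20000L, sor_omega = 1.8) {
  model <- match.arg(model)
  stopifnot(eps_solvent > 0, eps_solute > 0, kappa >= 0, temperature > 0,
            clamp_factor > 0)
  if (model == "external_grid" && is.null(dx_path))
    stop("external_grid model needs dx_path")
  e <- 1.602176634e-19   # C
  eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23
  lvac <- e^2 / (4 * pi * eps0 * kB * temperature) * 1e10 # Angstrom
  structure(list(model = model, eps_solvent = eps_solvent,
                 eps_solute = eps_solute, kappa = kappa,
                 temperature = temperature, lvac = lvac,
                 clamp_factor = clamp_factor, dx_path = dx_path,
                 sor_tol = sor_tol, sor_maxit = as.integer(sor_maxit),
                 sor_omega = sor_omega),
            class = "ep_model")
}

#' @export
print.ep_model <- function(x, ...) {
  cat(sprintf("electrostatic model '%s': eps_solvent %g, eps_solute %g, kappa %g 1/A, T %g K (lvac %.2f A)\n",
              x$model, x$eps_solvent, x$eps_solute, x$kappa, x$temperature,
              x$lvac))
  invisible(x)
}

#' Compute the potential field of a structure on a lattice
#'
#' Evaluates the electrostatic potential (kT/e) of the structure's charges at
#' every lattice point under the chosen [electrostatic_model()].  Both
#' built-in models are linear in the charges, so fields superpose and residue
#' nullification equals subtracting the nullified residue's own field.
#'
#' @param s a [charged_structure()]; ignored for `external_grid` except that
#'   it may be `NULL`.
#' @param lat the target lattice.
#' @param model an [electrostatic_model()]; default `debye_huckel`.
#' @return an [scalar_field()] of potentials in kT/e.
#' @export
compute_field <- function(s, lat, model = electrostatic_model()) {
  stopifnot(inherits(lat, "ep_lattice"), inherits(model, "ep_model"))
  if (model$model == "external_grid")
    return(load_dx_onto(model$dx_path, lat))
  stopifnot(inherits(s, "ep_structure"))
  if (nrow(s$atoms) < 1) stop("structure has no atoms")
  xyz <- atom_coords(s)
  q <- s$atoms$charge
  if (model$model == "debye_huckel") {
    vals <- cpp_dh_field(xyz, q, lat$origin, lat$spacing, lat$dims,
                         model$eps_solvent, model$kappa, model$lvac,
                         model$clamp_factor * lat$spacing)
    return(scalar_field(lat, vals))
  }
  # fd_lpb
  sol <- cpp_fd_lpb(xyz, s$atoms$radius, q, lat$origin, lat$spacing, lat$dims,
                    model$eps_solute, model$eps_solvent, model$kappa,
                    model$lvac, model$sor_tol, model$sor_maxit,
                    model$sor_omega)
  if (!isTRUE(sol$converged))
    stop(sprintf("fd_lpb did not converge in %d iterations (max residual %.3g kT/e)",
                 sol$iterations, sol$residual))
  scalar_field(lat, sol$phi)
}

#' Solute dielectric mask used by the fd_lpb model
#'
#' Logical lattice array: `TRUE` where a point lies inside the union of atom
#' balls (low-dielectric solute region).  Exposed so nullification can be
#' checked to leave the mask untouched.
#'
#' @param s a [charged_structure()].
#' @param lat the lattice.
#' @export
dielectric_mask <- function(s, lat) {
  d1 <- cpp_balls_distance(atom_coords(s), s$atoms$radius, 0,
                           lat$origin, lat$spacing, lat$dims)
  array(d1 <= 0, dim = lat$dims)
}

# ---- OpenDX scalar grids ---------------------------------------------------

#' Read an OpenDX scalar grid
#'
#' Parses the "object 1 class gridpositions" dialect written by APBS and
#' DelPhi converters.  The grid must be axis-aligned with equal spacing on the
#' three axes.  OpenDX stores values with the z index fastest; they are
#' re-ordered to the package's x-fastest layout.
#'
#' @param path file path.
#' @return an [scalar_field()].
#' @export
read_dx <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln)]
  cnt <- grep("object\\s+1\\s+class\\s+gridpositions\\s+counts", ln,
              value = TRUE)[1]
  if (is.na(cnt)) stop("not an OpenDX gridpositions file: ", path)
  dims <- as.integer(utils::tail(strsplit(trimws(cnt), "\\s+")[[1]], 3))
  origin <- as.numeric(strsplit(trimws(sub("^\\s*origin", "",
             grep("^\\s*origin", ln, value = TRUE)[1])), "\\s+")[[1]])
  deltas <- t(vapply(grep("^\\s*delta", ln, value = TRUE)[1:3], function(d) {
    as.numeric(strsplit(trimws(sub("^\\s*delta", "", d)), "\\s+")[[1]])
  }, numeric(3)))
  if (any(abs(deltas - diag(diag(deltas))) > 1e-9))
    stop("only axis-aligned DX grids are supported")
  h <- diag(deltas)
  if (max(abs(h - h[1])) > 1e-9)
    stop("only cubic (equal-spacing) DX grids are supported")
  d3 <- grep("object\\s+3\\s+class\\s+array", ln)
  stop_at <- grep("attribute|object\\s+\"|component", ln)
  stop_at <- stop_at[stop_at > d3[1]]
  last <- if (length(stop_at)) min(stop_at) - 1L else length(ln)
  vals <- as.numeric(unlist(strsplit(trimws(ln[(d3[1] + 1L):last]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(dims))
    stop(sprintf("DX data has %d values, expected %d", length(vals),
                 prod(dims)))
  # DX order: z fastest, x slowest -> stored array dims (z, y, x)
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  scalar_field(lattice3d(origin, h[1], dims), arr)
}

#' Write an OpenDX scalar grid
#'
#' @param field an [scalar_field()].
#' @param path file path.
#' @export
write_dx <- function(field, path) {
  stopifnot(inherits(field, "ep_field"))
  lat <- field$lattice
  vals <- as.vector(aperm(field$values, c(3, 2, 1))) # z fastest
  con <- file(path, "w")
  on.exit(close(con))
  h <- lat$spacing
  writeLines(c("# OpenDX scalar grid written by epsolid",
    sprintf("object 1 class gridpositions counts %d %d %d",
            lat$dims[1], lat$dims[2], lat$dims[3]),
    sprintf("origin %.9g %.9g %.9g", lat$origin[1], lat$origin[2],
            lat$origin[3]),
    sprintf("delta %.9g 0 0", h), sprintf("delta 0 %.9g 0", h),
    sprintf("delta 0 0 %.9g", h),
    sprintf("object 2 class gridconnections counts %d %d %d",
            lat$dims[1], lat$dims[2], lat$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.9g %.9g %.9g", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.9g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

# load a DX grid onto a lattice: exact match, or trilinear resample
load_dx_onto <- function(path, lat) {
  f <- read_dx(path)
  if (lattice_congruent(f$lattice, lat, tol = 1e-6)) {
    return(scalar_field(lat, f$values))
  }
  scalar_field(lat, trilinear_sample(f, lattice_points(lat)))
}

# trilinear interpolation of a field at arbitrary points; points outside the
# source grid are clamped to the border values
trilinear_sample <- function(field, pts) {
  lat <- field$lattice
  fr <- sweep(pts, 2, lat$origin) / lat$spacing
  fr <- pmin(pmax(fr, 0), matrix(rep(lat$dims - 1L, each = nrow(fr)),
                                 ncol = 3) - 1e-9)
  i0 <- floor(fr)
  w <- fr - i0
  v <- field$values
  d <- lat$dims
  at <- function(di, dj, dk) {
    ii <- pmin(i0[, 1] + di, d[1] - 1L)
    jj <- pmin(i0[, 2] + dj, d[2] - 1L)
    kk <- pmin(i0[, 3] + dk, d[3] - 1L)
    v[1L + ii + d[1] * (jj + d[2] * kk)]
  }
  out <- 0
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    wt <- (if (di) w[, 1] else 1 - w[, 1]) *
          (if (dj) w[, 2] else 1 - w[, 2]) *
          (if (dk) w[, 3] else 1 - w[, 3])
    out <- out + wt * at(di, dj, dk)
  }
  out
}
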