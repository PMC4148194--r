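#' Regular cubic lattice
#'
#' A lattice is the sampling frame shared by every volumetric object in the
#' package: scalar potential fields, occupancy maps and boundary meshes all
#' refer to the same axis-aligned grid of points at
#' `origin + spacing * (i, j, k)` for integer `i, j, k` starting at 0.
#' All coordinates are Angstrom, in the PDB frame of the input structures.
#'
#' @param origin numeric length-3, position of lattice point (0, 0, 0) in
#'   Angstrom.
#' @param spacing lattice edge length (the "resolution") in Angstrom; must be
#'   positive.  The package default used throughout the high-level drivers is
#'   0.5 Angstrom.
#' @param dims integer length-3, number of lattice points per axis (>= 2).
#' @return an object of class `"ep_lattice"`.
#' @examples
#' lat <- lattice3d(c(0, 0, 0), 0.5, c(21, 21, 21))
#' dim(lattice_points(lat))
#' @export
lattice3d <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3L, all(is.finite(origin)),
            length(spacing) == 1L, is.finite(spacing),
            length(dims) == 3L, all(!is.na(dims)))
  if (spacing <= 0) stop("lattice spacing must be > 0")
  if (any(dims < 2L)) stop("each lattice dimension must be >= 2")
  structure(list(origin = origin, spacing = as.numeric(spacing), dims = dims),
            class = "ep_lattice")
}

#' @export
print.ep_lattice <- function(x, ...) {
  cat(sprintf("cubic lattice: %d x %d x %d points, spacing %g A, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_lattice_points <- function(lat) prod(lat$dims)

#' Lattice point coordinates
#'
#' @param lat an [lattice3d()] object.
#' @return a `prod(dims) x 3` matrix of point coordinates (Angstrom), x index
#'   fastest, matching the storage order of field values and occupancies.
#' @export
lattice_points <- function(lat) {
  stopifnot(inherits(lat, "ep_lattice"))
  i <- seq_len(lat$dims[1]) - 1L
  j <- seq_len(lat$dims[2]) - 1L
  k <- seq_len(lat$dims[3]) - 1L
  cbind(lat$origin[1] + lat$spacing * rep(i, times = lat$dims[2] * lat$dims[3]),
        lat$origin[2] + lat$spacing * rep(rep(j, each = lat$dims[1]),
                                          times = lat$dims[3]),
        lat$origin[3] + lat$spacing * rep(k, each = lat$dims[1] * lat$dims[2]))
}

#' Test whether two lattices are congruent
#'
#' Two lattices are congruent when origin, spacing and dims agree within
#' `tol` (Angstrom).  CSG operations require congruent operands.
#'
#' @param a,b lattices.
#' @param tol absolute tolerance in Angstrom.
#' @export
lattice_congruent <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "ep_lattice"), inherits(b, "ep_lattice"))
  identical(a$dims, b$dims) &&
    all(abs(a$origin - b$origin) <= tol) &&
    abs(a$spacing - b$spacing) <= tol
}

stop_noncongruent <- function(a, b, what = "operation") {
  stop(sprintf(
    "%s requires congruent lattices; got [%s | spacing %g | origin %s] vs [%s | spacing %g | origin %s]",
    what,
    paste(a$dims, collapse = "x"), a$spacing,
    paste(sprintf("%g", a$origin), collapse = ","),
    paste(b$dims, collapse = "x"), b$spacing,
    paste(sprintf("%g", b$origin), collapse = ",")), call. = FALSE)
}

#' Build a lattice enclosing a set of points
#'
#' Convenience constructor: the lattice covers the bounding box of `xyz`
#' expanded by `padding` on every side, snapped outward to whole lattice
#' steps.
#'
#' @param xyz an `n x 3` coordinate matrix, or a [charged_structure()].
#' @param spacing lattice edge length in Angstrom (default 0.5).
#' @param padding margin added around the bounding box in Angstrom.
#' @export
lattice_around <- function(xyz, spacing = 0.5, padding = 5) {
  if (inherits(xyz, "ep_structure")) xyz <- atom_coords(xyz)
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 1L)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  lattice3d(lo, spacing, dims)
}

#' Scalar field sampled on a lattice
#'
#' Stores one finite value per lattice point: electrostatic potential in kT/e,
#' or a distance field in Angstrom.  Values are kept as a 3-d array with the
#' x index varying fastest.
#'
#' @param lattice an [lattice3d()] object.
#' @param values numeric vector or array of `prod(dims)` finite values.
#' @return object of class `"ep_field"` with elements `lattice` and `values`.
#' @export
scalar_field <- function(lattice, values) {
  stopifnot(inherits(lattice, "ep_lattice"))
  values <- as.numeric(values)
  if (length(values) != n_lattice_points(lattice))
    stop(sprintf("field needs %d values, got %d",
                 n_lattice_points(lattice), length(values)))
  if (!all(is.finite(values))) stop("field values must all be finite")
  structure(list(lattice = lattice,
                 values = array(values, dim = lattice$dims)),
            class = "ep_field")
}

#' @export
print.ep_field <- function(x, ...) {
  cat("scalar field on ")
  print(x$lattice)
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a function of position on a lattice
#'
#' @param lat a lattice.
#' @param f function taking an `n x 3` coordinate matrix, returning `n` values.
#' @export
field_from_function <- function(lat, f) {
  scalar_field(lat, f(lattice_points(lat)))
}

#' Isopotential threshold
#'
#' A threshold at `k` kT/e together with the side of the isopotential that the
#' solid occupies.  Following the sign convention used throughout the package,
#' positive `k` selects the region with potential greater than or equal to
#' `k`, and negative `k` the region with potential less than or equal to `k`;
#' the complementary regions are infinite in volume, so `k = 0` is rejected.
#' The side can be overridden for non-potential fields (e.g. distance fields).
#'
#' @param k threshold in kT/e (nonzero).
#' @param side `"above"` or `"below"`; default follows the sign of `k`.
#' @export
threshold_spec <- function(k, side = NULL) {
  stopifnot(length(k) == 1L, is.finite(k))
  if (k == 0) stop("k = 0 is not a valid isopotential threshold: the region on either side is infinite in volume")
  if (is.null(side)) side <- if (k > 0) "above" else "below"
  side <- match.arg(side, c("above", "below"))
  structure(list(k = as.numeric(k), side = side), class = "ep_threshold")
}

as_threshold <- function(spec) {
  if (inherits(spec, "ep_threshold")) spec else threshold_spec(spec)
}

#' Classify lattice points against an isopotential threshold
#'
#' Marks each lattice point as inside or outside the solid isopotential.
#' A point is inside when its value is `>= k` (side `"above"`) or `<= k`
#' (side `"below"`); exact equality counts as inside, so solids are
#' topologically closed.
#'
#' @param field an [scalar_field()].
#' @param spec an [threshold_spec()] (or a bare nonzero number).
#' @return a logical array over the lattice points.
#' @export
classify_points <- function(field, spec) {
  stopifnot(inherits(field, "ep_field"))
  spec <- as_threshold(spec)
  if (spec$side == "above") field$values >= spec$k else field$values <= spec$k
}
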