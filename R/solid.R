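#' @useDynLib epsolid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- triangle mesh helpers -------------------------------------------------

empty_mesh <- function() {
  list(vertices = matrix(numeric(0), 0, 3),
       triangles = matrix(integer(0), 0, 3))
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  stopifnot(is.matrix(v), ncol(v) == 3, is.matrix(tr), ncol(tr) == 3)
  if (nrow(tr) > 0) {
    if (min(tr) < 1L || max(tr) > nrow(v)) stop("triangle index out of range")
    if (any(tr[, 1] == tr[, 2] | tr[, 2] == tr[, 3] | tr[, 1] == tr[, 3]))
      stop("triangle repeats a vertex index")
  }
  mesh
}

#' Is a triangle mesh closed?
#'
#' A mesh is closed (has no boundary, so an enclosed volume is well defined)
#' when every directed edge is balanced by an equal number of reversed
#' copies, i.e. the triangles form a zero-boundary oriented 2-cycle.  For
#' smooth solids this reduces to every undirected edge being shared by
#' exactly two triangles with opposite orientation; at non-manifold voxel
#' junctions (two solids touching along a lattice edge) edges may be shared
#' by four.
#'
#' @param mesh a list with `vertices` (n x 3) and `triangles` (m x 3,
#'   1-based, counter-clockwise from outside).
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(TRUE)
  from <- c(tr[, 1], tr[, 2], tr[, 3])
  to   <- c(tr[, 2], tr[, 3], tr[, 1])
  n <- nrow(mesh$vertices) + 1
  identical(sort(from * n + to), sort(to * n + from))
}

mesh_signed_volume <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0) return(0)
  v <- mesh$vertices
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c_ <- v[tr[, 3], , drop = FALSE]
  # sum of signed tetrahedron volumes det[a b c] / 6 (Surveyor's formula)
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Volume enclosed by a closed triangle mesh
#'
#' Divergence-theorem (Surveyor's formula) volume
#' `| sum_t det[v1 v2 v3] | / 6` over the boundary triangles.
#'
#' @param mesh a triangle mesh (see [mesh_is_closed()]); an empty mesh has
#'   volume 0.
#' @return volume in cubic Angstrom.
#' @export
mesh_volume <- function(mesh) {
  validate_mesh(mesh)
  if (nrow(mesh$triangles) == 0) return(0)
  if (!mesh_is_closed(mesh))
    stop("mesh is not closed: enclosed volume is undefined")
  abs(mesh_signed_volume(mesh))
}

# ---- solid region ----------------------------------------------------------

# gfield: interpolation field, >= 0 at inside points where consistent with the
# occupancy; drives sub-lattice placement of boundary vertices.
new_solid <- function(lattice, occupancy, gfield = NULL, warn_clip = TRUE) {
  stopifnot(inherits(lattice, "ep_lattice"))
  occupancy <- array(as.logical(occupancy), dim = lattice$dims)
  if (anyNA(occupancy)) stop("occupancy must not contain NA")
  if (is.null(gfield)) gfield <- ifelse(occupancy, 1, -1)
  gfield <- array(as.numeric(gfield), dim = lattice$dims)
  d <- lattice$dims
  if (warn_clip && any(occupancy) &&
      (any(occupancy[c(1, d[1]), , ]) || any(occupancy[, c(1, d[2]), ]) ||
       any(occupancy[, , c(1, d[3])])))
    warning("solid reaches the lattice boundary; it was capped with boundary faces",
            call. = FALSE)
  mesh <- cpp_marching_cubes(occupancy, gfield, d, lattice$origin,
                             lattice$spacing)
  sv <- mesh_signed_volume(mesh)
  if (sv < 0) { # defensive: enforce outward orientation
    mesh$triangles <- mesh$triangles[, c(1, 3, 2), drop = FALSE]
    sv <- -sv
  }
  structure(list(lattice = lattice, occupancy = occupancy, gfield = gfield,
                 mesh = mesh, volume = abs(sv)),
            class = "ep_solid")
}

#' @export
print.ep_solid <- function(x, ...) {
  cat(sprintf("solid region: %d/%d lattice points inside, %d boundary triangles, volume %.3f A^3\n",
              sum(x$occupancy), length(x$occupancy), nrow(x$mesh$triangles),
              x$volume))
  invisible(x)
}

#' Is a solid empty?
#' @param S a solid region.
#' @export
is_empty_solid <- function(S) !any(S$occupancy)

#' An empty solid on a lattice
#' @param lattice the lattice to attach.
#' @export
empty_solid <- function(lattice) {
  new_solid(lattice, array(FALSE, lattice$dims))
}

#' Extract a solid isopotential by marching cubes
#'
#' Classifies lattice points against the threshold and extracts the closed
#' boundary mesh of the inside region.  Boundary vertices lie on lattice edges
#' joining an inside point to an outside point, at the linear-interpolation
#' parameter `t = (k - phi1) / (phi2 - phi1)` along the edge.  Solids that
#' reach the edge of the lattice are capped with boundary faces (with a
#' warning), so the enclosed volume is always well defined.
#'
#' @param field an [scalar_field()] of potentials (kT/e) or distances.
#' @param spec an [threshold_spec()] or bare nonzero threshold.
#' @return a solid region (class `"ep_solid"`) carrying the lattice, the
#'   point occupancy, the boundary mesh and its Surveyor's-formula volume.
#' @examples
#' lat <- lattice3d(c(-6, -6, -6), 0.5, c(25, 25, 25))
#' f <- field_from_function(lat, function(p) sqrt(rowSums(p^2)))
#' ball <- marching_cubes(f, threshold_spec(4, "below"))
#' solid_volume(ball) / (4 / 3 * pi * 4^3)
#' @export
marching_cubes <- function(field, spec) {
  stopifnot(inherits(field, "ep_field"))
  spec <- as_threshold(spec)
  occ <- classify_points(field, spec)
  g <- if (spec$side == "above") field$values - spec$k else spec$k - field$values
  new_solid(field$lattice, occ, g)
}

#' Volume of a solid region
#'
#' Returns the cached Surveyor's-formula volume of the boundary mesh,
#' in cubic Angstrom.
#'
#' @param S a solid region.
#' @export
solid_volume <- function(S) {
  stopifnot(inherits(S, "ep_solid"))
  S$volume
}

#' Voxel-count volume oracle
#'
#' `spacing^3` times the number of inside lattice points (each point owns the
#' half-open cube at its minimal corner).  Used as an independent check of the
#' mesh-based volume; the two agree to within the lattice-resolution regime.
#'
#' @param S a solid region.
#' @export
voxel_volume <- function(S) {
  stopifnot(inherits(S, "ep_solid"))
  S$lattice$spacing^3 * sum(S$occupancy)
}

# ---- CSG -------------------------------------------------------------------

#' Boolean operations on solid regions
#'
#' Constructive solid geometry on congruent lattices.  The output occupancy is
#' the pointwise boolean AND / OR / AND-NOT of the operands; the boundary mesh
#' is re-extracted from the combined occupancy.  Where a lattice edge's
#' crossing comes from a single operand the interpolated crossing position is
#' inherited (the combined interpolation fields are pointwise min/max, so a
#' no-op like `A` intersected with itself keeps its boundary bit-identical);
#' where the operands disagree with the combined occupancy the edge midpoint
#' is used.
#'
#' @param op one of `"intersection"`, `"union"`, `"difference"`.
#' @param A,B solid regions on congruent lattices.
#' @return a solid region.
#' @seealso [csg_intersection()], [csg_union()], [csg_difference()]
#' @export
csg <- function(op, A, B) {
  op <- match.arg(op, c("intersection", "union", "difference"))
  stopifnot(inherits(A, "ep_solid"), inherits(B, "ep_solid"))
  if (!lattice_congruent(A$lattice, B$lattice))
    stop_noncongruent(A$lattice, B$lattice, paste("CSG", op))
  occ <- switch(op,
                intersection = A$occupancy & B$occupancy,
                union        = A$occupancy | B$occupancy,
                difference   = A$occupancy & !B$occupancy)
  g <- switch(op,
              intersection = pmin(A$gfield, B$gfield),
              union        = pmax(A$gfield, B$gfield),
              difference   = pmin(A$gfield, -B$gfield))
  suppressWarnings(new_solid(A$lattice, occ, g))
}

#' @rdname csg
#' @export
csg_intersection <- function(A, B) csg("intersection", A, B)

#' @rdname csg
#' @export
csg_union <- function(A, B) csg("union", A, B)

#' @rdname csg
#' @export
csg_difference <- function(A, B) csg("difference", A, B)

#' Jaccard distance between two solids
#'
#' `1 - V(A intersect B) / V(A union B)`, the volume-normalized dissimilarity
#' used to compare cavity fields without bias from total volume.  Symmetric;
#' 0 for identical solids, 1 for disjoint ones.
#'
#' @param A,B solid regions on congruent lattices, not both empty.
#' @export
jaccard_distance <- function(A, B) {
  stopifnot(inherits(A, "ep_solid"), inherits(B, "ep_solid"))
  if (!lattice_congruent(A$lattice, B$lattice))
    stop_noncongruent(A$lattice, B$lattice, "jaccard_distance")
  if (is_empty_solid(A) && is_empty_solid(B))
    stop("Jaccard distance is undefined when both solids are empty")
  vu <- solid_volume(csg_union(A, B))
  if (vu == 0) stop("Jaccard distance is undefined: union has zero volume")
  vi <- solid_volume(csg_intersection(A, B))
  max(0, min(1, 1 - vi / vu))
}

#' Resample a solid onto another lattice
#'
#' Re-evaluates occupancy on the target lattice by a point-in-solid parity
#' test against the boundary mesh (axis-aligned ray with a small deterministic
#' offset against degenerate hits), then re-extracts the boundary using signed
#' distances to the source mesh near the new boundary.
#'
#' @param S a solid region with a closed boundary mesh.
#' @param target the target lattice; its spacing must be at most twice the
#'   source spacing.
#' @export
resample_to <- function(S, target) {
  stopifnot(inherits(S, "ep_solid"), inherits(target, "ep_lattice"))
  if (target$spacing > 2 * S$lattice$spacing + 1e-12)
    stop("target spacing must be at most twice the source spacing")
  if (is_empty_solid(S)) return(empty_solid(target))
  solid_from_mesh(S$mesh, target)
}

#' Build a solid from a closed boundary mesh
#'
#' Voxelizes a closed mesh onto a lattice (ray-parity occupancy) and rebuilds
#' the boundary at lattice resolution with signed-distance interpolation, so
#' the rebuilt volume tracks the input mesh volume at the lattice regime.
#'
#' @param mesh a closed triangle mesh (e.g. from [read_off()]).
#' @param lattice the target lattice.
#' @export
solid_from_mesh <- function(mesh, lattice) {
  validate_mesh(mesh)
  if (nrow(mesh$triangles) == 0) return(empty_solid(lattice))
  if (!mesh_is_closed(mesh))
    stop("input mesh is not closed; cannot define a solid")
  occ <- cpp_point_in_mesh(mesh$vertices, mesh$triangles, lattice$origin,
                           lattice$spacing, lattice$dims)
  g <- cpp_mesh_signed_near(mesh$vertices, mesh$triangles, occ,
                            lattice$origin, lattice$spacing, lattice$dims)
  new_solid(lattice, occ, g)
}

# ---- mesh and occupancy I/O ------------------------------------------------

#' Read and write OFF meshes
#'
#' Plain ASCII Object File Format: `OFF`, counts line, vertex lines, then
#' polygon lines (triangles).
#'
#' @param mesh a triangle mesh or a solid region (its boundary is written).
#' @param path file path.
#' @return `read_off` returns a triangle mesh list.
#' @export
write_off <- function(mesh, path) {
  if (inherits(mesh, "ep_solid")) mesh <- mesh$mesh
  validate_mesh(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  if (nrow(mesh$vertices))
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$triangles))
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- matrix(as.numeric(unlist(strsplit(ln[2 + seq_len(nv)], "\\s+"))),
                ncol = 3, byrow = TRUE)
  tri <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    tok <- as.integer(strsplit(ln[2 + nv + i], "\\s+")[[1]])
    if (tok[1] != 3L) stop("only triangle faces are supported (face ", i, ")")
    tri[i, ] <- tok[2:4] + 1L
  }
  validate_mesh(list(vertices = vtx, triangles = tri))
}

#' Read and write ASCII PLY meshes
#'
#' Minimal ascii-1.0 PLY support: vertex x/y/z properties and triangular
#' faces.
#'
#' @param mesh a triangle mesh or a solid region.
#' @param path file path.
#' @export
write_ply <- function(mesh, path) {
  if (inherits(mesh, "ep_solid")) mesh <- mesh$mesh
  validate_mesh(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(mesh$vertices))
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (nrow(mesh$triangles))
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  ln <- trimws(readLines(path))
  if (ln[1] != "ply") stop("not a PLY file: ", path)
  if (!any(grepl("^format\\s+ascii", ln))) stop("only ascii PLY is supported")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", ln, value = TRUE)[1]))
  body <- ln[(which(ln == "end_header")[1] + 1):length(ln)]
  body <- body[nzchar(body)]
  vtx <- matrix(as.numeric(unlist(strsplit(body[seq_len(nv)], "\\s+"))),
                ncol = 3, byrow = TRUE)[, 1:3, drop = FALSE]
  tri <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    tok <- as.integer(strsplit(body[nv + i], "\\s+")[[1]])
    if (tok[1] != 3L) stop("only triangle faces are supported (face ", i, ")")
    tri[i, ] <- tok[2:4] + 1L
  }
  validate_mesh(list(vertices = vtx, triangles = tri))
}

#' Read and write occupancy maps as run-length text
#'
#' Compact plain-text fixture format: a header with dims, origin and spacing,
#' then alternating run lengths of outside/inside points in storage order
#' (x fastest).
#'
#' @param S a solid region.
#' @param path file path.
#' @return `read_occupancy` rebuilds a solid (edge-midpoint boundary).
#' @export
write_occupancy <- function(S, path) {
  stopifnot(inherits(S, "ep_solid"))
  r <- rle(as.vector(S$occupancy))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("epsolid-occupancy 1",
               paste("dims", paste(S$lattice$dims, collapse = " ")),
               paste("origin", paste(sprintf("%.9g", S$lattice$origin),
                                     collapse = " ")),
               paste("spacing", sprintf("%.9g", S$lattice$spacing)),
               paste("first", as.integer(r$values[1])),
               paste(r$lengths, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  ln <- trimws(readLines(path))
  if (!startsWith(ln[1], "epsolid-occupancy"))
    stop("not an epsolid occupancy file: ", path)
  get <- function(key) {
    strsplit(sub(paste0("^", key, "\\s+"), "",
                 grep(paste0("^", key, " "), ln, value = TRUE)[1]), "\\s+")[[1]]
  }
  dims <- as.integer(get("dims"))
  origin <- as.numeric(get("origin"))
  spacing <- as.numeric(get("spacing"))
  first <- as.integer(get("first")[1])
  lens <- as.integer(strsplit(ln[length(ln)], "\\s+")[[1]])
  vals <- rep(rep(c(first == 1L, first != 1L), length.out = length(lens)), lens)
  lat <- lattice3d(origin, spacing, dims)
  suppressWarnings(new_solid(lat, vals))
}
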