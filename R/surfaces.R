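#' Parameters for surface and interface regions
#'
#' @param probe_radius solvent probe radius in Angstrom for the molecular
#'   (solvent-excluded) surface; default 1.4 (water).
#' @param interface_cutoff atom-atom distance (Angstrom) below which a residue
#'   counts as interfacial; default 5.
#' @param interface_sphere_radius radius (Angstrom) of the spheres unioned
#'   around interfacial atoms to build the interface region; default 5.
#' @export
region_params <- function(probe_radius = 1.4, interface_cutoff = 5.0,
                          interface_sphere_radius = 5.0) {
  stopifnot(probe_radius > 0, interface_cutoff > 0,
            interface_sphere_radius > 0)
  structure(list(probe_radius = probe_radius,
                 interface_cutoff = interface_cutoff,
                 interface_sphere_radius = interface_sphere_radius),
            class = "ep_region_params")
}

balls_distance_field <- function(s, lat, inflate = 0, radius_override = NULL) {
  xyz <- atom_coords(s)
  r <- if (is.null(radius_override)) s$atoms$radius
       else rep(radius_override, nrow(xyz))
  cpp_balls_distance(xyz, r, inflate, lat$origin, lat$spacing, lat$dims)
}

#' Union-of-balls solid of a structure
#'
#' Occupancy marks lattice points within `radius + inflate` of any atom; the
#' boundary comes from marching cubes on the signed distance field
#' `min_i(|p - x_i| - r_i - inflate)`.
#'
#' @param s a [charged_structure()]; an empty structure gives an empty solid.
#' @param lat the lattice.
#' @param inflate extra radius added to every atom (Angstrom).
#' @param radius_override when given, every ball uses this fixed radius
#'   instead of the atomic radii (used for interface-region spheres).
#' @export
union_of_balls_solid <- function(s, lat, inflate = 0, radius_override = NULL) {
  stopifnot(inherits(s, "ep_structure"), inherits(lat, "ep_lattice"))
  if (nrow(s$atoms) == 0) return(empty_solid(lat))
  d1 <- balls_distance_field(s, lat, inflate, radius_override)
  new_solid(lat, d1 <= 0, -d1)
}

#' Solvent-excluded (molecular) surface solid
#'
#' Approximates the classical rolling-probe molecular surface by a
#' morphological closing on the lattice: the union of atom balls is dilated by
#' the probe radius and then eroded by the same amount.  The erosion is
#' carried out as a power-distance transform against every probe position
#' whose clearance ball is known analytically, which keeps the boundary error
#' second-order in the lattice spacing rather than first-order.  The result
#' always contains the plain union of balls; crevices too narrow for the
#' probe are sealed.
#'
#' @param s a [charged_structure()].
#' @param lat the lattice.
#' @param p an [region_params()]; only `probe_radius` is used.
#' @export
molecular_surface_solid <- function(s, lat, p = region_params()) {
  stopifnot(inherits(s, "ep_structure"), inherits(lat, "ep_lattice"))
  if (nrow(s$atoms) == 0) return(empty_solid(lat))
  pr <- p$probe_radius
  h <- lat$spacing
  d1 <- balls_distance_field(s, lat, 0)
  # Probe centers are points whose probe ball misses the protein; each covers
  # a complement ball of radius d1 (clearance + probe), which makes the
  # erosion sub-lattice accurate.  Any covering probe center can be slid
  # toward the covered point until its clearance drops into a thin shell
  # above pr, so shell centers suffice; the thin shell also keeps the power
  # field's gradients symmetric across the boundary for edge interpolation.
  f <- ifelse(d1 > pr & d1 <= pr + 2 * h, -d1^2, Inf)
  pow <- cpp_power_transform(f, lat$dims, lat$spacing)
  occ <- (pow >= 0 & d1 <= pr) | (d1 <= 0)
  g <- ifelse(d1 > pr & pow >= 0, -1e9, pow)
  g[is.infinite(g)] <- -1e9
  new_solid(lat, occ, g)
}

#' Interfacial residues of a two-protein complex
#'
#' A residue of `A` is interfacial when any of its atoms lies within
#' `interface_cutoff` of any atom of `B`, and symmetrically.  All atoms count
#' (hydrogens too, when present); residues are not filtered by solvent
#' exposure, so buried hot-spot residues are kept.
#'
#' @param A,B [charged_structure()]s.
#' @param p an [region_params()].
#' @return list with residue-id vectors `A` and `B`, each in deterministic
#'   (chain, number) order.
#' @export
interface_residues <- function(A, B, p = region_params()) {
  stopifnot(inherits(A, "ep_structure"), inherits(B, "ep_structure"),
            nrow(A$atoms) > 0, nrow(B$atoms) > 0)
  da <- cpp_min_cross_dist(atom_coords(A), atom_coords(B))
  db <- cpp_min_cross_dist(atom_coords(B), atom_coords(A))
  ra <- unique(atom_rids(A)[da <= p$interface_cutoff])
  rb <- unique(atom_rids(B)[db <= p$interface_cutoff])
  list(A = intersect(residue_ids(A), ra), B = intersect(residue_ids(B), rb))
}

#' Interface region of a complex
#'
#' CSG union of spheres of radius `interface_sphere_radius` centered at every
#' atom of every interfacial residue (of both sides).  This is the spatial
#' window inside which interface fields are evaluated.
#'
#' @param A,B [charged_structure()]s in complex coordinates.
#' @param lat the lattice.
#' @param p an [region_params()].
#' @return a solid region; empty (with a warning) when no residues are
#'   interfacial.
#' @export
interface_region <- function(A, B, lat, p = region_params()) {
  ir <- interface_residues(A, B, p)
  keepA <- atom_rids(A) %in% ir$A
  keepB <- atom_rids(B) %in% ir$B
  if (!any(keepA) && !any(keepB)) {
    warning("no interfacial residues within the cutoff; interface region is empty",
            call. = FALSE)
    return(empty_solid(lat))
  }
  atoms <- rbind(A$atoms[keepA, , drop = FALSE], B$atoms[keepB, , drop = FALSE])
  atoms$serial <- seq_len(nrow(atoms))
  union_of_balls_solid(charged_structure(atoms), lat,
                       radius_override = p$interface_sphere_radius)
}

#' Build a cavity solid from a sphere-union spec or a mesh file
#'
#' Binding cavities are inputs to this package (cavity detection is out of
#' scope).  Two representations are accepted: a sphere-union specification (a
#' data.frame with columns `x`, `y`, `z`, `radius`, or a whitespace-delimited
#' text file of such rows), or a closed boundary mesh in OFF or PLY format,
#' which is voxelized onto the lattice.
#'
#' @param spec data.frame, or path to a sphere table / `.off` / `.ply` file.
#' @param lat the lattice.
#' @return a solid region.
#' @export
cavity_solid <- function(spec, lat) {
  stopifnot(inherits(lat, "ep_lattice"))
  if (is.character(spec)) {
    stopifnot(length(spec) == 1L)
    low <- tolower(spec)
    if (endsWith(low, ".off")) return(solid_from_mesh(read_off(spec), lat))
    if (endsWith(low, ".ply")) return(solid_from_mesh(read_ply(spec), lat))
    spec <- utils::read.table(spec, header = FALSE,
                              col.names = c("x", "y", "z", "radius"))
  }
  spec <- as.data.frame(spec)
  if (nrow(spec) == 0) stop("empty cavity specification")
  stopifnot(all(c("x", "y", "z", "radius") %in% names(spec)))
  atoms <- data.frame(serial = seq_len(nrow(spec)), name = "SPH",
                      resname = "CAV", chain = "X",
                      resnum = seq_len(nrow(spec)), icode = "",
                      x = spec$x, y = spec$y, z = spec$z,
                      radius = spec$radius, charge = 0,
                      stringsAsFactors = FALSE)
  union_of_balls_solid(charged_structure(atoms), lat)
}

#' Write a sphere-union cavity spec
#' @param spec data.frame with `x`, `y`, `z`, `radius`.
#' @param path file path.
#' @export
write_cavity_spec <- function(spec, path) {
  utils::write.table(spec[, c("x", "y", "z", "radius")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
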