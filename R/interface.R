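#' Interface field: a solid measure of electrostatic complementarity
#'
#' The region inside the interface where the potential of `A` alone is at or
#' beyond `+|k|` while the potential of `B` alone is at or beyond `-|k|` (or
#' vice versa for negative `k`).  Each protein's field is computed from its
#' own charges only, at complex coordinates; under the `fd_lpb` model the
#' partner's atoms still shape the dielectric by default (see
#' `partner_dielectric`), mirroring how an uncharged neighbor still focuses
#' the field.
#'
#' @param A,B [charged_structure()]s in complex coordinates.
#' @param region the interface-region solid (see [interface_region()]).
#' @param k signed threshold in kT/e (nonzero); `k > 0` selects
#'   `phi_A >= +k` against `phi_B <= -k`, `k < 0` swaps the signs.
#' @param model an [electrostatic_model()].
#' @param partner_dielectric under `fd_lpb`, include the partner's atoms
#'   (charges zeroed) in the dielectric mask; default `TRUE`.
#' @return a solid region on the region's lattice.
#' @export
interface_field <- function(A, B, region, k, model = electrostatic_model(),
                            partner_dielectric = TRUE) {
  stopifnot(inherits(region, "ep_solid"))
  if (k == 0) stop("k = 0 is not a valid threshold for an interface field")
  if (is_empty_solid(region))
    return(empty_solid(region$lattice))
  lat <- region$lattice
  phiA <- one_sided_field(A, B, lat, model, partner_dielectric)
  phiB <- one_sided_field(B, A, lat, model, partner_dielectric)
  kk <- abs(k)
  if (k > 0) {
    solA <- suppressWarnings(marching_cubes(phiA, threshold_spec(kk)))
    solB <- suppressWarnings(marching_cubes(phiB, threshold_spec(-kk)))
  } else {
    solA <- suppressWarnings(marching_cubes(phiA, threshold_spec(-kk)))
    solB <- suppressWarnings(marching_cubes(phiB, threshold_spec(kk)))
  }
  suppressWarnings(csg_intersection(csg_intersection(solA, solB), region))
}

# field of `self`'s charges alone; partner atoms optionally kept (uncharged)
# in the fd_lpb dielectric mask
one_sided_field <- function(self, partner, lat, model, partner_dielectric) {
  if (model$model == "fd_lpb" && isTRUE(partner_dielectric)) {
    pa <- partner$atoms
    pa$charge <- 0
    comb <- rbind(self$atoms, pa)
    comb$serial <- seq_len(nrow(comb))
    return(compute_field(charged_structure(comb), lat, model))
  }
  compute_field(self, lat, model)
}

#' Interface field set and electrostatic complementarity of a complex
#'
#' Builds the interface region, then the two interface fields of the complex
#' at `+k` and `-k`.  Their summed volume is the complex's electrostatic
#' complementarity `EC = V(i_pos) + V(i_neg)` in cubic Angstrom.
#'
#' @param A,B [charged_structure()]s in complex coordinates.
#' @param k threshold magnitude in kT/e (> 0).
#' @param model an [electrostatic_model()].
#' @param params an [region_params()].
#' @param lat optional lattice; default encloses both structures with padding
#'   `interface_sphere_radius + 2` at 0.5 A spacing.
#' @param region optional precomputed interface region solid.
#' @return object of class `"ep_field_set"` with `region`, `i_pos`, `i_neg`,
#'   `EC` and `k`.
#' @export
make_field_set <- function(A, B, k, model = electrostatic_model(),
                           params = region_params(), lat = NULL,
                           region = NULL) {
  stopifnot(k > 0)
  if (is.null(region)) {
    if (is.null(lat))
      lat <- lattice_around(rbind(atom_coords(A), atom_coords(B)),
                            spacing = 0.5,
                            padding = params$interface_sphere_radius + 2)
    region <- interface_region(A, B, lat, params)
  }
  if (is_empty_solid(region))
    warning("interface region is empty: EC = 0", call. = FALSE)
  i_pos <- interface_field(A, B, region, +k, model)
  i_neg <- interface_field(A, B, region, -k, model)
  structure(list(region = region, i_pos = i_pos, i_neg = i_neg,
                 EC = solid_volume(i_pos) + solid_volume(i_neg),
                 k = k),
            class = "ep_field_set")
}

#' @export
print.ep_field_set <- function(x, ...) {
  cat(sprintf("interface field set at k = %g kT/e\n", x$k))
  cat(sprintf("  interface region: %10.3f A^3\n", solid_volume(x$region)))
  cat(sprintf("  field at +k     : %10.3f A^3\n", solid_volume(x$i_pos)))
  cat(sprintf("  field at -k     : %10.3f A^3\n", solid_volume(x$i_neg)))
  cat(sprintf("  EC              : %10.3f A^3\n", x$EC))
  invisible(x)
}

#' Complementarity difference between two complexes
#'
#' `delta_EC = EC(variant) - EC(reference)`: negative values mean
#' electrostatic complementarity is diminished in the variant complex
#' relative to the reference, positive values that it is enhanced.
#'
#' @param ref,variant [make_field_set()] results at the same `k`.
#' @return signed volume difference in cubic Angstrom.
#' @export
delta_EC <- function(ref, variant) {
  stopifnot(inherits(ref, "ep_field_set"), inherits(variant, "ep_field_set"))
  if (!isTRUE(all.equal(ref$k, variant$k)))
    stop(sprintf("field sets built at different k (%g vs %g kT/e)",
                 ref$k, variant$k))
  variant$EC - ref$EC
}
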