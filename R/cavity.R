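#' Cavity field: electrostatics inside a binding cavity
#'
#' The CSG intersection of a solid isopotential with a binding-cavity solid:
#' the part of the electrostatically significant region that a ligand can
#' actually reach.
#'
#' @param iso a solid isopotential (from [marching_cubes()]).
#' @param cavity a cavity solid (from [cavity_solid()]), congruent lattice.
#' @export
cavity_field <- function(iso, cavity) {
  stopifnot(inherits(iso, "ep_solid"), inherits(cavity, "ep_solid"))
  if (!lattice_congruent(iso$lattice, cavity$lattice))
    stop_noncongruent(iso$lattice, cavity$lattice, "cavity_field")
  csg_intersection(iso, cavity)
}

#' Compare the electrostatics of two binding cavities
#'
#' Computes the volume algebra that separates conserved from varying
#' electrostatics between two aligned cavities.  With cavity fields `EA`,
#' `EB` and cavity solids `CA`, `CB` (all at the same threshold `k` and
#' side):
#'
#' * `I = CA intersect CB` -- the region solvent-accessible in both cavities;
#'   restricting to `I` guarantees the comparison is not influenced by steric
#'   differences.
#' * `eA = EA intersect I`, `eB = EB intersect I` -- the cavity fields inside
#'   the shared region.
#' * `v_conserved = V(eA intersect eB)` -- similar electrostatics in both.
#' * `v_A_minus_B = V(eA - eB)`, `v_B_minus_A = V(eB - eA)` -- regions of one
#'   electrostatic character in one cavity only; evidence that one protein
#'   could stabilize a ligand fragment the other cannot.
#'
#' @param EA,EB cavity fields (or solid isopotentials) of the two proteins.
#' @param CA,CB the two cavity solids.
#' @param k the [threshold_spec()] both fields were built at (recorded).
#' @return object of class `"ep_cavity_comparison"`: solids `I`, `eA`, `eB`
#'   and the five volumes.
#' @export
compare_cavities <- function(EA, EB, CA, CB, k) {
  for (S in list(EB, CA, CB))
    if (!lattice_congruent(EA$lattice, S$lattice))
      stop_noncongruent(EA$lattice, S$lattice, "compare_cavities")
  k <- as_threshold(k)
  I <- csg_intersection(CA, CB)
  if (is_empty_solid(I))
    stop("cavities do not overlap after alignment: I = CA intersect CB is empty")
  eA <- csg_intersection(EA, I)
  eB <- csg_intersection(EB, I)
  stopifnot(!any(eA$occupancy & !I$occupancy),
            !any(eB$occupancy & !I$occupancy))
  res <- list(I = I, eA = eA, eB = eB, k = k,
              v_I = solid_volume(I),
              v_eA = solid_volume(eA),
              v_eB = solid_volume(eB),
              v_conserved = solid_volume(csg_intersection(eA, eB)),
              v_A_minus_B = solid_volume(csg_difference(eA, eB)),
              v_B_minus_A = solid_volume(csg_difference(eB, eA)))
  class(res) <- "ep_cavity_comparison"
  res
}

#' @export
print.ep_cavity_comparison <- function(x, ...) {
  cat(sprintf("cavity comparison at k = %g kT/e (side %s)\n", x$k$k, x$k$side))
  cat(sprintf("  shared cavity region I : %10.3f A^3\n", x$v_I))
  cat(sprintf("  cavity field eA        : %10.3f A^3\n", x$v_eA))
  cat(sprintf("  cavity field eB        : %10.3f A^3\n", x$v_eB))
  cat(sprintf("  conserved (eA ^ eB)    : %10.3f A^3\n", x$v_conserved))
  cat(sprintf("  A-only (eA - eB)       : %10.3f A^3\n", x$v_A_minus_B))
  cat(sprintf("  B-only (eB - eA)       : %10.3f A^3\n", x$v_B_minus_A))
  invisible(x)
}
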