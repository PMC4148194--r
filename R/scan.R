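#' Intramolecular salt bridges by distance rule
#'
#' A basic side-chain nitrogen (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) within
#' `cutoff` of an acidic side-chain oxygen (Asp OD1/OD2, Glu OE1/OE2) flags a
#' salt bridge between the two residues.  Same-chain and cross-chain pairs are
#' reported with a flag.
#'
#' @param s a [charged_structure()].
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return data.frame with columns `basic`, `acidic` (residue ids),
#'   `distance`, `same_chain`; zero rows when none.
#' @export
salt_bridges <- function(s, cutoff = 4.0) {
  a <- s$atoms
  bas <- (a$resname == "ARG" & a$name %in% c("NH1", "NH2", "NE")) |
         (a$resname == "LYS" & a$name == "NZ") |
         (a$resname == "HIS" & a$name %in% c("ND1", "NE2"))
  aci <- (a$resname == "ASP" & a$name %in% c("OD1", "OD2")) |
         (a$resname == "GLU" & a$name %in% c("OE1", "OE2"))
  out <- data.frame(basic = character(0), acidic = character(0),
                    distance = numeric(0), same_chain = logical(0),
                    stringsAsFactors = FALSE)
  if (!any(bas) || !any(aci)) return(out)
  bi <- which(bas); ai <- which(aci)
  rid <- atom_rids(s)
  for (i in bi) for (j in ai) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff && rid[i] != rid[j]) {
      out <- rbind(out, data.frame(basic = rid[i], acidic = rid[j],
                                   distance = d,
                                   same_chain = a$chain[i] == a$chain[j],
                                   stringsAsFactors = FALSE))
    }
  }
  if (nrow(out)) {
    key <- paste(out$basic, out$acidic)
    out <- out[!duplicated(key), , drop = FALSE]
    out <- out[order(out$basic, out$acidic), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

salt_bridge_members <- function(s, cutoff = 4.0) {
  sb <- salt_bridges(s, cutoff)
  unique(c(sb$basic, sb$acidic))
}

#' Prediction threshold for cavity nullification scans
#'
#' `T = (v0 + v_min) / 2`: electrostatic differences reduced by one half of
#' the best reduction any single nullification achieves.  Residues whose
#' nullified difference volume is at or below `T` are predicted influential.
#'
#' @param v0 baseline difference volume (no nullification), cubic Angstrom.
#' @param v_min minimum difference volume over all single nullifications.
#' @export
cavity_prediction_threshold <- function(v0, v_min) (v0 + v_min) / 2

#' Prediction thresholds for interface nullification scans
#'
#' Upper threshold `T_u = max_r D_r / 2` and lower threshold
#' `T_l = min_r D_r / 2`, halves of the most complementarity-enhancing and
#' most complementarity-diminishing single nullifications.
#'
#' @param d vector of per-residue complementarity differences `D_r`
#'   (cubic Angstrom, signed).
#' @return list with `T_u` and `T_l`.
#' @export
interface_prediction_thresholds <- function(d) {
  list(T_u = max(d) / 2, T_l = min(d) / 2)
}

#' Per-residue nullification scan of a binding cavity
#'
#' Systematically nullifies each residue of the test structure, rebuilds its
#' potential field and cavity field, and measures the volume of the CSG
#' difference against the reference cavity field, all inside the shared
#' cavity region `I = C_test intersect C_ref`.  With baseline
#' `v0 = V((E_test ^ I) - (E_ref ^ I))` and per-residue volumes `v_r`, a
#' residue is predicted to create the electrostatic difference between the
#' two cavities when `v_r <= T = (v0 + min_r v_r) / 2`, i.e. when nullifying
#' it makes the cavity fields at least half as similar as is achievable by
#' any single residue.  Predicted residues that are members of an
#' intramolecular salt bridge are labeled `salt_bridge_stability` instead
#' (mutating them is expected to alter cavity stability as well as its
#' field).
#'
#' The difference is directed (nullified test field minus reference field) by
#' default; `direction = "symmetric"` adds the opposite difference.
#'
#' @param test the test [charged_structure()] (the one being scanned).
#' @param ref_field the reference protein's potential field
#'   ([scalar_field()], kT/e) on the analysis lattice.
#' @param C_test,C_ref cavity solids of test and reference on the same
#'   lattice.
#' @param k an [threshold_spec()] (or bare nonzero number, kT/e).
#' @param model an [electrostatic_model()].
#' @param direction `"test_minus_ref"` (default) or `"symmetric"`.
#' @param salt_bridge_cutoff Angstrom, for the bridge flags.
#' @return object of class `"ep_scan"`; see Details.
#' @export
scan_cavity <- function(test, ref_field, C_test, C_ref, k,
                        model = electrostatic_model(),
                        direction = c("test_minus_ref", "symmetric"),
                        salt_bridge_cutoff = 4.0) {
  direction <- match.arg(direction)
  stopifnot(inherits(test, "ep_structure"), inherits(ref_field, "ep_field"))
  k <- as_threshold(k)
  lat <- ref_field$lattice
  for (S in list(C_test, C_ref))
    if (!lattice_congruent(lat, S$lattice))
      stop_noncongruent(lat, S$lattice, "scan_cavity")
  I <- csg_intersection(C_test, C_ref)
  if (is_empty_solid(I))
    stop("cavities do not overlap after alignment: I = C_test intersect C_ref is empty")
  E_ref <- suppressWarnings(marching_cubes(ref_field, k))
  e_ref <- suppressWarnings(csg_intersection(E_ref, I))
  diff_vol <- function(e_test) {
    v <- solid_volume(suppressWarnings(csg_difference(e_test, e_ref)))
    if (direction == "symmetric")
      v <- v + solid_volume(suppressWarnings(csg_difference(e_ref, e_test)))
    v
  }
  test_cavity_field <- function(str) {
    f <- compute_field(str, lat, model)
    suppressWarnings(csg_intersection(
      suppressWarnings(marching_cubes(f, k)), I))
  }
  v0 <- diff_vol(test_cavity_field(test))
  rids <- residue_ids(test)
  vr <- vapply(rids, function(r) {
    diff_vol(test_cavity_field(nullify_residue(test, r)))
  }, numeric(1))
  bridged <- rids %in% salt_bridge_members(test, salt_bridge_cutoff)
  if (v0 <= 0) {
    warning("baseline difference volume is zero: cavity fields already agree, no predictions",
            call. = FALSE)
    Tthr <- NA_real_
    label <- rep("none", length(rids))
  } else {
    Tthr <- cavity_prediction_threshold(v0, min(vr))
    pred <- vr <= Tthr
    label <- ifelse(pred, ifelse(bridged, "salt_bridge_stability",
                                 "influential_difference"), "none")
  }
  records <- data.frame(residue_id = rids, statistic = unname(vr),
                        salt_bridge = bridged, label = label,
                        stringsAsFactors = FALSE)
  structure(list(kind = "cavity", k_used = k$k, side = k$side,
                 baseline = v0, T = Tthr, records = records,
                 predictions = records$residue_id[records$label != "none"],
                 notes = c("difference direction: nullified test field minus reference field",
                           "threshold T = (v0 + min v_r)/2 reconstructed from the half-reduction rule")),
            class = "ep_scan")
}

#' Cavity scan with automatic threshold selection
#'
#' Runs [scan_cavity()] at each threshold in `k_list` and keeps the one where
#' the per-residue difference volumes vary the most (largest
#' `max_r v_r - min_r v_r`), the level at which nullification is most
#' informative.
#'
#' @inheritParams scan_cavity
#' @param k_list candidate thresholds in kT/e
#'   (default `c(-2.5, -5, -7.5, -10)`).
#' @return the selected `"ep_scan"`, with a `k_spread` element recording the
#'   spread at each candidate.
#' @export
scan_cavity_auto <- function(test, ref_field, C_test, C_ref,
                             k_list = c(-2.5, -5, -7.5, -10),
                             model = electrostatic_model(), ...) {
  scans <- lapply(k_list, function(k)
    scan_cavity(test, ref_field, C_test, C_ref, k, model, ...))
  spread <- vapply(scans, function(sc)
    diff(range(sc$records$statistic)), numeric(1))
  best <- which.max(spread)
  out <- scans[[best]]
  out$k_spread <- stats::setNames(spread, k_list)
  out
}

#' Label residues from interface-scan statistics
#'
#' Applies the interface prediction rule to a vector of per-residue
#' complementarity differences `D_r`: residues at or below
#' `T_l = min(d) / 2` (and negative) contribute complementarity, residues at
#' or beyond `T_u = max(d) / 2` (and positive) hinder it.  Either threshold
#' is suppressed when at least `outlier_fraction` of the residues cross it
#' (the 10 percent rule: a change most residues make is not exceptional).
#' Predicted members of salt bridges are relabeled `salt_bridge_stability`.
#'
#' @param d numeric vector of `D_r` values (cubic Angstrom).
#' @param bridged logical vector: is the residue in an intramolecular salt
#'   bridge?
#' @param outlier_fraction threshold-suppression fraction (default 0.1).
#' @return list with `label` (character vector), `T_u`, `T_l`, and
#'   `thresholds_applied` (named logical).
#' @export
interface_scan_labels <- function(d, bridged = rep(FALSE, length(d)),
                                  outlier_fraction = 0.1) {
  stopifnot(length(bridged) == length(d))
  thr <- interface_prediction_thresholds(d)
  n <- length(d)
  cross_u <- d >= thr$T_u & d > 0
  cross_l <- d <= thr$T_l & d < 0
  apply_u <- sum(cross_u) < outlier_fraction * n
  apply_l <- sum(cross_l) < outlier_fraction * n
  label <- rep("none", n)
  if (apply_l) label[cross_l] <- "contributes_complementarity"
  if (apply_u) label[cross_u] <- "hinders_complementarity"
  label[label != "none" & bridged] <- "salt_bridge_stability"
  list(label = label, T_u = thr$T_u, T_l = thr$T_l,
       thresholds_applied = c(upper = apply_u, lower = apply_l))
}

#' Per-residue nullification scan of a protein-protein interface
#'
#' Builds the reference interface field set of the complex at `k`, then for
#' each residue of the scanned side nullifies it, rebuilds that side's
#' one-sided field, and measures `D_r = EC(variant) - EC(reference)`.
#' Significantly negative `D_r` (at or below `T_l = min_r D_r / 2`) labels
#' the residue `contributes_complementarity`; significantly positive `D_r`
#' (at or beyond `T_u = max_r D_r / 2`) labels it `hinders_complementarity`.
#' Each threshold is only applied when fewer than 10 percent of the scanned
#' residues cross it; otherwise the change is not considered exceptional and
#' that side of the rule is suppressed.  Predicted residues in intramolecular
#' salt bridges are labeled `salt_bridge_stability`.
#'
#' @param A,B [charged_structure()]s in complex coordinates.
#' @param side which structure to scan: `"A"` or `"B"`.
#' @param k threshold magnitude in kT/e (> 0).
#' @param model an [electrostatic_model()].
#' @param params an [region_params()].
#' @param lat optional lattice (see [make_field_set()]).
#' @param outlier_fraction the 10 percent rule (default 0.1).
#' @param salt_bridge_cutoff Angstrom.
#' @return object of class `"ep_scan"` with `T_u`, `T_l` and
#'   `thresholds_applied`.
#' @export
scan_interface <- function(A, B, side = c("A", "B"), k,
                           model = electrostatic_model(),
                           params = region_params(), lat = NULL,
                           outlier_fraction = 0.1,
                           salt_bridge_cutoff = 4.0) {
  side <- match.arg(side)
  stopifnot(k > 0)
  if (is.null(lat))
    lat <- lattice_around(rbind(atom_coords(A), atom_coords(B)),
                          spacing = 0.5,
                          padding = params$interface_sphere_radius + 2)
  region <- interface_region(A, B, lat, params)
  ref <- make_field_set(A, B, k, model, params, region = region)
  if (ref$EC <= 0)
    stop(sprintf("no complementarity at k = %g kT/e (reference EC = 0)", k))
  scanned <- if (side == "A") A else B
  rids <- residue_ids(scanned)
  dr <- vapply(rids, function(r) {
    if (side == "A") {
      fs <- make_field_set(nullify_residue(A, r), B, k, model, params,
                           region = region)
    } else {
      fs <- make_field_set(A, nullify_residue(B, r), k, model, params,
                           region = region)
    }
    delta_EC(ref, fs)
  }, numeric(1))
  bridged <- rids %in% salt_bridge_members(scanned, salt_bridge_cutoff)
  lab <- interface_scan_labels(dr, bridged, outlier_fraction)
  records <- data.frame(residue_id = rids, statistic = unname(dr),
                        salt_bridge = bridged, label = lab$label,
                        stringsAsFactors = FALSE)
  structure(list(kind = "interface", k_used = k, side = side,
                 baseline = ref$EC, T_u = lab$T_u, T_l = lab$T_l,
                 thresholds_applied = lab$thresholds_applied,
                 records = records,
                 predictions = records$residue_id[records$label != "none"],
                 notes = c("thresholds T_u = max D_r/2, T_l = min D_r/2 reconstructed from the half-reduction rule",
                           "labels are categorical; relative magnitudes of two predicted residues are not ranked")),
            class = "ep_scan")
}

#' Interface scan with automatic threshold selection
#'
#' Runs [scan_interface()] at each `k` in `k_list` and keeps the one where
#' the per-residue `D_r` spread is largest.  When one binding partner has
#' already been calibrated (e.g. the other side of the same complex), pass
#' its selected `k` directly to [scan_interface()] instead.
#'
#' @inheritParams scan_interface
#' @param k_list candidate thresholds in kT/e (default `c(1, 3, 5, 7, 9)`).
#' @export
scan_interface_auto <- function(A, B, side = c("A", "B"),
                                k_list = c(1, 3, 5, 7, 9),
                                model = electrostatic_model(), ...) {
  side <- match.arg(side)
  scans <- lapply(k_list, function(k) {
    tryCatch(scan_interface(A, B, side, k, model, ...),
             error = function(e) NULL)
  })
  ok <- !vapply(scans, is.null, logical(1))
  if (!any(ok)) stop("no candidate k produced a nonzero reference EC")
  spread <- rep(-Inf, length(scans))
  spread[ok] <- vapply(scans[ok], function(sc)
    diff(range(sc$records$statistic)), numeric(1))
  best <- which.max(spread)
  out <- scans[[best]]
  out$k_spread <- stats::setNames(spread, k_list)
  out
}

#' @export
print.ep_scan <- function(x, ...) {
  cat(sprintf("%s nullification scan at k = %g kT/e\n", x$kind, x$k_used))
  if (x$kind == "cavity") {
    cat(sprintf("  baseline v0 = %.3f A^3, prediction threshold T = %.3f A^3\n",
                x$baseline, x$T))
  } else {
    cat(sprintf("  reference EC = %.3f A^3, T_u = %.3f, T_l = %.3f (applied: upper %s, lower %s)\n",
                x$baseline, x$T_u, x$T_l,
                x$thresholds_applied["upper"], x$thresholds_applied["lower"]))
  }
  np <- length(x$predictions)
  cat(sprintf("  %d residue(s) scanned, %d predicted%s\n",
              nrow(x$records), np,
              if (np) paste0(": ", paste(x$predictions, collapse = ", "))
              else ""))
  invisible(x)
}
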