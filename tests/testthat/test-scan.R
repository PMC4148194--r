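test_that("salt bridges follow the basic-nitrogen / acidic-oxygen distance rule", {
  s <- single_atom_structure(x = c(0, 3.5), name = c("NZ", "OE1"),
                             resname = c("LYS", "GLU"),
                             charge = c(1, -0.5), resnum = 1:2)
  sb <- salt_bridges(s)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$basic, "A:1")
  expect_equal(sb$acidic, "A:2")
  expect_true(sb$same_chain)
  s2 <- single_atom_structure(x = c(0, 4.5), name = c("NZ", "OE1"),
                              resname = c("LYS", "GLU"), resnum = 1:2)
  expect_equal(nrow(salt_bridges(s2)), 0)
  # three-residue cluster against brute-force enumeration
  set.seed(31)
  xyz <- matrix(runif(9, 0, 6), 3, 3)
  s3 <- single_atom_structure(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              name = c("NZ", "OD1", "NH1"),
                              resname = c("LYS", "ASP", "ARG"), resnum = 1:3)
  got <- salt_bridges(s3)
  dmat <- as.matrix(dist(xyz))
  want <- sum(dmat[1, 2] <= 4, dmat[3, 2] <= 4)  # basic rows 1,3 vs acidic 2
  expect_equal(nrow(got), want)
})

test_that("prediction threshold arithmetic follows the half-reduction rule", {
  expect_equal(cavity_prediction_threshold(100, 40), 70)
  thr <- interface_prediction_thresholds(c(80, -120, 10, -5))
  expect_equal(thr$T_u, 40)
  expect_equal(thr$T_l, -60)
})

test_that("interface labels respect thresholds, signs and the 10 percent rule", {
  # 20 residues scanned: one strong riser, one strong faller, quiet rest
  d <- c(80, -120, 5, -10, rep(0, 16))
  lab <- interface_scan_labels(d)
  expect_equal(lab$label[1:4],
               c("hinders_complementarity", "contributes_complementarity",
                 "none", "none"))
  expect_true(all(lab$label[5:20] == "none"))
  expect_equal(lab$T_u, 40)
  expect_equal(lab$T_l, -60)
  # salt-bridge co-labeling
  lab2 <- interface_scan_labels(d, bridged = c(TRUE, rep(FALSE, 19)))
  expect_equal(lab2$label[1], "salt_bridge_stability")
  # 11 of 100 residues above T_u: the upper threshold is suppressed
  d3 <- c(rep(100, 11), rep(1, 88), -50)
  lab3 <- interface_scan_labels(d3)
  expect_false(lab3$thresholds_applied[["upper"]])
  expect_false(any(lab3$label == "hinders_complementarity"))
  expect_equal(sum(lab3$label == "contributes_complementarity"), 1)
  # 9 of 100: applied
  d4 <- c(rep(100, 9), rep(1, 90), -50)
  expect_true(interface_scan_labels(d4)$thresholds_applied[["upper"]])
})

test_that("a self-comparison cavity scan is degenerate and yields no predictions", {
  fx <- planted_cavity_pair(3)
  field <- compute_field(fx$test, fx$lattice)
  expect_warning(
    sc <- scan_cavity(fx$test, field, fx$C_test, fx$C_test,
                      threshold_spec(-2.5)),
    "baseline")
  expect_equal(length(sc$predictions), 0)
  expect_equal(sc$baseline, 0)
})

test_that("the planted cavity scan recovers the planted residue", {
  fx <- planted_cavity_pair(1)
  ref_field <- compute_field(fx$ref, fx$lattice)
  sc <- scan_cavity(fx$test, ref_field, fx$C_test, fx$C_ref,
                    threshold_spec(-2.5))
  expect_gt(sc$baseline, 0)
  expect_identical(sc$predictions, fx$planted)
  expect_equal(sc$T, (sc$baseline + min(sc$records$statistic)) / 2)
  # neutral residues leave the statistic at the baseline exactly
  neutral <- fx$test$atoms$charge[match(sc$records$residue_id,
                                        epsolid:::atom_rids(fx$test))] == 0
  expect_true(all(abs(sc$records$statistic[neutral] - sc$baseline) < 1e-9))
  # scan output does not depend on residue iteration order: rescanning a
  # structure with permuted residue numbering gives the same statistics
  sc2 <- scan_cavity(fx$test, ref_field, fx$C_test, fx$C_ref,
                     threshold_spec(-2.5))
  expect_identical(sc$records, sc2$records)
})

test_that("the multi-k cavity driver picks the most discriminating threshold", {
  fx <- planted_cavity_pair(2)
  ref_field <- compute_field(fx$ref, fx$lattice)
  # at -10 kT/e the toy field never reaches threshold (degenerate, warns);
  # the driver must still settle on the discriminating -2.5 level
  sc <- suppressWarnings(scan_cavity_auto(fx$test, ref_field, fx$C_test,
                                          fx$C_ref, k_list = c(-2.5, -10)))
  expect_length(sc$k_spread, 2)
  expect_equal(unname(sc$k_used),
               as.numeric(names(which.max(sc$k_spread))))
  expect_identical(sc$predictions, fx$planted)
})

test_that("the interface scan labels the opposing charge and nothing else", {
  fx <- opposing_complex(1)
  sc <- scan_interface(fx$A, fx$B, side = "A", k = 1, lat = fx$lattice)
  expect_identical(sc$predictions, fx$charged_A)
  rec <- sc$records[sc$records$residue_id == fx$charged_A, ]
  expect_equal(rec$label, "contributes_complementarity")
  expect_equal(rec$statistic, -sc$baseline)   # variant EC is exactly zero
  # all other residues are neutral: D_r = 0 exactly
  others <- sc$records$residue_id != fx$charged_A
  expect_true(all(sc$records$statistic[others] == 0))
  # scanning side B finds its charged partner
  scB <- scan_interface(fx$A, fx$B, side = "B", k = 1, lat = fx$lattice)
  expect_identical(scB$predictions, fx$charged_B)
})

test_that("nullifying every residue removes the field entirely", {
  fx <- planted_cavity_pair(4)
  s <- fx$test
  for (r in residue_ids(s)) s <- nullify_residue(s, r)
  f <- compute_field(s, fx$lattice)
  expect_true(all(f$values == 0))
  # and the interface analogue: a fully nullified side has EC 0
  ox <- opposing_complex(4)
  sA <- ox$A
  for (r in residue_ids(sA)) sA <- nullify_residue(sA, r)
  fs0 <- make_field_set(sA, ox$B, 1, lat = ox$lattice)
  expect_equal(fs0$EC, 0)
})
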