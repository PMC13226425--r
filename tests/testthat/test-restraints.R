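# minimal structure with a methyl group: three HG21/22/23 protons each
# exactly 4 A from a lone HA proton
methyl_ensemble <- function() {
  ring <- t(vapply(0:2, function(k) {
    a <- 2 * pi * k / 3
    c(4, 0, 0) + 0.7 * c(0, cos(a), sin(a))
  }, numeric(3)))
  # push ring protons back onto the 4 A sphere around the origin
  ring <- ring / sqrt(rowSums(ring^2)) * 4
  atoms <- data.frame(chain = "A",
                      resno = c(1, 2, 2, 2),
                      resname = c("ALA", "ILE", "ILE", "ILE"),
                      atom = c("HA", "HG21", "HG22", "HG23"),
                      element = "H", stringsAsFactors = FALSE)
  structure_ensemble(atoms, as.numeric(t(rbind(c(0, 0, 0), ring))))
}

test_that("pseudo-atom selections expand by wildcard and plain names", {
  ens <- methyl_ensemble()
  expect_length(expand_selection(ens$atoms, 2, "HG2#"), 3)
  expect_length(expand_selection(ens$atoms, 1, "HA"), 1)
  expect_error(expand_selection(ens$atoms, 1, "HZ9"),
               "unresolvable atom selection: residue 1 atom HZ9")
})

test_that("effective distances use r^-6 sum averaging and are symmetric", {
  ens <- methyl_ensemble()
  plain <- evaluate_restraint(list(res1 = 1, atom1 = "HA", res2 = 2,
                                   atom2 = "HG21"), ens)
  expect_equal(plain, 4.0, tolerance = 1e-9)
  eff <- evaluate_restraint(list(res1 = 1, atom1 = "HA", res2 = 2,
                                 atom2 = "HG2#"), ens)
  expect_equal(eff, (3 * 4^-6)^(-1 / 6), tolerance = 1e-9)
  expect_lt(eff, 4.0)  # sum averaging pulls the bound inward
  swapped <- evaluate_restraint(list(res1 = 2, atom1 = "HG2#", res2 = 1,
                                     atom2 = "HA"), ens)
  expect_equal(eff, swapped)
  # r^-6 effective distance vs centroid distance on this compact group
  centroid <- colMeans(model_coords(ens)[2:4, ])
  expect_lte(eff, sqrt(sum(centroid^2)) + 1e-9)
})

test_that("distance-level classification obeys the tolerance rule and
           partitions restraints", {
  # published EF-loop restraint table: per-conformer distances printed
  tab <- read_restraint_table(system.file("extdata",
                                          "i82_ef_loop_restraints.tsv",
                                          package = "igdyn"))
  cls <- classify_restraint_distances(tab$upper_A, tab$distance_IN,
                                      tab$distance_OUT, tolerance = 0.3)
  expect_true(all(cls$classification[tab$tag == "IN"] == "IN-specific"))
  expect_true(all(cls$classification[tab$tag == "OUT"] == "OUT-specific"))
  # every restraint lands in exactly one class
  expect_true(all(cls$classification %in%
                    c("both", "IN-specific", "OUT-specific", "neither")))
  # widening the tolerance never demotes a restraint toward "neither"
  rank <- function(x) match(x, c("neither", "IN-specific", "OUT-specific",
                                 "both"))
  loose <- classify_restraint_distances(tab$upper_A, tab$distance_IN,
                                        tab$distance_OUT, tolerance = 1.5)
  # a restraint compatible with a conformer stays compatible
  expect_true(all((cls$violation_IN <= 0.3) <= (loose$violation_IN <= 1.5)))
  expect_true(all((cls$violation_OUT <= 0.3) <= (loose$violation_OUT <= 1.5)))
  expect_true(all(rank(loose$classification) >= 0))  # partition intact
  expect_false(any(cls$classification == "both" &
                     loose$classification == "neither"))
})

test_that("ensemble-based classification recovers the toy construction", {
  toy <- toy_conformers()
  all_r <- rbind(toy$in_restraints, toy$out_restraints,
                 toy$shared_restraints)
  out <- classify_conformer_specific(all_r, toy$ensIN, toy$ensOUT,
                                     tolerance = 0.3)
  expect_equal(out$classification[out$tag == "IN"],
               rep("IN-specific", sum(out$tag == "IN")))
  expect_equal(out$classification[out$tag == "OUT"],
               rep("OUT-specific", sum(out$tag == "OUT")))
  expect_equal(out$classification[out$tag == "shared"],
               rep("both", sum(out$tag == "shared")))
  expect_true(all(out$violation_IN >= 0 & out$violation_OUT >= 0))
})

# idealized antiparallel beta-ladder: donor N-H of strand 1 pointing at
# carbonyl O of strand 2 with near-linear geometry
ladder_ensemble <- function(n_models = 20, break_last = FALSE) {
  rows <- list(); xyz <- c()
  for (i in 1:4) {   # strand 1 donors
    base <- c(3.5 * i, 0, 0)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = i, resname = "ALA",
      atom = c("N", "H", "CA", "C"), element = c("N", "H", "C", "C"))
    xyz <- c(xyz, base, base + c(0, 1, 0), base + c(1.2, -0.7, 0),
             base + c(2.4, 0, 0))
  }
  for (i in 1:4) {   # strand 2 acceptors, O at 1.9 A from each H
    base <- c(3.5 * i, 4.4, 0)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = 10 + i, resname = "ALA",
      atom = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"))
    xyz <- c(xyz, base, base + c(1.2, 0.7, 0), base + c(0.3, -1.0, 0),
             base + c(0, -1.5, 0))
  }
  atoms <- do.call(rbind, rows)
  coords <- matrix(rep(xyz, n_models), nrow = n_models, byrow = TRUE)
  if (break_last) {
    # last model: move all acceptor oxygens far away
    o_idx <- which(atoms$atom == "O")
    cols <- as.vector(rbind(3 * o_idx - 2, 3 * o_idx - 1, 3 * o_idx))
    coords[n_models, cols] <- coords[n_models, cols] + 50
  }
  structure_ensemble(atoms, coords)
}

test_that("hydrogen bonds are found in the ladder and gated by the
           presence fraction", {
  ens <- ladder_ensemble()
  hb <- detect_hbonds(ens, presence_fraction = 1)
  expect_equal(nrow(hb), 4)
  expect_equal(hb$donor_resno, 1:4)
  expect_true(all(hb$acceptor_resno == hb$donor_resno + 10))
  # identical models: thresholds 0.75 and 1.0 give identical output
  expect_identical(detect_hbonds(ens, presence_fraction = 0.75), hb)
  # a bond present in 19/20 models is excluded at fraction 1.0
  ens19 <- ladder_ensemble(break_last = TRUE)
  expect_equal(nrow(detect_hbonds(ens19, presence_fraction = 1)), 0)
  expect_equal(nrow(detect_hbonds(ens19, presence_fraction = 0.75)), 4)
})
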