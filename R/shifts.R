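# Chemical-shift classification rules and assignment-completeness
# statistics.

#' Proline cis/trans classification from Cbeta/Cgamma shifts
#'
#' The Cbeta - Cgamma chemical-shift difference separates the two proline
#' ring-pucker/isomer populations: trans prolines cluster at 4.51 +- 1.37
#' ppm and cis prolines at 9.64 +- 1.62 ppm.  The call goes to the
#' population with the smaller z-score; if the difference is more than 3
#' standard deviations from both populations the call is `ambiguous`.
#'
#' @param cb,cg Cbeta and Cgamma shifts in ppm (vectorized).
#' @return data frame with `delta` (ppm), `z_trans`, `z_cis`, `call`
#'   (`trans`, `cis` or `ambiguous`); rows with a missing shift get
#'   `call = NA`.
#' @examples
#' proline_isomer(31.8, 26.5)  # delta 5.3, trans
#' @export
proline_isomer <- function(cb, cg) {
  delta <- cb - cg
  z_trans <- abs(delta - 4.51) / 1.37
  z_cis <- abs(delta - 9.64) / 1.62
  call <- ifelse(!is.finite(delta), NA_character_,
                 ifelse(z_trans > 3 & z_cis > 3, "ambiguous",
                        ifelse(z_trans <= z_cis, "trans", "cis")))
  data.frame(delta = delta, z_trans = z_trans, z_cis = z_cis, call = call,
             stringsAsFactors = FALSE)
}

#' Cysteine redox state from the Cbeta shift
#'
#' Reduced (free thiol) cysteines have Cbeta shifts well below, and
#' disulfide-bonded (oxidized) cysteines well above, the mid-30 ppm
#' region.  Thresholds: reduced below 32 ppm, oxidized above 35 ppm,
#' ambiguous in between.
#'
#' @param cb Cbeta shift in ppm (vectorized).
#' @return character vector: `reduced`, `oxidized` or `ambiguous`.
#' @export
cysteine_redox <- function(cb) {
  ifelse(!is.finite(cb), NA_character_,
         ifelse(cb < 32, "reduced", ifelse(cb > 35, "oxidized", "ambiguous")))
}

# Assignable-resonance inventory per residue type.  One entry = one
# expected resonance: methyl protons count once, methylene protons twice
# (stereo pairs), fast-exchanging OH/SH protons and the lysine NH3+ group
# are excluded, and the arginine guanidinium NH2 groups are collapsed to
# one observable pair (NH/HH).  The backbone entries H, N, C, CA, HA
# (HA2/HA3 for glycine; no amide H for proline) are added automatically.
shift_inventory <- list(
  ALA = c("CB", "HB"),
  ARG = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
          "NE", "HE", "NH", "HH"),
  ASN = c("CB", "HB2", "HB3", "CG", "ND2", "HD21", "HD22"),
  ASP = c("CB", "HB2", "HB3", "CG"),
  CYS = c("CB", "HB2", "HB3"),
  GLN = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "NE2", "HE21",
          "HE22"),
  GLU = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD"),
  GLY = character(),
  HIS = c("CB", "HB2", "HB3", "CG", "CD2", "HD2", "CE1", "HE1", "ND1",
          "NE2"),
  ILE = c("CB", "HB", "CG1", "HG12", "HG13", "CG2", "HG2", "CD1", "HD1"),
  LEU = c("CB", "HB2", "HB3", "CG", "HG", "CD1", "HD1", "CD2", "HD2"),
  LYS = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3",
          "CE", "HE2", "HE3"),
  MET = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CE", "HE"),
  PHE = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1",
          "HE1", "CE2", "HE2", "CZ", "HZ"),
  PRO = c("CB", "HB2", "HB3", "CG", "HG2", "HG3", "CD", "HD2", "HD3"),
  SER = c("CB", "HB2", "HB3"),
  THR = c("CB", "HB", "CG2", "HG2"),
  TRP = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "NE1", "HE1",
          "CE2", "CE3", "HE3", "CZ2", "HZ2", "CZ3", "HZ3", "CH2", "HH2"),
  TYR = c("CB", "HB2", "HB3", "CG", "CD1", "HD1", "CD2", "HD2", "CE1",
          "HE1", "CE2", "HE2", "CZ"),
  VAL = c("CB", "HB", "CG1", "HG1", "CG2", "HG2"))

#' Theoretical assignable resonances for one residue type
#'
#' @param resname 3-letter residue code.
#' @return character vector of expected resonance names (backbone +
#'   side chain), per the documented inventory.
#' @export
expected_atoms <- function(resname) {
  resname <- toupper(resname)
  if (!resname %in% names(shift_inventory))
    stop("unknown residue type: ", resname)
  bb <- if (resname == "GLY") c("H", "N", "C", "CA", "HA2", "HA3")
  else if (resname == "PRO") c("N", "C", "CA", "HA")
  else c("H", "N", "C", "CA", "HA")
  c(bb, shift_inventory[[resname]])
}

#' Assignment completeness by nucleus
#'
#' Compares assigned shifts against the theoretical inventory of
#' assignable resonances for the sequence (see [expected_atoms]; the
#' inventory convention is documented there and deliberately excludes
#' fast-exchanging protons, so percentages from differently conventioned
#' software will differ by a few percent).
#'
#' @param shifts data frame with `residue_number`, `residue_name`,
#'   `atom_name` (shifts for atoms outside the inventory are excluded
#'   with a warning).
#' @param sequence character vector of 3-letter codes, one per residue,
#'   named or indexed 1..length; residue numbers in `shifts` must be
#'   within it.
#' @return list with `by_nucleus` (percent assigned for H, C, N),
#'   `overall` (percent), `assigned`, `theoretical` (counts by nucleus).
#' @export
completeness <- function(shifts, sequence) {
  sequence <- toupper(sequence)
  theo <- character()
  for (i in seq_along(sequence))
    theo <- c(theo, paste(i, expected_atoms(sequence[i])))
  theo_nuc <- substr(sub("^[0-9]+ ", "", theo), 1, 1)
  if (nrow(shifts)) {
    if (any(shifts$residue_number < 1 | shifts$residue_number > length(sequence)))
      stop("shift residue numbers outside the sequence")
    key <- paste(shifts$residue_number, shifts$atom_name)
    known <- key %in% theo
    if (any(!known)) {
      warning(sum(!known), " shift(s) for atoms outside the inventory ",
              "excluded (e.g. ", key[!known][1], ")")
      key <- key[known]
    }
    key <- unique(key)
  } else key <- character()
  asg_nuc <- substr(sub("^[0-9]+ ", "", key), 1, 1)
  pct <- function(nuc) {
    n_theo <- sum(theo_nuc == nuc)
    if (n_theo == 0) return(NA_real_)
    100 * sum(asg_nuc == nuc) / n_theo
  }
  by_nuc <- c(H = pct("H"), C = pct("C"), N = pct("N"))
  list(by_nucleus = by_nuc,
       overall = 100 * length(key) / length(theo),
       assigned = table(factor(asg_nuc, levels = c("H", "C", "N"))),
       theoretical = table(factor(theo_nuc, levels = c("H", "C", "N"))))
}
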