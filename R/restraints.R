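# NOE distance-restraint evaluation with pseudo-atom averaging, and
# conformer-specificity classification of restraints against alternative
# ensembles.

#' Expand an atom selection, resolving pseudo-atom wildcards
#'
#' A trailing `#` in an atom name selects all protons of the group that
#' share the stem (e.g. `HG2#` on Ile matches HG21/HG22/HG23; `HE#` on Tyr
#' matches HE1/HE2; methyl, methylene and chemically equivalent aromatic
#' protons follow standard IUPAC/XPLOR naming).  `HN` is accepted as an
#' alias for the backbone amide proton `H`.
#'
#' @param atoms atom table of a `structure_ensemble`.
#' @param resno residue number.
#' @param name atom name, optionally with a trailing `#`.
#' @return integer vector of atom-table row indices (>= 1), or an error
#'   naming the unresolvable selection.
#' @export
expand_selection <- function(atoms, resno, name) {
  in_res <- atoms$resno == resno
  if (grepl("#$", name)) {
    stem <- sub("#$", "", name)
    idx <- which(in_res & grepl(paste0("^", stem, "[0-9]*$"), atoms$atom))
  } else {
    idx <- which(in_res & atoms$atom == name)
    if (!length(idx) && name == "HN")
      idx <- which(in_res & atoms$atom == "H")
    if (!length(idx) && name == "H")
      idx <- which(in_res & atoms$atom == "HN")
  }
  if (!length(idx))
    stop("unresolvable atom selection: residue ", resno, " atom ", name)
  idx
}

#' Effective distance of a (pseudo-atom) restraint in one model
#'
#' For selections expanding to proton groups the effective distance is the
#' r^-6 sum-averaged value used in ARIA-style restraint handling,
#' \deqn{d_{eff} = \left(\sum_{pairs} d^{-6}\right)^{-1/6},}
#' which reduces to the plain distance for a single proton pair and is
#' symmetric in the two selections.
#'
#' @param restraint list or one-row data frame with `res1`, `atom1`,
#'   `res2`, `atom2`.
#' @param ensemble a `structure_ensemble`.
#' @param model_index model used for evaluation (default 1, the
#'   representative).
#' @return effective distance in Angstrom.
#' @export
evaluate_restraint <- function(restraint, ensemble, model_index = 1) {
  at <- ensemble$atoms
  i1 <- expand_selection(at, restraint$res1, restraint$atom1)
  i2 <- expand_selection(at, restraint$res2, restraint$atom2)
  xyz <- model_coords(ensemble, model_index)
  d6 <- 0
  for (a in i1) for (b in i2) {
    d2 <- sum((xyz[a, ] - xyz[b, ])^2)
    d6 <- d6 + d2^(-3)
  }
  d6^(-1 / 6)
}

#' Classify restraints by conformer compatibility from distances
#'
#' Pure distance-level rule shared by the ensemble-based classifier and by
#' analyses of published per-conformer distance tables: the violation
#' against a conformer is max(0, distance - upper); a restraint is
#' compatible with a conformer when that violation does not exceed the
#' tolerance.  Classes: `both`, `IN-specific`, `OUT-specific`, `neither`.
#'
#' @param upper upper bound(s), Angstrom.
#' @param distance_IN,distance_OUT effective distances in the two
#'   conformers (vectorized).
#' @param tolerance maximal allowed violation (default 0.3 Angstrom).
#' @return data frame with `violation_IN`, `violation_OUT`,
#'   `classification`.
#' @export
classify_restraint_distances <- function(upper, distance_IN, distance_OUT,
                                         tolerance = 0.3) {
  v_in <- pmax(0, distance_IN - upper)
  v_out <- pmax(0, distance_OUT - upper)
  ok_in <- v_in <= tolerance
  ok_out <- v_out <= tolerance
  cls <- ifelse(ok_in & ok_out, "both",
                ifelse(ok_in, "IN-specific",
                       ifelse(ok_out, "OUT-specific", "neither")))
  data.frame(violation_IN = v_in, violation_OUT = v_out,
             classification = cls, stringsAsFactors = FALSE)
}

#' Classify restraints against two conformer ensembles
#'
#' Evaluates every restraint in the representative (first) model of each
#' ensemble and applies the tolerance rule of
#' [classify_restraint_distances].
#'
#' @param restraints restraint data frame (columns `res1`, `atom1`,
#'   `res2`, `atom2`, `upper_A`, optional `tag`).
#' @param ensIN,ensOUT `structure_ensemble` objects for the two
#'   conformers.
#' @param tolerance maximal allowed violation, Angstrom (default 0.3).
#' @param model_index model used in both ensembles (default 1).
#' @return the input restraints with added columns `distance_IN`,
#'   `distance_OUT`, `violation_IN`, `violation_OUT`, `classification`.
#' @export
classify_conformer_specific <- function(restraints, ensIN, ensOUT,
                                        tolerance = 0.3, model_index = 1) {
  d_in <- numeric(nrow(restraints))
  d_out <- numeric(nrow(restraints))
  for (i in seq_len(nrow(restraints))) {
    d_in[i] <- evaluate_restraint(restraints[i, ], ensIN, model_index)
    d_out[i] <- evaluate_restraint(restraints[i, ], ensOUT, model_index)
  }
  cls <- classify_restraint_distances(restraints$upper_A, d_in, d_out,
                                      tolerance)
  cbind(restraints,
        data.frame(distance_IN = d_in, distance_OUT = d_out),
        cls)
}

#' Detect backbone hydrogen bonds consistently present in an ensemble
#'
#' Geometric criterion per model: backbone amide N-H donor, oxygen
#' acceptor, H...O distance below `dist_cutoff` and N-H...O angle at the
#' proton above `angle_cutoff`.  A donor/acceptor pair is reported when it
#' satisfies the criterion in at least `presence_fraction` of the models
#' (the convention used when promoting observed H-bonds to restraints,
#' e.g. 15 out of the best 20 structures).
#'
#' @param ensemble a `structure_ensemble` with amide protons.
#' @param presence_fraction minimum fraction of models (default 15/20).
#' @param dist_cutoff H...acceptor distance cutoff, Angstrom (default 2.5).
#' @param angle_cutoff donor-H...acceptor angle cutoff, degrees (default
#'   120).
#' @return data frame with `donor_resno`, `acceptor_resno`,
#'   `acceptor_atom`, `fraction`.
#' @export
detect_hbonds <- function(ensemble, presence_fraction = 15 / 20,
                          dist_cutoff = 2.5, angle_cutoff = 120) {
  at <- ensemble$atoms
  don_h <- which(at$atom %in% c("H", "HN"))
  acc <- which(at$element == "O")
  if (!length(don_h) || !length(acc)) {
    return(data.frame(donor_resno = integer(), acceptor_resno = integer(),
                      acceptor_atom = character(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  counts <- new.env(parent = emptyenv())
  M <- n_models(ensemble)
  for (m in seq_len(M)) {
    xyz <- model_coords(ensemble, m)
    for (h in don_h) {
      rN <- which(at$resno == at$resno[h] & at$atom == "N")
      if (length(rN) != 1) next
      for (a in acc) {
        if (at$resno[a] == at$resno[h]) next
        v_ho <- xyz[a, ] - xyz[h, ]
        d <- sqrt(sum(v_ho^2))
        if (d >= dist_cutoff) next
        v_hn <- xyz[rN, ] - xyz[h, ]
        cosang <- sum(v_hn * v_ho) / (sqrt(sum(v_hn^2)) * d)
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang <= angle_cutoff) next
        key <- paste(at$resno[h], at$resno[a], at$atom[a], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(data.frame(donor_resno = integer(), acceptor_resno = integer(),
                      acceptor_atom = character(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  frac <- vapply(keys, function(k) counts[[k]] / M, numeric(1))
  out <- data.frame(donor_resno = as.integer(parts[, 1]),
                    acceptor_resno = as.integer(parts[, 2]),
                    acceptor_atom = parts[, 3],
                    fraction = unname(frac), stringsAsFactors = FALSE)
  out <- out[out$fraction >= presence_fraction, , drop = FALSE]
  out <- out[order(out$donor_resno, out$acceptor_resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}
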