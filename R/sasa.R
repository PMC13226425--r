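# Solvent-accessible surface area by sphere sampling (Shrake-Rupley) and
# buried interface areas between atom groups.

# deterministic near-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# standard heavy-atom radii (Angstrom); hydrogens are ignored entirely
sasa_radius <- function(elements) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- unname(r[elements])
  out[is.na(out)] <- 1.70
  out
}

#' Solvent-accessible surface area of a set of atoms
#'
#' Shrake-Rupley sphere sampling: each heavy atom's solvent-expanded
#' sphere (atom radius + probe) is covered with a deterministic
#' near-uniform point set and the accessible fraction is the fraction of
#' points outside every other atom's expanded sphere.  Hydrogens are
#' ignored.  Published interface areas are radii-set dependent; the radii
#' used here are C 1.70, N 1.55, O 1.52, S 1.80 Angstrom.
#'
#' @param xyz n x 3 coordinate matrix (heavy atoms).
#' @param elements element symbols, length n.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return numeric vector of per-atom accessible areas in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, elements, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  keep <- elements != "H"
  xyz <- xyz[keep, , drop = FALSE]
  elements <- elements[keep]
  n <- nrow(xyz)
  rad <- sasa_radius(elements) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour lists via a distance cutoff keep this O(n * k)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + maxr & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rad[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  total <- numeric(length(keep))
  total[keep] <- out
  total
}

#' Buried interface area between two atom groups
#'
#' \deqn{A_{buried} = (SASA_A + SASA_B - SASA_{AB}) / 2}
#' where each SASA is computed on the group alone (or on the union), with
#' a 1.4 Angstrom probe.  The groups must be disjoint; the result is
#' symmetric in A and B and zero for well-separated groups.
#'
#' @param ensemble a `structure_ensemble`.
#' @param groupA,groupB residue-number vectors defining the two groups.
#' @param model_index model to use (default 1).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @return buried area in Angstrom^2 (one number).
#' @export
buried_surface <- function(ensemble, groupA, groupB, model_index = 1,
                           probe = 1.4, n_points = 960) {
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  at <- ensemble$atoms
  xyz <- model_coords(ensemble, model_index)
  selA <- at$resno %in% groupA & at$element != "H"
  selB <- at$resno %in% groupB & at$element != "H"
  if (!any(selA) || !any(selB)) stop("empty group selection")
  sA <- sum(sasa_atoms(xyz[selA, , drop = FALSE], at$element[selA],
                       probe, n_points))
  sB <- sum(sasa_atoms(xyz[selB, , drop = FALSE], at$element[selB],
                       probe, n_points))
  selAB <- selA | selB
  sAB <- sum(sasa_atoms(xyz[selAB, , drop = FALSE], at$element[selAB],
                        probe, n_points))
  (sA + sB - sAB) / 2
}
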