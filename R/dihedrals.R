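# Backbone torsion angles and circular statistics.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2 -> p3 bond, the angle is the
#' clockwise rotation carrying the p1-p2 bond onto the p3-p4 bond; cis = 0,
#' trans = 180.  Returned in degrees in (-180, 180\].
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors.
#' @return angle in degrees.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0))  # trans: 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  stopifnot(all(is.finite(c(p1, p2, p3, p4))))
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi angles of one model
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Angles are undefined (`NA`) at chain termini, where a neighbour residue
#' is missing, or across a chain break (peptide-bond C-N distance above
#' 2.5 Angstrom).
#'
#' @param ensemble a `structure_ensemble`.
#' @param model_index 1-based model number.
#' @return data frame with columns `resno`, `phi`, `psi` (degrees).
#' @export
phi_psi <- function(ensemble, model_index = 1) {
  at <- ensemble$atoms
  xyz <- model_coords(ensemble, model_index)
  get_atom <- function(resno, name) {
    i <- which(at$resno == resno & at$atom == name)
    if (length(i) != 1) return(NULL)
    xyz[i, ]
  }
  resnos <- sort(unique(at$resno))
  out <- data.frame(resno = resnos, phi = NA_real_, psi = NA_real_)
  for (k in seq_along(resnos)) {
    r <- resnos[k]
    N <- get_atom(r, "N"); CA <- get_atom(r, "CA"); C <- get_atom(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    Cprev <- get_atom(r - 1, "C")
    if (!is.null(Cprev) && sqrt(sum((N - Cprev)^2)) <= 2.5)
      out$phi[k] <- dihedral(Cprev, N, CA, C)
    Nnext <- get_atom(r + 1, "N")
    if (!is.null(Nnext) && sqrt(sum((Nnext - C)^2)) <= 2.5)
      out$psi[k] <- dihedral(N, CA, C, Nnext)
  }
  out
}

#' Minimal circular difference between two angles
#'
#' The smallest absolute angular separation on the circle, in \[0, 180\]
#' degrees; invariant under adding multiples of 360 to either input.
#'
#' @param a,b angles in degrees (vectorized).
#' @return degrees in \[0, 180\].
#' @examples
#' circular_difference(179, -179)  # 2
#' circular_difference(84, -70)    # 154
#' @export
circular_difference <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
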