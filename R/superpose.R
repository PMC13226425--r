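# Rigid-body superposition (Kabsch algorithm) and per-residue RMSD.

#' Least-squares rigid-body superposition of two coordinate sets
#'
#' Kabsch algorithm: the optimal proper rotation is obtained from the SVD
#' of the covariance of the centred coordinate sets, with the usual sign
#' correction so the returned rotation always has determinant +1.
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows
#'   (>= 3 non-collinear points).
#' @return list with `rotation` (3 x 3), `translation` (length 3; the fit
#'   maps `mobile %*% t(rotation) + translation` onto `reference`),
#'   `rmsd` (Angstrom, after the fit).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs >= 3 matched atoms, got ", n)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinearity check: rank of the centred reference
  if (sum(svd(B)$d > 1e-8 * max(1, max(abs(B)))) < 2)
    stop("superposition atoms are collinear")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)), rmsd = rmsd)
}

# apply a superposition to raw coordinates
apply_superposition <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, `+`)
}

# match atoms of two ensembles by (resno, atom name); returns index pairs
match_atoms <- function(atomsA, atomsB, maskA, maskB) {
  keyA <- paste(atomsA$resno, atomsA$atom)[maskA]
  keyB <- paste(atomsB$resno, atomsB$atom)[maskB]
  common <- intersect(keyA, keyB)
  iA <- which(maskA)[match(common, keyA)]
  iB <- which(maskB)[match(common, keyB)]
  list(iA = iA, iB = iB, resno = atomsA$resno[iA])
}

#' Per-residue RMSD within or between structure ensembles
#'
#' With two ensembles: the representative (first) model of `ensB` is
#' superposed onto that of `ensA` once, globally, on the ordered-backbone
#' fit region, and the per-residue RMSD between the two representatives is
#' reported over the chosen atom selection.  With one ensemble: every
#' model is superposed onto model 1 the same way and the per-residue
#' values are the mean RMSD of models 2..M to model 1 (ensemble spread).
#' Residues missing from one input are skipped with a notice.
#'
#' @param ensA a `structure_ensemble`.
#' @param ensB optional second ensemble.
#' @param selection `"backbone"` (N, CA, C) or `"heavy"` atoms.
#' @param fit_residues residue numbers defining the global superposition
#'   region (default: all residues common to the inputs).
#' @return data frame with columns `resno` and `rmsd`; the global RMSD of
#'   the superposition fit is in attribute `"global_rmsd"`.
#' @export
per_residue_rmsd <- function(ensA, ensB = NULL,
                             selection = c("backbone", "heavy"),
                             fit_residues = NULL) {
  selection <- match.arg(selection)
  atA <- ensA$atoms
  xyzA <- model_coords(ensA, 1)
  if (!is.null(ensB)) {
    atB <- ensB$atoms
    xyzB <- model_coords(ensB, 1)
    fitm <- match_atoms(atA, atB,
                        atom_selection(atA, "backbone", fit_residues),
                        atom_selection(atB, "backbone", fit_residues))
    fit <- superpose(xyzB[fitm$iB, ], xyzA[fitm$iA, ])
    xyzB <- apply_superposition(xyzB, fit)
    selm <- match_atoms(atA, atB, atom_selection(atA, selection),
                        atom_selection(atB, selection))
    only <- setdiff(unique(atA$resno), unique(atB$resno))
    if (length(only)) message("residues absent in one input skipped: ",
                              paste(only, collapse = ", "))
    d2 <- rowSums((xyzA[selm$iA, , drop = FALSE] -
                     xyzB[selm$iB, , drop = FALSE])^2)
    res <- vapply(split(d2, selm$resno), function(v) sqrt(mean(v)), numeric(1))
    out <- data.frame(resno = as.integer(names(res)), rmsd = unname(res))
    out <- out[order(out$resno), ]
    attr(out, "global_rmsd") <- fit$rmsd
    rownames(out) <- NULL
    return(out)
  }
  # ensemble spread: models 2..M vs model 1
  fit_mask <- atom_selection(atA, "backbone", fit_residues)
  sel_mask <- atom_selection(atA, selection)
  M <- n_models(ensA)
  if (M < 2) stop("ensemble spread needs >= 2 models")
  acc <- matrix(0, nrow = sum(sel_mask), ncol = M - 1)
  for (m in 2:M) {
    xm <- model_coords(ensA, m)
    fit <- superpose(xm[fit_mask, ], xyzA[fit_mask, ])
    xm <- apply_superposition(xm, fit)
    acc[, m - 1] <- rowSums((xm[sel_mask, , drop = FALSE] -
                               xyzA[sel_mask, , drop = FALSE])^2)
  }
  resno <- atA$resno[sel_mask]
  per_model_res <- apply(acc, 2, function(d2)
    vapply(split(d2, resno), function(v) sqrt(mean(v)), numeric(1)))
  per_model_res <- matrix(per_model_res, ncol = M - 1)
  res <- rowMeans(per_model_res)
  out <- data.frame(resno = as.integer(names(split(acc[, 1], resno))),
                    rmsd = unname(res))
  out <- out[order(out$resno), ]
  rownames(out) <- NULL
  out
}
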