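# Multi-model structure container.
#
# A `structure_ensemble` holds one atom table shared by all models plus an
# n_models x 3N coordinate matrix (bio3d xyz layout).  Model numbers in
# the user interface are 1-based, as in PDB MODEL records.

#' Construct a structure ensemble from an atom table and coordinates
#'
#' @param atoms data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`.
#' @param xyz numeric matrix, one row per model, 3 * n_atoms columns in
#'   x1,y1,z1,x2,... order; a single model may be given as a vector.
#' @param source_id free-text identifier (file name, accession, ...).
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, xyz, source_id = "") {
  need <- c("chain", "resno", "resname", "atom", "element")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atoms), all(is.finite(xyz)))
  structure(list(atoms = atoms, xyz = xyz, source_id = source_id),
            class = "structure_ensemble")
}

#' Number of models in an ensemble
#' @param ensemble a `structure_ensemble`.
#' @return integer.
#' @export
n_models <- function(ensemble) nrow(ensemble$xyz)

#' Coordinates of one model as an n_atoms x 3 matrix
#' @param ensemble a `structure_ensemble`.
#' @param model_index 1-based model number.
#' @return numeric matrix with columns x, y, z.
#' @export
model_coords <- function(ensemble, model_index = 1) {
  stopifnot(model_index >= 1, model_index <= n_models(ensemble))
  matrix(ensemble$xyz[model_index, ], ncol = 3, byrow = TRUE)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %s: %d model(s), %d atoms, residues %d-%d\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              n_models(x), nrow(x$atoms), min(x$atoms$resno),
              max(x$atoms$resno)))
  invisible(x)
}

#' Read a (multi-model) PDB file into a structure ensemble
#'
#' Parses ATOM records with bio3d; heteroatoms and waters are excluded by
#' default.  MODEL/ENDMDL bookkeeping is validated first: an opened MODEL
#' without a matching ENDMDL (or vice versa) is an error naming the
#' offending line, and all models must share the same atom list.
#'
#' @param path PDB file.
#' @param keep_hetero keep HETATM records (default FALSE).
#' @return a `structure_ensemble`.
#' @export
read_pdb_ensemble <- function(path, keep_hetero = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  open_at <- 0L
  for (i in seq_along(lines)) {
    tag <- substr(lines[i], 1, 6)
    if (startsWith(tag, "MODEL")) {
      if (open_at > 0L)
        stop("PDB parse error: MODEL at line ", i,
             " opened before ENDMDL for MODEL at line ", open_at)
      open_at <- i
    } else if (startsWith(tag, "ENDMDL")) {
      if (open_at == 0L)
        stop("PDB parse error: ENDMDL without MODEL at line ", i)
      open_at <- 0L
    }
  }
  if (open_at > 0L)
    stop("PDB parse error: missing ENDMDL for MODEL opened at line ", open_at)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" | keep_hetero
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  idx <- which(keep)
  if (!length(idx)) stop("no atoms retained from ", path)
  xyz_cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  elem <- at$elesy[idx]
  bad <- is.na(elem) | !nzchar(trimws(elem))
  if (any(bad)) elem[bad] <- substr(gsub("[0-9]", "", at$elety[idx][bad]), 1, 1)
  atoms <- data.frame(chain = at$chain[idx], resno = at$resno[idx],
                      resname = at$resid[idx], atom = at$elety[idx],
                      element = trimws(elem), stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  structure_ensemble(atoms, pdb$xyz[, xyz_cols, drop = FALSE],
                     source_id = basename(path))
}

#' Write a structure ensemble as a (multi-model) PDB file
#'
#' @param ensemble a `structure_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  bio3d::write.pdb(file = path,
                   xyz = ensemble$xyz,
                   resno = at$resno, resid = at$resname,
                   chain = at$chain, elety = at$atom, elesy = at$element)
  invisible(path)
}

# logical atom mask for a named selection
atom_selection <- function(atoms, selection = c("backbone", "heavy", "all"),
                           residues = NULL) {
  selection <- match.arg(selection)
  sel <- switch(selection,
                backbone = atoms$atom %in% c("N", "CA", "C"),
                heavy = atoms$element != "H",
                all = rep(TRUE, nrow(atoms)))
  if (!is.null(residues)) sel <- sel & atoms$resno %in% residues
  sel
}
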