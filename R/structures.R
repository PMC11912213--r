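AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974)

#' Construct a molecular structure
#'
#' Lightweight container: a table of atom records with coordinates in
#' angstroms and a contiguous residue numbering, plus optional per-residue
#' secondary-structure labels (H/E/C, e.g. collapsed from external DSSP
#' output).
#'
#' @param atoms data.frame with columns `elety` (atom name), `resno` (residue
#'   index), `resid` (3-letter residue type), `x`, `y`, `z`, and optionally
#'   `element` (inferred from the atom name when absent)
#' @param ss optional per-residue character vector in `c("H","E","C")`
#' @return object of class `pstructure`
#' @export
pstructure <- function(atoms, ss = NULL) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("elety", "resno", "resid", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  resno <- sort(unique(as.integer(atoms$resno)))
  if (!all(resno == seq_along(resno) + min(resno) - 1L))
    stop("residue indices must be contiguous")
  if (is.null(atoms$element))
    atoms$element <- sub("^[0-9]*([A-Za-z]).*", "\\1", atoms$elety)
  atoms$element <- toupper(atoms$element)
  if (!is.null(ss)) {
    stopifnot(length(ss) == length(resno), all(ss %in% c("H", "E", "C")))
  }
  structure(list(atoms = atoms, ss = ss), class = "pstructure")
}

#' @export
print.pstructure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues (%s)\n", nrow(x$atoms),
              length(unique(x$atoms$resno)),
              paste0(substr(structure_sequence(x), 1, 20),
                     if (nchar(structure_sequence(x)) > 20) "..." else "")))
  invisible(x)
}

#' One-letter sequence of a structure
#' @param s a [pstructure()]
#' @return character scalar
#' @export
structure_sequence <- function(s) {
  stopifnot(inherits(s, "pstructure"))
  res <- s$atoms[!duplicated(s$atoms$resno), c("resno", "resid")]
  res <- res[order(res$resno), ]
  letters1 <- AA1[res$resid]
  if (anyNA(letters1))
    stop("nonstandard residue(s): ",
         paste(unique(res$resid[is.na(letters1)]), collapse = ", "))
  paste(letters1, collapse = "")
}

#' Bundle structures into an ensemble
#'
#' All members must share one sequence and the same atom selection (same
#' atom names per residue), so per-atom quantities are comparable.
#'
#' @param structures list of [pstructure()] objects
#' @param reference index of the alignment reference (default 1)
#' @return object of class `structure_ensemble`
#' @export
structure_ensemble <- function(structures, reference = 1) {
  stopifnot(length(structures) >= 1,
            all(vapply(structures, inherits, TRUE, "pstructure")))
  key <- function(s) paste(s$atoms$resno, s$atoms$elety, collapse = "|")
  if (length(unique(vapply(structures, key, ""))) != 1)
    stop("ensemble members differ in residue/atom layout")
  seqs <- vapply(structures, structure_sequence, "")
  if (length(unique(seqs)) != 1) stop("ensemble members differ in sequence")
  structure(list(members = structures, reference = reference,
                 sequence = seqs[1]),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble: %d members, %d residues\n",
              length(x$members), nchar(x$sequence)))
  invisible(x)
}

coords_of <- function(s, rows) as.matrix(s$atoms[rows, c("x", "y", "z")])

#' Select atoms of a structure
#'
#' Selection modes: `"alignment"` — main-chain N, CA, C, O plus side-chain
#' carbon atoms (the RMSF alignment convention); `"calpha"` — CA only;
#' `"cbeta"` — CB with CA fallback for glycine (the contact-map convention);
#' `"all"`.
#'
#' @param s a [pstructure()]
#' @param mode selection mode
#' @return integer row indices into `s$atoms`
#' @export
atom_selection <- function(s, mode = c("alignment", "calpha", "cbeta", "all")) {
  mode <- match.arg(mode)
  a <- s$atoms
  switch(mode,
    all = seq_len(nrow(a)),
    calpha = which(a$elety == "CA"),
    alignment = which(a$elety %in% c("N", "CA", "C", "O") |
                        (a$element == "C" & !(a$elety %in% c("CA", "C")))),
    cbeta = {
      idx <- integer()
      for (r in sort(unique(a$resno))) {
        rows <- which(a$resno == r)
        cb <- rows[a$elety[rows] == "CB"]
        ca <- rows[a$elety[rows] == "CA"]
        if (length(cb) > 0) idx <- c(idx, cb[1])
        else if (length(ca) > 0) idx <- c(idx, ca[1])
        else stop("residue ", r, " has neither CB nor CA")
      }
      idx
    })
}

#' Kabsch superposition and RMSD
#'
#' Least-squares optimal rigid superposition of `B`'s selected atoms onto
#' `A`'s via singular value decomposition, with a proper rotation enforced
#' (determinant +1). Returns the rotation, translation and the RMSD over the
#' selection after superposition.
#'
#' @param A,B [pstructure()] objects with identical selections
#' @param selection selection mode passed to [atom_selection()], or an
#'   integer vector of atom rows
#' @return list (`rotation` 3x3, `translation` length-3, `rmsd` angstroms);
#'   the transform maps B coordinates onto A as `t(R %*% t(xyz)) + tr`
#' @export
kabsch_rmsd <- function(A, B, selection = "alignment") {
  selA <- if (is.numeric(selection)) selection else atom_selection(A, selection)
  selB <- if (is.numeric(selection)) selection else atom_selection(B, selection)
  if (length(selA) != length(selB) || length(selA) < 3)
    stop("selections must match and contain at least 3 atoms")
  P <- coords_of(A, selA); Q <- coords_of(B, selB)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv <- svd(P0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300))  # rank < 2: collinear or coincident
    stop("degenerate (collinear or coincident) selection")
  H <- t(Q0) %*% P0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Qr - P0)^2)))
  list(rotation = R, translation = cp - as.numeric(R %*% cq), rmsd = rmsd)
}

apply_transform <- function(s, rotation, translation) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param ensemble a [structure_ensemble()]
#' @param selection selection mode (see [atom_selection()])
#' @return symmetric matrix of RMSDs (angstroms) with zero diagonal
#' @export
rmsd_matrix <- function(ensemble, selection = "alignment") {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n <- length(ensemble$members)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <-
      kabsch_rmsd(ensemble$members[[i]], ensemble$members[[j]], selection)$rmsd
  }
  M
}

#' Align every member of an ensemble to the reference
#'
#' @param ensemble a [structure_ensemble()]
#' @param selection selection used for the superposition
#' @return the aligned ensemble
#' @export
align_ensemble <- function(ensemble, selection = "alignment") {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  ref <- ensemble$members[[ensemble$reference]]
  ensemble$members <- lapply(ensemble$members, function(s) {
    fit <- kabsch_rmsd(ref, s, selection)
    apply_transform(s, fit$rotation, fit$translation)
  })
  ensemble
}

#' Per-residue root-mean-square fluctuation
#'
#' Members are aligned to the reference over `selection`, each residue is
#' represented by the centroid of its selected atoms, and the RMSF is the
#' root-mean-square deviation of those centroids about the ensemble-mean
#' position.
#'
#' @param ensemble a [structure_ensemble()]
#' @param selection atoms representing each residue
#' @param align_selection atoms used for the superposition (defaults to
#'   `selection`; pass a restricted set to keep a locally mobile region from
#'   biasing the global fit)
#' @return numeric vector, one value (angstroms) per residue
#' @export
rmsf <- function(ensemble, selection = "alignment",
                 align_selection = selection) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (length(ensemble$members) == 1) {
    warning("single-member ensemble: RMSF is identically zero")
    return(rep(0, nchar(ensemble$sequence)))
  }
  aligned <- align_ensemble(ensemble, align_selection)
  sel <- if (is.numeric(selection)) selection
         else atom_selection(aligned$members[[1]], selection)
  resno <- aligned$members[[1]]$atoms$resno[sel]
  cents <- lapply(aligned$members, function(s) {
    xyz <- coords_of(s, sel)
    t(vapply(sort(unique(resno)),
             function(r) colMeans(xyz[resno == r, , drop = FALSE]),
             numeric(3)))
  })
  mean_cent <- Reduce("+", cents) / length(cents)
  dev2 <- lapply(cents, function(cc) rowSums((cc - mean_cent)^2))
  sqrt(Reduce("+", dev2) / length(dev2))
}

#' Radius of gyration
#'
#' `sqrt(sum w_i |r_i - r_cm|^2 / sum w_i)`, mass-weighted by default (the
#' cpptraj "rgyr" convention); unknown elements fall back to carbon mass
#' with a warning.
#'
#' @param s a [pstructure()]
#' @param mass_weighted logical
#' @return angstroms
#' @export
radius_of_gyration <- function(s, mass_weighted = TRUE) {
  stopifnot(inherits(s, "pstructure"), nrow(s$atoms) >= 1)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (mass_weighted) {
    w <- ATOMIC_MASS[s$atoms$element]
    if (anyNA(w)) {
      warning("unknown element(s); using carbon mass")
      w[is.na(w)] <- ATOMIC_MASS[["C"]]
    }
  } else {
    w <- rep(1, nrow(xyz))
  }
  cm <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, cm)^2)) / sum(w))
}

residue_rep_coords <- function(s) {
  unname(coords_of(s, atom_selection(s, "cbeta")))
}

#' Mean and standard deviation distance maps of an ensemble
#'
#' Inter-residue distances between CB atoms (CA for glycine), aggregated
#' across the ensemble (population standard deviation, so a single structure
#' gives all-zero spread).
#'
#' @param ensemble a [structure_ensemble()]
#' @return list of matrices `mean` and `std` (angstroms)
#' @export
distance_maps <- function(ensemble) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  ds <- lapply(ensemble$members, function(s)
    unname(as.matrix(stats::dist(residue_rep_coords(s)))))
  m <- Reduce("+", ds) / length(ds)
  v <- Reduce("+", lapply(ds, function(d) (d - m)^2)) / length(ds)
  list(mean = m, std = sqrt(v))
}

#' Binary residue contact map
#'
#' CASP convention: residues are in contact iff the distance between their
#' CB atoms (CA for glycine) is at most `cutoff` (inclusive). The diagonal
#' is 1 (self-connections, as required by the row-normalized GCN adjacency).
#'
#' @param s a [pstructure()]
#' @param cutoff angstroms (default 8)
#' @return symmetric 0/1 matrix with unit diagonal
#' @export
binary_contact_map <- function(s, cutoff = 8) {
  d <- as.matrix(stats::dist(residue_rep_coords(s)))
  A <- unname((d <= cutoff) * 1)
  diag(A) <- 1
  A
}
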