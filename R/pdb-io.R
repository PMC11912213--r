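#' Write an ensemble as a multi-MODEL PDB file
#'
#' Minimal PDB writer (ATOM/MODEL/ENDMDL/TER/END records) sufficient for the
#' toy CA/CB ensembles and for interchange with standard readers.
#'
#' @param ensemble a [structure_ensemble()] (or single [pstructure()])
#' @param path output file
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  if (inherits(ensemble, "pstructure"))
    ensemble <- structure_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "structure_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(ensemble$members) > 1
  for (m in seq_along(ensemble$members)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- ensemble$members[[m]]$atoms
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)),
      ifelse(nchar(a$elety) < 4, paste0(" ", a$elety), a$elety),
      a$resid, a$resno, a$x, a$y, a$z, a$element), con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (possibly multi-MODEL) PDB file as a structure ensemble
#'
#' Parsing is delegated to `bio3d::read.pdb`; each MODEL becomes one ensemble
#' member sharing the atom table of the first.
#'
#' @param path PDB file
#' @param reference alignment reference index
#' @return a [structure_ensemble()]
#' @export
read_ensemble_pdb <- function(path, reference = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                      resid = pdb$atom$resid,
                      x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z)
  el <- pdb$atom$elesy
  if (!is.null(el) && !all(is.na(el)) && !all(el == ""))
    atoms$element <- trimws(el)
  n_models <- nrow(pdb$xyz)
  members <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    a <- atoms
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    pstructure(a)
  })
  structure_ensemble(members, reference = reference)
}
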