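#' Canonical amyloid-beta monomer sequences
#'
#' One-letter sequences of the 28-, 40- and 42-residue amyloid-beta
#' peptides (the shorter forms are N-terminal truncations of the 42-mer).
#'
#' @param length 28, 40 or 42
#' @return character scalar
#' @export
abeta_sequence <- function(length = c(42, 40, 28)) {
  length <- as.integer(length[1])
  full <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
  if (!length %in% c(28L, 40L, 42L)) stop("length must be 28, 40 or 42")
  substr(full, 1, length)
}

#' Residue classification used throughout the package
#'
#' Hydrophobic class `{G, A, V, L, I, P, F, M, W}` (glycine included; this is
#' the class assignment that reproduces the standard hydrophobic-residue
#' counts for the three amyloid-beta peptides), the polar complement, and
#' fixed formal charges at neutral pH (Asp/Glu -1, Lys/Arg +1, His neutral;
#' free termini +1 and -1, cancelling).
#'
#' @return list: `hydrophobic`, `polar` (character vectors of one-letter
#'   codes), `charge` (named numeric), `terminal_charge` (net, 0)
#' @export
residue_classification <- function() {
  aa <- names(AA3)
  hydrophobic <- c("G", "A", "V", "L", "I", "P", "F", "M", "W")
  charge <- stats::setNames(rep(0, 20), aa)
  charge[c("D", "E")] <- -1
  charge[c("K", "R")] <- 1
  list(hydrophobic = hydrophobic,
       polar = setdiff(aa, hydrophobic),
       charge = charge,
       terminal_charge = 0)
}

check_sequence <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters1, names(AA3))
  if (length(bad) > 0)
    stop("nonstandard residue letter(s): ", paste(unique(bad), collapse = ", "))
  letters1
}

#' Hydrophobic residue count and fraction of a sequence
#'
#' @param sequence one-letter amino-acid string
#' @return list (`count`, `fraction`)
#' @export
hydrophobic_content <- function(sequence) {
  letters1 <- check_sequence(sequence)
  n <- sum(letters1 %in% residue_classification()$hydrophobic)
  list(count = n, fraction = n / length(letters1))
}

#' Net formal charge of a peptide at neutral pH
#'
#' Sum of fixed side-chain charges (Asp/Glu -1, Lys/Arg +1, His neutral)
#' plus the free-termini pair (+1 - 1 = 0).
#'
#' @param sequence one-letter amino-acid string
#' @return integer net charge
#' @export
net_formal_charge <- function(sequence) {
  letters1 <- check_sequence(sequence)
  cls <- residue_classification()
  as.integer(sum(cls$charge[letters1]) + cls$terminal_charge)
}
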