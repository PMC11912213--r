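# Meiler-style physicochemical descriptors per residue: steric bulk,
# polarizability, volume, hydrophobicity, isoelectric point, helix and
# sheet propensity. Z-scored over the 20 residues before use.
PHYSCHEM7 <- matrix(c(
  1.28, 0.05, 1.00,  0.31,  6.11, 0.42, 0.23,  # A
  2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25,  # R
  1.60, 0.13, 2.95, -0.60,  6.52, 0.21, 0.22,  # N
  1.60, 0.11, 2.78, -0.77,  2.95, 0.25, 0.20,  # D
  1.77, 0.13, 2.43,  1.54,  6.35, 0.17, 0.41,  # C
  1.56, 0.18, 3.95, -0.22,  5.65, 0.36, 0.25,  # Q
  1.56, 0.15, 3.78, -0.64,  3.09, 0.42, 0.21,  # E
  0.00, 0.00, 0.00,  0.00,  6.07, 0.13, 0.15,  # G
  2.99, 0.23, 4.66,  0.13,  7.69, 0.27, 0.30,  # H
  4.19, 0.19, 4.00,  1.80,  6.04, 0.30, 0.45,  # I
  2.59, 0.19, 4.00,  1.70,  6.04, 0.39, 0.31,  # L
  1.89, 0.22, 4.77, -0.99,  9.99, 0.32, 0.27,  # K
  2.35, 0.22, 4.43,  1.23,  5.71, 0.38, 0.32,  # M
  2.94, 0.29, 5.89,  1.79,  5.67, 0.30, 0.38,  # F
  2.67, 0.00, 2.72,  0.72,  6.80, 0.13, 0.34,  # P
  1.31, 0.06, 1.60, -0.04,  5.70, 0.20, 0.28,  # S
  3.03, 0.11, 2.60,  0.26,  5.60, 0.21, 0.36,  # T
  3.21, 0.41, 8.08,  2.25,  5.94, 0.32, 0.42,  # W
  2.94, 0.30, 6.47,  0.96,  5.66, 0.25, 0.41,  # Y
  3.67, 0.14, 3.00,  1.22,  6.02, 0.27, 0.49), # V
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"), NULL))

.feature_cache <- new.env(parent = emptyenv())

# 20 standard-residue rows/columns of BLOSUM62 (from Biostrings), scaled by
# 1/10 so feature magnitudes are O(1).
blosum_block <- function() {
  if (is.null(.feature_cache$blosum)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    aa <- rownames(PHYSCHEM7)
    .feature_cache$blosum <- env$BLOSUM62[aa, aa] / 10
  }
  .feature_cache$blosum
}

physchem_block <- function() {
  if (is.null(.feature_cache$physchem)) {
    .feature_cache$physchem <- scale(PHYSCHEM7)[, , drop = FALSE]
  }
  .feature_cache$physchem
}

#' Collapse 8-class DSSP labels to helix/sheet/coil
#'
#' `H`, `G`, `I` become helix; `E`, `B` sheet; everything else coil.
#'
#' @param labels character vector of DSSP codes (or already-collapsed codes)
#' @return character vector in `c("H","E","C")`
#' @export
collapse_dssp <- function(labels) {
  out <- rep("C", length(labels))
  out[labels %in% c("H", "G", "I")] <- "H"
  out[labels %in% c("E", "B")] <- "E"
  out
}

#' Build a residue graph for the solubility GCN
#'
#' Nodes are residues; edges are the binary 8-angstrom CB contact map with
#' self-connections, row-normalized by the degree matrix. Node features are
#' assembled in fixed blocks: BLOSUM62 row (20), physicochemical descriptors
#' (7), secondary-structure one-hot (3), min-max-scaled SASA (1), and
#' zero-filled evolutionary blocks (PSSM 20 + HMM 30) when no profiles are
#' available, padded with zeros to `width` (default 91).
#'
#' @param structure a [pstructure()] (used for the sequence, the contact map
#'   and the default SASA); may be `NULL` if `sequence` and `contact_map`
#'   are given directly
#' @param sasa_res optional per-residue SASA values; computed with [sasa()]
#'   from the structure when `NULL` and a structure is given, else zero
#' @param ss_labels optional per-residue secondary-structure labels (8-class
#'   DSSP accepted, collapsed with [collapse_dssp()]); default all coil
#' @param sequence,contact_map direct inputs overriding the structure
#' @param width feature width; blocks are truncated/zero-padded to it
#' @return object of class `protein_graph`: `sequence`, `n`, `A`, `Ahat`
#'   (row-normalized adjacency), `H0` (`n x width`)
#' @export
build_protein_graph <- function(structure = NULL, sasa_res = NULL,
                                ss_labels = NULL, sequence = NULL,
                                contact_map = NULL, width = 91) {
  if (is.null(sequence)) {
    stopifnot(inherits(structure, "pstructure"))
    sequence <- structure_sequence(structure)
  }
  letters1 <- check_sequence(sequence)
  n <- length(letters1)
  if (is.null(contact_map)) {
    stopifnot(inherits(structure, "pstructure"))
    contact_map <- binary_contact_map(structure)
  }
  A <- (contact_map > 0) * 1
  diag(A) <- 1
  stopifnot(nrow(A) == n, isTRUE(all.equal(A, t(A))))
  if (is.null(sasa_res)) {
    sasa_res <- if (!is.null(structure))
      sasa(structure, default_radius = 1.7)$residue$area else rep(0, n)
  }
  stopifnot(length(sasa_res) == n)
  rng <- range(sasa_res)
  sasa_scaled <- if (diff(rng) > 0) (sasa_res - rng[1]) / diff(rng) else rep(0, n)
  if (is.null(ss_labels)) ss_labels <- rep("C", n)
  ss_labels <- collapse_dssp(ss_labels)
  stopifnot(length(ss_labels) == n)
  ss1h <- t(vapply(ss_labels, function(l) as.numeric(c("H", "E", "C") == l),
                   numeric(3)))
  H0 <- cbind(blosum_block()[letters1, , drop = FALSE],
              physchem_block()[letters1, , drop = FALSE],
              ss1h, sasa_scaled,
              matrix(0, n, 50))    # PSSM (20) + HMM (30), absent
  if (ncol(H0) < width) H0 <- cbind(H0, matrix(0, n, width - ncol(H0)))
  if (ncol(H0) > width) H0 <- H0[, seq_len(width), drop = FALSE]
  dimnames(H0) <- NULL
  # row-normalize; the last nonzero entry absorbs the rounding residue so
  # every row sums to exactly 1 in double precision
  Ahat <- unname(A / rowSums(A))
  for (i in seq_len(n)) {
    nz <- which(Ahat[i, ] > 0)
    last <- nz[length(nz)]
    Ahat[i, last] <- 1 - sum(Ahat[i, nz[-length(nz)]])
  }
  structure(list(sequence = sequence, n = n, A = A, Ahat = Ahat, H0 = H0,
                 width = width),
            class = "protein_graph")
}

#' Initialize a solubility GCN
#'
#' Two row-normalized graph-convolution layers with ReLU, additive-attention
#' pooling with `heads` heads (`score_h(i) = v_h . tanh(Wa h_i)`, softmax
#' over nodes), and a final linear map + sigmoid. The map from the pooled
#' representation to the pre-sigmoid logit is linear so that per-residue
#' attributions are exactly additive.
#'
#' @param width input feature width
#' @param hidden sizes of the two GCN layers
#' @param d_att attention projection size
#' @param heads attention heads
#' @param seed RNG seed for the initial weights
#' @return object of class `solubility_model`
#' @export
init_solubility_model <- function(width = 91, hidden = c(32, 32), d_att = 16,
                                  heads = 4, seed = 1) {
  set.seed(seed)
  gauss <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                   nr, nc)
  structure(list(
    W0 = gauss(width, hidden[1]),
    W1 = gauss(hidden[1], hidden[2]),
    Wa = gauss(hidden[2], d_att),
    V = gauss(d_att, heads),
    w = stats::rnorm(heads * hidden[2], sd = sqrt(1 / (heads * hidden[2]))),
    b = 0,
    dims = list(width = width, hidden = hidden, d_att = d_att, heads = heads),
    seed = seed),
    class = "solubility_model")
}

#' Forward pass of the solubility GCN
#'
#' @param graph a [build_protein_graph()] result
#' @param model a [init_solubility_model()] / [train_solubility()] model
#' @return list: `score` in (0,1), `logit`, hidden states `H1`, `H2`,
#'   attention weights `alpha` (`n x heads`, columns sum to 1), pooled
#'   representation `r`, and pre-activation caches used by backprop
#' @export
gcn_forward <- function(graph, model) {
  stopifnot(inherits(graph, "protein_graph"),
            inherits(model, "solubility_model"))
  if (ncol(graph$H0) != nrow(model$W0))
    stop("feature width (", ncol(graph$H0), ") does not match the model (",
         nrow(model$W0), ")")
  AH0 <- graph$Ahat %*% graph$H0
  M0 <- AH0 %*% model$W0
  H1 <- pmax(M0, 0)
  AH1 <- graph$Ahat %*% H1
  M1 <- AH1 %*% model$W1
  H2 <- pmax(M1, 0)
  Tn <- tanh(H2 %*% model$Wa)
  S <- Tn %*% model$V
  E <- exp(sweep(S, 2, apply(S, 2, max)))
  alpha <- sweep(E, 2, colSums(E), "/")
  r <- as.numeric(t(H2) %*% alpha)     # heads * d2, head-major blocks
  logit <- sum(model$w * r) + model$b
  list(score = stats::plogis(logit), logit = logit, H1 = H1, H2 = H2,
       alpha = alpha, r = r, AH0 = AH0, AH1 = AH1, M0 = M0, M1 = M1,
       Tn = Tn)
}

#' Per-residue attribution of the solubility prediction
#'
#' Each residue's contribution is its attention weight in every head applied
#' to its hidden node vector and passed through the final linear map, summed
#' over heads — the linear output *before* the sigmoid, which is the
#' additive scale: the contributions plus the bias reproduce the pre-sigmoid
#' logit exactly. Negative contributions push towards insolubility.
#'
#' @param graph a `protein_graph`
#' @param model a `solubility_model`
#' @return object of class `attribution_report`: data.frame `residues`
#'   (`position`, `aa`, `contribution`), `bias`, `logit`, `score`
#' @export
residue_attribution <- function(graph, model) {
  fw <- gcn_forward(graph, model)
  d2 <- model$dims$hidden[2]
  heads <- model$dims$heads
  contrib <- numeric(graph$n)
  for (h in seq_len(heads)) {
    wh <- model$w[((h - 1) * d2 + 1):(h * d2)]
    contrib <- contrib + fw$alpha[, h] * as.numeric(fw$H2 %*% wh)
  }
  structure(list(
    residues = data.frame(position = seq_len(graph$n),
                          aa = strsplit(graph$sequence, "")[[1]],
                          contribution = contrib),
    bias = model$b, logit = fw$logit, score = fw$score),
    class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("Solubility %.4f (logit %.4f = bias %.4f + sum of %d residue contributions)\n",
              x$score, x$logit, x$bias, nrow(x$residues)))
  top <- x$residues[order(x$residues$contribution)[1:min(5, nrow(x$residues))], ]
  cat("  most insolubilizing residues:\n")
  for (k in seq_len(nrow(top)))
    cat(sprintf("    %s%d  %+.4f\n", top$aa[k], top$position[k],
                top$contribution[k]))
  invisible(x)
}

#' Predict solubility for a list of graphs
#' @param model a `solubility_model`
#' @param graphs list of `protein_graph`
#' @return numeric vector in (0,1)
#' @export
predict_solubility <- function(model, graphs) {
  vapply(graphs, function(g) gcn_forward(g, model)$score, 1.0)
}
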