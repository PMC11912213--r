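#' Generate a multi-funnel kinetic transition network with planted structure
#'
#' Each funnel is a random tree of minima whose energies rise away from the
#' funnel bottom, with intra-funnel transition states in a fixed barrier
#' window above the bottom; funnels are chained through high-energy
#' transition states at `inter_funnel_barrier` above the higher of the two
#' bottoms. Because the inter-funnel barrier exceeds every intra-funnel
#' barrier, threshold clustering at any threshold between the two scales
#' provably recovers the planted funnel assignment, with the planted bottoms
#' as representatives. Harmonic rates on the result satisfy detailed balance
#' by construction.
#'
#' @param n_funnels number of funnels
#' @param minima_per_funnel minima in each funnel (scalar or vector)
#' @param bottom_energies funnel bottom energies, kcal/mol (default evenly
#'   spaced downward from -10, funnel 1 lowest)
#' @param intra_barrier_range `c(lo, hi)`: intra-funnel transition-state
#'   energies sit in `bottom + [lo, hi]`; member minima in
#'   `bottom + (0, 0.45 lo)`
#' @param inter_funnel_barrier barrier of the funnel-joining transition
#'   states above the higher bottom; must exceed `hi`
#' @param seed RNG seed (`NULL`: use the current RNG state)
#' @return list: `ktn` (strict-validated), `assignment` (named funnel index
#'   per minimum id), `representatives` (planted funnel-bottom ids)
#' @export
generate_funnel_ktn <- function(n_funnels, minima_per_funnel = 10,
                                bottom_energies = NULL,
                                intra_barrier_range = c(2, 4),
                                inter_funnel_barrier = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_funnels >= 1, all(minima_per_funnel >= 1),
            intra_barrier_range[1] > 0,
            intra_barrier_range[2] >= intra_barrier_range[1])
  if (inter_funnel_barrier <= intra_barrier_range[2])
    stop("infeasible funnel spec: inter-funnel barrier must exceed the ",
         "largest intra-funnel barrier")
  m <- rep(minima_per_funnel, length.out = n_funnels)
  if (is.null(bottom_energies))
    bottom_energies <- -10 - 1.5 * (seq_len(n_funnels) - 1)
  bottom_energies <- rep(bottom_energies, length.out = n_funnels)
  lo <- intra_barrier_range[1]; hi <- intra_barrier_range[2]
  minima <- list(); tss <- list()
  assignment <- integer(); bottoms <- integer()
  next_id <- 1L
  for (f in seq_len(n_funnels)) {
    ids <- next_id:(next_id + m[f] - 1L)
    next_id <- next_id + m[f]
    bottoms <- c(bottoms, ids[1])
    e <- c(bottom_energies[f],
           if (m[f] > 1) bottom_energies[f] +
             stats::runif(m[f] - 1, 0.05, 0.45 * lo))
    minima[[f]] <- data.frame(id = ids, energy = e)
    assignment[as.character(ids)] <- f
    if (m[f] > 1) {
      parent <- vapply(seq_len(m[f] - 1),
                       function(k) ids[sample.int(k, 1)], 1L)
      tss[[f]] <- data.frame(
        energy = bottom_energies[f] + stats::runif(m[f] - 1, lo, hi),
        min1 = parent, min2 = ids[-1])
    }
  }
  inter <- if (n_funnels > 1) {
    data.frame(
      energy = pmax(bottom_energies[-n_funnels], bottom_energies[-1]) +
        inter_funnel_barrier,
      min1 = bottoms[-n_funnels], min2 = bottoms[-1])
  }
  ts <- do.call(rbind, c(tss, list(inter)))
  if (is.null(ts)) {
    ts <- data.frame(id = integer(), energy = numeric(),
                     min1 = integer(), min2 = integer())
  } else {
    ts <- data.frame(id = seq_len(nrow(ts)), ts)
  }
  net <- validate_ktn(do.call(rbind, minima), ts, policy = "strict")
  list(ktn = net, assignment = assignment, representatives = bottoms)
}

#' Two-state network with prescribed barriers
#'
#' Minimum 1 at energy 0, minimum 2 at `barrier_forward - barrier_backward`,
#' one transition state at `barrier_forward`: the analytic fixture for
#' single-exponential first-passage behaviour.
#'
#' @param barrier_forward,barrier_backward kcal/mol (> 0)
#' @return a [ktn()] object
#' @export
generate_two_state <- function(barrier_forward, barrier_backward) {
  stopifnot(barrier_forward > 0, barrier_backward > 0)
  ktn(data.frame(id = 1:2, energy = c(0, barrier_forward - barrier_backward)),
      data.frame(id = 1L, energy = barrier_forward, min1 = 1L, min2 = 2L))
}

#' Two-funnel network with a kinetic trap (multi-peak FPT fixture)
#'
#' A source minimum branches between a fast direct path to the sink funnel
#' and a low-lying trap whose only escape is back over a much higher
#' barrier. Probability started at the source splits between the two routes,
#' so the first-passage-time distribution to the sink has (at least) two
#' well-separated peaks with non-negligible amplitudes.
#'
#' @param trap_depth escape barrier out of the trap, kcal/mol
#' @param fast_barrier source-to-trap barrier
#' @param direct_barrier source-to-sink barrier
#' @return list: `ktn`, `source`, `trap`, `sink` (minimum ids)
#' @export
generate_trap_ktn <- function(trap_depth = 12, fast_barrier = 2,
                              direct_barrier = 3) {
  stopifnot(trap_depth > fast_barrier)
  e_s <- -10
  ts_st <- e_s + fast_barrier
  net <- ktn(
    data.frame(id = 1:3, energy = c(e_s, ts_st - trap_depth, e_s - 10)),
    data.frame(id = 1:2, energy = c(ts_st, e_s + direct_barrier),
               min1 = c(1L, 1L), min2 = c(2L, 3L)))
  list(ktn = net, source = 1L, trap = 2L, sink = 3L)
}

#' Deep-trap network for conditioning studies
#'
#' A trap state whose outflow rate is `trap_rate` (default 1e-18 in reduced
#' time units) feeds a hub with `n_satellites` fast side states and a fast
#' sink connection. The slowest relaxation rate is then
#' `trap_rate * P(absorb at the sink before returning to the trap)`, with
#' the splitting probability computable from the well-conditioned fast
#' subnetwork — an analytically controlled value that double-precision
#' eigendecomposition of the full matrix cannot resolve, but a pGT-reduced
#' network can.
#'
#' @param trap_rate outflow rate from the trap (sets the barrier via the
#'   rate model)
#' @param n_satellites fast side states on the hub
#' @param model a [rate_model()] (defines the barrier corresponding to
#'   `trap_rate`)
#' @return list: `ktn`, `trap`, `hub`, `sink` ids
#' @export
generate_deep_trap_ktn <- function(trap_rate = 1e-18, n_satellites = 8,
                                   model = rate_model()) {
  barrier <- -log(trap_rate) / model$beta
  e_hub <- -1
  ids <- seq_len(n_satellites + 3L)
  sink <- length(ids)
  sat <- 2L + seq_len(n_satellites)
  minima <- data.frame(id = ids,
                       energy = c(-barrier, e_hub, rep(e_hub, n_satellites), -3))
  ts <- data.frame(id = seq_len(n_satellites + 2L),
                   energy = 0,
                   min1 = c(1L, rep(2L, n_satellites), 2L),
                   min2 = c(2L, sat, sink))
  list(ktn = validate_ktn(minima, ts, policy = "strict"),
       trap = 1L, hub = 2L, sink = sink)
}

unit_sphere <- function(n) {
  z <- stats::rnorm(3 * n)
  m <- matrix(z, ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Generate toy peptide conformer ensembles
#'
#' Calpha/Cbeta pseudo-structures in three geometry modes: ideal alpha-helix
#' (rise 1.5 angstroms and 100 degrees per residue on a 2.3-angstrom radius),
#' fully extended (3.5 angstroms per residue), or a random coil (3.8-angstrom
#' virtual bonds with random directions). Cbeta atoms sit 1.5 angstroms off
#' the local backbone (omitted for glycine). Per-model Gaussian jitter with
#' standard deviation `jitter` emulates conformational spread.
#'
#' @param n_residues chain length
#' @param mode `"helix"`, `"extended"` or `"coil"`
#' @param jitter per-coordinate Gaussian sd, angstroms
#' @param n_models ensemble size
#' @param sequence one-letter sequence (default: random)
#' @param seed RNG seed (`NULL`: use the current RNG state)
#' @return a [structure_ensemble()]
#' @export
generate_toy_peptides <- function(n_residues, mode = c("helix", "extended", "coil"),
                                  jitter = 0, n_models = 1, sequence = NULL,
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sequence))
    sequence <- paste(sample(names(AA3), n_residues, replace = TRUE),
                      collapse = "")
  letters1 <- check_sequence(sequence)
  stopifnot(length(letters1) == n_residues)
  i <- seq_len(n_residues) - 1
  ca <- switch(mode,
    helix = cbind(2.3 * cos(i * 100 * pi / 180),
                  2.3 * sin(i * 100 * pi / 180),
                  1.5 * i),
    extended = cbind(3.5 * i, 0.5 * (-1)^i, 0),
    coil = {
      steps <- 3.8 * unit_sphere(n_residues - 1)
      apply(rbind(0, steps), 2, cumsum)
    })
  # Cbeta direction: away from the local backbone midpoint
  cb_dir <- t(vapply(seq_len(n_residues), function(k) {
    lo <- max(1, k - 1); hi <- min(n_residues, k + 1)
    v <- ca[k, ] - (ca[lo, ] + ca[hi, ]) / 2
    if (sqrt(sum(v^2)) < 1e-6) v <- c(0, 0, 1)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  members <- lapply(seq_len(n_models), function(m) {
    rows <- list()
    for (k in seq_len(n_residues)) {
      rows[[length(rows) + 1]] <- data.frame(
        elety = "CA", resno = k, resid = AA3[[letters1[k]]],
        x = ca[k, 1], y = ca[k, 2], z = ca[k, 3], element = "C")
      if (letters1[k] != "G") {
        cb <- ca[k, ] + 1.5 * cb_dir[k, ]
        rows[[length(rows) + 1]] <- data.frame(
          elety = "CB", resno = k, resid = AA3[[letters1[k]]],
          x = cb[1], y = cb[2], z = cb[3], element = "C")
      }
    }
    a <- do.call(rbind, rows)
    if (jitter > 0) {
      a$x <- a$x + stats::rnorm(nrow(a), sd = jitter)
      a$y <- a$y + stats::rnorm(nrow(a), sd = jitter)
      a$z <- a$z + stats::rnorm(nrow(a), sd = jitter)
    }
    pstructure(a)
  })
  structure_ensemble(members)
}

#' Generate a labelled synthetic solubility dataset with planted ground truth
#'
#' Random coil peptide graphs whose label is a sigmoid of the sum of planted
#' additive per-residue contributions plus clipped Gaussian noise. The
#' planted contribution of a residue depends only on its class
#' (hydrophobic / charged / polar, hydrophobic most negative by default) and
#' is embedded *exactly* in the BLOSUM62 feature block (class effects are
#' mapped through the inverse of the BLOSUM62 submatrix), so the target is
#' an additive linear functional of the node features. Per-graph residue
#' composition is biased by a random hydrophobic propensity to spread the
#' labels.
#'
#' @param n_graphs dataset size
#' @param class_effects named contributions per residue class
#' @param noise_sd label noise standard deviation
#' @param effect_scale multiplies the mean planted contribution to set the
#'   logit scale
#' @param n_range residue-count range, inclusive
#' @param seed RNG seed
#' @return list: `graphs`, `labels`, `truth` (list with `u` per-residue-type
#'   contributions, `blosum_weights`, per-graph `logits` and per-node
#'   `contributions`)
#' @export
generate_solubility_dataset <- function(n_graphs,
                                        class_effects = c(hydrophobic = -0.55,
                                                          charged = 0.45,
                                                          polar = 0.15),
                                        noise_sd = 0.05, effect_scale = 6,
                                        n_range = c(15, 35), seed = 1) {
  stopifnot(noise_sd >= 0, n_graphs >= 1)
  set.seed(seed)
  cls <- residue_classification()
  charged <- names(cls$charge)[cls$charge != 0]
  aa <- names(AA3)
  u <- stats::setNames(rep(class_effects[["polar"]], 20), aa)
  u[cls$hydrophobic] <- class_effects[["hydrophobic"]]
  u[charged] <- class_effects[["charged"]]
  blosum_weights <- solve(t(blosum_block()), u)
  graphs <- vector("list", n_graphs)
  labels <- numeric(n_graphs)
  logits <- numeric(n_graphs)
  contributions <- vector("list", n_graphs)
  hyd <- cls$hydrophobic
  other <- setdiff(aa, hyd)
  for (gidx in seq_len(n_graphs)) {
    n <- sample(seq(n_range[1], n_range[2]), 1)
    f <- stats::runif(1, 0.15, 0.7)
    pick_h <- stats::runif(n) < f
    letters1 <- ifelse(pick_h, sample(hyd, n, replace = TRUE),
                       sample(other, n, replace = TRUE))
    seqn <- paste(letters1, collapse = "")
    ens <- generate_toy_peptides(n, mode = "coil", sequence = seqn)
    graphs[[gidx]] <- build_protein_graph(ens$members[[1]],
                                          sasa_res = rep(0, n))
    contributions[[gidx]] <- unname(u[letters1] * effect_scale / n)
    logits[gidx] <- sum(contributions[[gidx]])
    labels[gidx] <- min(1, max(0, stats::plogis(logits[gidx]) +
                                 stats::rnorm(1, sd = noise_sd)))
  }
  list(graphs = graphs, labels = labels,
       truth = list(u = u, blosum_weights = blosum_weights,
                    logits = logits, contributions = contributions,
                    effect_scale = effect_scale))
}
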