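# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation paths they check.

# connected components by hand-rolled breadth-first search over TS records
bfs_components <- function(net) {
  ids <- net$minima$id
  seen <- stats::setNames(rep(FALSE, length(ids)), as.character(ids))
  comps <- list()
  for (s in ids) {
    if (seen[as.character(s)]) next
    comp <- s; seen[as.character(s)] <- TRUE
    frontier <- s
    while (length(frontier) > 0) {
      nb <- integer()
      for (m in frontier) {
        hit <- net$ts$min1 == m | net$ts$min2 == m
        other <- c(net$ts$min2[net$ts$min1 == m], net$ts$min1[net$ts$min2 == m])
        other <- unique(other[!seen[as.character(other)]])
        seen[as.character(other)] <- TRUE
        nb <- c(nb, other)
      }
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# minimax (widest-path) barrier matrix: B[i, j] = smallest possible maximum
# TS energy over all paths i -> j, by Floyd-Warshall on the max semiring
minimax_barrier_matrix <- function(net) {
  ids <- net$minima$id
  n <- length(ids)
  B <- matrix(Inf, n, n, dimnames = list(as.character(ids), as.character(ids)))
  diag(B) <- -Inf
  for (r in seq_len(nrow(net$ts))) {
    a <- as.character(net$ts$min1[r]); b <- as.character(net$ts$min2[r])
    B[a, b] <- B[b, a] <- min(B[a, b], net$ts$energy[r])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    via <- max(B[i, k], B[k, j])
    if (via < B[i, j]) B[i, j] <- B[j, i] <- via
  }
  B
}

# greedy threshold clustering replicated directly on the minimax matrix
minimax_threshold_clusters <- function(net, threshold) {
  B <- minimax_barrier_matrix(net)
  ids <- net$minima$id
  energy <- net$minima$energy
  ord <- order(energy, ids)
  assigned <- rep(FALSE, length(ids))
  clusters <- list()
  for (k in ord) {
    if (assigned[k]) next
    # members: unassigned minima whose minimax barrier to the seed, over
    # paths through unassigned minima only, is within threshold; on the
    # restricted network recompute minimax among unassigned
    sub <- which(!assigned)
    subnet <- list(minima = net$minima[sub, , drop = FALSE],
                   ts = net$ts[net$ts$min1 %in% ids[sub] &
                                 net$ts$min2 %in% ids[sub], , drop = FALSE])
    Bs <- minimax_barrier_matrix(subnet)
    seed_chr <- as.character(ids[k])
    memb <- subnet$minima$id[Bs[seed_chr, ] <= energy[k] + threshold]
    clusters[[length(clusters) + 1]] <- sort(unique(c(ids[k], memb)))
    assigned[match(clusters[[length(clusters)]], ids)] <- TRUE
  }
  clusters
}

# exposed area of two overlapping spheres (closed form), radii already
# probe-inflated
two_sphere_exposed <- function(R1, R2, d) {
  area <- c(4 * pi * R1^2, 4 * pi * R2^2)
  if (d >= R1 + R2) return(area)
  if (d + R1 <= R2) area[1] <- 0
  else area[1] <- area[1] - 2 * pi * R1 * (R1 - (d^2 + R1^2 - R2^2) / (2 * d))
  if (d + R2 <= R1) area[2] <- 0
  else area[2] <- area[2] - 2 * pi * R2 * (R2 - (d^2 + R2^2 - R1^2) / (2 * d))
  area
}

# Random multi-funnel network with randomized shape, for property tests.
# Inter-funnel barriers stay moderate (3.5-6 kcal/mol) so the slowest
# timescale is within ~1e4 of the fastest: the regime where double-precision
# linear algebra supports 1e-8 cross-validation between independent routes.
# Deep-trap stiffness beyond that is exercised separately through pGT.
random_funnel_net <- function(seed, max_funnels = 3, max_minima = 12) {
  set.seed(seed)
  nf <- sample.int(max_funnels, 1)
  generate_funnel_ktn(nf, sample(3:max_minima, nf, replace = TRUE),
                      intra_barrier_range = sort(stats::runif(2, 1.5, 3)),
                      inter_funnel_barrier = stats::runif(1, 3.5, 6))
}

# rigidly rotated + translated copy of a structure
random_rigid_copy <- function(s, seed) {
  set.seed(seed)
  a <- stats::runif(3, -pi, pi)
  Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[2]), -sin(a[2]), 0, sin(a[2]), cos(a[2])), 3, 3)
  tr <- stats::runif(3, -20, 20)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  xyz <- sweep(xyz, 2, tr, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# half-up rounding of a printed percentage, guarded against binary artefacts
# (57.5 stored as 57.4999... must still print as 58)
percent_printed <- function(fraction) floor(100 * fraction + 0.5 + 1e-9)

# RMSD oracle: optimize rotation over Euler angles with a generic optimizer
# (no SVD involved)
euler_rmsd_oracle <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    matrix(c(cy * cz, cy * sz, -sy,
             sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
             cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
           3, 3, byrow = TRUE)
  }
  obj <- function(a) sqrt(mean(rowSums((Q0 %*% t(rotmat(a)) - P0)^2)))
  best <- Inf
  for (s in 1:25) {
    a0 <- stats::runif(3, -pi, pi)
    r <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}
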