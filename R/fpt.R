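#' Reduce the master equation to an absorbing-sink problem
#'
#' For first-passage-time analysis the sink states are made absorbing: their
#' rows and columns are removed from `Q`, while the escape rates *into* the
#' sink remain inside the diagonal escape terms of the retained states. The
#' resulting reduced transition matrix has column sums <= 0, with strict
#' deficit exactly for states draining into the sink.
#'
#' @param rates a [build_rate_matrices()] result
#' @param sink,source disjoint, nonempty sets of minimum ids
#' @param p0 optional initial weights over `source` (normalized internally);
#'   default uniform
#' @return object of class `sink_reduction`: `Q_tilde`, `ids` (retained
#'   minimum ids), `p0` over the retained space, `sink`
#' @export
reduce_to_sink <- function(rates, sink, source, p0 = NULL) {
  stopifnot(inherits(rates, "rate_matrices"))
  ids <- rates$ids
  sink <- as.integer(sink); source <- as.integer(source)
  if (length(sink) == 0 || length(source) == 0)
    stop("sink and source must be nonempty")
  if (length(intersect(sink, source)) > 0)
    stop("sink and source must be disjoint")
  if (!all(c(sink, source) %in% ids))
    stop("sink/source ids not in the network")
  # reachability on the undirected rate graph
  g <- igraph::graph_from_adjacency_matrix(rates$K > 0, mode = "max")
  comp <- igraph::components(g)$membership
  sink_comps <- unique(comp[match(sink, ids)])
  bad <- source[!(comp[match(source, ids)] %in% sink_comps)]
  if (length(bad) > 0)
    stop("sink unreachable from source minima: ", paste(bad, collapse = ", "))
  keep <- !(ids %in% sink)
  Q_tilde <- rates$Q[keep, keep, drop = FALSE]
  rid <- ids[keep]
  p0v <- stats::setNames(numeric(length(rid)), as.character(rid))
  if (is.null(p0)) {
    p0v[as.character(source)] <- 1 / length(source)
  } else {
    stopifnot(length(p0) == length(source), all(p0 >= 0), sum(p0) > 0)
    p0v[as.character(source)] <- p0 / sum(p0)
  }
  structure(list(Q_tilde = Q_tilde, ids = rid, p0 = p0v, sink = sink),
            class = "sink_reduction")
}

# Detailed-balance weights for the retained space, recovered from the rate
# matrix itself by balancing log-ratios along a spanning tree. Returns NULL
# if the network is not reversible to within tolerance.
balance_weights <- function(Q) {
  n <- nrow(Q)
  lw <- rep(NA_real_, n)
  K <- Q; diag(K) <- 0
  for (root in seq_len(n)) {
    if (!is.na(lw[root])) next
    lw[root] <- 0
    queue <- root
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which((K[, j] > 0 | K[j, ] > 0) & is.na(lw))
      for (i in nb) {
        if (K[i, j] <= 0 || K[j, i] <= 0) return(NULL) # one-way edge
        lw[i] <- lw[j] + log(K[i, j]) - log(K[j, i])
        queue <- c(queue, i)
      }
    }
  }
  w <- exp(lw - max(lw))
  # verify balance on every edge (not just the tree)
  for (j in seq_len(n)) {
    i <- which(K[, j] > 0)
    if (length(i) == 0) next
    if (any(K[j, i] <= 0)) return(NULL)
    r <- abs(K[i, j] * w[j] - K[j, i] * w[i]) /
      pmax(K[i, j] * w[j], K[j, i] * w[i])
    if (any(r > 1e-8)) return(NULL)
  }
  w
}

#' Eigenmode decomposition of the reduced transition matrix
#'
#' Decomposes `Q_tilde` into eigenmodes `(lambda_l, x_l, y_l)` with
#' amplitudes `A_l = (1 . x_l)(y_l . p0)`. Detailed balance of the parent
#' network makes `Q_tilde` symmetrizable by the equilibrium-weighted
#' similarity transform, so the decomposition is performed with a symmetric
#' eigensolver (real spectrum, orthogonal modes, much better conditioning
#' than a general dense solve). Eigenvalues are sorted slowest first
#' (ascending `|lambda|`).
#'
#' @param reduction a [reduce_to_sink()] result
#' @return object of class `eigenmode_set`: `lambda` (negative reals),
#'   `X` (right eigenvectors, columns), `Y` (left eigenvectors, rows),
#'   `A` (amplitudes), `ids`, `p0`
#' @export
eigenmodes <- function(reduction) {
  stopifnot(inherits(reduction, "sink_reduction"))
  Q <- reduction$Q_tilde
  n <- nrow(Q)
  w <- balance_weights(Q)
  if (is.null(w))
    stop("reduced network is not reversible; cannot symmetrize")
  sw <- sqrt(w)
  S <- Q * outer(1 / sw, sw)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lambda <- es$values
  tol <- 1e-12 * max(abs(lambda))
  if (any(lambda > tol))
    stop("non-negative eigenvalue detected: the eigenproblem is too ",
         "ill-conditioned at this time-scale separation; reduce the network ",
         "with pgt_reduce() first")
  lambda <- pmin(lambda, 0)
  X <- es$vectors * sw        # right eigenvectors (columns)
  Y <- t(es$vectors / sw)     # left eigenvectors (rows)
  ord <- order(abs(lambda))
  lambda <- lambda[ord]; X <- X[, ord, drop = FALSE]; Y <- Y[ord, , drop = FALSE]
  A <- as.numeric(colSums(X) * (Y %*% reduction$p0))
  # clip round-off negatives; genuinely negative amplitudes are legitimate
  A[A < 0 & A > -1e-10] <- 0
  structure(list(lambda = lambda, X = X, Y = Y, A = A,
                 ids = reduction$ids, p0 = reduction$p0),
            class = "eigenmode_set")
}

#' First-passage-time distribution from eigenmodes
#'
#' `p(t) = sum_l A_l |lambda_l| exp(lambda_l t)`. Because rates are
#' exponentially sensitive to barriers the distribution is reported in
#' log-time, `y = ln t`, where `ptilde(y) = e^y p(e^y)` and each mode alone
#' peaks at `y* = -ln|lambda_l|` with height `A_l / e`. Both the analytic
#' per-mode peaks and the empirical local maxima of the summed `ptilde` on
#' the grid are reported.
#'
#' @param modes an [eigenmodes()] result
#' @param y_range optional `c(min, max)` for the `y = ln t` grid; extended
#'   with a warning if it does not cover every mode peak +- 5
#' @param n_grid grid points (default 2048, trapezoid quadrature)
#' @param amplitude_cutoff modes with `|A_l|` below this are dropped from the
#'   peak report (dominant-mode convention)
#' @return object of class `fpt_distribution`: `y`, `density` (ptilde),
#'   `mode_peaks` (data.frame: mode, lambda, A, y_star, height),
#'   `empirical_peaks` (data.frame: y, height), `modes`
#' @export
fpt_distribution <- function(modes, y_range = NULL, n_grid = 2048,
                             amplitude_cutoff = 0.01) {
  stopifnot(inherits(modes, "eigenmode_set"))
  lam <- modes$lambda; A <- modes$A
  y_star <- -log(abs(lam))
  lo <- min(y_star) - 5; hi <- max(y_star) + 5
  if (is.null(y_range)) {
    y_range <- c(lo, hi)
  } else if (y_range[1] > lo || y_range[2] < hi) {
    warning("y grid extended to cover all mode peaks +- 5 log-units")
    y_range <- c(min(y_range[1], lo), max(y_range[2], hi))
  }
  y <- seq(y_range[1], y_range[2], length.out = n_grid)
  # ptilde(y) = sum_l A_l |lam_l| exp(y - |lam_l| e^y)
  dens <- rep(0, n_grid)
  for (l in seq_along(lam)) {
    dens <- dens + A[l] * abs(lam[l]) * exp(y - abs(lam[l]) * exp(y))
  }
  keep <- abs(A) >= amplitude_cutoff
  mode_peaks <- data.frame(mode = which(keep), lambda = lam[keep],
                           A = A[keep], y_star = y_star[keep],
                           height = A[keep] / exp(1))
  imax <- which(diff(sign(diff(dens))) == -2) + 1
  empirical_peaks <- data.frame(y = y[imax], height = dens[imax])
  structure(list(y = y, density = dens, mode_peaks = mode_peaks,
                 empirical_peaks = empirical_peaks, modes = modes),
            class = "fpt_distribution")
}

#' Mean first passage time
#'
#' Computed by the direct linear solve `t(Q_tilde) tau = -1`, `MFPT =
#' tau . p0` — no eigendecomposition involved, so this is the standard
#' independent cross-check for the eigenmode route
#' ([mfpt_from_modes()], `sum_l A_l / |lambda_l|`).
#'
#' @param reduction a [reduce_to_sink()] result
#' @return scalar mean first passage time (reduced time units)
#' @export
mfpt <- function(reduction) {
  stopifnot(inherits(reduction, "sink_reduction"))
  tau <- tryCatch(solve(t(reduction$Q_tilde), rep(-1, nrow(reduction$Q_tilde))),
                  error = function(e) stop("singular reduced matrix: sink unreachable"))
  as.numeric(tau %*% reduction$p0)
}

#' @rdname mfpt
#' @param modes an [eigenmodes()] result
#' @export
mfpt_from_modes <- function(modes) {
  stopifnot(inherits(modes, "eigenmode_set"))
  sum(modes$A / abs(modes$lambda))
}

#' Attribute an eigenmode to minima
#'
#' The relative contribution of each retained state to an eigenmode's
#' time scale is measured by the magnitudes of its right-eigenvector
#' components, normalized to sum to 1. This is what colours minima by the
#' FPT peak they belong to.
#'
#' @param modes an [eigenmodes()] result
#' @param mode_id index into the sorted modes (1 = slowest)
#' @param top_k how many states to return
#' @return data.frame (`id`, `weight`) sorted by decreasing weight
#' @export
mode_attribution <- function(modes, mode_id = 1, top_k = 10) {
  stopifnot(inherits(modes, "eigenmode_set"),
            mode_id >= 1, mode_id <= length(modes$lambda))
  w <- abs(modes$X[, mode_id])
  w <- w / sum(w)
  ord <- order(-w)
  utils::head(data.frame(id = modes$ids[ord], weight = w[ord]), top_k)
}
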