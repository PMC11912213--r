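#' Branching-probability representation of a rate network
#'
#' Graph transformation works on branching probabilities
#' `P[i, j] = K[i, j] / D[j, j]` and mean waiting times `tau_j = 1 / D[j, j]`
#' rather than on the rate matrix directly: every quantity stays in `[0, 1]`
#' or positive, which is what makes state elimination numerically stable.
#' Escape to the sink is kept implicitly as the column-sum deficit of `P`.
#'
#' @param rates a [build_rate_matrices()] result
#' @param sink minimum ids treated as an external absorber (may be empty for
#'   a closed network, in which case columns sum to exactly 1)
#' @return object of class `branching_rep`: `P` (with accumulated self-loop
#'   probabilities on the diagonal, 0 initially), `tau`, `ids`, `sink`
#' @export
to_branching <- function(rates, sink = integer()) {
  stopifnot(inherits(rates, "rate_matrices"))
  ids <- rates$ids
  sink <- as.integer(sink)
  keep <- !(ids %in% sink)
  D <- diag(rates$D)[keep]
  if (any(D <= 0))
    stop("state(s) with zero escape rate (isolated): ",
         paste(ids[keep][D <= 0], collapse = ", "))
  K <- rates$K[keep, keep, drop = FALSE]
  P <- unname(sweep(K, 2, D, "/"))
  structure(list(P = P, tau = unname(1 / D), ids = ids[keep], sink = sink),
            class = "branching_rep")
}

#' Convert a branching representation back to rate matrices
#'
#' Inverse of [to_branching()]: accumulated self-loop probability is
#' renormalized away (`P -> P/(1 - P[j,j])`, `tau -> tau/(1 - P[j,j])`) and
#' rates recovered as `K[i, j] = P[i, j] / tau_j`. The diagonal escape matrix
#' `D[j, j] = 1/tau_j` retains any direct sink escape, so `Q = K - D` is the
#' reduced absorbing-sink transition matrix.
#'
#' @param rep a `branching_rep`
#' @return a `rate_matrices` object on the retained states (with the sink
#'   folded into the escape diagonal; field `sink` carries the sink ids)
#' @export
to_rates <- function(rep) {
  stopifnot(inherits(rep, "branching_rep"))
  keep_self <- 1 - diag(rep$P)
  if (any(keep_self < 1e-14))
    stop("numerically trapped state(s) after elimination")
  P <- sweep(rep$P, 2, keep_self, "/")
  diag(P) <- 0
  tau <- rep$tau / keep_self
  K <- sweep(P, 2, tau, "/")
  D <- diag(1 / tau, nrow(K))
  dimnames(K) <- list(as.character(rep$ids), as.character(rep$ids))
  dimnames(D) <- dimnames(K)
  structure(list(K = K, D = D, Q = K - D, ids = rep$ids, model = NULL,
                 sink = rep$sink),
            class = "rate_matrices")
}

#' Eliminate one state by graph transformation
#'
#' Exact removal of state `x`: for all remaining states,
#' `P[i, j] <- P[i, j] + P[i, x] P[x, j] / (1 - P[x, x])` and
#' `tau_j <- tau_j + P[x, j] tau_x / (1 - P[x, x])`. First-passage statistics
#' between the remaining states (and to the sink) are preserved exactly.
#'
#' @param rep a `branching_rep`
#' @param x minimum id to eliminate
#' @return the reduced `branching_rep`
#' @export
eliminate_state <- function(rep, x) {
  stopifnot(inherits(rep, "branching_rep"))
  k <- match(x, rep$ids)
  if (is.na(k)) stop("state ", x, " not in the representation")
  denom <- 1 - rep$P[k, k]
  if (denom < 1e-14)
    stop("state ", x, " is numerically trapped (1 - P[x,x] < 1e-14); ",
         "change the elimination order")
  out <- rep$P[k, -k]   # P[x, j]
  into <- rep$P[-k, k]  # P[i, x]
  P <- rep$P[-k, -k, drop = FALSE] + outer(into, out) / denom
  tau <- rep$tau[-k] + out * rep$tau[k] / denom
  structure(list(P = P, tau = tau, ids = rep$ids[-k], sink = rep$sink),
            class = "branching_rep")
}

#' Partial graph transformation of a rate network
#'
#' Eliminates every state outside `retain` (the sink is external throughout),
#' preserving mean first-passage statistics between the retained states and
#' the sink exactly. Used to retain only the states at the bottom of
#' competing funnels before eigendecomposition: the reduction improves the
#' condition number so that slow, rate-determining eigenmodes that are lost
#' in double precision on the full network become computable.
#'
#' @param rates a [build_rate_matrices()] result
#' @param retain minimum ids to keep (nonempty, disjoint from `sink`)
#' @param sink minimum ids treated as the absorber
#' @param order elimination order: `"min-degree"` (default; fewest current
#'   connections first, recomputed after each elimination) or a vector of
#'   minimum ids
#' @return a reduced `rate_matrices` object on `retain` (sink escape in the
#'   diagonal)
#' @export
pgt_reduce <- function(rates, retain, sink, order = "min-degree") {
  stopifnot(inherits(rates, "rate_matrices"))
  retain <- as.integer(retain); sink <- as.integer(sink)
  if (length(retain) == 0) stop("retain must be nonempty")
  if (length(intersect(retain, sink)) > 0) stop("retain and sink must be disjoint")
  rep <- to_branching(rates, sink)
  if (!all(retain %in% rep$ids)) stop("retain ids not in the network")
  eliminate <- setdiff(rep$ids, retain)
  if (is.numeric(order)) {
    ord <- as.integer(order)
    if (!setequal(ord, eliminate)) stop("explicit order must cover exactly the eliminated states")
    for (x in ord) rep <- eliminate_state(rep, x)
  } else {
    while (length(rep$ids) > length(retain)) {
      cand <- which(!(rep$ids %in% retain))
      deg <- vapply(cand, function(k) {
        sum(rep$P[-k, k] > 0) + sum(rep$P[k, -k] > 0)
      }, 1L)
      x <- rep$ids[cand[which.min(deg)]]
      rep <- eliminate_state(rep, x)
    }
  }
  to_rates(rep)
}

#' Sink reduction of a pGT-reduced network
#'
#' A [pgt_reduce()] result already has the sink folded into its escape
#' diagonal, so its `Q` is directly the reduced absorbing transition matrix;
#' this wraps it as a `sink_reduction` for [eigenmodes()] / [mfpt()].
#'
#' @param reduced a `rate_matrices` from [pgt_reduce()]
#' @param source minimum ids (must be retained)
#' @param p0 optional weights over `source`
#' @return a `sink_reduction`
#' @export
as_sink_reduction <- function(reduced, source, p0 = NULL) {
  stopifnot(inherits(reduced, "rate_matrices"))
  source <- as.integer(source)
  if (!all(source %in% reduced$ids))
    stop("source ids not retained in the reduced network")
  p0v <- stats::setNames(numeric(length(reduced$ids)), as.character(reduced$ids))
  if (is.null(p0)) {
    p0v[as.character(source)] <- 1 / length(source)
  } else {
    stopifnot(length(p0) == length(source), all(p0 >= 0), sum(p0) > 0)
    p0v[as.character(source)] <- p0 / sum(p0)
  }
  structure(list(Q_tilde = reduced$Q, ids = reduced$ids, p0 = p0v,
                 sink = reduced$sink),
            class = "sink_reduction")
}
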