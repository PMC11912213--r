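#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' Harmonic transition-state-theory rate model
#'
#' Under the uniform-frequency approximation every minimum and transition
#' state is assigned the same average frequency factor `nu_av`, so the
#' harmonic TST prefactor collapses to `nu_av` and all times are naturally
#' reported in reduced units of `1/nu_av` (the default `nu_av = 1`).
#' `kappa`, the count of vibrational degrees of freedom, cancels under the
#' approximation and is carried for documentation only.
#'
#' @param temperature kelvin (> 0); default 300
#' @param nu_av average frequency factor, 1/time; defines the time unit
#' @param k_B Boltzmann constant, kcal/(mol K)
#' @param kappa vibrational degrees of freedom (informational)
#' @return object of class `rate_model`
#' @export
rate_model <- function(temperature = 300, nu_av = 1, k_B = KB_KCAL,
                       kappa = NULL) {
  stopifnot(temperature > 0, nu_av > 0, k_B > 0)
  structure(list(temperature = temperature, nu_av = nu_av, k_B = k_B,
                 kappa = kappa, beta = 1 / (k_B * temperature)),
            class = "rate_model")
}

#' Harmonic TST rate over a single barrier
#'
#' Rate for escape from a minimum at potential energy `V_min` over a
#' transition state at `V_ts`: `nu_av * exp(-(V_ts - V_min)/(k_B T))`.
#' Barriers so large that the rate underflows double precision are floored
#' to 0 with a warning.
#'
#' @param V_ts,V_min energies, kcal/mol; `V_ts >= V_min`
#' @param model a [rate_model()]
#' @return rate in units of `nu_av`
#' @export
harmonic_rate <- function(V_ts, V_min, model = rate_model()) {
  barrier <- V_ts - V_min
  if (any(barrier < 0))
    stop("negative barrier: transition state below minimum (validate the KTN first)")
  logk <- log(model$nu_av) - barrier * model$beta
  k <- exp(logk)
  if (any(k == 0 & is.finite(logk))) {
    warning("rate(s) below double-precision range floored to 0")
  }
  k
}

#' Assemble master-equation matrices for a KTN
#'
#' Builds the rate matrix `K` with the column convention
#' `K[i, j] = rate from minimum j to minimum i` (so the master equation is
#' `dP/dt = Q P` with `Q = K - D`), the diagonal escape-rate matrix
#' `D[j, j] = sum_i K[i, j]`, and `Q`. Parallel transition states between the
#' same pair contribute additively. Because each edge's forward and backward
#' rates share the same transition-state energy, detailed balance
#' `K[i,j] pi_j = K[j,i] pi_i` holds exactly, which makes `Q` symmetrizable
#' with a real spectrum.
#'
#' @param x a [ktn()] object (should be a single connected component for
#'   kinetics; a warning is issued otherwise)
#' @param model a [rate_model()]
#' @return object of class `rate_matrices`: list with `K`, `D`, `Q`,
#'   `ids` (minimum id per matrix row/column) and `model`
#' @export
build_rate_matrices <- function(x, model = rate_model()) {
  stopifnot(inherits(x, "ktn"))
  n <- nrow(x$minima)
  if (n == 0) stop("empty network")
  ids <- x$minima$id
  K <- matrix(0, n, n, dimnames = list(as.character(ids), as.character(ids)))
  if (nrow(x$ts) > 0) {
    ia <- match(x$ts$min1, ids)
    ib <- match(x$ts$min2, ids)
    ka <- harmonic_rate(x$ts$energy, x$minima$energy[ia], model) # a -> b
    kb <- harmonic_rate(x$ts$energy, x$minima$energy[ib], model) # b -> a
    for (r in seq_along(ia)) {
      K[ib[r], ia[r]] <- K[ib[r], ia[r]] + ka[r]
      K[ia[r], ib[r]] <- K[ia[r], ib[r]] + kb[r]
    }
  }
  if (length(connected_components(x)) > 1)
    warning("KTN has more than one connected component; kinetics assume one")
  D <- diag(colSums(K), n)
  dimnames(D) <- dimnames(K)
  Q <- K - D
  structure(list(K = K, D = D, Q = Q, ids = ids, model = model),
            class = "rate_matrices")
}

#' Boltzmann equilibrium distribution over minima
#'
#' `pi_j` proportional to `exp(-E_j / k_B T)` under the harmonic
#' uniform-frequency approximation (point-group degeneracies ignored by
#' default, matching the uniform-frequency rate estimate; set
#' `use_degeneracy = TRUE` to weight by them). The minimum energy is
#' subtracted before exponentiation to avoid overflow.
#'
#' @param x a [ktn()] object
#' @param model a [rate_model()]
#' @param use_degeneracy weight states by their point-group order
#' @return named probability vector over minimum ids, summing to 1
#' @export
equilibrium_distribution <- function(x, model = rate_model(),
                                     use_degeneracy = FALSE) {
  stopifnot(inherits(x, "ktn"))
  e <- x$minima$energy
  w <- exp(-(e - min(e)) * model$beta)
  if (use_degeneracy) w <- w * x$minima$degeneracy
  stats::setNames(w / sum(w), as.character(x$minima$id))
}
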