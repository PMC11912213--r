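#' Construct a kinetic transition network
#'
#' A kinetic transition network (KTN) is the graph of local minima of a
#' potential energy landscape (nodes) and the transition states connecting
#' them (edges). Energies are in kcal/mol throughout. Parallel transition
#' states between the same pair of minima are kept as separate records;
#' thermodynamics and kinetics are computed from this object downstream.
#'
#' @param minima data.frame with columns `id`, `energy`, and optionally
#'   `log_freq_product` (log of the normal-mode frequency product; unused
#'   under the uniform-frequency approximation) and `degeneracy` (point-group
#'   order, default 1).
#' @param transition_states data.frame with columns `id`, `energy`, `min1`,
#'   `min2`. May have zero rows (a network with no kinetics).
#' @return An object of class `ktn`: list with `minima`, `ts` and `adjacency`
#'   (per-minimum integer vector of incident transition-state ids).
#' @export
ktn <- function(minima, transition_states) {
  minima <- as.data.frame(minima)
  transition_states <- as.data.frame(transition_states)
  stopifnot(all(c("id", "energy") %in% names(minima)))
  if (anyDuplicated(minima$id)) stop("minimum ids must be unique")
  if (!all(is.finite(minima$energy))) stop("minimum energies must be finite")
  if (is.null(minima$log_freq_product))
    minima$log_freq_product <- rep(0, nrow(minima))
  if (is.null(minima$degeneracy)) minima$degeneracy <- rep(1L, nrow(minima))
  if (nrow(transition_states) > 0) {
    stopifnot(all(c("id", "energy", "min1", "min2") %in% names(transition_states)))
  } else {
    transition_states <- data.frame(id = integer(), energy = numeric(),
                                    min1 = integer(), min2 = integer())
  }
  adjacency <- build_adjacency(minima$id, transition_states)
  structure(list(minima = minima, ts = transition_states, adjacency = adjacency),
            class = "ktn")
}

build_adjacency <- function(min_ids, ts) {
  adj <- stats::setNames(vector("list", length(min_ids)), as.character(min_ids))
  for (k in seq_along(adj)) adj[[k]] <- integer()
  if (nrow(ts) > 0) {
    for (r in seq_len(nrow(ts))) {
      a <- as.character(ts$min1[r]); b <- as.character(ts$min2[r])
      adj[[a]] <- c(adj[[a]], ts$id[r])
      if (b != a) adj[[b]] <- c(adj[[b]], ts$id[r])
    }
  }
  adj
}

#' @export
print.ktn <- function(x, ...) {
  cat(sprintf("Kinetic transition network: %d minima, %d transition states\n",
              nrow(x$minima), nrow(x$ts)))
  cat(sprintf("  energy range [%.4f, %.4f] kcal/mol\n",
              min(x$minima$energy), max(x$minima$energy)))
  invisible(x)
}

parse_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(NULL)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  list(fields = fields, line_no = keep)
}

num_field <- function(s, line_no, what) {
  # tolerate U+2212 minus from copy-pasted tables
  v <- suppressWarnings(as.numeric(gsub("−", "-", s)))
  if (any(is.na(v)))
    stop(sprintf("malformed %s field on line %d", what, line_no))
  v
}

#' Read a min.data-style minima database
#'
#' Plain-text file, one local minimum per line, whitespace-separated with the
#' potential energy (kcal/mol) first; optional second field is the log
#' frequency product and optional third the point-group order. Extra fields
#' are ignored. Minima are numbered 1..N in file order, matching the
#' convention that structures are labelled by the order of discovery in the
#' database.
#'
#' @param path file path
#' @return data.frame of minima (`id`, `energy`, `log_freq_product`,
#'   `degeneracy`)
#' @export
read_min_data <- function(path) {
  p <- parse_numeric_table(path)
  if (is.null(p)) stop("empty minima file: ", path)
  n <- length(p$fields)
  energy <- numeric(n); lfp <- numeric(n); deg <- rep(1L, n)
  for (k in seq_len(n)) {
    f <- p$fields[[k]]
    energy[k] <- num_field(f[1], p$line_no[k], "energy")
    if (length(f) >= 2) lfp[k] <- num_field(f[2], p$line_no[k], "frequency")
    if (length(f) >= 3) {
      d <- num_field(f[3], p$line_no[k], "degeneracy")
      if (d >= 1) deg[k] <- as.integer(d)
    }
  }
  data.frame(id = seq_len(n), energy = energy, log_freq_product = lfp,
             degeneracy = deg)
}

#' Read a ts.data-style transition-state database
#'
#' One transition state per line: energy, two metadata fields (log frequency
#' product and point-group order, ignored here), then the ids of the two
#' minima it connects; trailing fields are ignored. Three- or four-field
#' lines are read with the metadata fields dropped from the right, so
#' "energy min1 min2" also parses.
#'
#' @param path file path
#' @return data.frame of transition states (`id`, `energy`, `min1`, `min2`);
#'   zero rows for an empty file (a network with no kinetics is valid)
#' @export
read_ts_data <- function(path) {
  p <- parse_numeric_table(path)
  if (is.null(p))
    return(data.frame(id = integer(), energy = numeric(),
                      min1 = integer(), min2 = integer()))
  n <- length(p$fields)
  energy <- numeric(n); m1 <- integer(n); m2 <- integer(n)
  for (k in seq_len(n)) {
    f <- p$fields[[k]]
    if (length(f) < 3)
      stop(sprintf("transition-state line %d has fewer than 3 fields",
                   p$line_no[k]))
    energy[k] <- num_field(f[1], p$line_no[k], "energy")
    # canonical layout: energy, two metadata fields, min1, min2 (trailing
    # fields ignored); reduced layouts drop metadata from the right
    i1 <- min(length(f) - 1L, 4L)
    m1[k] <- as.integer(num_field(f[i1], p$line_no[k], "min1"))
    m2[k] <- as.integer(num_field(f[i1 + 1L], p$line_no[k], "min2"))
    if (m1[k] <= 0 || m2[k] <= 0)
      stop(sprintf("transition state on line %d references a minimum id <= 0",
                   p$line_no[k]))
  }
  data.frame(id = seq_len(n), energy = energy, min1 = m1, min2 = m2)
}

#' Write minima / transition-state tables in the plain-text dialect
#'
#' Inverse of [read_min_data()] / [read_ts_data()]; energies are written with
#' enough digits to round-trip double precision.
#'
#' @param minima,transition_states tables as returned by the readers
#' @param path output file
#' @export
write_min_data <- function(minima, path) {
  writeLines(sprintf("%.17g %.17g %d", minima$energy, minima$log_freq_product,
                     minima$degeneracy), path)
  invisible(path)
}

#' @rdname write_min_data
#' @export
write_ts_data <- function(transition_states, path) {
  ts <- transition_states
  writeLines(sprintf("%.17g 0 1 %d %d", ts$energy, ts$min1, ts$min2), path)
  invisible(path)
}

#' Validate parsed stationary-point tables into a KTN
#'
#' Drops transition states whose endpoints are missing from the minima table
#' or identical (degenerate rearrangements, which carry no inter-minimum
#' kinetics). A transition state below the energy of either endpoint is
#' physically inconsistent: under `policy = "clamp"` (the default, the common
#' situation in coarse-grained databases) its energy is lifted to the higher
#' endpoint energy with a warning; under `policy = "strict"` it is an error.
#'
#' @param minima,transition_states parsed tables
#' @param policy `"clamp"` or `"strict"`
#' @return a validated [ktn()] object
#' @export
validate_ktn <- function(minima, transition_states, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  minima <- as.data.frame(minima)
  ts <- as.data.frame(transition_states)
  if (nrow(ts) > 0) {
    known <- minima$id
    missing_ep <- !(ts$min1 %in% known & ts$min2 %in% known)
    if (any(missing_ep)) {
      warning(sprintf("dropping %d transition state(s) with missing endpoints: %s",
                      sum(missing_ep),
                      paste(ts$id[missing_ep], collapse = ", ")))
      ts <- ts[!missing_ep, , drop = FALSE]
    }
    dgn <- ts$min1 == ts$min2
    if (any(dgn)) {
      warning(sprintf("dropping %d degenerate-rearrangement transition state(s)",
                      sum(dgn)))
      ts <- ts[!dgn, , drop = FALSE]
    }
    if (nrow(ts) > 0) {
      e1 <- minima$energy[match(ts$min1, minima$id)]
      e2 <- minima$energy[match(ts$min2, minima$id)]
      lift <- pmax(e1, e2)
      low <- ts$energy < lift
      if (any(low)) {
        if (policy == "strict")
          stop("transition state(s) below an endpoint energy: ",
               paste(ts$id[low], collapse = ", "))
        warning(sprintf("clamping %d transition-state energie(s) to the higher endpoint",
                        sum(low)))
        ts$energy[low] <- lift[low]
      }
    }
  }
  ktn(minima, ts)
}

#' Connected components of a KTN
#'
#' Minima belong to the same component iff they are linked by transition
#' states. Components are reported largest first, ties and member order by
#' lowest minimum id, so the result is invariant under permutation of the
#' transition-state records.
#'
#' @param x a [ktn()] object
#' @return list of integer vectors of minimum ids
#' @export
connected_components <- function(x) {
  stopifnot(inherits(x, "ktn"))
  ids <- x$minima$id
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(x$ts$min1), to = as.character(x$ts$min2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(ids)))
  mem <- igraph::components(g)$membership
  comp <- split(as.integer(names(mem)), mem)
  comp <- lapply(comp, sort)
  ord <- order(-vapply(comp, length, 1L), vapply(comp, min, 1L))
  unname(comp[ord])
}

#' Export / import a KTN as JSON
#'
#' @param x a [ktn()] object
#' @param path output path
#' @export
write_ktn_json <- function(x, path) {
  stopifnot(inherits(x, "ktn"))
  obj <- list(
    minima = x$minima[, c("id", "energy", "log_freq_product", "degeneracy")],
    ts = x$ts[, c("id", "energy", "min1", "min2")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ktn_json
#' @export
read_ktn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ktn(as.data.frame(obj$minima), as.data.frame(obj$ts))
}
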