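ts_filtered_graph <- function(x, ceiling) {
  ts <- x$ts[x$ts$energy <= ceiling, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = data.frame(from = as.character(ts$min1), to = as.character(ts$min2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(x$minima$id)))
}

#' Superbasin partition at an energy ceiling
#'
#' Two minima belong to the same superbasin iff they can interconvert through
#' transition states at or below the ceiling. Minima whose own energy exceeds
#' the ceiling are singleton blocks flagged inactive ("not yet born" at that
#' energy in a disconnectivity graph). Raising the ceiling only merges
#' blocks, never splits them.
#'
#' @param x a [ktn()] object
#' @param energy_ceiling kcal/mol
#' @return list with `blocks` (list of sorted minimum-id vectors, largest
#'   first then by lowest member) and `active` (logical per block: lowest
#'   member at or below the ceiling)
#' @export
superbasins <- function(x, energy_ceiling) {
  stopifnot(inherits(x, "ktn"))
  g <- ts_filtered_graph(x, energy_ceiling)
  mem <- igraph::components(g)$membership
  blocks <- lapply(split(as.integer(names(mem)), mem), sort)
  ord <- order(-vapply(blocks, length, 1L), vapply(blocks, min, 1L))
  blocks <- unname(blocks[ord])
  emin <- vapply(blocks, function(b)
    min(x$minima$energy[match(b, x$minima$id)]), 1.0)
  list(blocks = blocks, active = emin <= energy_ceiling)
}

#' Threshold funnel clustering
#'
#' Partitions the minima into funnels: sets of minima that can interconvert
#' without exceeding a threshold energy above the set's lowest member. The
#' definition is made unique by a greedy ascending sweep: seed at the
#' globally lowest unassigned minimum `m`, flood-fill the unassigned minima
#' reachable through transition states with energy `<= E(m) + threshold`,
#' close the cluster, repeat. Seeding in ascending energy order guarantees
#' each seed is provably its cluster's lowest member. Ties on equal energies
#' are broken by smaller id (database order).
#'
#' @param x a [ktn()] object
#' @param threshold kcal/mol above each cluster's lowest member
#' @return object of class `cluster_partition`: `threshold` and `clusters`,
#'   a list of lists (`members`, `seed`, `seed_energy`), in seeding order
#' @export
threshold_clusters <- function(x, threshold) {
  stopifnot(inherits(x, "ktn"), threshold >= 0)
  ids <- x$minima$id
  energy <- x$minima$energy
  ord <- order(energy, ids)
  assigned <- stats::setNames(rep(FALSE, length(ids)), as.character(ids))
  clusters <- list()
  for (k in ord) {
    seed <- ids[k]
    if (assigned[as.character(seed)]) next
    ceiling_e <- energy[k] + threshold
    # flood fill among unassigned minima via TSs at or below the ceiling
    members <- seed
    assigned[as.character(seed)] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- integer()
      for (m in frontier) {
        tsids <- x$adjacency[[as.character(m)]]
        if (length(tsids) == 0) next
        tsr <- x$ts[match(tsids, x$ts$id), , drop = FALSE]
        tsr <- tsr[tsr$energy <= ceiling_e, , drop = FALSE]
        if (nrow(tsr) == 0) next
        nb <- unique(ifelse(tsr$min1 == m, tsr$min2, tsr$min1))
        nb <- nb[!assigned[as.character(nb)]]
        if (length(nb) > 0) {
          assigned[as.character(nb)] <- TRUE
          nxt <- c(nxt, nb)
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
    }
    clusters[[length(clusters) + 1]] <-
      list(members = sort(members), seed = seed, seed_energy = energy[k])
  }
  structure(list(threshold = threshold, clusters = clusters),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Funnel clustering at threshold %.3f kcal/mol: %d cluster(s)\n",
              x$threshold, length(x$clusters)))
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 1L)
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster representatives ("selected minima")
#'
#' The lowest-energy member of each cluster (its seed by construction of the
#' greedy ascending sweep; ties broken by smaller id).
#'
#' @param partition a [threshold_clusters()] result
#' @return integer vector of minimum ids, one per cluster
#' @export
cluster_representatives <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  vapply(partition$clusters, function(cl) cl$seed, 1L)
}

#' Disconnectivity tree of a landscape
#'
#' Superbasin analysis on a ladder of energy levels: the highest level is
#' `global minimum energy + n_levels * delta_E` and levels descend in steps
#' of `delta_E`. Superbasins at each level are nested by inclusion into the
#' level above; each minimum hangs as a leaf (at its own energy) below its
#' block at the finest level.
#'
#' @param x a [ktn()] object
#' @param n_levels number of levels (>= 2)
#' @param delta_E level spacing, kcal/mol (> 0)
#' @return object of class `disconnectivity_tree`: `levels` (descending
#'   energies), `nodes` (data.frame: node, level, energy, parent, n_members,
#'   lowest_id, lowest_energy), `members` (list per node), `leaves`
#'   (data.frame: id, energy, node at finest level)
#' @export
disconnectivity_graph <- function(x, n_levels, delta_E) {
  stopifnot(inherits(x, "ktn"), n_levels >= 2, delta_E > 0)
  emin <- min(x$minima$energy)
  span <- max(c(x$minima$energy, x$ts$energy)) - emin
  if (delta_E > span)
    warning("delta_E exceeds the landscape energy span; tree is degenerate")
  levels <- emin + delta_E * seq(n_levels, 1)
  nodes <- data.frame(node = integer(), level = integer(), energy = numeric(),
                      parent = integer(), n_members = integer(),
                      lowest_id = integer(), lowest_energy = numeric())
  members <- list()
  prev <- list() # node index per minimum id at the level above
  nid <- 0L
  for (li in seq_along(levels)) {
    part <- superbasins(x, levels[li])
    for (b in part$blocks) {
      nid <- nid + 1L
      eb <- x$minima$energy[match(b, x$minima$id)]
      parent <- if (li == 1) NA_integer_ else prev[[as.character(b[1])]]
      nodes[nid, ] <- list(nid, li, levels[li], parent, length(b),
                           b[which.min(eb)], min(eb))
      members[[nid]] <- b
    }
    prev <- list()
    this_level <- which(nodes$level == li)
    for (k in this_level) for (m in members[[k]]) prev[[as.character(m)]] <- k
  }
  leaves <- data.frame(
    id = x$minima$id, energy = x$minima$energy,
    node = vapply(as.character(x$minima$id), function(m) prev[[m]], 1L))
  structure(list(levels = levels, nodes = nodes, members = members,
                 leaves = leaves),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat(sprintf("Disconnectivity tree: %d levels (%.3f .. %.3f kcal/mol), %d nodes, %d leaves\n",
              length(x$levels), max(x$levels), min(x$levels),
              nrow(x$nodes), nrow(x$leaves)))
  invisible(x)
}

#' Serialize a disconnectivity tree
#'
#' JSON (nodes with parent links and member counts) or a flat text dump
#' (level, node, parent, members) for external disconnectivity plotters.
#'
#' @param tree a [disconnectivity_graph()] result
#' @param path output file
#' @param format `"json"` or `"tree"`
#' @export
write_disconnectivity <- function(tree, path, format = c("json", "tree")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(levels = tree$levels, nodes = tree$nodes, leaves = tree$leaves)
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  } else {
    lines <- sprintf("%d %d %s %s", tree$nodes$level, tree$nodes$node,
                     ifelse(is.na(tree$nodes$parent), "-",
                            as.character(tree$nodes$parent)),
                     vapply(tree$members, paste, "", collapse = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Energies relative to a reference minimum
#'
#' `Delta E_j = E_j - E_reference`, as used to report funnel bottoms relative
#' to an experimental starting structure.
#'
#' @param x a [ktn()] object
#' @param reference_id minimum id of the reference
#' @param ids minima to report (default all)
#' @return data.frame (`id`, `energy`, `delta_E`)
#' @export
relative_energies <- function(x, reference_id, ids = NULL) {
  stopifnot(inherits(x, "ktn"))
  ref <- match(reference_id, x$minima$id)
  if (is.na(ref)) stop("reference minimum ", reference_id, " not in the network")
  if (is.null(ids)) ids <- x$minima$id
  k <- match(ids, x$minima$id)
  if (anyNA(k)) stop("unknown minimum id(s): ", paste(ids[is.na(k)], collapse = ", "))
  data.frame(id = ids, energy = x$minima$energy[k],
             delta_E = x$minima$energy[k] - x$minima$energy[ref])
}
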