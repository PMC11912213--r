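# Bondi-type van der Waals radii (angstroms)
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Deterministic quasi-uniform sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default water, 1.4 angstroms) over the structure:
#' for each atom, quasi-uniform points on its probe-inflated sphere are
#' tested for burial inside any neighbour's inflated sphere, and the exposed
#' fraction times the sphere area gives the atom's SASA. Residue totals are
#' summed and partitioned into hydrophobic and polar classes (see
#' [residue_classification()]); polar + hydrophobic equals the total exactly.
#'
#' @param s a [pstructure()]
#' @param probe probe radius, angstroms
#' @param n_sphere_points quadrature points per atom (default 960,
#'   FreeSASA-comparable accuracy)
#' @param default_radius fallback van der Waals radius for unknown elements;
#'   `NULL` (default) makes unknown elements an error
#' @return list: `atom` (per-atom areas), `residue` (data.frame resno, resid,
#'   area, class), `total`, `polar`, `hydrophobic` (square angstroms)
#' @export
sasa <- function(s, probe = 1.4, n_sphere_points = 960, default_radius = NULL) {
  stopifnot(inherits(s, "pstructure"))
  el <- s$atoms$element
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("unknown element(s): ", paste(unique(el[is.na(r)]), collapse = ", "),
           " (set default_radius to proceed)")
    r[is.na(r)] <- default_radius
  }
  ri <- unname(r) + probe
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  area <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (ri[i] + ri)^2 & seq_len(n) != i)
    p <- sweep(pts * ri[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[exposed, 1] - xyz[j, 1])^2 + (p[exposed, 2] - xyz[j, 2])^2 +
        (p[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj2 > ri[j]^2
    }
    area[i] <- 4 * pi * ri[i]^2 * mean(exposed)
  }
  res <- s$atoms[!duplicated(s$atoms$resno), c("resno", "resid")]
  res <- res[order(res$resno), ]
  res$area <- vapply(res$resno, function(rr) sum(area[s$atoms$resno == rr]), 1.0)
  cls <- residue_classification()
  res$class <- ifelse(AA1[res$resid] %in% cls$hydrophobic, "hydrophobic", "polar")
  polar <- sum(res$area[res$class == "polar"])
  hydrophobic <- sum(res$area[res$class == "hydrophobic"])
  list(atom = area, residue = res, total = polar + hydrophobic,
       polar = polar, hydrophobic = hydrophobic)
}
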