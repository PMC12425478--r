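# Solvent-accessible surface area by Shrake-Rupley quadrature.

# deterministic, approximately uniform unit-sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure: each atom is surfaced with a
#' deterministic quasi-uniform point set at radius r_vdw + probe, and the
#' fraction of points not buried inside any neighbouring atom's expanded
#' sphere gives its exposed area.
#'
#' @param s a `nitro_structure`
#' @param probe probe radius in Angstrom (water: 1.4)
#' @param n_points quadrature points per atom
#' @param radii named vector of van der Waals radii by element symbol;
#'   elements absent from the table raise an error
#' @return list: `atom_area` (per-atom, Angstrom^2, in atom-table order),
#'   `residue_area` (named by residue key), `total`
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = VDW_RADII) {
  a <- s$atoms
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown))
    stopf("no van der Waals radius for element(s): %s",
          paste(unknown, collapse = ", "))
  r <- unname(radii[a$element]) + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbour search via cell-free cutoff (structures here are small)
  maxr <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < r[i] + r[nb]]
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- rowSums(sweep(p[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- dj > r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  keys <- residue_key(a$chain, a$resno, a$insert)
  list(atom_area = areas,
       residue_area = tapply(areas, factor(keys, levels = unique(keys)), sum),
       total = sum(areas))
}

#' Relative per-residue SASA (fraction of the residue's theoretical maximum)
#'
#' @param s a `nitro_structure`
#' @param sasa_result optional precomputed [sasa()] output
#' @param max_table named vector of per-residue maximum areas (one-letter
#'   codes); defaults to the shipped theoretical table
#' @param ... passed to [sasa()]
#' @return named numeric vector, residue key -> relative SASA
#' @export
relative_sasa <- function(s, sasa_result = NULL, max_table = MAX_SASA, ...) {
  if (is.null(sasa_result)) sasa_result <- sasa(s, ...)
  rt <- residue_table(s)
  ra <- sasa_result$residue_area[rt$key]
  mx <- max_table[rt$aa]
  mx[is.na(mx)] <- mean(max_table)  # non-standard residues: generic cap
  stats::setNames(as.numeric(ra) / as.numeric(mx), rt$key)
}
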