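# Rigid-body superposition (Kabsch) and RMSD-family metrics.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation mapping `query`
#' onto `ref` with minimal root-mean-square deviation. Reflections are
#' corrected by flipping the sign of the smallest singular direction.
#'
#' @param coords_ref n x 3 matrix, Angstrom
#' @param coords_query n x 3 matrix, same row order
#' @return list: `rotation` (3 x 3, orthonormal, det +1), `translation`
#'   (length-3), `rmsd` (Angstrom), `n_atoms`. The fitted query is
#'   `coords_query %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(coords_ref, coords_query) {
  P <- as.matrix(coords_ref); Q <- as.matrix(coords_query)
  if (!all(dim(P) == dim(Q))) stopf("coordinate sets differ in shape")
  n <- nrow(P)
  if (n < 3) stopf("superposition needs at least 3 atoms")
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stopf("non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (sum(svd(Pc)$d > 1e-8) < 2 || sum(svd(Qc)$d > 1e-8) < 2)
    stopf("degenerate (collinear or coincident) configuration")
  H <- crossprod(Qc, Pc)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - fitted)^2)))
  list(rotation = R, translation = as.numeric(cp - R %*% cq),
       rmsd = rmsd, n_atoms = n)
}

# apply a superposition to row-coordinates
apply_superposition <- function(coords, sp)
  sweep(as.matrix(coords) %*% t(sp$rotation), 2, sp$translation, "+")

#' Root-mean-square deviation of two aligned structures
#'
#' Coordinates of the aligned residues (Cα by default, or all atoms shared
#' by name within each aligned residue pair) are superposed by
#' [kabsch_superpose()] and the RMSD
#' \deqn{RMSD = \sqrt{\frac{1}{N}\sum_i^N (x_i^{ref} - x_i)^2}}
#' is returned. Aligned residues for which the selection is empty are
#' dropped with a warning.
#'
#' With `refine = TRUE` the sequence-guided correspondence is additionally
#' restricted to its structurally consistent core by iterative
#' superposition (superpose, keep pairs closer than `cutoff`, re-superpose,
#' up to `max_iter` rounds), emulating how structural aligners report RMSD
#' over the aligned core rather than over every sequence-aligned residue.
#'
#' @param ref,query `nitro_structure` objects
#' @param ap an aligned pair from [sequence_correspondence()]
#' @param atoms "ca" (default) or "all"
#' @param refine restrict to the structurally consistent core (default
#'   FALSE: all aligned residues enter the superposition)
#' @param cutoff,max_iter refinement distance cutoff (Angstrom) and
#'   iteration limit
#' @return RMSD in Angstrom
#' @export
rmsd <- function(ref, query, ap, atoms = c("ca", "all"), refine = FALSE,
                 cutoff = 8, max_iter = 10) {
  .rmsd_core(ref, query, ap, atoms = match.arg(atoms), refine = refine,
             cutoff = cutoff, max_iter = max_iter)$rmsd
}

.rmsd_core <- function(ref, query, ap, atoms = "ca", refine = FALSE,
                       cutoff = 8, max_iter = 10) {
  co <- aligned_coords(ref, query, ap, atoms = atoms)
  sp <- kabsch_superpose(co$ref, co$query)
  if (!refine) return(list(rmsd = sp$rmsd, n = sp$n_atoms))
  keep <- rep(TRUE, nrow(co$ref))
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums((co$ref - apply_superposition(co$query, sp))^2))
    new_keep <- d < cutoff
    if (sum(new_keep) < 3 || all(new_keep == keep)) break
    keep <- new_keep
    sp <- kabsch_superpose(co$ref[keep, , drop = FALSE],
                           co$query[keep, , drop = FALSE])
  }
  list(rmsd = sp$rmsd, n = sp$n_atoms)
}

#' Length-normalized RMSD (RMSD100)
#'
#' \deqn{RMSD_{100} = RMSD \cdot \frac{1}{1 + \ln\sqrt{L/100}}}
#' corrects the dependence of RMSD on structural-alignment length; it
#' equals RMSD at L = 100.
#'
#' @param rmsd_value RMSD in Angstrom
#' @param L aligned length (residues)
#' @return normalized RMSD in Angstrom
#' @export
rmsd100 <- function(rmsd_value, L) {
  denom <- 1 + log(sqrt(L / 100))
  if (denom <= 0)
    stopf("RMSD100 undefined: 1 + ln sqrt(L/100) = %.3f <= 0 at L = %d",
          denom, L)
  rmsd_value / denom
}

#' Per-residue Cα-Cα deviation after global superposition
#'
#' @param ref,query `nitro_structure` objects
#' @param ap aligned pair
#' @return named numeric vector, reference residue key -> distance (Angstrom)
#' @export
per_residue_deviation <- function(ref, query, ap) {
  co <- aligned_coords(ref, query, ap, atoms = "ca")
  sp <- kabsch_superpose(co$ref, co$query)
  fitted <- apply_superposition(co$query, sp)
  d <- sqrt(rowSums((co$ref - fitted)^2))
  stats::setNames(d, rownames(co$ref))
}

#' Local RMSD around a structural site (e.g. an active site)
#'
#' Selects the aligned residues whose reference Cα lies within `radius` of
#' any listed site residue Cα, superposes locally on that selection only,
#' and returns the Cα RMSD.
#'
#' @param ref,query `nitro_structure` objects
#' @param ap aligned pair
#' @param site_residues reference residue keys ("chain|resno|insert")
#'   defining the site
#' @param radius inclusion radius in Angstrom
#' @return local Cα RMSD in Angstrom
#' @export
local_site_rmsd <- function(ref, query, ap, site_residues, radius = 8) {
  rc <- ca_coords(ref)
  missing_site <- setdiff(site_residues, rownames(rc))
  if (length(missing_site))
    stopf("site residue(s) not in reference: %s",
          paste(missing_site, collapse = ", "))
  co <- aligned_coords(ref, query, ap, atoms = "ca")
  site_xyz <- rc[site_residues, , drop = FALSE]
  near <- vapply(seq_len(nrow(co$ref)), function(i)
    min(sqrt(rowSums(sweep(site_xyz, 2, co$ref[i, ])^2))) <= radius,
    logical(1))
  if (sum(near) < 3) stopf("fewer than 3 aligned residues within the site")
  kabsch_superpose(co$ref[near, , drop = FALSE],
                   co$query[near, , drop = FALSE])$rmsd
}
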